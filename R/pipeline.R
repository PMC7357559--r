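# Pipeline orchestration: one configuration object, staged execution
# (homology -> hairpin -> quantification -> genomic characterisation),
# summary tables shaped like the study's report tables, and a run manifest.

#' Build and validate a pipeline configuration
#'
#' Inputs may be file paths or in-memory objects (data.frames from the
#' reader functions; FASTQ entries may be per-sample read data.frames).
#' Thresholds default to the annotation criteria: full-length identity
#' > 93 %, at most 1 seed / 2 non-seed mismatches per mature arm, hairpin
#' MFE of at most -15 kcal/mol folded with 10-nt flanks, internal bulges
#' strictly below 6 nt, 10-kb same-strand clusters, and an expression call
#' of >= 10 reads over >= 3 individuals.
#'
#' @param genome,annotations,reference inputs (paths or objects).
#' @param fastqs named character vector of FASTQ paths or named list of
#'   read data.frames; NULL runs annotation without expression.
#' @param adapter 3' adapter used for QC.
#' @param out_dir optional output directory for report tables.
#' @param identity,seed_mm,nonseed_mm,mfe,bulge,flank,cluster_gap,min_reads,min_individuals
#'   thresholds as above.
#' @param scan_k,scan_floor homology seeding parameters.
#' @return validated config list of class "mirhom_config".
#' @export
pipeline_config <- function(genome, annotations, reference, fastqs = NULL,
                            adapter = "TGGAATTCTCGGGTGCCAAGG", out_dir = NULL,
                            identity = 93, seed_mm = 1L, nonseed_mm = 2L,
                            mfe = -15, bulge = 6L, flank = 10L,
                            cluster_gap = 10000L, min_reads = 10L,
                            min_individuals = 3L, scan_k = 12L,
                            scan_floor = 85) {
  num_ok <- function(x) length(x) == 1L && is.finite(x)
  if (!num_ok(identity) || identity <= 0 || identity > 100)
    .stopf("identity threshold must be in (0, 100]")
  if (!num_ok(mfe) || mfe >= 0) .stopf("MFE threshold must be negative and finite")
  for (v in c(seed_mm, nonseed_mm, bulge, flank, cluster_gap, min_reads,
              min_individuals, scan_k))
    if (!num_ok(v) || v < 0) .stopf("thresholds must be finite and non-negative")
  if (!num_ok(scan_floor) || scan_floor > identity)
    .stopf("scan floor must not exceed the identity threshold")
  for (inp in list(genome, annotations, reference)) {
    if (is.character(inp) && length(inp) == 1L && !file.exists(inp))
      .stopf("missing input path: %s", inp)
  }
  if (is.character(fastqs)) {
    miss <- fastqs[!file.exists(fastqs)]
    if (length(miss) > 0L) .stopf("missing FASTQ path(s): %s", paste(miss, collapse = ", "))
  }
  structure(list(genome = genome, annotations = annotations,
                 reference = reference, fastqs = fastqs, adapter = adapter,
                 out_dir = out_dir, identity = identity, seed_mm = seed_mm,
                 nonseed_mm = nonseed_mm, mfe = mfe, bulge = bulge,
                 flank = flank, cluster_gap = cluster_gap,
                 min_reads = min_reads, min_individuals = min_individuals,
                 scan_k = scan_k, scan_floor = scan_floor),
            class = "mirhom_config")
}

.load_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

#' Genome-derived mature table of validated candidate loci
#'
#' Mature sequences are the genome slices at the reference mature offsets
#' (the target species' own mature variants). Mature names follow the
#' shared-mature convention of [reference_matures()]; duplicate rows from
#' paralogous loci collapse to one record per (mature, sequence, precursor).
#'
#' @param validated data.frame from [validate_loci()].
#' @param reference data.frame from [parse_reference_set()].
#' @return data.frame `mature_name`, `precursor_name`, `arm`, `sequence`.
#' @export
candidate_matures <- function(validated, reference) {
  ridx <- match(validated$ref, reference$name)
  base <- sub("-[0-9]+$", "", validated$ref)
  rows <- list()
  for (arm in c("5p", "3p")) {
    s <- reference[[paste0("m", arm, "_start")]][ridx]
    e <- reference[[paste0("m", arm, "_end")]][ridx]
    has <- !is.na(s)
    if (!any(has)) next
    rows[[arm]] <- data.frame(
      mature_name = paste0(base[has], "-", arm),
      precursor_name = validated$ref[has], arm = arm,
      sequence = norm_seq(substr(validated$genome_subseq[has], s[has], e[has])),
      stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, rows))
}

#' Run the full annotation pipeline
#'
#' homology scan -> candidate filtering -> hairpin folding/validation ->
#' (optional) small RNA quantification -> genomic characterisation. The run
#' is deterministic: identical configuration and inputs give identical
#' outputs.
#'
#' @param config list from [pipeline_config()].
#' @return list: `candidates`, `validated`, `high_confidence`, `matures`,
#'   `quant` (NULL without fastqs), `library_stats`, `annotation`,
#'   `manifest` (per-stage record counts), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mirhom_config"))
  genome <- .load_input(config$genome, read_fasta)
  annotations <- .load_input(config$annotations, read_gff3)
  reference <- .load_input(config$reference, parse_reference_set)
  manifest <- list()
  note <- function(stage, n_in, n_out)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)

  hits <- scan_genome(genome, reference, k = config$scan_k,
                      floor_identity = config$scan_floor)
  note("homology_scan", nrow(reference), nrow(hits))
  thr <- homology_thresholds()
  thr$identity <- config$identity; thr$seed_mm <- config$seed_mm
  thr$nonseed_mm <- config$nonseed_mm
  candidates <- filter_candidates(hits, reference, thr)
  note("homology_filter", nrow(hits), nrow(candidates))
  hthr <- list(mfe = config$mfe, bulge = config$bulge, flank = config$flank)
  validated <- validate_loci(genome, candidates, reference, hthr)
  hc <- validated[validated$high_confidence, , drop = FALSE]
  note("hairpin_validation", nrow(candidates), nrow(hc))
  matures <- candidate_matures(hc, reference)

  quant <- NULL; stats_tab <- NULL
  if (!is.null(config$fastqs)) {
    fq <- config$fastqs
    if (is.character(fq) && is.null(names(fq)))
      names(fq) <- sprintf("sample%d", seq_along(fq))
    libs <- list(); qc <- list(); assigned <- list()
    for (s in names(fq)) {
      reads <- if (is.character(fq)) read_fastq(fq[[s]]) else fq[[s]]
      flt <- qc_filter(reads, config$adapter)
      lib <- collapse_and_map(flt$reads, genome, sample_id = s)
      lib <- classify_annotation(lib, annotations)
      asg <- assign_reads_to_mirnas(lib, matures)
      libs[[s]] <- lib; qc[[s]] <- flt; assigned[[s]] <- asg
    }
    mat_names <- assigned[[1]]$mature_name
    counts <- matrix(vapply(assigned, function(a)
      a$count[match(mat_names, a$mature_name)], integer(length(mat_names))),
      nrow = length(mat_names), dimnames = list(mat_names, names(fq)))
    clean <- vapply(libs, `[[`, 0L, "clean_reads")
    expressed <- call_known_mirnas(counts, config$min_reads, config$min_individuals)
    tpm_mat <- tpm(counts, clean)
    expr <- data.frame(mature_name = mat_names,
                       precursors = assigned[[1]]$precursors,
                       counts, tpm_mat, mean_tpm = rowMeans(tpm_mat),
                       expressed = expressed, stringsAsFactors = FALSE,
                       check.names = FALSE)
    colnames(expr)[seq(3, 2 + ncol(counts))] <- paste0("count_", colnames(counts))
    colnames(expr)[seq(3 + ncol(counts), 2 + 2 * ncol(counts))] <-
      paste0("tpm_", colnames(counts))
    rownames(expr) <- NULL
    quant <- list(libraries = libs, qc = lapply(qc, `[[`, "tally"),
                  counts = counts, clean_reads = clean, expression = expr,
                  assigned = assigned)
    note("quantification", sum(vapply(qc, `[[`, 0L, "input")), sum(clean))
    stats_tab <- summarize_library_stats(libs, assigned)
  }

  loci <- genomic_interval(hc$chrom, hc$start, hc$end, hc$strand,
                           name = hc$locus_name)
  species <- stats::setNames(reference$species[match(hc$ref, reference$name)],
                             hc$locus_name)
  expression <- if (!is.null(quant)) quant$expression else NULL
  annotation <- annotate_mirna_set(loci, annotations, matures, species,
                                   expression = expression,
                                   max_gap = config$cluster_gap)
  note("characterisation", nrow(hc), nrow(annotation$loci))

  result <- list(candidates = candidates, validated = validated,
                 high_confidence = hc, matures = matures, quant = quant,
                 library_stats = stats_tab, annotation = annotation,
                 manifest = do.call(rbind, manifest), config = config)
  if (!is.null(config$out_dir)) write_pipeline_reports(result, config$out_dir)
  result
}

#' Per-library summary table
#'
#' The Table-1-shaped report: per sample, total clean reads after QC,
#' unique sRNA tags, clean reads assigned to mature miRNAs and unique tags
#' assigned to mature miRNAs, plus an `Average` column (arithmetic mean,
#' reported to the nearest integer).
#'
#' @param libraries list of per-sample objects from [collapse_and_map()].
#' @param assignments list of per-sample data.frames from
#'   [assign_reads_to_mirnas()].
#' @return data.frame with a `metric` column, one column per sample, and
#'   `Average`.
#' @export
summarize_library_stats <- function(libraries, assignments) {
  if (length(libraries) == 0L) .stopf("no libraries to summarise")
  samples <- vapply(libraries, `[[`, "", "sample_id")
  m <- rbind(
    clean_reads = vapply(libraries, `[[`, 0L, "clean_reads"),
    unique_srnas = vapply(libraries, function(l) nrow(l$tags), 0L),
    clean_reads_for_mirnas = vapply(assignments, function(a)
      attr(a, "reads_assigned"), 0L),
    unique_srnas_for_mirnas = vapply(assignments, function(a)
      attr(a, "tags_assigned"), 0L))
  colnames(m) <- samples
  avg <- floor(rowMeans(m) + 0.5)  # nearest integer, .5 rounds up
  data.frame(metric = rownames(m), m, Average = as.integer(avg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the pipeline's report tables
#'
#' @param result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(result$candidates, "candidates.tsv")
  tsv(result$validated, "validated.tsv")
  tsv(result$annotation$loci, "loci_annotated.tsv")
  cl <- result$annotation$clusters
  tsv(cl[, c("cluster_id", "span", "n_members", "members", "seed_class")],
      "clusters.tsv")
  tsv(result$annotation$mirrors, "mirror_pairs.tsv")
  if (!is.null(result$quant)) tsv(result$quant$expression, "expression.tsv")
  if (!is.null(result$library_stats)) tsv(result$library_stats, "library_stats.tsv")
  tsv(result$manifest, "manifest.tsv")
  hc <- result$high_confidence
  if (nrow(hc) > 0L) {
    loci <- genomic_interval(hc$chrom, hc$start, hc$end, hc$strand,
                             name = hc$locus_name)
    write_bed(loci, file.path(dir, "high_confidence.bed"))
    write_gff3(data.frame(feature_class = "miRNA_primary_transcript",
                          chrom = hc$chrom, start = hc$start, end = hc$end,
                          strand = hc$strand, gene_id = hc$locus_name,
                          stringsAsFactors = FALSE),
               file.path(dir, "high_confidence.gff3"))
  }
  if (!is.null(result$annotation$correlation)) {
    co <- result$annotation$correlation
    tsv(data.frame(rho = co$rho, p_value = co$p_value, n = co$n),
        "age_expression_correlation.tsv")
  }
  invisible(dir)
}
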