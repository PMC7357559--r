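# Small RNA-seq quantification: per-library QC filtering, read collapsing,
# perfect-match genome placement, annotation-based exclusion, assignment of
# tags to mature miRNAs, expression calling with support thresholds, and
# TPM normalisation.

#' Default QC parameters
#'
#' @return list: `max_adapter_mm` (adapter detected when aligned with at
#'   most this many mismatches, i.e. "fewer than three"), `min_overlap`
#'   (minimum adapter bases overlapping the read 3' end), `max_n_frac`
#'   (reads with more than this fraction of N are removed), `low_qual_phred`
#'   (a base below this Phred score is low quality), `max_lowqual_frac`
#'   (reads with more than this fraction of low-quality bases are removed),
#'   `min_len` (reads shorter than this after trimming are removed),
#'   `error_rate` (mismatches allowed in a partial adapter overlap scale
#'   with its length, `min(max_adapter_mm, floor(overlap * error_rate))`,
#'   so short chance overlaps must match exactly).
#' @export
qc_params <- function() {
  list(max_adapter_mm = 2L, min_overlap = 6L, max_n_frac = 0.10,
       low_qual_phred = 20L, max_lowqual_frac = 0.5, min_len = 18L,
       error_rate = 0.1)
}

# first adapter start position within each sequence (NA if none): ungapped
# scan, adapter prefix of >= min_overlap nt, mismatch allowance scaled by
# the overlap length.
.adapter_start <- function(seqs, adapter, max_mm, min_overlap, error_rate = 0.1) {
  out <- rep(NA_integer_, length(seqs))
  la <- nchar(adapter)
  aint <- utf8ToInt(adapter)
  lens <- nchar(seqs)
  for (W in unique(lens)) {
    idx <- which(lens == W)
    if (W < min_overlap) next
    m <- matrix(utf8ToInt(paste(seqs[idx], collapse = "")), nrow = length(idx),
                ncol = W, byrow = TRUE)
    first <- rep(NA_integer_, length(idx))
    for (p in 1:(W - min_overlap + 1L)) {
      ov <- min(la, W - p + 1L)
      allowed <- min(max_mm, floor(ov * error_rate))
      mm <- rowSums(m[, p:(p + ov - 1L), drop = FALSE] != rep(aint[1:ov], each = length(idx)))
      hit <- is.na(first) & mm <= allowed
      first[hit] <- p
      if (!anyNA(first)) break
    }
    out[idx] <- first
  }
  out
}

#' QC-filter a small RNA library
#'
#' Removes a read if any of four rules fires, attributing each removal to
#' the first matching rule: (1) the read is adapter/primer - the insert
#' left after 3'-adapter trimming is empty or itself still aligns to the
#' adapter; (2) more than 10 % unknown (N) bases; (3) more than 50 %
#' low-quality bases; (4) shorter than 18 nt. The 3' adapter is trimmed
#' (with up to `max_adapter_mm` mismatches) before the checks.
#'
#' @param reads data.frame from [read_fastq()].
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param params list from [qc_params()].
#' @return list: `reads` (clean, trimmed reads), `tally` (named removals per
#'   rule: adapter, n_bases, low_quality, short), `input`, `clean`.
#' @export
qc_filter <- function(reads, adapter, params = qc_params()) {
  adapter <- norm_seq(adapter)
  if (nchar(adapter) < 8L) .stopf("adapter must be at least 8 nt")
  n <- nrow(reads)
  seqs <- toupper(reads$sequence)
  qual <- reads$quality
  if (anyNA(seqs) || anyNA(qual) || any(nchar(qual) != nchar(seqs)))
    .stopf("reads must carry a quality string per base")
  er <- if (is.null(params$error_rate)) 0.1 else params$error_rate
  p1 <- .adapter_start(seqs, adapter, params$max_adapter_mm, params$min_overlap, er)
  ins <- ifelse(is.na(p1), seqs, substr(seqs, 1L, p1 - 1L))
  qins <- ifelse(is.na(p1), qual, substr(qual, 1L, p1 - 1L))
  len <- nchar(ins)
  # rule 1: adapter/primer reads
  r1 <- (!is.na(p1) & len == 0L)
  nonempty <- which(len > 0L)
  r1[nonempty] <- !is.na(.adapter_start(ins[nonempty], adapter,
                                        params$max_adapter_mm, params$min_overlap, er))
  r1 <- r1 | (!is.na(p1) & len == 0L)
  # rule 2: unknown bases
  nfrac <- ifelse(len > 0L, nchar(gsub("[^N]", "", ins)) / len, 1)
  r2 <- nfrac > params$max_n_frac
  # rule 3: low-quality bases
  cutoff_char <- intToUtf8(params$low_qual_phred + 33L)
  lowq <- vapply(qins, function(q) sum(utf8ToInt(q) < utf8ToInt(cutoff_char)), 0L,
                 USE.NAMES = FALSE)
  r3 <- ifelse(len > 0L, lowq / len, 1) > params$max_lowqual_frac
  # rule 4: short reads
  r4 <- len < params$min_len
  rule <- rep(0L, n)
  rule[r4] <- 4L; rule[r3] <- 3L; rule[r2] <- 2L; rule[r1] <- 1L
  keep <- rule == 0L
  tally <- c(adapter = sum(rule == 1L), n_bases = sum(rule == 2L),
             low_quality = sum(rule == 3L), short = sum(rule == 4L))
  clean <- data.frame(id = reads$id[keep], sequence = ins[keep],
                      quality = qins[keep], stringsAsFactors = FALSE)
  list(reads = clean, tally = tally, input = n, clean = nrow(clean))
}

#' Collapse clean reads to unique tags and place them on the genome
#'
#' Identical read sequences are collapsed to (tag, count). A tag is kept
#' only if its full length matches the genome exactly on either strand;
#' multi-position tags retain all placements.
#'
#' @param clean_reads data.frame of QC-passed reads.
#' @param genome data.frame from [read_fasta()].
#' @param sample_id label for this library.
#' @return list (`sample_id`, `clean_reads` count, `tags` data.frame with
#'   `tag`, `count`, `mapped`, and `placements` data.frame with `tag`,
#'   `chrom`, `start`, `end`, `strand`).
#' @export
collapse_and_map <- function(clean_reads, genome, sample_id = "sample") {
  tab <- table(norm_seq(clean_reads$sequence))
  tags <- data.frame(tag = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  mappable <- which(!grepl("N", tags$tag, fixed = TRUE) & nchar(tags$tag) > 0L)
  plc <- list(); pi <- 0L
  if (length(mappable) > 0L) {
    tg <- tags$tag[mappable]
    tg_rc <- revcomp(tg)
    W0 <- min(nchar(tg))
    # one constant-width prefix dictionary; full-length check at each hit
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(
      c(substr(tg, 1L, W0), substr(tg_rc, 1L, W0))))
    full <- c(tg, tg_rc)
    wlen <- nchar(full)
    ori <- rep(c("+", "-"), each = length(tg))
    tagname <- c(tg, tg)
    for (ci in seq_len(nrow(genome))) {
      contig <- norm_seq(genome$sequence[ci])
      mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(contig))
      starts <- Biostrings::startIndex(mi)
      starts[vapply(starts, is.null, TRUE)] <- list(integer(0))
      nhit <- lengths(starts)
      hitpat <- rep(seq_along(full), nhit)
      s <- unlist(starts, use.names = FALSE)
      if (length(s) == 0L) next
      e <- s + wlen[hitpat] - 1L
      ok <- e <= nchar(contig) & substr(rep(contig, length(s)), s, e) == full[hitpat]
      if (!any(ok)) next
      pi <- pi + 1L
      plc[[pi]] <- data.frame(
        tag = tagname[hitpat[ok]], chrom = genome$id[ci],
        start = s[ok], end = e[ok], strand = ori[hitpat[ok]],
        stringsAsFactors = FALSE)
    }
  }
  placements <- if (pi > 0L) do.call(rbind, plc) else
    data.frame(tag = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), stringsAsFactors = FALSE)
  tags$mapped <- tags$tag %in% placements$tag
  list(sample_id = sample_id, clean_reads = nrow(clean_reads),
       tags = tags, placements = placements)
}

#' Remove tags matching structural RNA, repeats or exons
#'
#' A tag is discarded when any of its genome placements overlaps (by at
#' least 1 nt, strand-blind) a feature of a discard class; the survivors
#' proceed to miRNA assignment.
#'
#' @param library list from [collapse_and_map()].
#' @param annotations data.frame from [read_gff3()].
#' @param discard_classes feature classes that disqualify a tag.
#' @return the library with `tags$annotation_excluded` set and placements of
#'   excluded tags dropped.
#' @export
classify_annotation <- function(library, annotations,
                                discard_classes = c("rRNA", "tRNA", "snRNA",
                                                    "snoRNA", "repeat",
                                                    "exon", "UTR")) {
  excl <- character(0)
  ann <- annotations[annotations$feature_class %in% discard_classes, , drop = FALSE]
  if (nrow(ann) > 0L && nrow(library$placements) > 0L) {
    agr <- annotations_to_granges(ann)
    pgr <- GenomicRanges::GRanges(library$placements$chrom,
                                  IRanges::IRanges(library$placements$start,
                                                   library$placements$end))
    hit <- GenomicRanges::countOverlaps(pgr, agr, ignore.strand = TRUE) > 0L
    excl <- unique(library$placements$tag[hit])
  }
  library$tags$annotation_excluded <- library$tags$tag %in% excl
  library$placements <- library$placements[!(library$placements$tag %in% excl), ,
                                           drop = FALSE]
  library
}

#' Assign mapped tags to mature miRNAs
#'
#' A tag is assigned to a mature miRNA when both are 5'-co-aligned with a
#' 3' trimming tolerance of `len_tol` nt, the seed (positions 2-8) matches
#' exactly, and at most `nonseed_mm` mismatches occur outside the seed over
#' the compared length. A tag matching several matures counts once per
#' distinct mature name; identical matures encoded by several precursors
#' yield a single expression record listing all precursors.
#'
#' @param library list from [collapse_and_map()]/[classify_annotation()];
#'   only mapped, non-excluded tags are considered.
#' @param matures data.frame from [reference_matures()] (or the equivalent
#'   table of genome-derived matures).
#' @param len_tol,nonseed_mm assignment tolerances.
#' @return data.frame `mature_name`, `precursors`, `count` for this library.
#' @export
assign_reads_to_mirnas <- function(library, matures, len_tol = 2L, nonseed_mm = 2L) {
  tags <- library$tags
  use <- tags$mapped & !isTRUE_or_col(tags$annotation_excluded)
  tags <- tags[use, , drop = FALSE]
  umat <- unique(matures[, c("mature_name", "sequence")])
  counts <- stats::setNames(integer(nrow(umat)), umat$mature_name)
  tag_hit <- logical(nrow(tags))
  if (nrow(tags) > 0L && nrow(umat) > 0L) {
    for (mi in seq_len(nrow(umat))) {
      ms <- umat$sequence[mi]
      lm <- nchar(ms)
      cand <- which(abs(nchar(tags$tag) - lm) <= len_tol)
      for (ti in cand) {
        ts <- tags$tag[ti]
        w <- min(nchar(ts), lm)
        a <- utf8ToInt(substr(ts, 1L, w)); b <- utf8ToInt(substr(ms, 1L, w))
        mm <- a != b
        pos <- seq_len(w)
        if (any(mm[pos >= 2L & pos <= 8L])) next
        if (sum(mm[pos < 2L | pos > 8L]) > nonseed_mm) next
        counts[mi] <- counts[mi] + tags$count[ti]
        tag_hit[ti] <- TRUE
      }
    }
  }
  prec <- vapply(umat$mature_name, function(nm) {
    paste(sort(unique(matures$precursor_name[matures$mature_name == nm])),
          collapse = ",")
  }, "")
  out <- data.frame(mature_name = umat$mature_name, precursors = unname(prec),
                    count = unname(counts), stringsAsFactors = FALSE)
  attr(out, "reads_assigned") <- as.integer(sum(tags$count[tag_hit]))
  attr(out, "tags_assigned") <- as.integer(sum(tag_hit))
  out
}

# helper: treat a missing logical column as all-FALSE
isTRUE_or_col <- function(x) if (is.null(x)) FALSE else x

#' Call expressed miRNAs across samples
#'
#' A mature miRNA is called expressed when it is supported by at least
#' `min_reads` reads summed over all samples and detected (count > 0) in at
#' least `min_individuals` samples. A precursor is expressed if either of
#' its arms passes.
#'
#' @param counts integer matrix, matures x samples.
#' @param min_reads,min_individuals support thresholds.
#' @return logical vector along the rows of `counts`.
#' @export
call_known_mirnas <- function(counts, min_reads = 10L, min_individuals = 3L) {
  if (ncol(counts) < min_individuals)
    .stopf("experiment has %d samples; the >=%d-individuals threshold is unsatisfiable",
           ncol(counts), min_individuals)
  rowSums(counts) >= min_reads & rowSums(counts > 0L) >= min_individuals
}

#' Transcripts-per-million normalisation
#'
#' `tpm[m, s] = counts[m, s] / clean_reads[s] * 1e6`.
#'
#' @param counts integer matrix (or vector), features x samples.
#' @param clean_reads per-sample totals of clean reads after QC.
#' @return numeric matrix of TPM values, same shape as `counts`.
#' @export
tpm <- function(counts, clean_reads) {
  counts <- as.matrix(counts)
  if (length(clean_reads) != ncol(counts))
    .stopf("clean_reads must have one entry per sample")
  if (any(clean_reads <= 0L)) .stopf("clean_reads must be positive")
  sweep(counts, 2L, clean_reads, "/") * 1e6
}

#' Quantify mature miRNA expression across libraries
#'
#' Runs QC, collapsing, genome placement, annotation exclusion and miRNA
#' assignment per library, then combines per-sample counts, applies the
#' expression call and normalises to TPM.
#'
#' @param fastqs named character vector of FASTQ paths (names = sample ids).
#' @param genome,annotations,matures inputs as in the stage functions.
#' @param adapter 3' adapter sequence.
#' @param min_reads,min_individuals expression-call thresholds.
#' @param params QC parameters.
#' @return list: `libraries` (per-sample stage objects), `qc` (per-sample
#'   tallies), `counts` (matures x samples), `clean_reads`, `expression`
#'   data.frame (per-sample raw counts and TPM, `mean_tpm`, `expressed`).
#' @export
quantify_libraries <- function(fastqs, genome, annotations, matures, adapter,
                               min_reads = 10L, min_individuals = 3L,
                               params = qc_params()) {
  if (is.null(names(fastqs)) || any(!nzchar(names(fastqs))))
    names(fastqs) <- sprintf("sample%d", seq_along(fastqs))
  libs <- list(); qc <- list(); assigned <- list()
  for (s in names(fastqs)) {
    reads <- read_fastq(fastqs[[s]])
    flt <- qc_filter(reads, adapter, params)
    lib <- collapse_and_map(flt$reads, genome, sample_id = s)
    lib <- classify_annotation(lib, annotations)
    asg <- assign_reads_to_mirnas(lib, matures)
    libs[[s]] <- lib; qc[[s]] <- flt$tally; assigned[[s]] <- asg
  }
  mat_names <- assigned[[1]]$mature_name
  counts <- vapply(assigned, function(a) a$count[match(mat_names, a$mature_name)],
                   integer(length(mat_names)))
  counts <- matrix(counts, nrow = length(mat_names),
                   dimnames = list(mat_names, names(fastqs)))
  clean <- vapply(libs, `[[`, 0L, "clean_reads")
  expressed <- call_known_mirnas(counts, min_reads, min_individuals)
  tpm_mat <- tpm(counts, clean)
  expr <- data.frame(mature_name = mat_names,
                     precursors = assigned[[1]]$precursors,
                     counts, tpm_mat, mean_tpm = rowMeans(tpm_mat),
                     expressed = expressed,
                     stringsAsFactors = FALSE, check.names = FALSE)
  colnames(expr)[seq(3, 2 + ncol(counts))] <- paste0("count_", names(fastqs))
  colnames(expr)[seq(3 + ncol(counts), 2 + 2 * ncol(counts))] <-
    paste0("tpm_", names(fastqs))
  rownames(expr) <- NULL
  list(libraries = libs, qc = qc, counts = counts, clean_reads = clean,
       expression = expr)
}
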