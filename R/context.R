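# Genomic characterisation of annotated miRNA loci: context classes
# (intergenic / intronic / exonic / UTR / splice-site-overlapping), mirror
# (antisense) pairs, 10-kb same-strand clusters with homo-/hetero-seed
# classes, conservation-age categories, and the age-expression correlation.

#' Classify the genomic context of miRNA loci
#'
#' A locus is `exonic` if it lies fully inside an exon (`UTR` when inside an
#' annotated UTR feature), `splice_site_overlapping` if it crosses an exon
#' boundary in the interior of a gene (an SO-miRNA), `intronic` if it lies
#' inside a gene but outside all exons (introns are derived gene-minus-exon
#' space, never stored), and `intergenic` otherwise. Containment ignores the
#' host strand; the host gene id is recorded where available.
#'
#' @param loci interval data.frame (with `name`).
#' @param annotations data.frame from [read_gff3()].
#' @return `loci` with appended `context` and `host_gene` columns.
#' @export
classify_context <- function(loci, annotations) {
  lgr <- intervals_to_granges(loci)
  cls <- function(fc) annotations_to_granges(
    annotations[annotations$feature_class == fc, , drop = FALSE])
  genes <- cls("gene"); exons <- cls("exon"); utrs <- cls("UTR")
  within_any <- function(q, s) {
    if (length(s) == 0L) return(rep(FALSE, length(q)))
    GenomicRanges::countOverlaps(q, s, type = "within", ignore.strand = TRUE) > 0L
  }
  overlaps_any <- function(q, s) {
    if (length(s) == 0L) return(rep(FALSE, length(q)))
    GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0L
  }
  in_exon <- within_any(lgr, exons)
  in_utr <- within_any(lgr, utrs)
  in_gene <- within_any(lgr, genes)
  touches_exon <- overlaps_any(lgr, exons)
  context <- rep("intergenic", nrow(loci))
  context[in_gene] <- "intronic"
  context[in_gene & touches_exon & !in_exon] <- "splice_site_overlapping"
  context[in_exon] <- "exonic"
  context[in_exon & in_utr] <- "UTR"
  host <- rep(NA_character_, nrow(loci))
  if (length(genes) > 0L) {
    ov <- GenomicRanges::findOverlaps(lgr, genes, type = "within",
                                      ignore.strand = TRUE, select = "first")
    gid <- genes$gene_id[ov]
    host[!is.na(ov)] <- gid[!is.na(ov)]
  }
  loci$context <- context
  loci$host_gene <- host
  loci
}

#' Find mirror (antisense) miRNA pairs
#'
#' Two distinct pre-miRNA loci form a mirror pair when they lie on the same
#' chromosome, on opposite strands, and overlap by at least one nucleotide -
#' two hairpins transcribed and processed from both strands of one locus.
#'
#' @param loci interval data.frame with unique `name`s.
#' @return data.frame of symmetric pairs (`name1` < `name2` lexicographically).
#' @export
find_mirror_pairs <- function(loci) {
  gr <- intervals_to_granges(loci)
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  keep <- q < s & loci$strand[q] != loci$strand[s] & loci$chrom[q] == loci$chrom[s]
  a <- loci$name[q[keep]]; b <- loci$name[s[keep]]
  swap <- a > b
  data.frame(name1 = ifelse(swap, b, a), name2 = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

#' Detect 10-kb same-strand miRNA gene clusters
#'
#' Per chromosome and strand, loci sorted by start are chained while the
#' edge-to-edge gap to the previous locus (`next start - previous end - 1`)
#' is at most `max_gap`; chains of two or more loci are clusters. The
#' pairwise rule is extended transitively, and the result partitions the
#' loci (each locus belongs to at most one cluster).
#'
#' @param loci interval data.frame with unique `name`s.
#' @param max_gap maximum inter-locus gap in nt.
#' @return data.frame, one row per cluster: `cluster_id`, `span`
#'   (chrom:start-end strand notation), `chrom`, `start`, `end`, `strand`,
#'   `n_members`, `members` (comma-joined names in start order).
#' @export
detect_clusters <- function(loci, max_gap = 10000L) {
  if (anyDuplicated(loci$name)) .stopf("duplicate locus names")
  grp <- paste(loci$chrom, loci$strand, sep = "\r")
  clusters <- list(); ci <- 0L
  for (g in split(loci, grp)) {
    g <- g[order(g$start, g$end, g$name), ]
    if (nrow(g) < 2L) next
    gap <- g$start[-1L] - cummax_end(g$end)[-nrow(g)] - 1L
    run <- cumsum(c(1L, as.integer(gap > max_gap)))
    for (r in split(g, run)) {
      if (nrow(r) < 2L) next
      ci <- ci + 1L
      clusters[[ci]] <- data.frame(
        chrom = r$chrom[1], start = min(r$start), end = max(r$end),
        strand = r$strand[1], n_members = nrow(r),
        members = paste(r$name, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (ci == 0L) {
    return(data.frame(cluster_id = character(0), span = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, clusters)
  out <- out[order(out$chrom, out$start, out$strand), ]
  out <- cbind(cluster_id = sprintf("cluster%d", seq_len(nrow(out))),
               span = sprintf("%s:%d-%d%s", out$chrom, out$start, out$end, out$strand),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# running maximum of interval ends (overlapping loci must not break a chain)
cummax_end <- function(end) cummax(end)

#' Seed class of a miRNA cluster
#'
#' `homo` when all member seed sequences (positions 2-8 of each member's
#' dominant mature miRNA) are identical, `hetero` otherwise.
#'
#' @param members character vector of member locus names.
#' @param seeds named character vector: locus name -> seed sequence.
#' @return `"homo"` or `"hetero"`.
#' @export
classify_cluster_seed <- function(members, seeds) {
  s <- seeds[members]
  if (anyNA(s)) .stopf("cluster member(s) without a mature seed: %s",
                       paste(members[is.na(s)], collapse = ", "))
  if (length(unique(norm_seq(s))) == 1L) "homo" else "hetero"
}

#' Seed sequence (positions 2-8) of each locus's dominant mature
#'
#' The seed is taken from the more abundant arm when expression is
#' available for both; otherwise from the 5p arm, falling back to 3p.
#'
#' @param matures data.frame with `precursor_name`, `arm`, `sequence` and
#'   optionally `mean_tpm`.
#' @return named character vector, precursor name -> 7-nt seed.
#' @export
dominant_seed <- function(matures) {
  out <- vapply(split(matures, matures$precursor_name), function(m) {
    if (!is.null(m$mean_tpm) && !anyNA(m$mean_tpm) && nrow(m) > 1L) {
      m <- m[order(-m$mean_tpm), ]
    } else {
      m <- m[order(match(m$arm, c("5p", "3p"))), ]
    }
    substr(norm_seq(m$sequence[1]), 2L, 8L)
  }, "")
  out
}

#' Default species-to-clade table
#'
#' Maps species labels to the narrowest clade bracket used for miRNA age
#' assignment: `vertebrate` marks non-mammal vertebrates, `mammal`
#' non-primate mammals, `primate` non-Cercopithecidae primates and
#' `cercopithecidae` Old World monkeys of that family.
#'
#' @return named character vector.
#' @export
default_clade_table <- function() {
  c(dre = "vertebrate", gga = "vertebrate", xtr = "vertebrate",
    aca = "vertebrate", oan = "vertebrate",
    mmu = "mammal", rno = "mammal", bta = "mammal", cfa = "mammal",
    ssc = "mammal", ocu = "mammal",
    hsa = "primate", ptr = "primate", ggo = "primate", ppy = "primate",
    cja = "primate",
    mml = "cercopithecidae", mfa = "cercopithecidae", pan = "cercopithecidae")
}

#' Assign a conservation-age category from a homolog species set
#'
#' The age is the broadest clade in which homologs occur: `vertebrate` if
#' any homolog species is a non-mammal vertebrate, else `mammal` if any is
#' a non-primate mammal, else `primate` if any is a non-Cercopithecidae
#' primate, else `cercopithecidae`. Ordinal rank 1 marks the oldest class.
#'
#' @param species character vector of species labels (or a single
#'   comma-separated string).
#' @param clade_table named map from species label to clade; see
#'   [default_clade_table()].
#' @return list `category` (character) and `rank` (1 = vertebrate ...
#'   4 = cercopithecidae).
#' @export
assign_age <- function(species, clade_table = default_clade_table()) {
  if (length(species) == 1L && grepl(",", species))
    species <- strsplit(species, ",")[[1]]
  species <- trimws(species)
  unknown <- setdiff(species, names(clade_table))
  if (length(unknown) > 0L)
    .stopf("unknown species label(s): %s", paste(unknown, collapse = ", "))
  clades <- clade_table[species]
  order_ <- c("vertebrate", "mammal", "primate", "cercopithecidae")
  rank <- min(match(clades, order_))
  list(category = order_[rank], rank = rank)
}

#' Spearman correlation between miRNA age and expression
#'
#' Rank correlation (average-rank tie handling) between the age of miRNAs
#' and their mean expression, with a two-sided p-value from the t
#' approximation. Ages are coded so that older categories score higher;
#' a positive rho therefore means older miRNAs are more highly expressed.
#'
#' @param age_rank integer age ranks as from [assign_age()] (1 = oldest).
#' @param mean_tpm mean expression per miRNA.
#' @return list `rho`, `p_value`, `n`.
#' @export
spearman_age_expression <- function(age_rank, mean_tpm) {
  n <- length(age_rank)
  if (n != length(mean_tpm)) .stopf("length mismatch")
  if (n < 4L) .stopf("need at least 4 observations")
  age_score <- max(age_rank) + 1L - age_rank  # older -> higher
  rx <- rank(age_score); ry <- rank(mean_tpm)
  rho <- stats::cor(rx, ry)
  if (is.na(rho)) .stopf("correlation undefined (constant input)")
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Characterise an annotated miRNA gene set
#'
#' Convenience wrapper running context classification, mirror-pair search,
#' cluster detection with seed classes, age assignment and (when expression
#' is supplied) the age-expression correlation.
#'
#' @param loci interval data.frame with unique `name`s.
#' @param annotations data.frame from [read_gff3()].
#' @param matures mature table (see [dominant_seed()]).
#' @param species named character vector: locus name -> comma-separated
#'   homolog species set.
#' @param expression optional data.frame with `mature_name`, `mean_tpm`.
#' @param max_gap cluster gap threshold.
#' @param clade_table species-to-clade map.
#' @return list: `loci` (with context, host gene, age), `mirrors`,
#'   `clusters` (with `seed_class`), `correlation` (or NULL).
#' @export
annotate_mirna_set <- function(loci, annotations, matures, species,
                               expression = NULL, max_gap = 10000L,
                               clade_table = default_clade_table()) {
  loci <- classify_context(loci, annotations)
  ages <- lapply(species[loci$name], assign_age, clade_table = clade_table)
  loci$age_category <- vapply(ages, `[[`, "", "category")
  loci$age_rank <- vapply(ages, `[[`, 0L, "rank")
  mirrors <- find_mirror_pairs(loci)
  clusters <- detect_clusters(loci, max_gap = max_gap)
  if (!is.null(expression)) {
    m <- merge(matures, expression[, c("mature_name", "mean_tpm")],
               by = "mature_name", all.x = TRUE)
    seeds <- dominant_seed(m)
  } else seeds <- dominant_seed(matures)
  # locus names may extend precursor names (paralog loci); map via prefix
  locus_seed <- seeds[sub("@.*$", "", loci$name)]
  names(locus_seed) <- loci$name
  if (nrow(clusters) > 0L) {
    clusters$seed_class <- vapply(strsplit(clusters$members, ","), function(mem) {
      classify_cluster_seed(mem, locus_seed)
    }, "")
  } else clusters$seed_class <- character(0)
  correlation <- NULL
  if (!is.null(expression)) {
    prec_expr <- precursor_mean_tpm(matures, expression)
    idx <- match(sub("@.*$", "", loci$name), names(prec_expr))
    ok <- !is.na(idx)
    if (sum(ok) >= 4L) {
      correlation <- spearman_age_expression(loci$age_rank[ok],
                                             prec_expr[idx[ok]])
    }
  }
  list(loci = loci, mirrors = mirrors, clusters = clusters,
       correlation = correlation)
}

# mean TPM per precursor: sum of its arms' mean TPM
precursor_mean_tpm <- function(matures, expression) {
  m <- merge(matures, expression[, c("mature_name", "mean_tpm")],
             by = "mature_name")
  v <- tapply(m$mean_tpm, m$precursor_name, sum)
  stats::setNames(as.numeric(v), names(v))
}
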