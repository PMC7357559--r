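# Homology search: map reference pre-miRNAs onto a genome by exact k-mer
# seeding plus banded extension, then apply the conserved-miRNA criteria:
# full-length identity > 93 %, at most one mismatch in the mature seed
# (positions 2-8) and at most two outside it, and one reference per genomic
# locus (paralogous loci of one reference are allowed).

#' Percent identity of a banded global alignment
#'
#' Aligns two same-length (within the band) sequences globally with a banded
#' dynamic program; gap columns count as mismatches, so the result is
#' `100 * matches / alignment_columns`.
#'
#' @param ref_seq,genome_subseq sequences (U and T compare equal).
#' @param band band half-width in columns.
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(ref_seq, genome_subseq, band = 3L) {
  if (nchar(ref_seq) == 0L || nchar(genome_subseq) == 0L)
    .stopf("percent_identity: empty sequence")
  r <- banded_align_cpp(norm_seq(ref_seq), norm_seq(genome_subseq), as.integer(band))
  r$identity
}

#' Seed and non-seed mismatches between a reference mature and a candidate
#'
#' Ungapped position-wise comparison of two equal-length mature sequences.
#' The seed is positions 2-8 of the mature (1-based, 5' to 3'), the primary
#' determinant of target pairing; all other positions are non-seed.
#'
#' @param ref_mature,candidate_mature equal-length mature sequences.
#' @return named integer vector `c(seed = ..., nonseed = ...)`.
#' @export
mature_mismatches <- function(ref_mature, candidate_mature) {
  a <- .chars(norm_seq(ref_mature))
  b <- .chars(norm_seq(candidate_mature))
  if (length(a) != length(b))
    .stopf("mature length mismatch (%d vs %d); gapped mature alignments are rejected upstream",
           length(a), length(b))
  mm <- a != b
  seed <- seq_len(length(a)) >= 2L & seq_len(length(a)) <= 8L
  c(seed = sum(mm & seed), nonseed = sum(mm & !seed))
}

#' Scan a genome for homologs of reference pre-miRNAs
#'
#' Exact k-mer seeding on both strands followed by banded-alignment scoring
#' of every seeded window; windows reaching the floor identity are reported
#' as raw hits covering the full precursor length.
#'
#' @param genome data.frame from [read_fasta()] (or named character vector).
#' @param reference data.frame from [parse_reference_set()].
#' @param k seed k-mer length; must not exceed the shortest precursor.
#' @param floor_identity minimum percent identity for a raw hit.
#' @param band band half-width of the extension alignment.
#' @param merge collapse overlapping same-reference hits to the best-scoring
#'   window (tie broken to the smallest start). Set to `FALSE` to obtain the
#'   full set of windows at or above the floor.
#' @param max_hits_per_ref keep at most this many hits per reference
#'   (best identity first).
#' @return data.frame of hits: `ref`, `chrom`, `start`, `end`, `strand`,
#'   `similarity`, `genome_subseq` (the genome slice, reverse-complemented
#'   for minus-strand hits so it is co-directional with the reference).
#' @export
scan_genome <- function(genome, reference, k = 12L, floor_identity = 85,
                        band = 3L, merge = TRUE, max_hits_per_ref = Inf) {
  if (is.character(genome)) {
    genome <- data.frame(id = names(genome), sequence = unname(genome),
                         stringsAsFactors = FALSE)
  }
  k <- as.integer(k)
  if (any(nchar(reference$precursor) < k))
    .stopf("seed length k = %d exceeds the shortest precursor (%d nt)",
           k, min(nchar(reference$precursor)))
  gseq <- norm_seq(genome$sequence)
  names(gseq) <- genome$id
  # query k-mer table over all references and both orientations
  pres <- norm_seq(reference$precursor)
  qtab <- list(); qi <- 0L
  for (ri in seq_len(nrow(reference))) {
    for (strand in c("+", "-")) {
      query <- if (strand == "+") pres[ri] else revcomp(pres[ri])
      m <- nchar(query)
      qi <- qi + 1L
      qtab[[qi]] <- data.frame(kmer = substring(query, 1:(m - k + 1L), k:m),
                               ref_i = ri, strand = strand,
                               qpos = 1:(m - k + 1L), stringsAsFactors = FALSE)
    }
  }
  qtab <- do.call(rbind, qtab)
  ukmer <- unique(qtab$kmer)
  qrow_by_kmer <- split(seq_len(nrow(qtab)),
                        factor(match(qtab$kmer, ukmer), levels = seq_along(ukmer)))
  hits <- list(); hi <- 0L
  for (ci in seq_along(gseq)) {
    contig <- gseq[[ci]]
    L <- nchar(contig)
    if (L < k) next
    gm <- match(substring(contig, 1:(L - k + 1L), k:L), ukmer)
    gpos <- which(!is.na(gm))
    if (length(gpos) == 0L) next
    rows <- qrow_by_kmer[gm[gpos]]
    nrep <- lengths(rows)
    gg <- rep(gpos, nrep)
    rr <- unlist(rows, use.names = FALSE)
    seeds <- data.frame(ref_i = qtab$ref_i[rr], strand = qtab$strand[rr],
                        diag = gg - qtab$qpos[rr] + 1L, stringsAsFactors = FALSE)
    for (grp in split(seeds, paste(seeds$ref_i, seeds$strand))) {
      ri <- grp$ref_i[1]; strand <- grp$strand[1]
      query <- if (strand == "+") pres[ri] else revcomp(pres[ri])
      m <- nchar(query)
      if (m > L) next
      diags <- unique(grp$diag)
      starts <- unique(rep(diags, each = 2L * band + 1L) +
                         rep(-band:band, length(diags)))
      starts <- sort(starts[starts >= 1L & starts + m - 1L <= L])
      if (length(starts) == 0L) next
      ident <- vapply(starts, function(s) {
        banded_align_cpp(query, substr(contig, s, s + m - 1L), band)$identity
      }, 0)
      keep <- which(ident >= floor_identity)
      if (length(keep) == 0L) next
      win <- substr(rep(contig, length(keep)), starts[keep], starts[keep] + m - 1L)
      hi <- hi + 1L
      hits[[hi]] <- data.frame(
        ref = reference$name[ri], chrom = genome$id[ci],
        start = starts[keep], end = starts[keep] + m - 1L, strand = strand,
        similarity = ident[keep],
        genome_subseq = if (strand == "+") win else revcomp(win),
        stringsAsFactors = FALSE)
    }
  }
  if (hi == 0L) {
    return(data.frame(ref = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), similarity = numeric(0),
                      genome_subseq = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  if (merge) out <- merge_overlapping_hits(out)
  if (is.finite(max_hits_per_ref)) {
    out <- do.call(rbind, lapply(split(out, out$ref), function(h) {
      h[order(-h$similarity, h$chrom, h$start), ][seq_len(min(nrow(h), max_hits_per_ref)), ]
    }))
  }
  out <- out[order(out$ref, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Collapse overlapping windows of the same reference on the same
# chrom/strand to the best-identity window (ties to the smallest start).
merge_overlapping_hits <- function(hits) {
  grp <- paste(hits$ref, hits$chrom, hits$strand, sep = "\r")
  out <- lapply(split(hits, grp), function(h) {
    h <- h[order(h$start), ]
    run <- cumsum(c(1L, as.integer(h$start[-1] > cummax(h$end)[-nrow(h)])))
    do.call(rbind, lapply(split(h, run), function(r) {
      r[order(-r$similarity, r$start), ][1, ]
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default thresholds of the homology filter
#' @return list with `identity` (strict lower bound, percent), `seed_mm`,
#'   `nonseed_mm` (inclusive upper bounds per mature arm) and `overlap_frac`
#'   (fraction of the shorter locus above which two same-strand hits conflict).
#' @export
homology_thresholds <- function() {
  list(identity = 93, seed_mm = 1L, nonseed_mm = 2L, overlap_frac = 0.5)
}

#' Filter raw hits into candidate loci
#'
#' Keeps hits with full-length similarity strictly above the identity
#' threshold and, for every mature arm present on the reference, at most
#' `seed_mm` mismatches in the seed (positions 2-8) and `nonseed_mm` outside
#' it. Overlapping loci (same strand, reciprocal overlap of at least
#' `overlap_frac` of the shorter) are then resolved so each genomic locus is
#' assigned to a single reference: highest similarity wins, ties go to the
#' lexicographically smallest reference name. One reference may keep several
#' non-overlapping loci (paralogs).
#'
#' @param hits data.frame from [scan_genome()].
#' @param reference data.frame from [parse_reference_set()].
#' @param thresholds list as returned by [homology_thresholds()].
#' @return data.frame of candidate loci, one row per accepted hit, with
#'   locus coordinates, `similarity`, per-arm `seed_mm_5p`, `nonseed_mm_5p`,
#'   `seed_mm_3p`, `nonseed_mm_3p` (NA for absent arms) and a unique
#'   `locus_name` ("ref@chrom:start-end strand").
#' @export
filter_candidates <- function(hits, reference, thresholds = homology_thresholds()) {
  empty <- data.frame(ref = character(0), chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0), similarity = numeric(0),
                      genome_subseq = character(0),
                      seed_mm_5p = integer(0), nonseed_mm_5p = integer(0),
                      seed_mm_3p = integer(0), nonseed_mm_3p = integer(0),
                      locus_name = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  ridx <- match(hits$ref, reference$name)
  if (any(is.na(ridx))) .stopf("hits reference unknown names")
  mm <- matrix(NA_integer_, nrow(hits), 4,
               dimnames = list(NULL, c("seed_mm_5p", "nonseed_mm_5p",
                                       "seed_mm_3p", "nonseed_mm_3p")))
  ok_arm <- rep(TRUE, nrow(hits))
  for (arm in c("5p", "3p")) {
    s <- reference[[paste0("m", arm, "_start")]][ridx]
    e <- reference[[paste0("m", arm, "_end")]][ridx]
    has <- !is.na(s)
    for (i in which(has)) {
      v <- mature_mismatches(substr(reference$precursor[ridx[i]], s[i], e[i]),
                             substr(hits$genome_subseq[i], s[i], e[i]))
      mm[i, paste0("seed_mm_", arm)] <- v[["seed"]]
      mm[i, paste0("nonseed_mm_", arm)] <- v[["nonseed"]]
      ok_arm[i] <- ok_arm[i] && v[["seed"]] <= thresholds$seed_mm &&
        v[["nonseed"]] <= thresholds$nonseed_mm
    }
  }
  cand <- cbind(hits, as.data.frame(mm))
  cand <- cand[cand$similarity > thresholds$identity & ok_arm, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # locus deduplication: greedy by similarity, name
  cand <- cand[order(-cand$similarity, cand$ref, cand$chrom, cand$start), ]
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (j in acc) {
      if (cand$chrom[i] != cand$chrom[j] || cand$strand[i] != cand$strand[j]) next
      ov <- min(cand$end[i], cand$end[j]) - max(cand$start[i], cand$start[j]) + 1L
      if (ov <= 0L) next
      shorter <- min(cand$end[i] - cand$start[i], cand$end[j] - cand$start[j]) + 1L
      if (ov >= thresholds$overlap_frac * shorter) { conflict <- TRUE; break }
    }
    if (!conflict) acc <- c(acc, i)
  }
  cand <- cand[acc, , drop = FALSE]
  cand$locus_name <- sprintf("%s@%s:%d-%d%s", cand$ref, cand$chrom,
                             cand$start, cand$end, cand$strand)
  cand <- cand[order(cand$chrom, cand$start, cand$strand), ]
  rownames(cand) <- NULL
  cand
}
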