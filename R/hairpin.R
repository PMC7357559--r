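# Hairpin validation of candidate pre-miRNA loci: extract the locus with
# short genomic flanks, fold it, dissect the stem-loop, and apply the three
# structural acceptance criteria (mature within one arm, no internal
# loop/bulge of 6 nt or more, MFE of at most -15 kcal/mol) plus the
# supporting-evidence rule for high confidence.

#' Extract a locus sequence with genomic flanks
#'
#' Returns the locus sequence extended by `flank` nt on each side (clipped
#' at contig ends), reverse-complemented for minus-strand loci, in the RNA
#' alphabet. The realised flank lengths (relative to the returned, reading
#' orientation) are attached as attributes `flank5p`/`flank3p`.
#'
#' @param genome data.frame from [read_fasta()] or named character vector.
#' @param locus one-row interval (list or data.frame row with `chrom`,
#'   `start`, `end`, `strand`).
#' @param flank nt of context on each side.
#' @return character scalar (RNA alphabet) with flank attributes.
#' @export
extract_with_flanks <- function(genome, locus, flank = 10L) {
  if (is.character(genome)) {
    genome <- data.frame(id = names(genome), sequence = unname(genome),
                         stringsAsFactors = FALSE)
  }
  ci <- match(locus$chrom, genome$id)
  if (is.na(ci)) .stopf("chromosome '%s' not in genome", locus$chrom)
  L <- nchar(genome$sequence[ci])
  if (locus$start < 1L || locus$end > L)
    .stopf("locus %s:%d-%d outside contig (length %d)",
           locus$chrom, locus$start, locus$end, L)
  a <- max(1L, locus$start - flank)
  b <- min(L, locus$end + flank)
  s <- norm_seq(substr(genome$sequence[ci], a, b))
  up <- locus$start - a       # genomic upstream flank realised
  down <- b - locus$end       # genomic downstream flank realised
  if (locus$strand == "-") {
    s <- revcomp(s)
    f5 <- down; f3 <- up
  } else {
    f5 <- up; f3 <- down
  }
  out <- to_rna(s)
  attr(out, "flank5p") <- f5
  attr(out, "flank3p") <- f3
  out
}

#' Dissect the stem-loop of a folded structure
#'
#' Identifies the single hairpin of the structure: the helix running from
#' the outermost to the innermost base pair around the one terminal loop.
#' Structures with zero pairs raise an error; structures with more than one
#' terminal loop (multibranched, or several separate hairpins) are flagged
#' `is_hairpin = FALSE` and carry no spans.
#'
#' For every internal loop or bulge between consecutive stem pairs the
#' number of unpaired nucleotides on the larger side is recorded;
#' `max_internal_bulge` is the maximum over the stem.
#'
#' @param structure dot-bracket string.
#' @return list with `is_hairpin`, `arm5p` (c(start, end)), `arm3p`, `loop`,
#'   `n_stem_pairs`, `max_internal_bulge`.
#' @export
hairpin_features <- function(structure) {
  pt <- pair_table(structure)
  paired <- which(pt > 0L)
  if (length(paired) == 0L) .stopf("no stem: structure has no base pairs")
  opens <- which(pt > seq_along(pt))        # i with partner j > i
  # terminal (hairpin) loops: closing pairs with no pairs inside
  closing <- opens[vapply(opens, function(i) {
    j <- pt[i]
    i + 1L > j - 1L || all(pt[(i + 1L):(j - 1L)] == 0L)
  }, TRUE)]
  if (length(closing) != 1L) {
    return(list(is_hairpin = FALSE, arm5p = NULL, arm3p = NULL, loop = NULL,
                n_stem_pairs = length(opens), max_internal_bulge = NA_integer_))
  }
  # walk outward from the closing pair collecting the nested helix
  stem_i <- sort(opens)                      # in a single-hairpin structure all
  stem_j <- pt[stem_i]                       # pairs are nested around the loop
  inner <- max(stem_i)
  outer <- min(stem_i)
  bulges <- integer(0)
  ord <- order(stem_i)
  for (t in seq_len(length(stem_i) - 1L)) {
    i1 <- stem_i[ord[t]]; j1 <- stem_j[ord[t]]
    i2 <- stem_i[ord[t + 1L]]; j2 <- stem_j[ord[t + 1L]]
    left <- i2 - i1 - 1L
    right <- j1 - j2 - 1L
    if (left > 0L || right > 0L) bulges <- c(bulges, max(left, right))
  }
  list(is_hairpin = TRUE,
       arm5p = c(outer, inner),
       arm3p = c(pt[inner], pt[outer]),
       loop = c(inner + 1L, pt[inner] - 1L),
       n_stem_pairs = length(stem_i),
       max_internal_bulge = if (length(bulges) > 0L) max(bulges) else 0L)
}

#' Default hairpin acceptance thresholds
#' @return list: `mfe` (kcal/mol, pass iff MFE <= mfe), `bulge` (pass iff
#'   the largest internal loop/bulge side is strictly below this), `flank`
#'   (nt of genomic context folded on each side of the locus).
#' @export
hairpin_thresholds <- function() list(mfe = -15, bulge = 6L, flank = 10L)

#' Apply the structural acceptance criteria to one folded candidate
#'
#' @param features list from [hairpin_features()].
#' @param mfe folding free energy of the candidate (kcal/mol).
#' @param mature_spans list of `c(start, end)` positions of each present
#'   mature arm in the folded sequence's coordinates (i.e. offset by the
#'   realised 5' flank); NULL entries are skipped.
#' @param thresholds list from [hairpin_thresholds()].
#' @return logical vector: `passes_mature_in_arm` (every mature lies fully
#'   within one arm of the stem), `passes_bulge`
#'   (`max_internal_bulge < bulge`), `passes_mfe` (`mfe <= threshold`).
#' @export
validate_hairpin <- function(features, mfe, mature_spans,
                             thresholds = hairpin_thresholds()) {
  in_arm <- function(span, arm) {
    !is.null(arm) && span[1] >= arm[1] && span[2] <= arm[2]
  }
  spans <- Filter(Negate(is.null), mature_spans)
  mature_ok <- isTRUE(features$is_hairpin) && length(spans) > 0L &&
    all(vapply(spans, function(sp) {
      in_arm(sp, features$arm5p) || in_arm(sp, features$arm3p)
    }, TRUE))
  c(passes_mature_in_arm = mature_ok,
    passes_bulge = !is.na(features$max_internal_bulge) &&
      features$max_internal_bulge < thresholds$bulge,
    passes_mfe = mfe <= thresholds$mfe)
}

#' Fold and validate candidate loci
#'
#' Extracts every candidate locus with flanks, folds it, applies the three
#' structural criteria, and marks candidates as high confidence when all
#' three pass and the reference carries supporting evidence (annotated as a
#' miRNA elsewhere, experimentally supported homolog, or previously
#' reported in the target species).
#'
#' @param genome data.frame from [read_fasta()].
#' @param candidates data.frame from [filter_candidates()].
#' @param reference data.frame from [parse_reference_set()].
#' @param thresholds list from [hairpin_thresholds()].
#' @return `candidates` with appended columns `mfe`, `structure`,
#'   `n_stem_pairs`, `max_internal_bulge`, the three `passes_*` flags and
#'   `high_confidence`.
#' @export
validate_loci <- function(genome, candidates, reference,
                          thresholds = hairpin_thresholds()) {
  n <- nrow(candidates)
  if (n == 0L) {
    for (col in c("mfe", "structure", "n_stem_pairs", "max_internal_bulge",
                  "passes_mature_in_arm", "passes_bulge", "passes_mfe",
                  "high_confidence")) candidates[[col]] <- logical(0)
    return(candidates)
  }
  seqs <- character(n); f5 <- integer(n)
  for (i in seq_len(n)) {
    s <- extract_with_flanks(genome, candidates[i, ], flank = thresholds$flank)
    seqs[i] <- as.character(s)
    f5[i] <- attr(s, "flank5p")
  }
  fold <- fold_mfe(seqs, ids = candidates$locus_name)
  ridx <- match(candidates$ref, reference$name)
  res <- matrix(NA, n, 3)
  nsp <- integer(n); bulge <- integer(n)
  for (i in seq_len(n)) {
    feats <- hairpin_features(fold$structure[i])
    nsp[i] <- feats$n_stem_pairs
    bulge[i] <- if (is.na(feats$max_internal_bulge)) NA_integer_ else feats$max_internal_bulge
    spans <- list()
    for (arm in c("5p", "3p")) {
      s <- reference[[paste0("m", arm, "_start")]][ridx[i]]
      e <- reference[[paste0("m", arm, "_end")]][ridx[i]]
      if (!is.na(s)) spans[[arm]] <- c(s + f5[i], e + f5[i])
    }
    res[i, ] <- validate_hairpin(feats, fold$mfe[i], spans, thresholds)
  }
  candidates$mfe <- fold$mfe
  candidates$structure <- fold$structure
  candidates$n_stem_pairs <- nsp
  candidates$max_internal_bulge <- bulge
  candidates$passes_mature_in_arm <- res[, 1]
  candidates$passes_bulge <- res[, 2]
  candidates$passes_mfe <- res[, 3]
  support <- reference$annotated_elsewhere[ridx] |
    reference$experimentally_supported[ridx] | reference$previously_reported[ridx]
  candidates$high_confidence <- res[, 1] & res[, 2] & res[, 3] & support
  candidates
}

#' Write fold results in dot-bracket (RNAfold-style) format
#' @param fold data.frame from [fold_mfe()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(fold, path) {
  writeLines(paste0(">", fold$id, "\n", fold$sequence, "\n", fold$structure,
                    sprintf(" (%.2f)", fold$mfe)), path)
  invisible(path)
}
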