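# Reference pre-miRNA sets. Records travel as FASTA whose headers carry a
# flat key=value dialect:
#
#   >mir-1 species=hsa,mmu,dre m5p=6-27 m3p=45-66 flags=annotated,experimental
#   UGGAAUGUAAAGAAGUAUGUAU...
#
# keys: species  comma-separated labels of the species in which homologs of
#                this precursor are annotated (used for age assignment);
#       m5p/m3p  1-based inclusive span of the mature arm inside the
#                precursor (at least one arm required);
#       flags    any of {annotated, experimental, macaque}: annotated as a
#                miRNA in another species / homolog has experimental
#                support / previously reported in the target species.

#' Parse a reference pre-miRNA set
#'
#' @param path FASTA file in the header dialect described above.
#' @return data.frame with one row per precursor: `name`, `species`
#'   (comma-separated homolog species set), `precursor`, mature spans
#'   (`m5p_start`..`m3p_end`, NA when the arm is absent), mature sequences
#'   (`mature5p`, `mature3p`), and the logical support flags
#'   `annotated_elsewhere`, `experimentally_supported`,
#'   `previously_reported`.
#' @export
parse_reference_set <- function(path) {
  fa <- read_fasta(path)
  parse_reference_records(fa$id, fa$description, fa$sequence)
}

parse_reference_records <- function(name, description, sequence) {
  dup <- unique(name[duplicated(name)])
  if (length(dup) > 0L) .stopf("duplicate reference names: %s", paste(dup, collapse = ", "))
  kv <- function(desc, key) {
    m <- regmatches(desc, regexec(sprintf("(?:^|\\s)%s=(\\S+)", key), desc))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  span <- function(s) {
    out <- matrix(NA_integer_, length(s), 2)
    ok <- !is.na(s)
    m <- regmatches(s[ok], regexec("^([0-9]+)-([0-9]+)$", s[ok]))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) .stopf("malformed mature span: %s", paste(s[ok][bad], collapse = ", "))
    out[ok, 1] <- as.integer(vapply(m, `[`, "", 2L))
    out[ok, 2] <- as.integer(vapply(m, `[`, "", 3L))
    out
  }
  m5 <- span(kv(description, "m5p"))
  m3 <- span(kv(description, "m3p"))
  flags <- kv(description, "flags")
  has_flag <- function(f) !is.na(flags) & grepl(f, flags, fixed = TRUE)
  plen <- nchar(sequence)
  no_arm <- is.na(m5[, 1]) & is.na(m3[, 1])
  if (any(no_arm)) .stopf("reference record(s) with no mature arm: %s",
                          paste(name[no_arm], collapse = ", "))
  oob <- (!is.na(m5[, 1]) & (m5[, 1] < 1 | m5[, 2] > plen | m5[, 1] > m5[, 2])) |
         (!is.na(m3[, 1]) & (m3[, 1] < 1 | m3[, 2] > plen | m3[, 1] > m3[, 2]))
  if (any(oob)) .stopf("mature span outside precursor for: %s",
                       paste(name[oob], collapse = ", "))
  sub_or_na <- function(seq, s, e) ifelse(is.na(s), NA_character_, substr(seq, s, e))
  data.frame(
    name = name,
    species = kv(description, "species"),
    precursor = sequence,
    m5p_start = m5[, 1], m5p_end = m5[, 2],
    m3p_start = m3[, 1], m3p_end = m3[, 2],
    mature5p = sub_or_na(sequence, m5[, 1], m5[, 2]),
    mature3p = sub_or_na(sequence, m3[, 1], m3[, 2]),
    annotated_elsewhere = has_flag("annotated"),
    experimentally_supported = has_flag("experimental"),
    previously_reported = has_flag("macaque"),
    stringsAsFactors = FALSE)
}

#' Write a reference pre-miRNA set
#'
#' Inverse of [parse_reference_set()]; writing then parsing reproduces the
#' table field for field.
#'
#' @param ref reference data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path) {
  desc <- vapply(seq_len(nrow(ref)), function(i) {
    parts <- character(0)
    if (!is.na(ref$species[i])) parts <- c(parts, paste0("species=", ref$species[i]))
    if (!is.na(ref$m5p_start[i]))
      parts <- c(parts, sprintf("m5p=%d-%d", ref$m5p_start[i], ref$m5p_end[i]))
    if (!is.na(ref$m3p_start[i]))
      parts <- c(parts, sprintf("m3p=%d-%d", ref$m3p_start[i], ref$m3p_end[i]))
    fl <- c("annotated", "experimental", "macaque")[
      c(ref$annotated_elsewhere[i], ref$experimentally_supported[i],
        ref$previously_reported[i])]
    if (length(fl) > 0) parts <- c(parts, paste0("flags=", paste(fl, collapse = ",")))
    paste(parts, collapse = " ")
  }, "")
  write_fasta(data.frame(id = ref$name, sequence = ref$precursor,
                         description = desc, stringsAsFactors = FALSE), path)
}

#' Mature miRNA table of a reference set
#'
#' One row per present mature arm. The mature name is the precursor name
#' stripped of a trailing copy suffix ("-1", "-2", ...) plus the arm suffix,
#' following the convention that paralogous precursors (mir-181a-1,
#' mir-181a-2) encode the same mature miRNA (miR-181a-5p).
#'
#' @param ref reference data.frame from [parse_reference_set()].
#' @return data.frame with `mature_name`, `precursor_name`, `arm`,
#'   `sequence` (normalised alphabet), `start`, `end`.
#' @export
reference_matures <- function(ref) {
  base <- sub("-[0-9]+$", "", ref$name)
  rows <- list()
  for (arm in c("5p", "3p")) {
    s <- ref[[paste0("m", arm, "_start")]]
    has <- !is.na(s)
    if (!any(has)) next
    rows[[arm]] <- data.frame(
      mature_name = paste0(base[has], "-", arm),
      precursor_name = ref$name[has],
      arm = arm,
      sequence = norm_seq(ref[[paste0("mature", arm)]][has]),
      start = ref[[paste0("m", arm, "_start")]][has],
      end = ref[[paste0("m", arm, "_end")]][has],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
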