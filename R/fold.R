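# Minimum-free-energy folding. The thermodynamic engine is ViennaRNA's
# RNAfold/RNAeval (Turner nearest-neighbour parameters at 37 degrees C),
# driven through the command line; structure parsing, hairpin feature
# extraction and validation logic live in this package.

.vienna_check <- function(tool) {
  p <- Sys.which(tool)
  if (!nzchar(p)) .stopf("%s not found on the PATH; install ViennaRNA", tool)
  p
}

.validate_rna_input <- function(sequences, min_len = 10L) {
  if (length(sequences) == 0L) .stopf("no sequences to fold")
  .assert_alphabet(sequences, what = "fold input")
  if (any(nchar(sequences) < min_len))
    .stopf("fold input shorter than %d nt", min_len)
  to_rna(sequences)
}

#' Fold sequences to their minimum-free-energy structure
#'
#' Computes the MFE secondary structure of each sequence under the Turner
#' nearest-neighbour energy model at 37 degrees C via `RNAfold`. N bases are
#' accepted and treated as unpairable; T is read as U. Deterministic.
#'
#' @param sequences character vector of RNA/DNA sequences (length >= 10 nt).
#' @param ids optional names for the result rows.
#' @return data.frame with `id`, `sequence` (RNA alphabet), `structure`
#'   (dot-bracket, same length) and `mfe` (kcal/mol, <= 0).
#' @export
fold_mfe <- function(sequences, ids = NULL) {
  rna <- .validate_rna_input(sequences)
  if (is.null(ids)) ids <- if (!is.null(names(sequences))) names(sequences) else
    sprintf("seq%d", seq_along(sequences))
  .vienna_check("RNAfold")
  fin <- tempfile(fileext = ".fa")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste0(">", seq_along(rna), "\n", rna), fin)
  out <- system2("RNAfold", c("--noPS", "--infile", fin), stdout = TRUE)
  hdr <- grep("^>", out)
  if (length(hdr) != length(rna)) .stopf("unexpected RNAfold output")
  struct <- character(length(rna)); mfe <- numeric(length(rna))
  for (i in seq_along(hdr)) {
    line <- out[hdr[i] + 2L]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", line))[[1]]
    if (length(m) != 3L) .stopf("cannot parse RNAfold line: %s", line)
    struct[i] <- m[2]; mfe[i] <- as.numeric(m[3])
  }
  if (any(nchar(struct) != nchar(rna))) .stopf("RNAfold structure length mismatch")
  data.frame(id = ids, sequence = rna, structure = struct, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Free energy of given structures on a sequence
#'
#' Evaluates each dot-bracket structure on `sequence` under the same energy
#' rules as [fold_mfe()] (via `RNAeval`). Used by the exhaustive-enumeration
#' checks: the minimum over all structures must equal the folded MFE.
#'
#' @param sequence one RNA/DNA sequence.
#' @param structures character vector of dot-bracket strings.
#' @return numeric vector of energies (kcal/mol).
#' @export
eval_structure_energy <- function(sequence, structures) {
  rna <- .validate_rna_input(sequence, min_len = 1L)
  if (length(rna) != 1L) .stopf("one sequence at a time")
  if (any(nchar(structures) != nchar(rna))) .stopf("structure length mismatch")
  .vienna_check("RNAeval")
  fin <- tempfile()
  on.exit(unlink(fin), add = TRUE)
  writeLines(as.vector(rbind(rep(rna, length(structures)), structures)), fin)
  out <- system2("RNAeval", c("--infile", fin), stdout = TRUE)
  elines <- grep("^[.()]+\\s+\\(", out, value = TRUE)
  if (length(elines) != length(structures)) .stopf("unexpected RNAeval output")
  as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", elines))
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string over \{(, ), .\} (no pseudoknots).
#' @return integer vector: position of the partner, 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- .chars(structure)
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) .stopf("unbalanced brackets at position %d", i)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") .stopf("invalid structure character '%s'", ch[i])
  }
  if (length(stack) > 0L) .stopf("unbalanced brackets: %d unclosed", length(stack))
  pt
}
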