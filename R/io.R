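# Readers/writers for the standard formats the pipeline touches. Parsing of
# FASTA/FASTQ is delegated to Biostrings and GFF3 to rtracklayer; this layer
# adds the package's validation rules (duplicate ids, coordinate sanity, the
# closed feature-class set) and plain data.frame return types.

#' Read a FASTA file
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return data.frame with columns `id` (first header token, must be unique),
#'   `sequence` (uppercased, whitespace-free, U/T preserved as read) and
#'   `description` (remainder of the header line).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("FASTA file contains no records: %s", path)
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L) .stopf("duplicate FASTA ids: %s", paste(dup, collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  .assert_alphabet(seqs, what = sprintf("FASTA file %s", path))
  data.frame(id = id, sequence = unname(seqs), description = desc,
             stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param x data.frame with `id`, `sequence` and optionally `description`.
#' @param path output file (".gz" suffix enables compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  hdr <- x$id
  if (!is.null(x$description)) {
    hdr <- ifelse(is.na(x$description) | x$description == "",
                  x$id, paste(x$id, x$description))
  }
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file (optionally gzip-compressed), 4-line records.
#' @return data.frame with columns `id`, `sequence` and `quality` (the raw
#'   Phred+33 quality string, same length as the sequence). Decode with
#'   [phred_scores()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) .stopf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
  qual <- as.character(S4Vectors::mcols(set)$qualities)
  seqs <- as.character(set)
  if (any(nchar(qual) != nchar(seqs))) {
    bad <- names(set)[nchar(qual) != nchar(seqs)][1]
    .stopf("sequence/quality length mismatch at record '%s' in %s", bad, path)
  }
  data.frame(id = sub("\\s.*$", "", names(set)), sequence = unname(seqs),
             quality = unname(qual), stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Phred+33)
#' @param x data.frame with `id`, `sequence`, `quality`.
#' @param path output file (".gz" suffix enables compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", x$id, "\n", x$sequence, "\n+\n", x$quality), con)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#' @param quality character vector of quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' Default GFF3 type mapping
#'
#' Maps GFF3 `type` values onto the package's closed feature-class set
#' \{exon, UTR, gene, rRNA, tRNA, snRNA, snoRNA, repeat\}. Annotation sources
#' disagree on type vocabularies, so the table is an argument of
#' [read_gff3()] and can be replaced.
#'
#' @return named character vector, GFF3 type -> feature class.
#' @export
default_feature_map <- function() {
  c(exon = "exon",
    five_prime_UTR = "UTR", three_prime_UTR = "UTR", UTR = "UTR",
    gene = "gene",
    rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA",
    repeat_region = "repeat", dispersed_repeat = "repeat")
}

#' Read genome annotations from GFF3
#'
#' @param path GFF3 file (1-based inclusive coordinates; optionally gzipped).
#' @param feature_map named character vector mapping GFF3 types to the closed
#'   feature-class set; see [default_feature_map()]. Types absent from the
#'   map are skipped and counted.
#' @return data.frame with columns `feature_class`, `chrom`, `start`, `end`,
#'   `strand`, `gene_id` (the GFF3 ID/Parent where present). The number of
#'   skipped features is attached as attribute `"skipped"`.
#' @export
read_gff3 <- function(path, feature_map = default_feature_map()) {
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  # light pre-scan so coordinate errors carry a line number
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con); close(con)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
      if (!is.na(s) && !is.na(e) && s > e)
        .stopf("GFF3 line %d: start (%d) > end (%d)", i, s, e)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mapped <- feature_map[type]
  keep <- !is.na(mapped)
  out <- data.frame(
    feature_class = unname(mapped[keep]),
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    gene_id = if (!is.null(gr$ID)) as.character(gr$ID)[keep] else NA_character_,
    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  attr(out, "skipped") <- sum(!keep)
  out
}

#' Write annotation features to GFF3
#' @param x data.frame with `feature_class`, `chrom`, `start`, `end`,
#'   `strand` and optionally `gene_id`.
#' @param path output file.
#' @param source source string for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path, source = "mirhom") {
  attrs <- if (!is.null(x$gene_id) && !all(is.na(x$gene_id))) {
    ifelse(is.na(x$gene_id), ".", paste0("ID=", x$gene_id))
  } else rep(".", nrow(x))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   x$chrom, source, x$feature_class, x$start, x$end, x$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Convert an annotation table to GRanges
#' @param x annotation data.frame from [read_gff3()].
#' @return `GRanges` with a `feature_class` metadata column.
#' @export
annotations_to_granges <- function(x) {
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end),
                               strand = x$strand)
  gr$feature_class <- x$feature_class
  gr$gene_id <- if (!is.null(x$gene_id)) x$gene_id else NA_character_
  gr
}
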