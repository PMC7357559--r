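# Genomic intervals: 1-based inclusive coordinates with an explicit strand,
# printed in the "chrom:start-end<strand>" notation used throughout the
# package's report tables. BED export converts to 0-based half-open.

#' Construct a table of genomic intervals
#'
#' The universal coordinate type of the package: 1-based inclusive
#' chrom/start/end plus a strand in \{+,-\}. Stored as a plain data.frame so
#' it round-trips through TSV reports; convert to `GRanges` with
#' [intervals_to_granges()] for overlap arithmetic.
#'
#' @param chrom character chromosome names.
#' @param start,end 1-based inclusive positions, `1 <= start <= end`.
#' @param strand "+" or "-".
#' @param name optional locus names.
#' @return data.frame with columns name, chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand, name = NULL) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(start)) || any(is.na(end))) .stopf("interval coordinates must be integers")
  if (any(start < 1L)) .stopf("interval start must be >= 1 (1-based inclusive coordinates)")
  if (any(end < start)) .stopf("interval end must be >= start")
  if (!all(strand %in% c("+", "-"))) .stopf("strand must be '+' or '-'")
  if (is.null(name)) name <- rep(NA_character_, n)
  data.frame(name = rep_len(as.character(name), n), chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Format intervals in locus notation
#'
#' @param x interval data.frame from [genomic_interval()].
#' @return character vector like `"chr1:128814989-128815918+"`.
#' @export
format_locus <- function(x) sprintf("%s:%d-%d%s", x$chrom, x$start, x$end, x$strand)

#' Parse locus notation
#'
#' Inverse of [format_locus()]: `"chr1:100-200+"` becomes a one-row interval
#' table.
#'
#' @param s character vector of locus strings with a trailing strand sign.
#' @return interval data.frame.
#' @export
parse_locus <- function(s) {
  m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)([+-])$", s))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) .stopf("cannot parse locus string(s): %s", paste(s[bad], collapse = ", "))
  genomic_interval(chrom = vapply(m, `[`, "", 2L),
                   start = as.integer(vapply(m, `[`, "", 3L)),
                   end = as.integer(vapply(m, `[`, "", 4L)),
                   strand = vapply(m, `[`, "", 5L))
}

#' Convert an interval table to GRanges
#' @param x interval data.frame.
#' @return `GenomicRanges::GRanges` with locus names where present.
#' @export
intervals_to_granges <- function(x) {
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end), strand = x$strand)
  if (!is.null(x$name) && !all(is.na(x$name))) names(gr) <- x$name
  gr
}

#' Export intervals to a BED file
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param x interval data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                    name = ifelse(is.na(x$name), ".", x$name),
                    score = 0L, strand = x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into an interval table
#'
#' @param path BED file written by [write_bed()].
#' @return interval data.frame (1-based inclusive), so that
#'   `read_bed(write_bed(x))` is the identity on coordinates.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  genomic_interval(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
                   strand = bed[[6]],
                   name = ifelse(bed[[4]] == ".", NA_character_, bed[[4]]))
}
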