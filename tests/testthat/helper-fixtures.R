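# Fixture builders: everything is constructed in code at test time.

# a reference data.frame row in the shape parse_reference_set() returns
ref_row <- function(name, precursor, m5p = NULL, m3p = NULL,
                    species = "hsa,mmu", annotated = TRUE,
                    experimental = FALSE, macaque = FALSE) {
  sub_or_na <- function(sp) if (is.null(sp)) NA_character_ else
    substr(precursor, sp[1], sp[2])
  data.frame(name = name, species = species, precursor = precursor,
             m5p_start = if (is.null(m5p)) NA_integer_ else m5p[1],
             m5p_end = if (is.null(m5p)) NA_integer_ else m5p[2],
             m3p_start = if (is.null(m3p)) NA_integer_ else m3p[1],
             m3p_end = if (is.null(m3p)) NA_integer_ else m3p[2],
             mature5p = sub_or_na(m5p), mature3p = sub_or_na(m3p),
             annotated_elsewhere = annotated,
             experimentally_supported = experimental,
             previously_reported = macaque, stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute the bases at `pos` with a different letter
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# genome with sequences planted at known offsets inside random background
plant_genome <- function(chrom_len, plants) {
  # plants: list of list(chrom, at, seq, strand)
  chroms <- unique(vapply(plants, `[[`, "", "chrom"))
  seqs <- stats::setNames(vapply(chrom_len[chroms], rand_dna, ""), chroms)
  for (p in plants) {
    s <- if (p$strand == "+") p$seq else revcomp(p$seq)
    substr(seqs[p$chrom], p$at, p$at + nchar(s) - 1L) <- s
  }
  data.frame(id = names(seqs), sequence = unname(seqs), stringsAsFactors = FALSE)
}

reads_df <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(seqs))
  data.frame(id = ids, sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

# small cached truth/simulation shared across test files (built once)
small_truth_config <- function() {
  cfg <- truth_config()
  cfg$chrom_lengths <- c(chr1 = 160000L, chr2 = 130000L)
  cfg$n_by_age <- c(vertebrate = 3L, mammal = 3L, primate = 4L, cercopithecidae = 2L)
  cfg$n_by_context <- c(intergenic = 6L, intronic = 3L, exonic = 1L, UTR = 1L,
                        splice_site_overlapping = 1L)
  cfg$clusters <- list(list(n = 2L, seed_class = "homo"))
  cfg
}

.cache <- new.env(parent = emptyenv())

cached_small_truth <- function() {
  if (is.null(.cache$truth)) .cache$truth <- generate_truth_set(small_truth_config(), seed = 42L)
  .cache$truth
}

cached_small_sim <- function() {
  if (is.null(.cache$sim)) {
    specs <- library_specs(n_samples = 4L, n_reads = 8000L)
    .cache$sim <- simulate_libraries(cached_small_truth(), specs, seed = 42L)
  }
  .cache$sim
}
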