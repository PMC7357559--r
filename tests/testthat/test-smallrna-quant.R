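# QC filtering, tag collapsing/placement, annotation exclusion, miRNA
# assignment, expression calling and TPM normalisation.

ADAPT <- "TGGAATTCTCGGGTGCCAAGG"

test_that("QC removes reads by the four rules in order and tallies them", {
  mk <- function(ins, qual_ins = strrep("I", nchar(ins))) {
    s <- substr(paste0(ins, ADAPT, strrep("A", 36)), 1, 36)
    q <- substr(paste0(qual_ins, strrep("I", 36)), 1, 36)
    list(s = s, q = q)
  }
  good <- mk(rand_dna(22))
  dimer <- mk("")                                    # rule 1: pure adapter
  n2of20 <- mk("ACGTACGTACGTACGTACNN")               # 2 N of 20 = 10.0 %: kept
  n3of20 <- mk("ACGTACGTACGTACGTANNN")               # 15 % N: rule 2
  lowq <- mk(rand_dna(20), paste0(strrep("#", 11), strrep("I", 9)))  # 55 %: rule 3
  short <- mk(rand_dna(17))                          # rule 4
  reads <- reads_df(c(good$s, dimer$s, n2of20$s, n3of20$s, lowq$s, short$s),
                    c(good$q, dimer$q, n2of20$q, n3of20$q, lowq$q, short$q))
  out <- qc_filter(reads, ADAPT)
  expect_equal(out$clean, 2L)
  expect_equal(unname(out$tally), c(1L, 1L, 1L, 1L))
  expect_equal(sum(out$tally), out$input - out$clean)
  # trimming removed the adapter tail from the survivors
  expect_equal(sort(nchar(out$reads$sequence)), c(20L, 22L))
  expect_error(qc_filter(reads, "ACGT"), "at least 8")
})

test_that("QC is idempotent", {
  sim <- cached_small_sim()
  one <- qc_filter(sim$reads[[1]], ADAPT)
  two <- qc_filter(one$reads, ADAPT)
  expect_equal(two$reads, one$reads)
  expect_equal(unname(two$tally), rep(0L, 4))
})

test_that("QC rejection tallies account for every removed read on simulated data", {
  sim <- cached_small_sim()
  for (s in names(sim$reads)) {
    out <- qc_filter(sim$reads[[s]], ADAPT)
    expect_equal(sum(out$tally), out$input - out$clean)
  }
})

test_that("collapsing keeps perfect full-length genome matches with all placements", {
  set.seed(41)
  g <- plant_genome(c(c1 = 3000L), list(
    list(chrom = "c1", at = 101L, seq = "ACGTACGTTAGCCATGACGTAC", strand = "+")))
  # plant the same 22-mer a second time
  tag <- "ACGTACGTTAGCCATGACGTAC"
  substr(g$sequence, 2001, 2022) <- tag
  reads <- reads_df(c(tag, tag, mutate_at(tag, 11), revcomp(tag), rand_dna(22)))
  lib <- collapse_and_map(reads, g, "s")
  tags <- lib$tags
  expect_equal(tags$count[tags$tag == tag], 2L)             # identical reads collapse
  expect_true(tags$mapped[tags$tag == tag])
  expect_false(tags$mapped[tags$tag == mutate_at(tag, 11)]) # 1 mismatch: dropped
  expect_true(tags$mapped[tags$tag == revcomp(tag)])        # minus strand counts
  pl <- lib$placements[lib$placements$tag == tag, ]
  expect_equal(sort(pl$start), c(101L, 2001L))              # multi-placement retained
  expect_equal(unique(pl$strand), "+")
  plrc <- lib$placements[lib$placements$tag == revcomp(tag), ]
  expect_equal(unique(plrc$strand), "-")
})

test_that("tags overlapping excluded annotation classes are discarded", {
  set.seed(43)
  g <- data.frame(id = "c1", sequence = rand_dna(2000), stringsAsFactors = FALSE)
  ann <- data.frame(feature_class = c("rRNA", "exon"), chrom = "c1",
                    start = c(101L, 501L), end = c(220L, 620L), strand = "+",
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  t_rrna <- substr(g$sequence, 120, 140)
  t_edge <- substr(g$sequence, 600, 620)   # 1-nt exon overlap would be 620 only
  t_edge1 <- substr(g$sequence, 620, 640)  # overlaps the exon by exactly 1 nt
  t_free <- substr(g$sequence, 1500, 1521)
  lib <- collapse_and_map(reads_df(c(t_rrna, t_edge, t_edge1, t_free)), g, "s")
  lib <- classify_annotation(lib, ann)
  ex <- lib$tags$annotation_excluded[match(c(t_rrna, t_edge, t_edge1, t_free),
                                           lib$tags$tag)]
  expect_equal(ex, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("tag-to-mature assignment enforces the seed and non-seed rules", {
  m <- "ACGTTGCAACGGATCCTAGGAC"  # 22 nt
  matures <- data.frame(mature_name = c("mir-a-5p", "mir-a-5p"),
                        precursor_name = c("mir-a-1", "mir-a-2"), arm = "5p",
                        sequence = m, stringsAsFactors = FALSE)
  lib <- list(tags = data.frame(
    tag = c(m, substr(m, 1, 20), mutate_at(m, c(10, 15, 20)), mutate_at(m, 3)),
    count = c(5L, 2L, 7L, 9L), mapped = TRUE, annotation_excluded = FALSE,
    stringsAsFactors = FALSE))
  asg <- assign_reads_to_mirnas(lib, matures)
  expect_equal(nrow(asg), 1L)  # identical mature from 2 precursors: one record
  expect_equal(asg$precursors, "mir-a-1,mir-a-2")
  # exact tag + 3'-trimmed tag count; 3 non-seed mm and 1 seed mm do not
  expect_equal(asg$count, 5L + 2L)
  expect_equal(attr(asg, "reads_assigned"), 7L)
  expect_equal(attr(asg, "tags_assigned"), 2L)
})

test_that("expression call needs 10 reads total and 3 individuals", {
  expect_true(call_known_mirnas(matrix(c(3, 3, 3, 2), 1), 10, 3))
  expect_false(call_known_mirnas(matrix(c(10, 0, 0, 0), 1), 10, 3))
  expect_true(call_known_mirnas(matrix(c(4, 3, 3, 0), 1), 10, 3))
  expect_error(call_known_mirnas(matrix(c(10, 10), 1), 10, 3), "unsatisfiable")
})

test_that("TPM follows the clean-read normalisation formula", {
  expect_equal(unname(tpm(matrix(50), 1e7)[1, 1]), 5.0)
  expect_equal(unname(tpm(matrix(0), 1e7)[1, 1]), 0.0)
  m <- tpm(matrix(c(10, 20), 1), c(1e6, 2e6))
  expect_equal(unname(m[1, ]), c(10, 10))
  expect_equal(mean(m), 10)
  expect_error(tpm(matrix(1), 0), "positive")
})

test_that("noise-free libraries reproduce the simulator's truth counts exactly", {
  # plain intergenic/intronic loci and a hetero-seed cluster only: exonic
  # loci are excluded at annotation filtering by design, and homo-seed
  # paralogs share identical matures that are counted once per name
  cfg <- small_truth_config()
  cfg$n_by_context <- c(intergenic = 8L, intronic = 4L, exonic = 0L, UTR = 0L,
                        splice_site_overlapping = 0L)
  cfg$clusters <- list(list(n = 2L, seed_class = "hetero"))
  truth <- generate_truth_set(cfg, seed = 77L)
  specs <- library_specs(n_samples = 4L, n_reads = 4000L)
  for (i in seq_along(specs)) specs[[i]]$noise_fractions[] <- 0
  sim <- simulate_libraries(truth, specs, seed = 99L)
  for (s in names(sim$reads)) {
    flt <- qc_filter(sim$reads[[s]], specs[[1]]$adapter)
    expect_equal(unname(flt$tally), rep(0L, 4))  # every read is a clean tag
    lib <- collapse_and_map(flt$reads, truth$genome, s)
    lib <- classify_annotation(lib, truth$annotations)
    asg <- assign_reads_to_mirnas(lib, truth$matures)
    want <- sim$truth_counts[, s]
    got <- asg$count[match(names(want), asg$mature_name)]
    expect_equal(got, unname(want))
  }
})
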