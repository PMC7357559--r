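# Homology scan and the conserved-miRNA filter criteria.

test_that("percent identity counts matches over alignment columns", {
  a <- strrep("ACGTTGCAAC", 6)  # 60 nt
  expect_equal(percent_identity(a, a), 100)
  expect_equal(percent_identity(a, mutate_at(a, c(3, 17, 33, 50))),
               100 * 56 / 60, tolerance = 1e-9)  # 93.33, passes > 93
  expect_equal(percent_identity(a, mutate_at(a, c(3, 17, 33, 50, 58))),
               100 * 55 / 60, tolerance = 1e-9)  # 91.67, fails
  expect_error(percent_identity("", a), "empty")
  # U and T compare equal
  expect_equal(percent_identity(gsub("T", "U", a), a), 100)
})

test_that("mature mismatches split at the seed boundary (positions 2-8)", {
  m <- "ACGTACGTACGTACGTACGTAC"  # 22 nt
  expect_equal(mature_mismatches(m, m), c(seed = 0L, nonseed = 0L))
  expect_equal(mature_mismatches(m, mutate_at(m, 5)), c(seed = 1L, nonseed = 0L))
  expect_equal(mature_mismatches(m, mutate_at(m, c(1, 9, 22))),
               c(seed = 0L, nonseed = 3L))
  expect_error(mature_mismatches(m, substr(m, 1, 21)), "length")
})

test_that("scan finds planted precursors on both strands with correct similarity", {
  set.seed(7)
  pre <- rand_dna(60)
  ref <- ref_row("mir-p", pre, m5p = c(5, 26))
  genome <- plant_genome(c(chrA = 4000L, chrB = 3000L),
                         list(list(chrom = "chrA", at = 1501L, seq = pre, strand = "+"),
                              list(chrom = "chrB", at = 901L,
                                   seq = mutate_at(pre, c(10, 30, 50)), strand = "-")))
  hits <- scan_genome(genome, ref, k = 8)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_equal(plus$start, 1501L)
  expect_equal(plus$similarity, 100)
  expect_equal(plus$genome_subseq, pre)
  expect_equal(minus$start, 901L)
  expect_equal(minus$similarity, 100 * 57 / 60, tolerance = 1e-9)  # 95.0
  # minus-strand subseq is the reverse complement of the genome slice
  expect_equal(minus$genome_subseq,
               revcomp(substr(genome$sequence[genome$id == "chrB"], 901, 960)))
  expect_error(scan_genome(genome, ref, k = 70), "shortest precursor")
})

test_that("filter enforces the three criteria and one-reference-per-locus", {
  pre <- strrep("ACGTTGCAAC", 10)  # 100 nt
  ref <- rbind(ref_row("mir-a", pre, m5p = c(31, 52)),
               ref_row("mir-b", pre, m5p = c(31, 52)))
  mk_hit <- function(ref_name, start, subseq, sim) {
    data.frame(ref = ref_name, chrom = "chr1", start = start,
               end = start + nchar(subseq) - 1L, strand = "+",
               similarity = sim, genome_subseq = subseq, stringsAsFactors = FALSE)
  }
  # similarity exactly 93.0 (7 mismatches outside the mature) is rejected: > 93 is strict
  sub7 <- mutate_at(pre, c(1, 5, 10, 15, 60, 70, 80))
  out <- filter_candidates(mk_hit("mir-a", 1000, sub7, 93.0), ref)
  expect_equal(nrow(out), 0L)
  # 96 % with clean mature passes
  sub4 <- mutate_at(pre, c(1, 5, 60, 70))
  out <- filter_candidates(mk_hit("mir-a", 1000, sub4, 96.0), ref)
  expect_equal(nrow(out), 1L)
  expect_equal(out$seed_mm_5p, 0L)
  expect_equal(out$nonseed_mm_5p, 0L)
  expect_true(is.na(out$seed_mm_3p))
  # two references on one locus: highest similarity wins
  both <- rbind(mk_hit("mir-b", 1000, sub4, 98.0), mk_hit("mir-a", 1010, sub4, 95.0))
  out <- filter_candidates(both, ref)
  expect_equal(out$ref, "mir-b")
  # one reference, three disjoint loci: all kept (paralogs)
  par3 <- rbind(mk_hit("mir-a", 1000, sub4, 96), mk_hit("mir-a", 5000, sub4, 96),
                mk_hit("mir-a", 9000, sub4, 96))
  expect_equal(nrow(filter_candidates(par3, ref)), 3L)
  # mature-arm criteria: 2 seed mismatches reject, 3 non-seed reject
  seed2 <- mutate_at(pre, c(33, 35))     # mature positions 3 and 5
  expect_equal(nrow(filter_candidates(mk_hit("mir-a", 1000, seed2, 98), ref)), 0L)
  non3 <- mutate_at(pre, c(40, 45, 50))  # mature positions 10, 15, 20
  expect_equal(nrow(filter_candidates(mk_hit("mir-a", 1000, non3, 97), ref)), 0L)
})

test_that("scan equals the brute-force slide oracle on small genomes", {
  set.seed(11)
  for (case in 1:4) {
    pres <- replicate(3, rand_dna(sample(55:75, 1)))
    refs <- do.call(rbind, lapply(seq_along(pres), function(i)
      ref_row(sprintf("mir-o%d", i), pres[i], m5p = c(5, 26))))
    plants <- list(
      list(chrom = "g1", at = 2001L, seq = mutate_at(pres[1], sample(55, 3)), strand = "+"),
      list(chrom = "g1", at = 9001L, seq = mutate_at(pres[2], sample(55, 4)), strand = "-"),
      list(chrom = "g1", at = 15001L, seq = pres[3], strand = "+"))
    genome <- plant_genome(c(g1 = 20000L), plants)
    raw <- scan_genome(genome, refs, k = 8, merge = FALSE)
    oracle <- slide_scan_oracle(genome, refs)
    expect_equal(hit_key(raw), hit_key(oracle))
    expect_equal(sort(raw$similarity), sort(oracle$similarity), tolerance = 1e-9)
  }
})

test_that("raising the identity threshold never increases the candidate count", {
  set.seed(13)
  pre <- rand_dna(60)
  ref <- ref_row("mir-m", pre, m5p = c(5, 26))
  genome <- plant_genome(c(g = 12000L), list(
    list(chrom = "g", at = 1001L, seq = pre, strand = "+"),
    list(chrom = "g", at = 4001L, seq = mutate_at(pre, 1:3), strand = "+"),
    list(chrom = "g", at = 8001L, seq = mutate_at(pre, c(1, 11, 21, 31)), strand = "-")))
  hits <- scan_genome(genome, ref, k = 8)
  n_prev <- Inf
  for (thr in c(85, 90, 93, 95, 99)) {
    th <- homology_thresholds(); th$identity <- thr
    n <- nrow(filter_candidates(hits, ref, th))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("reverse-complementing the genome flips strands but preserves the candidate set", {
  set.seed(17)
  pre <- rand_dna(64)
  ref <- ref_row("mir-s", pre, m5p = c(6, 27))
  genome <- plant_genome(c(g = 9000L), list(
    list(chrom = "g", at = 1501L, seq = mutate_at(pre, c(2, 40)), strand = "+"),
    list(chrom = "g", at = 6001L, seq = mutate_at(pre, c(3, 33)), strand = "-")))
  L <- nchar(genome$sequence)
  flipped <- data.frame(id = "g", sequence = revcomp(genome$sequence),
                        stringsAsFactors = FALSE)
  a <- filter_candidates(scan_genome(genome, ref, k = 8), ref)
  b <- filter_candidates(scan_genome(flipped, ref, k = 8), ref)
  # map b back onto the original coordinates
  b_start <- L - b$end + 1L
  b_strand <- ifelse(b$strand == "+", "-", "+")
  expect_equal(sort(paste(a$start, a$strand)), sort(paste(b_start, b_strand)))
  expect_equal(sort(a$similarity), sort(b$similarity), tolerance = 1e-9)
  expect_equal(sort(a$genome_subseq), sort(b$genome_subseq))
})
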