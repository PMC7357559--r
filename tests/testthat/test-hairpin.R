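# Folding, stem-loop dissection and the structural acceptance criteria.

test_that("flank extraction extends, clips and reverse-complements", {
  set.seed(23)
  g <- data.frame(id = "c", sequence = rand_dna(100), stringsAsFactors = FALSE)
  mid <- list(chrom = "c", start = 30L, end = 49L, strand = "+")
  s <- extract_with_flanks(g, mid, flank = 10)
  expect_equal(nchar(s), 40L)
  expect_equal(attr(s, "flank5p"), 10L)
  expect_equal(as.character(s), gsub("T", "U", substr(g$sequence, 20, 59)))
  near <- list(chrom = "c", start = 4L, end = 23L, strand = "+")
  s2 <- extract_with_flanks(g, near, flank = 10)
  expect_equal(attr(s2, "flank5p"), 3L)  # clipped at the contig start
  expect_equal(attr(s2, "flank3p"), 10L)
  minus <- list(chrom = "c", start = 30L, end = 49L, strand = "-")
  s3 <- extract_with_flanks(g, minus, flank = 10)
  expect_equal(as.character(s3), gsub("T", "U", revcomp(substr(g$sequence, 20, 59))))
  expect_equal(attr(s3, "flank5p"), 10L)
  outside <- list(chrom = "c", start = 95L, end = 120L, strand = "+")
  expect_error(extract_with_flanks(g, outside), "outside")
})

test_that("folding is deterministic, bounded at zero and validates its input", {
  f <- fold_mfe("AAAAAAAAAA")
  expect_equal(f$structure, "..........")
  expect_equal(f$mfe, 0)
  expect_error(fold_mfe("ACGTXACGTT"), "alphabet")
  expect_error(fold_mfe("ACGU"), "shorter")
  # N is accepted and unpairable
  fn <- fold_mfe("GGGGGNAAAANCCCCC")
  expect_true(fn$mfe <= 0)
  # frozen regression value: 20-bp GC stem closed by a GAAA loop
  stem <- "GCGGCCGCGGCCGGCCGCGG"
  f2 <- fold_mfe(paste0(stem, "GAAA", revcomp(stem)))
  expect_equal(f2$mfe, -54.8, tolerance = 1e-9)
  expect_equal(f2$structure, paste0(strrep("(", 20), "....", strrep(")", 20)))
})

test_that("MFE equals exhaustive enumeration on short sequences", {
  set.seed(29)
  for (k in 1:25) {
    n <- sample(15:25, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    expect_equal(fold_mfe(seq)$mfe, oracle_mfe(seq), tolerance = 0.011,
                 label = seq)
  }
})

test_that("pair tables reject unbalanced or invalid structures", {
  expect_equal(pair_table("((..))"), c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_error(pair_table("(()"), "unbalanced")
  expect_error(pair_table("())"), "unbalanced")
  expect_error(pair_table("(.x)"), "invalid")
})

test_that("stem-loop dissection finds arms, loop and the largest bulge", {
  ft <- hairpin_features("((((....))))")
  expect_true(ft$is_hairpin)
  expect_equal(ft$arm5p, c(1L, 4L))
  expect_equal(ft$loop, c(5L, 8L))
  expect_equal(ft$arm3p, c(9L, 12L))
  expect_equal(ft$n_stem_pairs, 4L)
  expect_equal(ft$max_internal_bulge, 0L)

  ft2 <- hairpin_features("((((..((((....))))))))")
  expect_equal(ft2$max_internal_bulge, 2L)  # 2-nt loop on one side only
  expect_equal(ft2$n_stem_pairs, 8L)

  ft3 <- hairpin_features("((...))..((...))")  # two separate hairpins
  expect_false(ft3$is_hairpin)
  ft4 <- hairpin_features(paste0("(((", "((...))", ".", "((...))", ")))"))  # multibranch
  expect_false(ft4$is_hairpin)
  expect_error(hairpin_features("......"), "no stem")
  # asymmetric internal loop: larger side counts
  ft5 <- hairpin_features("(((...((((....))))..)))")
  expect_equal(ft5$max_internal_bulge, 3L)
})

test_that("structural criteria: mature in one arm, bulge < 6, MFE at most -15", {
  ft <- list(is_hairpin = TRUE, arm5p = c(1, 30), arm3p = c(45, 74),
             loop = c(31, 44), n_stem_pairs = 25L, max_internal_bulge = 5L)
  ok <- validate_hairpin(ft, mfe = -30, mature_spans = list(`5p` = c(5, 26)))
  expect_true(all(ok))
  # mature spanning the terminal loop fails criterion 1
  bad <- validate_hairpin(ft, mfe = -30, mature_spans = list(`5p` = c(25, 46)))
  expect_false(bad[["passes_mature_in_arm"]])
  # bulge boundary: 5 passes, 6 fails (strict n < 6)
  ft6 <- ft; ft6$max_internal_bulge <- 6L
  expect_false(validate_hairpin(ft6, -30, list(`5p` = c(5, 26)))[["passes_bulge"]])
  # MFE boundary: exactly -15 passes ("no more than -15")
  expect_true(validate_hairpin(ft, -15, list(`5p` = c(5, 26)))[["passes_mfe"]])
  expect_false(validate_hairpin(ft, -14.9, list(`5p` = c(5, 26)))[["passes_mfe"]])
  # non-hairpin structures cannot place the mature in an arm
  ftx <- list(is_hairpin = FALSE, arm5p = NULL, arm3p = NULL, loop = NULL,
              n_stem_pairs = 8L, max_internal_bulge = NA_integer_)
  expect_false(validate_hairpin(ftx, -30, list(`5p` = c(5, 26)))[["passes_mature_in_arm"]])
})

test_that("relaxing thresholds never un-passes a candidate", {
  set.seed(31)
  fts <- lapply(1:20, function(i)
    list(is_hairpin = TRUE, arm5p = c(1, 30), arm3p = c(45, 74),
         loop = c(31, 44), n_stem_pairs = 20L,
         max_internal_bulge = sample(0:8, 1)))
  mfes <- runif(20, -40, -5)
  strict <- list(mfe = -15, bulge = 6L, flank = 10L)
  loose <- list(mfe = -10, bulge = 8L, flank = 10L)
  for (i in 1:20) {
    a <- validate_hairpin(fts[[i]], mfes[i], list(`5p` = c(5, 26)), strict)
    b <- validate_hairpin(fts[[i]], mfes[i], list(`5p` = c(5, 26)), loose)
    expect_true(all(b[a]))  # passing under strict implies passing under loose
  }
})

test_that("validated loci inherit support evidence for the high-confidence call", {
  truth <- cached_small_truth()
  cand <- filter_candidates(scan_genome(truth$genome, truth$reference),
                            truth$reference)
  val <- validate_loci(truth$genome, cand, truth$reference)
  expect_true(all(val$mfe <= -15))
  expect_true(all(val$passes_mature_in_arm))
  # high confidence requires all three structural criteria plus support
  expect_equal(val$high_confidence,
               val$passes_mature_in_arm & val$passes_bulge & val$passes_mfe)
  # support held by construction in the synthetic reference
  expect_true(all(truth$reference$annotated_elsewhere))
})

test_that("dot-bracket output round-trips sequence, structure and energy", {
  f <- fold_mfe(c("GGGGCCCCGGGGAAAACCCC", "ACGUACGUACGUACGUACGU"), ids = c("a", "b"))
  p <- withr::local_tempfile(fileext = ".db")
  write_dotbracket(f, p)
  lines <- readLines(p)
  expect_equal(lines[1], ">a")
  expect_equal(lines[2], f$sequence[1])
  expect_match(lines[3], sprintf("(%.2f)", f$mfe[1]), fixed = TRUE)
})
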