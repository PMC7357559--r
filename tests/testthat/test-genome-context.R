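# Context classes, mirror pairs, clusters, seed classes, ages and the
# age-expression correlation.

make_ann <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(feature_class = r[[1]], chrom = r[[2]], start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), strand = r[[5]],
               gene_id = if (length(r) > 5) r[[6]] else NA_character_,
               stringsAsFactors = FALSE)))
}

test_that("context classes are mutually exclusive and follow containment rules", {
  ann <- make_ann(
    list("gene", "c1", 1000, 9000, "+", "g1"),
    list("exon", "c1", 1000, 1500, "+", "g1"),
    list("exon", "c1", 8500, 9000, "+", "g1"),
    list("gene", "c1", 20000, 26000, "+", "g2"),
    list("exon", "c1", 21000, 25000, "+", "g2"),
    list("UTR", "c1", 21000, 22000, "+", "g2"))
  loci <- genomic_interval("c1",
    start = c(3000, 1400, 21100, 23000, 50000),
    end = c(3070, 1560, 21170, 23070, 50070),
    strand = "+", name = paste0("L", 1:5))
  out <- classify_context(loci, ann)
  expect_equal(out$context, c("intronic", "splice_site_overlapping", "UTR",
                              "exonic", "intergenic"))
  expect_equal(out$host_gene[1], "g1")
  expect_true(is.na(out$host_gene[5]))
  # every locus gets exactly one class from the closed set
  expect_true(all(out$context %in% c("intergenic", "intronic", "exonic", "UTR",
                                     "splice_site_overlapping")))
})

test_that("mirror pairs require opposite strands and overlap", {
  loci <- genomic_interval("c1",
    start = c(100, 120, 300, 400, 600),
    end = c(180, 200, 380, 480, 680),
    strand = c("+", "-", "+", "+", "-"),
    name = c("a", "b", "c", "d", "e"))
  out <- find_mirror_pairs(loci)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$name1, out$name2), c("a", "b"))
  # same-strand overlap (c/d would need opposite strands) and adjacent
  # opposite-strand loci (d/e) do not pair
})

test_that("clusters chain same-strand neighbours within the gap threshold", {
  twoloci <- function(gap, strands = c("+", "+")) {
    genomic_interval("c1", start = c(1000, 1000 + 70 + gap),
                     end = c(1069, 1069 + 70 + gap), strand = strands,
                     name = c("x", "y"))
  }
  expect_equal(detect_clusters(twoloci(9999))$n_members, 2L)
  expect_equal(detect_clusters(twoloci(10000))$n_members, 2L)  # gap <= 10 kb
  expect_equal(nrow(detect_clusters(twoloci(10001))), 0L)
  expect_equal(nrow(detect_clusters(twoloci(9999, c("+", "-")))), 0L)
  # transitive chaining: A-B 8 kb, B-C 8 kb form one 3-member cluster
  chain <- genomic_interval("c1", start = c(1000, 9070, 17140),
                            end = c(1069, 9139, 17209), strand = "+",
                            name = c("A", "B", "C"))
  cl <- detect_clusters(chain)
  expect_equal(cl$n_members, 3L)
  expect_equal(cl$members, "A,B,C")
  expect_equal(cl$span, "c1:1000-17209+")
  expect_error(detect_clusters(rbind(chain, chain)), "duplicate")
})

test_that("cluster detection equals brute-force transitive closure and ignores input order", {
  set.seed(53)
  for (case in 1:30) {
    n <- sample(5:60, 1)
    loci <- genomic_interval(
      chrom = sample(paste0("c", 1:3), n, replace = TRUE),
      start = st <- sample.int(300000L, n),
      end = st + sample(50:120, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      name = sprintf("L%02d", 1:n))
    got <- cluster_sets(detect_clusters(loci))
    want <- brute_force_clusters(loci)
    expect_true(same_partition(got, want))
    shuf <- loci[sample(n), ]
    expect_true(same_partition(cluster_sets(detect_clusters(shuf)), want))
  }
})

test_that("seed classes compare the 7-nt seed across members", {
  seeds <- c(a = "GTAAACA", b = "GTAAACA", c = "ATAAACA")
  expect_equal(classify_cluster_seed(c("a", "b"), seeds), "homo")
  expect_equal(classify_cluster_seed(c("a", "c"), seeds), "hetero")
  expect_equal(classify_cluster_seed(c("a", "b", "c"), seeds), "hetero")
  expect_error(classify_cluster_seed(c("a", "z"), seeds), "z")
  # U/T never separates seeds
  expect_equal(classify_cluster_seed(c("a", "u"), c(seeds, u = "GUAAACA")), "homo")
})

test_that("dominant seed prefers the more abundant arm and falls back to 5p", {
  mat <- data.frame(precursor_name = c("m1", "m1", "m2"),
                    arm = c("5p", "3p", "5p"),
                    sequence = c("AAGTAAACATTTTTTTTTTTTT", "CCGTCCCCATTTTTTTTTTTTT",
                                 "GGGTTTTCATTTTTTTTTTTTT"),
                    mean_tpm = c(5, 50, 2), stringsAsFactors = FALSE)
  s <- dominant_seed(mat)
  expect_equal(unname(s["m1"]), "CGTCCCC")  # 3p wins on abundance
  mat$mean_tpm <- NULL
  s2 <- dominant_seed(mat)
  expect_equal(unname(s2["m1"]), "AGTAAAC")  # 5p fallback
})

test_that("age assignment takes the broadest clade of the homolog set", {
  expect_equal(assign_age(c("hsa", "mmu", "dre"))$category, "vertebrate")
  expect_equal(assign_age(c("hsa", "mmu", "dre"))$rank, 1L)
  expect_equal(assign_age(c("hsa", "mmu"))$category, "mammal")
  expect_equal(assign_age(c("hsa", "mml"))$category, "primate")
  expect_equal(assign_age("mfa,mml")$category, "cercopithecidae")
  expect_equal(assign_age("mfa,mml")$rank, 4L)
  expect_error(assign_age(c("hsa", "xyz")), "xyz")
})

test_that("age-expression correlation is a Spearman rank test with older coded higher", {
  # perfectly monotone, untied: oldest (rank 1) most expressed
  age <- 1:5
  expr <- c(100, 50, 10, 5, 1)
  r <- spearman_age_expression(age, expr)
  expect_equal(r$rho, 1.0)
  r2 <- spearman_age_expression(age, rev(expr))
  expect_equal(r2$rho, -1.0)
  # ties get average ranks: perfect ordering with tied ages stays below 1
  rt <- spearman_age_expression(c(1, 1, 2, 2, 3, 3, 4, 4),
                                c(100, 90, 50, 40, 10, 8, 2, 1))
  expect_lt(rt$rho, 1.0)
  expect_gt(rt$rho, 0.9)
  expect_error(spearman_age_expression(1:3, 1:3), "at least 4")
  # matches the rank-formula oracle and the t-approximation p-value
  set.seed(59)
  for (case in 1:20) {
    n <- sample(8:40, 1)
    a <- sample(1:4, n, replace = TRUE)
    e <- rlnorm(n)
    r <- spearman_age_expression(a, e)
    expect_equal(r$rho, rank_rho_oracle(5 - a, e), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(5 - a, e, method = "spearman", exact = FALSE))
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
  }
})
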