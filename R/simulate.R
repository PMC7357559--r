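# Synthetic ground truth: a toy genome with planted pre-miRNA hairpin loci
# (clusters, a mirror pair, intronic/exonic/UTR/splice-site placements), a
# diverged reference set, annotations, an age-structured expression model,
# and simulated multi-individual small RNA libraries.

#' Default configuration of the synthetic truth set
#'
#' The defaults emulate a blood small-RNA study in an Old World monkey:
#' four age classes with mean expression scaled 160:10:1 for
#' vertebrate:mammal:primate-conserved miRNAs (Cercopithecidae-specific
#' below primate), a locus mix dominated by intergenic and intronic
#' placements with a few exonic/UTR/splice-site-overlapping loci, two
#' clusters and one antisense mirror pair.
#'
#' @return list of generator settings; override fields as needed.
#' @export
truth_config <- function() {
  list(
    chrom_lengths = c(chr1 = 220000L, chr2 = 180000L, chr3 = 140000L),
    n_by_age = c(vertebrate = 6L, mammal = 7L, primate = 13L,
                 cercopithecidae = 4L),
    n_by_context = c(intergenic = 15L, intronic = 12L, exonic = 1L,
                     UTR = 1L, splice_site_overlapping = 1L),
    clusters = list(list(n = 3L, seed_class = "homo"),
                    list(n = 2L, seed_class = "hetero")),
    mirror_pairs = 1L,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    stem_len = 30L, loop_len = 11L, mature_len = 22L, stem_wobbles = 2L,
    ref_substitutions = 2L,
    expression_scale = c(vertebrate = 160, mammal = 10, primate = 1,
                         cercopithecidae = 0.3),
    arm_fraction_5p = 0.75,
    expression_jitter_sd = 0.25,
    species_pool = list(
      vertebrate = c("hsa", "mmu", "dre"),
      mammal = c("hsa", "mmu", "bta"),
      primate = c("hsa", "ptr"),
      cercopithecidae = c("mml", "mfa")),
    n_rrna = 2L, n_trna = 3L,
    unit_spacing = 12000L,
    cluster_gap_range = c(1500L, 6000L))
}

.rand_seq <- function(n, p = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Does a (possibly flank-extended) hairpin fold into a clean single stem
# with both matures inside the arms? Used for rejection sampling below.
.folds_clean <- function(seq, m5, m3, max_bulge = 5L) {
  f <- fold_mfe(seq)
  ft <- hairpin_features(f$structure)
  in_arm <- function(sp, arm) !is.null(arm) && sp[1] >= arm[1] && sp[2] <= arm[2]
  isTRUE(ft$is_hairpin) && ft$max_internal_bulge <= max_bulge &&
    (in_arm(m5, ft$arm5p) || in_arm(m5, ft$arm3p)) &&
    (in_arm(m3, ft$arm5p) || in_arm(m3, ft$arm3p)) && f$mfe <= -25
}

# A pre-miRNA hairpin: left arm, loop, right arm = revcomp(left) with
# `wobbles` substitutions. Matures sit inside the arms with a 2-nt offset
# between the duplex ends, as Dicer leaves. Rejection-sampled so (i) the
# minimum-free-energy structure of the bare precursor really is a single
# clean hairpin (random arms occasionally fold into branched structures)
# and (ii) no mature arm mimics the sequencing adapter, whose reads QC
# would rightly discard as adapter artefacts.
.make_hairpin <- function(stem_len, loop_len, mature_len, wobbles,
                          left_fixed = NULL,
                          adapter = "TGGAATTCTCGGGTGCCAAGG") {
  P <- 2L * stem_len + loop_len
  m5 <- c(5L, 5L + mature_len - 1L)
  m3 <- c(P - m5[2] + 1L - 2L, P - m5[1] + 1L - 2L)
  for (try in 1:50) {
    left <- if (is.null(left_fixed)) .rand_seq(stem_len, p = c(A = .2, C = .3, G = .3, T = .2))
            else left_fixed
    loop <- .rand_seq(loop_len, p = c(A = .5, C = .5))  # A/C loop cannot self-pair
    right <- revcomp(left)
    if (wobbles > 0L) {
      seed3 <- (m3[1] + 1L):(m3[1] + 7L)  # keep the 3p seed intact
      pool <- setdiff((stem_len + loop_len + 1L):P, seed3)
      pos <- sample(pool, wobbles)
      ch <- .chars(right)
      for (p in pos) {
        i <- p - stem_len - loop_len
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      }
      right <- paste(ch, collapse = "")
    }
    pre <- paste0(left, loop, right)
    mats <- c(substr(pre, m5[1], m5[2]), substr(pre, m3[1], m3[2]))
    adapter_free <- all(is.na(.adapter_start(c(mats, revcomp(mats)), adapter,
                                             2L, 6L, 0.1)))
    if (adapter_free && .folds_clean(pre, m5, m3, max_bulge = 3L))
      return(list(precursor = pre, m5p = m5, m3p = m3))
  }
  .stopf("could not sample a cleanly folding hairpin in 50 tries")
}

# substitute n positions of `seq`, avoiding `avoid` (1-based positions)
.substitute <- function(seq, n, avoid = integer(0)) {
  ch <- .chars(seq)
  pool <- setdiff(seq_along(ch), avoid)
  pos <- sample(pool, n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic truth set
#'
#' Plants hairpin pre-miRNA loci in a random genome so that every planted
#' precursor is retrievable verbatim from its interval (reverse-complemented
#' on the minus strand), cluster members share a strand with inter-locus
#' gaps at most 10 kb, the mirror pair overlaps on opposite strands, and
#' each locus carries an age category with an expression weight ordered
#' vertebrate > mammal > primate > cercopithecidae. The reference set is
#' the planted precursors diverged by `ref_substitutions` substitutions
#' outside the mature seeds. Deterministic given `seed`.
#'
#' @param config list from [truth_config()].
#' @param seed integer RNG seed governing all draws.
#' @return list: `genome` (data.frame id/sequence), `annotations`,
#'   `reference` (diverged homolog set), `loci` (planted intervals with age,
#'   context, cluster id, mirror partner, expression weight), `matures`
#'   (genome-true mature table), `config`, `seed`.
#' @export
generate_truth_set <- function(config = truth_config(), seed = 1455L) {
  set.seed(seed)
  cfg <- config
  n <- sum(cfg$n_by_age)
  if (sum(cfg$n_by_context) != n)
    .stopf("context counts (%d) must sum to the age counts (%d)",
           sum(cfg$n_by_context), n)
  n_cluster_members <- sum(vapply(cfg$clusters, `[[`, 0L, "n"))
  n_mirror <- 2L * cfg$mirror_pairs
  ages <- sample(rep(names(cfg$n_by_age), cfg$n_by_age))
  contexts <- rep(names(cfg$n_by_context), cfg$n_by_context)
  # cluster members and mirror loci need plain intergenic/intronic context
  plain <- which(contexts %in% c("intergenic", "intronic"))
  if (length(plain) < n_cluster_members + n_mirror)
    .stopf("not enough intergenic/intronic loci for clusters and mirror pairs")
  loci <- data.frame(name = sprintf("mir-s%02d", seq_len(n)),
                     age_category = ages, context = contexts,
                     cluster_id = NA_character_, mirror_partner = NA_character_,
                     stringsAsFactors = FALSE)
  take <- plain
  # layout units: each unit is placed >= unit_spacing from the previous
  units <- list(); ui <- 0L
  for (k in seq_along(cfg$clusters)) {
    idx <- take[seq_len(cfg$clusters[[k]]$n)]; take <- take[-seq_len(cfg$clusters[[k]]$n)]
    loci$cluster_id[idx] <- sprintf("tcluster%d", k)
    ui <- ui + 1L
    units[[ui]] <- list(type = "cluster", idx = idx,
                        seed_class = cfg$clusters[[k]]$seed_class)
  }
  for (k in seq_len(cfg$mirror_pairs)) {
    idx <- take[1:2]; take <- take[-(1:2)]
    loci$mirror_partner[idx[1]] <- loci$name[idx[2]]
    loci$mirror_partner[idx[2]] <- loci$name[idx[1]]
    ui <- ui + 1L
    units[[ui]] <- list(type = "mirror", idx = idx)
  }
  for (i in setdiff(seq_len(n), unlist(lapply(units, `[[`, "idx")))) {
    ui <- ui + 1L
    units[[ui]] <- list(type = "single", idx = i)
  }
  units <- sample(units)
  # sequences: hairpins per locus (mirror partners derive from the genome)
  P <- 2L * cfg$stem_len + cfg$loop_len
  hp <- vector("list", n)
  # seeds of homo-clusters must agree: reuse the first member's hairpin arms
  for (u in units) {
    if (u$type == "cluster" && identical(u$seed_class, "homo")) {
      # members share the left arm (hence the 5p mature and its seed), as
      # local duplications do; loops and right-arm wobbles are fresh
      base <- .make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len, cfg$stem_wobbles,
                            adapter = cfg$adapter)
      hp[[u$idx[1]]] <- base
      base_left <- substr(base$precursor, 1L, cfg$stem_len)
      for (j in seq_along(u$idx)[-1]) {
        hp[[u$idx[j]]] <- .make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len,
                                        cfg$stem_wobbles, left_fixed = base_left,
                                        adapter = cfg$adapter)
      }
    } else if (u$type == "mirror") {
      hp[[u$idx[1]]] <- .make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len, 0L,
                                      adapter = cfg$adapter)
      # partner filled in after genome assembly
    } else if (u$type == "single" || u$type == "cluster") {
      for (i in u$idx) {
        if (is.null(hp[[i]]))
          hp[[i]] <- .make_hairpin(cfg$stem_len, cfg$loop_len, cfg$mature_len,
                                   cfg$stem_wobbles, adapter = cfg$adapter)
      }
    }
  }
  # placement
  chroms <- names(cfg$chrom_lengths)
  cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
  loci$chrom <- NA_character_; loci$start <- NA_integer_
  loci$end <- NA_integer_; loci$strand <- NA_character_
  place <- function(unit) {
    need <- if (unit$type == "cluster")
      length(unit$idx) * (P + max(cfg$cluster_gap_range)) else P
    ok <- chroms[cursor[chroms] + cfg$unit_spacing + need + 1000L <=
                   cfg$chrom_lengths[chroms]]
    if (length(ok) == 0L)
      .stopf("genome too small to place the requested loci without overlap")
    ch <- if (length(ok) == 1L) ok else sample(ok, 1L)
    at <- cursor[ch] + cfg$unit_spacing + sample.int(2000L, 1L)
    list(chrom = ch, at = as.integer(at))
  }
  for (u in units) {
    p <- place(u)
    if (u$type == "cluster") {
      strand <- sample(c("+", "-"), 1L)
      at <- p$at
      for (i in u$idx) {
        loci$chrom[i] <- p$chrom; loci$start[i] <- at; loci$end[i] <- at + P - 1L
        loci$strand[i] <- strand
        at <- at + P + sample(seq(cfg$cluster_gap_range[1], cfg$cluster_gap_range[2]), 1L)
      }
      cursor[p$chrom] <- max(loci$end[u$idx])
    } else if (u$type == "mirror") {
      i1 <- u$idx[1]; i2 <- u$idx[2]
      loci$chrom[c(i1, i2)] <- p$chrom
      loci$start[c(i1, i2)] <- p$at; loci$end[c(i1, i2)] <- p$at + P - 1L
      loci$strand[i1] <- "+"; loci$strand[i2] <- "-"
      cursor[p$chrom] <- p$at + P - 1L
    } else {
      i <- u$idx
      loci$chrom[i] <- p$chrom; loci$start[i] <- p$at; loci$end[i] <- p$at + P - 1L
      loci$strand[i] <- sample(c("+", "-"), 1L)
      cursor[p$chrom] <- p$at + P - 1L
    }
  }
  # genome assembly
  genome_seq <- vapply(chroms, function(ch) .rand_seq(cfg$chrom_lengths[[ch]]), "")
  for (i in seq_len(n)) {
    if (is.null(hp[[i]])) next  # mirror partner: genome already carries it
    slice <- if (loci$strand[i] == "+") hp[[i]]$precursor else revcomp(hp[[i]]$precursor)
    substr(genome_seq[loci$chrom[i]], loci$start[i], loci$end[i]) <- slice
  }
  # mirror partners read their precursor off the (now final) genome
  for (i in which(!is.na(loci$mirror_partner))) {
    if (!is.null(hp[[i]])) next
    slice <- substr(genome_seq[loci$chrom[i]], loci$start[i], loci$end[i])
    pre <- if (loci$strand[i] == "+") slice else revcomp(slice)
    j <- match(loci$mirror_partner[i], loci$name)
    hp[[i]] <- list(precursor = pre,
                    m5p = c(P - hp[[j]]$m3p[2] + 1L, P - hp[[j]]$m3p[1] + 1L),
                    m3p = c(P - hp[[j]]$m5p[2] + 1L, P - hp[[j]]$m5p[1] + 1L))
  }
  # flank check: the 10-nt genomic context folded with each locus must not
  # disturb the hairpin (random flanks occasionally form outer helices with
  # large internal loops); resample offending flank bases
  genome_df <- function() data.frame(id = chroms, sequence = unname(genome_seq),
                                     stringsAsFactors = FALSE)
  locus_clean <- function(i) {
    s <- extract_with_flanks(genome_df(), loci[i, ], flank = 10L)
    f5 <- attr(s, "flank5p")
    .folds_clean(as.character(s), hp[[i]]$m5p + f5, hp[[i]]$m3p + f5)
  }
  for (u in units) {
    idx <- u$idx
    if (anyNA(idx)) next
    for (try in 1:50) {
      if (all(vapply(idx, locus_clean, TRUE))) break
      if (try == 50L) .stopf("could not sample clean flanks for locus %s",
                             paste(loci$name[idx], collapse = ","))
      ch <- loci$chrom[idx[1]]
      a <- min(loci$start[idx]); b <- max(loci$end[idx])
      substr(genome_seq[ch], max(1L, a - 10L), a - 1L) <- .rand_seq(min(10L, a - 1L))
      substr(genome_seq[ch], b + 1L, b + 10L) <- .rand_seq(10L)
      if (u$type == "cluster" && length(idx) > 1L) {
        for (i in idx[-1]) {  # inner flanks of cluster members
          s0 <- loci$start[i]
          substr(genome_seq[ch], s0 - 10L, s0 - 1L) <- .rand_seq(10L)
        }
        for (i in idx[-length(idx)]) {
          e0 <- loci$end[i]
          substr(genome_seq[ch], e0 + 1L, e0 + 10L) <- .rand_seq(10L)
        }
      }
    }
  }
  genome <- genome_df()
  # annotations
  ann <- list(); ai <- 0L
  add <- function(fc, ch, s, e, strand, gid) {
    ai <<- ai + 1L
    ann[[ai]] <<- data.frame(feature_class = fc, chrom = ch, start = as.integer(s),
                             end = as.integer(e), strand = strand, gene_id = gid,
                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    s <- loci$start[i]; e <- loci$end[i]; ch <- loci$chrom[i]; st <- loci$strand[i]
    gid <- paste0("gene_", loci$name[i])
    ctx <- loci$context[i]
    if (ctx == "intronic") {
      add("gene", ch, s - 1200L, e + 1200L, st, gid)
      add("exon", ch, s - 1200L, s - 900L, st, gid)
      add("exon", ch, e + 900L, e + 1200L, st, gid)
    } else if (ctx == "exonic") {
      add("gene", ch, s - 800L, e + 800L, st, gid)
      add("exon", ch, s - 100L, e + 100L, st, gid)
    } else if (ctx == "UTR") {
      add("gene", ch, s - 800L, e + 800L, st, gid)
      add("exon", ch, s - 100L, e + 100L, st, gid)
      add("UTR", ch, s - 100L, e + 100L, st, gid)
    } else if (ctx == "splice_site_overlapping") {
      add("gene", ch, s - 1000L, e + 1000L, st, gid)
      add("exon", ch, s + 40L, e + 500L, st, gid)
    }
  }
  for (k in seq_len(cfg$n_rrna)) {
    p <- place(list(type = "single", idx = NA))
    add("rRNA", p$chrom, p$at, p$at + 500L, "+", sprintf("rrna%d", k))
    cursor[p$chrom] <- p$at + 500L
  }
  for (k in seq_len(cfg$n_trna)) {
    p <- place(list(type = "single", idx = NA))
    add("tRNA", p$chrom, p$at, p$at + 80L, "+", sprintf("trna%d", k))
    cursor[p$chrom] <- p$at + 80L
  }
  annotations <- do.call(rbind, ann)
  # reference set: diverged homologs with support flags and species sets
  ref <- data.frame(name = loci$name, stringsAsFactors = FALSE)
  ref$species <- vapply(loci$age_category, function(a)
    paste(cfg$species_pool[[a]], collapse = ","), "")
  avoid_for <- function(h) c(h$m5p[1] + 1L:7L, h$m3p[1] + 1L:7L)
  ref$precursor <- vapply(seq_len(n), function(i)
    .substitute(hp[[i]]$precursor, cfg$ref_substitutions, avoid_for(hp[[i]])), "")
  ref$m5p_start <- vapply(hp, function(h) h$m5p[1], 0L)
  ref$m5p_end <- vapply(hp, function(h) h$m5p[2], 0L)
  ref$m3p_start <- vapply(hp, function(h) h$m3p[1], 0L)
  ref$m3p_end <- vapply(hp, function(h) h$m3p[2], 0L)
  ref$mature5p <- substr(ref$precursor, ref$m5p_start, ref$m5p_end)
  ref$mature3p <- substr(ref$precursor, ref$m3p_start, ref$m3p_end)
  ref$annotated_elsewhere <- TRUE
  ref$experimentally_supported <- stats::runif(n) < 0.5
  ref$previously_reported <- stats::runif(n) < 0.3
  # genome-true matures (what the sequenced tags are copies of)
  matures <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- hp[[i]]
    data.frame(mature_name = paste0(loci$name[i], c("-5p", "-3p")),
               precursor_name = loci$name[i], arm = c("5p", "3p"),
               sequence = c(substr(h$precursor, h$m5p[1], h$m5p[2]),
                            substr(h$precursor, h$m3p[1], h$m3p[2])),
               start = c(h$m5p[1], h$m3p[1]), end = c(h$m5p[2], h$m3p[2]),
               stringsAsFactors = FALSE)
  }))
  # expression model: age-scaled weight with mild lognormal jitter
  loci$expression_weight <- cfg$expression_scale[loci$age_category] *
    exp(stats::rnorm(n, 0, cfg$expression_jitter_sd))
  list(genome = genome, annotations = annotations, reference = ref,
       loci = loci[, c("name", "chrom", "start", "end", "strand", "age_category",
                       "context", "cluster_id", "mirror_partner",
                       "expression_weight")],
       matures = matures, config = cfg, seed = seed)
}

#' Default per-library simulation settings
#'
#' @param n_samples number of individuals.
#' @param n_reads reads per library.
#' @return list of library specs: sample id, read count, fixed read length,
#'   3' adapter, and noise fractions (adapter dimers, high-N, low-quality,
#'   short inserts, structural rRNA/tRNA fragments); the remainder of each
#'   library is mature-miRNA tags.
#' @export
library_specs <- function(n_samples = 4L, n_reads = 100000L) {
  lapply(seq_len(n_samples), function(s) {
    list(sample_id = sprintf("S%02d", s), n_reads = as.integer(n_reads),
         read_length = 36L, adapter = "TGGAATTCTCGGGTGCCAAGG",
         noise_fractions = c(adapter = 0.04, high_n = 0.02, low_quality = 0.04,
                             short = 0.05, structural = 0.10),
         nb_dispersion = 0.2)
  })
}

#' Simulate small RNA libraries from a truth set
#'
#' Mature-miRNA reads are exact genomic copies of the planted mature arms;
#' per-sample counts are negative-binomially distributed around the locus
#' expression weights. Noise reads cover the four QC-removable classes
#' (adapter dimers, >10 % N, >50 % low-quality bases, <18 nt inserts) plus
#' rRNA/tRNA fragments that survive QC but are excluded at annotation
#' filtering. Reads are fixed-length with the 3' adapter filling the tail.
#'
#' @param truth list from [generate_truth_set()].
#' @param specs list from [library_specs()].
#' @param seed RNG seed.
#' @return list: `reads` (named list of per-sample data.frames with id,
#'   sequence, quality), `truth_counts` (emitted mature-tag counts, matures
#'   with all-zero rows dropped), `specs`.
#' @export
simulate_libraries <- function(truth, specs = library_specs(), seed = 1455L) {
  set.seed(seed + 1L)
  cfg <- truth$config
  mat <- truth$matures
  if (any(nchar(mat$sequence) < 18L | nchar(mat$sequence) > 30L))
    .stopf("mature tag length outside 18-30 nt")
  w <- truth$loci$expression_weight[match(mat$precursor_name, truth$loci$name)]
  w <- w * ifelse(mat$arm == "5p", cfg$arm_fraction_5p, 1 - cfg$arm_fraction_5p)
  w <- w / sum(w)
  feat <- truth$annotations[truth$annotations$feature_class %in% c("rRNA", "tRNA"), ]
  out <- list(); counts <- NULL
  for (sp in specs) {
    nf <- sp$noise_fractions
    if (sum(nf) >= 1) .stopf("noise fractions must sum to < 1")
    n_noise <- round(nf * sp$n_reads)
    n_mir <- sp$n_reads - sum(n_noise)
    cnt <- stats::rnbinom(nrow(mat), mu = w * n_mir, size = 1 / sp$nb_dispersion)
    finish <- function(ins, qual_ins = NULL) {
      if (length(ins) == 0L)
        return(list(seq = character(0), qual = character(0)))
      L <- sp$read_length
      seqs <- substr(paste0(ins, sp$adapter,
                            strrep("A", L)), 1L, L)
      qual <- if (is.null(qual_ins)) rep(strrep("I", L), length(ins)) else
        substr(paste0(qual_ins, strrep("I", L)), 1L, L)
      list(seq = seqs, qual = qual)
    }
    reads <- list()
    reads$mir <- finish(rep(mat$sequence, cnt))
    reads$adapter <- finish(rep("", n_noise[["adapter"]]))
    hi <- vapply(seq_len(n_noise[["high_n"]]), function(k) {
      s <- .chars(.rand_seq(22L)); s[sample(22L, 7L)] <- "N"; paste(s, collapse = "")
    }, "")
    reads$high_n <- finish(hi)
    lq <- vapply(seq_len(n_noise[["low_quality"]]), function(k) .rand_seq(22L), "")
    lq_qual <- vapply(seq_len(n_noise[["low_quality"]]), function(k) {
      q <- rep("I", 22L); q[sample(22L, 14L)] <- "#"; paste(q, collapse = "")
    }, "")
    reads$low_quality <- finish(lq, lq_qual)
    sh <- vapply(seq_len(n_noise[["short"]]), function(k)
      .rand_seq(sample(12:17, 1L)), "")
    reads$short <- finish(sh)
    nst <- n_noise[["structural"]]
    fi <- sample(nrow(feat), nst, replace = TRUE)
    len <- sample(19:28, nst, replace = TRUE)
    s0 <- feat$start[fi] +
      floor(stats::runif(nst) * (feat$end[fi] - feat$start[fi] - len + 2L))
    chrom_seq <- truth$genome$sequence[match(feat$chrom[fi], truth$genome$id)]
    fr <- substr(chrom_seq, s0, s0 + len - 1L)
    flip <- stats::runif(nst) < 0.5
    if (any(flip)) fr[flip] <- revcomp(fr[flip])
    reads$structural <- finish(fr)
    seqs <- unlist(lapply(reads, `[[`, "seq"), use.names = FALSE)
    qual <- unlist(lapply(reads, `[[`, "qual"), use.names = FALSE)
    ord <- sample(length(seqs))
    out[[sp$sample_id]] <- data.frame(
      id = sprintf("%s_r%06d", sp$sample_id, seq_along(seqs)),
      sequence = seqs[ord], quality = qual[ord], stringsAsFactors = FALSE)
    counts <- cbind(counts, cnt)
  }
  colnames(counts) <- vapply(specs, `[[`, "", "sample_id")
  rownames(counts) <- mat$mature_name
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  list(reads = out, truth_counts = counts, specs = specs)
}

#' Write a truth set and simulated libraries to disk
#'
#' Writes genome.fa, annotations.gff3, reference.fa, loci.tsv,
#' sample FASTQ files and the truth count table.
#'
#' @param truth list from [generate_truth_set()].
#' @param sim optional list from [simulate_libraries()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_set <- function(truth, sim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_gff3(truth$annotations, file.path(dir, "annotations.gff3"))
  write_reference_set(truth$reference, file.path(dir, "reference.fa"))
  utils::write.table(truth$loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim)) {
    for (s in names(sim$reads))
      write_fastq(sim$reads[[s]], file.path(dir, paste0(s, ".fastq.gz")))
    utils::write.table(data.frame(mature_name = rownames(sim$truth_counts),
                                  sim$truth_counts, check.names = FALSE),
                       file.path(dir, "truth_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
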