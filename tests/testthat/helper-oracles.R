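# Independent oracles used by the property-style tests. These deliberately
# re-derive results by brute force (exhaustive enumeration, full sliding,
# all-pairs closure) rather than reusing the package's search strategies.

# All non-crossing secondary structures of a short RNA: canonical pairs
# only, hairpin loops of at least 3 nt. Memoised interval recursion.
enumerate_structures <- function(seq) {
  s <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  canpair <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- paste0(".", rec(i + 1L, j))
    k0 <- i + 4L
    if (k0 <= j) {
      for (k in k0:j) {
        if (canpair(s[i], s[k])) {
          inner <- rec(i + 1L, k - 1L)
          rest <- rec(k + 1L, j)
          out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest, paste0)))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  if (n < 6L) return(strrep(".", n))
  rec(1L, n)
}

# MFE by exhaustive enumeration: minimum energy over every structure,
# scored with the same energy rules as fold_mfe().
oracle_mfe <- function(seq) {
  st <- enumerate_structures(seq)
  min(eval_structure_energy(seq, st))
}

# cluster partition by brute force: all-pairs within-gap same-strand
# relation, then transitive closure via union-find
brute_force_clusters <- function(loci, max_gap = 10000L) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (loci$chrom[i] != loci$chrom[j] || loci$strand[i] != loci$strand[j]) next
    gap <- max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j]) - 1L
    if (gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(loci$name, comp)
  sets <- Filter(function(g) length(g) >= 2L, groups)
  unname(lapply(sets, function(g) sort(g)))
}

# full-slide homology oracle: banded identity of every window start on
# both strands, thresholded at the floor
slide_scan_oracle <- function(genome, reference, floor_identity = 85, band = 3L) {
  rows <- list(); k <- 0L
  for (ci in seq_len(nrow(genome))) {
    contig <- norm_seq(genome$sequence[ci])
    for (ri in seq_len(nrow(reference))) {
      pre <- norm_seq(reference$precursor[ri])
      if (nchar(pre) > nchar(contig)) next
      for (strand in c("+", "-")) {
        query <- if (strand == "+") pre else revcomp(pre)
        ident <- mirhom:::slide_banded_identity_cpp(query, contig, band)
        hit <- which(ident >= floor_identity)
        for (s in hit) {
          k <- k + 1L
          rows[[k]] <- data.frame(ref = reference$name[ri],
                                  chrom = genome$id[ci], start = s,
                                  strand = strand,
                                  similarity = ident[s],
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L) return(data.frame(ref = character(0), chrom = character(0),
                                 start = integer(0), strand = character(0),
                                 similarity = numeric(0)))
  do.call(rbind, rows)
}

# Spearman rho from first principles (average ranks + Pearson formula)
rank_rho_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

hit_key <- function(df) sort(paste(df$ref, df$chrom, df$start, df$strand))

cluster_sets <- function(clusters) {
  unname(lapply(strsplit(clusters$members, ","), sort))
}

same_partition <- function(a, b) {
  length(a) == length(b) &&
    setequal(vapply(a, paste, "", collapse = "|"),
             vapply(b, paste, "", collapse = "|"))
}
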