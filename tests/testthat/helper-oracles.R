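# Independent brute-force oracles and small fixtures, built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# small genome specification used across module tests
tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 3L, chrom_length = 1e5L, n_mirna_loci = 40L,
         n_pirna_clusters = 25L, n_trna_genes = 80L, n_repeat_elements = 40L,
         n_exons = 50L,
         feature_lengths = c(mirna = 80L, pirna_cluster = 1200L, trna = 75L,
                             `repeat` = 300L, exon = 400L),
         seed = seed),
    list(...)
  )
  do.call(genome_spec, args)
}

make_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                             min_w = 5L, max_w = 60L) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  st <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = st, end = st + w - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# O(n^2) fixed-point pairwise merging of same-strand intervals with gap
# tolerance (1-based closed coordinates; bases-between <= max_gap merges).
brute_merge <- function(df, max_gap) {
  repeat {
    merged <- FALSE
    i <- 1L
    while (i <= nrow(df)) {
      j <- i + 1L
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j] && df$strand[i] == df$strand[j]) {
          gap <- max(df$start[i], df$start[j]) -
            min(df$end[i], df$end[j]) - 1L
          if (gap <= max_gap) {
            df$start[i] <- min(df$start[i], df$start[j])
            df$end[i] <- max(df$end[i], df$end[j])
            df <- df[-j, , drop = FALSE]
            merged <- TRUE
            next
          }
        }
        j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  df[order(df$chrom, df$strand, df$start, df$end), , drop = FALSE]
}

# exhaustive all-vs-all interval intersection
brute_intersect <- function(q, s, strandedness = "ignore") {
  out <- list()
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] != s$chrom[j]) next
      if (strandedness == "same" && q$strand[i] != s$strand[j]) next
      if (strandedness == "opposite" && q$strand[i] == s$strand[j]) next
      if (q$start[i] <= s$end[j] && s$start[j] <= q$end[i]) {
        out[[length(out) + 1L]] <- data.frame(
          query_idx = i, subject_idx = j,
          overlap_width = min(q$end[i], s$end[j]) -
            max(q$start[i], s$start[j]) + 1L)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_idx = integer(0), subject_idx = integer(0),
                      overlap_width = integer(0)))
  }
  do.call(rbind, out)
}

# scalar all-pairs overlap counting
brute_count <- function(features, aln) {
  counts <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(aln))) {
      if (features$chrom[i] == aln$chrom[j] &&
          features$start[i] <= aln$end[j] &&
          aln$start[j] <= features$end[i]) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# exhaustive complete-linkage agglomeration; returns merge heights and the
# partition (list of index sets) after each merge
brute_complete_linkage <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical string signature of a partition (list of integer vectors)
partition_signature <- function(parts) {
  paste(sort(vapply(parts, function(p) paste(sort(p), collapse = ","),
                    character(1))), collapse = ";")
}

# partition of an hclust tree after m merges
hclust_partition <- function(hc, m) {
  k <- length(hc$order) - m
  ct <- cutree(hc, k = k)
  unname(split(seq_along(ct), ct))
}

# direct exhaustive summation for the exact conditioned NB test
brute_nbinom_p <- function(kA, kB, muA, sizeA, muB, sizeB) {
  K <- kA + kB
  ps <- numeric(K + 1L)
  for (a in 0:K) {
    ps[a + 1L] <- dnbinom(a, mu = muA, size = sizeA) *
      dnbinom(K - a, mu = muB, size = sizeB)
  }
  pobs <- ps[kA + 1L]
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]) / sum(ps))
}

# textbook BH step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
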