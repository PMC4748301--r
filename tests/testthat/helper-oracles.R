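# Independent brute-force oracles used to validate the implementations.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# regex-based six-frame ORF scan, independent of the package's codon-index
# implementation; internal codons may contain N, start/stop may not
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  frames <- list(`+1` = substring(s, 1), `+2` = substring(s, 2),
                 `+3` = substring(s, 3), `-1` = substring(rc, 1),
                 `-2` = substring(rc, 2), `-3` = substring(rc, 3))
  best_aa <- 0L
  best_frame <- NA_character_
  pat <- "^ATG(?:(?!TAA|TAG|TGA)[ACGTN]{3})*?(?:TAA|TAG|TGA)"
  for (fr in names(frames)) {
    fs <- frames[[fr]]
    starts <- as.integer(gregexpr("ATG", fs, fixed = TRUE)[[1]])
    starts <- starts[starts > 0 & (starts - 1) %% 3 == 0]  # frame-aligned
    fr_best <- 0L
    for (st in starts) {
      m <- regexpr(pat, substring(fs, st), perl = TRUE)
      if (m[1] == 1) {
        fr_best <- max(fr_best,
                       as.integer(attr(m, "match.length") / 3 - 1))
      }
    }
    if (fr_best > best_aa) {
      best_aa <- fr_best
      best_frame <- fr
    }
  }
  list(longest_orf_aa = best_aa, frame = best_frame)
}

# O(n^3) triple-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        tom[i, j] <- 1
        next
      }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
      }
      tom[i, j] <- (l + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j])
    }
  }
  tom
}

# exact term-by-term hypergeometric upper tail via binomial coefficients
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# rank-Pearson Spearman oracle
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# empirical-CDF sup-difference oracle for the two-sample KS statistic
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  f1 <- vapply(grid, function(g) mean(x <= g), numeric(1))
  f2 <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(f1 - f2))
}

# single-exon transcript helper
tx_list <- function(...) {
  items <- list(...)
  GenomicRanges::GRangesList(lapply(items, function(it) {
    GenomicRanges::GRanges(it$chrom %||% "chr1",
                           IRanges::IRanges(it$start, it$end),
                           strand = it$strand %||% "*")
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
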