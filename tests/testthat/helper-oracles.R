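# Independent brute-force oracles and shared fixtures, kept deliberately
# naive (double loops) so they cannot share a defect with the vectorised
# implementations they check.

small_genome <- function(n_chrom = 2, len = 100, bin_size = 50e3) {
  genome_spec(stats::setNames(rep(as.integer(len), n_chrom),
                              paste0("chr", seq_len(n_chrom))), bin_size)
}

default_genome <- function() {
  genome_spec(stats::setNames(rep(400L, 10), paste0("chr", 1:10)), 50e3)
}

# per-diagonal mean of unmasked entries, no pooling
brute_expected <- function(mat) {
  m <- mat$mat
  n <- nrow(m)
  sums <- rep(0, n - 1); cnts <- rep(0, n - 1)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(m[i, j])) {
      d <- j - i
      sums[d] <- sums[d] + m[i, j]
      cnts[d] <- cnts[d] + 1
    }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

# saddle sums/counts by explicit double loop over all cis pairs
brute_saddle <- function(oe_list, labels, min_dist, max_dist = Inf) {
  Q <- attr(labels, "n_quantiles")
  g <- labels$genome
  sums <- matrix(0, Q, Q); cnts <- matrix(0, Q, Q)
  for (m in oe_list) {
    lab <- labels$values[chrom_slice(g, m$chrom)]
    n <- nrow(m$mat)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- m$mat[i, j]
      dbp <- (j - i) * m$bin_size
      if (is.na(v) || is.na(lab[i]) || is.na(lab[j])) next
      if (dbp < min_dist || dbp > max_dist) next
      p <- lab[i]; q <- lab[j]
      sums[p, q] <- sums[p, q] + v; cnts[p, q] <- cnts[p, q] + 1
      sums[q, p] <- sums[q, p] + v; cnts[q, p] <- cnts[q, p] + 1
    }
  }
  list(saddle = ifelse(cnts > 0, sums / cnts, NA_real_), pair_counts = cnts)
}

# corner strength by explicit averaging over raw pair values
brute_corner_strength <- function(oe_list, labels, corner_fraction = 0.2,
                                  min_dist = NULL) {
  Q <- attr(labels, "n_quantiles")
  if (is.null(min_dist)) min_dist <- 2 * oe_list[[1]]$bin_size
  k <- max(1, floor(corner_fraction * Q))
  g <- labels$genome
  acc <- list(aa = c(0, 0), bb = c(0, 0), ab = c(0, 0))
  for (m in oe_list) {
    lab <- labels$values[chrom_slice(g, m$chrom)]
    n <- nrow(m$mat)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- m$mat[i, j]
      if (is.na(v) || is.na(lab[i]) || is.na(lab[j])) next
      if ((j - i) * m$bin_size < min_dist) next
      hi <- c(lab[i] > Q - k, lab[j] > Q - k)
      lo <- c(lab[i] <= k, lab[j] <= k)
      key <- if (all(hi)) "aa" else if (all(lo)) "bb"
             else if (any(hi) && any(lo)) "ab" else NA
      if (is.na(key)) next
      acc[[key]] <- acc[[key]] + c(v, 1)
    }
  }
  aa <- acc$aa[1] / acc$aa[2]; bb <- acc$bb[1] / acc$bb[2]; ab <- acc$ab[1] / acc$ab[2]
  (aa * bb) / ab^2
}

# random symmetric count matrix with a few masked bins
random_count_matrix <- function(n, seed, chrom = "chr1", bin_size = 50e3,
                                n_masked = 2) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * n, 8), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    masked <- sample(n, n_masked)
    m[masked, ] <- 0
    m[, masked] <- 0
    contact_matrix(chrom, bin_size, m)
  })
}
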