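test_that("balancing equalises marginals and masks empty or outlier bins", {
  m <- random_count_matrix(30, seed = 1, n_masked = 0)
  bal <- balance_matrix(m)
  rs <- rowSums(bal$mat, na.rm = TRUE)[bal$mask]
  expect_lt(sd(rs) / mean(rs), 1e-5)
  expect_true(bal$balanced)
  expect_equal(sum(!is.na(bal$weights)), sum(bal$mask))
  # a 4x4 matrix with one empty row: that bin masked, 3 balanced
  m4 <- matrix(c(0, 2, 3, 0,
                 2, 0, 4, 0,
                 3, 4, 0, 0,
                 0, 0, 0, 0), 4, 4)
  b4 <- balance_matrix(contact_matrix("chr1", 1e5, m4), mad_max = 100)
  expect_equal(b4$mask, c(TRUE, TRUE, TRUE, FALSE))
  rs4 <- rowSums(b4$mat, na.rm = TRUE)[1:3]
  expect_lt(max(abs(rs4 / mean(rs4) - 1)), 1e-5)
})

test_that("balancing an already balanced matrix is a fixed point up to scale", {
  m <- random_count_matrix(40, seed = 2, n_masked = 2)
  b1 <- balance_matrix(m)
  b2 <- balance_matrix(b1)
  r <- b2$mat / b1$mat
  expect_lt(diff(range(r, na.rm = TRUE)) / mean(r, na.rm = TRUE), 1e-4)
  expect_error(balance_matrix(contact_matrix("chr1", 1e5, matrix(0, 5, 5))),
               "all bins masked")
})

test_that("expected-by-distance reproduces a pure distance function", {
  n <- 60
  d <- abs(outer(1:n, 1:n, "-"))
  f <- function(d) 10 / (1 + d)
  cm <- contact_matrix("chr1", 5e4, f(d), mask = rep(TRUE, n),
                       balanced = TRUE)
  ed <- expected_by_distance(cm, min_pairs = 1)
  expect_equal(ed$expected, f(1:(n - 1)))
  expect_error(expected_by_distance(random_count_matrix(20, 3)), "balanced")
})

test_that("O/E has unit per-diagonal means and preserves masking", {
  m <- balance_matrix(random_count_matrix(50, seed = 4, n_masked = 3))
  oe <- observed_over_expected(m)
  n <- nrow(oe$mat)
  d <- abs(outer(1:n, 1:n, "-"))
  for (dd in c(2, 5, 17)) {
    expect_equal(mean(oe$mat[d == dd], na.rm = TRUE), 1, tolerance = 1e-9)
  }
  expect_true(all(is.na(oe$mat[!m$mask, ])))
  expect_true(all(is.na(oe$mat[d < 2])))
})

test_that("the decay exponent is recovered from the expectation's O/E input", {
  g <- small_genome(1, 300)
  seg <- segment_genome(g, 300, seed = 1)  # single domain: no structure
  gt <- genotype_spec("flat", 0, coverage = 100, seed = 1)
  e <- simulate_hic(seg, gt, decay_alpha = 1, delta = 0, noise = "none")[[1]]
  cm <- contact_matrix(e$chrom, e$bin_size, e$mat, balanced = TRUE)
  ed <- expected_by_distance(cm, min_pairs = 1)
  keep <- ed$dist <= 100
  fit <- lm(log(ed$expected[keep]) ~ log(ed$dist[keep]))
  expect_lt(abs(coef(fit)[2] - (-1)), 0.05)
})

test_that("noiseless block-model O/E takes two values per diagonal", {
  g <- small_genome(1, 100)
  seg <- segment_genome(g, 20, seed = 5)
  gt <- genotype_spec("wt", 0, coverage = 100, seed = 5)
  e <- simulate_hic(seg, gt, decay_alpha = 1, delta = 0.25, noise = "none")[[1]]
  cm <- contact_matrix(e$chrom, e$bin_size, e$mat, balanced = TRUE)
  oe <- observed_over_expected(cm, min_pairs = 1)
  n <- nrow(oe$mat)
  d <- abs(outer(1:n, 1:n, "-"))
  for (dd in c(3, 11)) {
    vals <- sort(unique(round(oe$mat[d == dd], 10)))
    expect_lte(length(vals), 2)
    if (length(vals) == 2) {
      expect_equal(vals[2] / vals[1], exp(0.5), tolerance = 1e-8)
    }
  }
})

test_that("scaling curves are normalised, scale-invariant, and replica-aware", {
  m <- balance_matrix(random_count_matrix(120, seed = 6, n_masked = 0))
  sc1 <- contact_scaling(list(m))
  width <- 1 / 8
  expect_equal(sum(sc1$freq * width), 1, tolerance = 1e-9)
  # times 7: identical curve
  m7 <- contact_matrix(m$chrom, m$bin_size, m$mat * 7, mask = m$mask, balanced = TRUE)
  expect_equal(contact_scaling(list(m7))$freq, sc1$freq, tolerance = 1e-12)
  # three identical replicas: median is the curve, sd 0
  sc3 <- contact_scaling(list(list(m), list(m), list(m)))
  expect_equal(sc3$freq, sc1$freq)
  expect_equal(max(sc3$freq_sd), 0)
  expect_error(contact_scaling(list(m, contact_matrix("chr2", 1e5, matrix(0, 12, 12),
                                                      balanced = TRUE))),
               "bin size")
})

test_that("steeper decay lowers the curve at long range and slopes recover", {
  g <- small_genome(1, 300)
  seg <- segment_genome(g, 300, seed = 2)
  slope_of <- function(alpha) {
    gt <- genotype_spec("x", 0, coverage = 200, seed = 3)
    e <- simulate_hic(seg, gt, decay_alpha = alpha, delta = 0, noise = "none")[[1]]
    cm <- contact_matrix(e$chrom, e$bin_size, e$mat, balanced = TRUE)
    sc <- contact_scaling(list(cm))
    keep <- sc$n_pairs > 50
    coef(lm(log(sc$freq[keep]) ~ log(sc$dist_bp[keep])))[2]
  }
  s1 <- slope_of(1); s15 <- slope_of(1.5)
  expect_lt(abs(s1 - (-1)), 0.1)
  expect_lt(abs(s15 - (-1.5)), 0.1)
})

test_that("range fractions sum to one and match combinatorial expectations", {
  # all signal on the first off-diagonal at 50 kb bins
  n <- 50
  m <- matrix(0, n, n)
  m[cbind(1:(n - 1), 2:n)] <- 1
  m <- m + t(m)
  cm <- contact_matrix("chr1", 50e3, m, mask = rep(TRUE, n), balanced = TRUE)
  fr <- range_fractions(cm)
  expect_equal(fr$short_fraction, 1)
  expect_equal(fr$long_fraction, 0)
  # uniform matrix on a 20 Mb chromosome: fractions = pair-count proportions
  n2 <- 400
  u <- matrix(1, n2, n2); diag(u) <- 0
  cu <- contact_matrix("chr1", 50e3, u, mask = rep(TRUE, n2), balanced = TRUE)
  fr2 <- range_fractions(cu)
  d <- abs(outer(1:n2, 1:n2, "-"))[upper.tri(u)]
  expect_equal(fr2$short_fraction, mean(d * 50e3 <= 0.3e6))
  expect_equal(fr2$long_fraction, mean(d * 50e3 >= 10e6))
  expect_equal(fr2$short_fraction + fr2$mid_fraction + fr2$long_fraction, 1,
               tolerance = 1e-9)
  expect_error(range_fractions(cm, short_max = 11e6, long_min = 10e6), "below")
})

test_that("differential maps are zero on identity and antisymmetric on swap", {
  a <- balance_matrix(random_count_matrix(40, seed = 8, n_masked = 2))
  b <- balance_matrix(random_count_matrix(40, seed = 9, n_masked = 2))
  z <- differential_map(a, a)
  expect_equal(max(abs(z$mat), na.rm = TRUE), 0)
  ab <- differential_map(a, b)
  ba <- differential_map(b, a)
  expect_equal(ab$mat, -ba$mat, tolerance = 1e-12)
  expect_error(differential_map(a, balance_matrix(random_count_matrix(30, 1))),
               "share")
})

test_that("matrix coarsening sums counts blockwise", {
  m <- random_count_matrix(10, seed = 10, n_masked = 0)
  co <- coarsen_matrix(m, 5)
  expect_equal(dim(co$mat), c(2, 2))
  expect_equal(co$mat[1, 2], sum(m$mat[1:5, 6:10]))
  expect_equal(co$bin_size, 5 * m$bin_size)
  expect_error(coarsen_matrix(balance_matrix(m), 2), "raw counts")
})

test_that("coordinate-list contact text round-trips", {
  m <- random_count_matrix(25, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(m, path)
  back <- read_contacts(path, 25, m$bin_size)
  expect_equal(back$mat[m$mask, m$mask], m$mat[m$mask, m$mask])
  expect_equal(back$chrom, m$chrom)
})
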