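noiseless_oe_panel <- function(seed = 1, delta = 0.25, lambda = 0, n_chrom = 2,
                               len = 100) {
  g <- genome_spec(stats::setNames(rep(as.integer(len), n_chrom),
                                   paste0("chr", seq_len(n_chrom))), 50e3)
  seg <- segment_genome(g, 20, seed = seed)
  list(genome = g, seg = seg,
       oe = structured_oe_expectation(seg, delta, lambda),
       rt = make_rt_track(seg, 0, seed = seed))
}

test_that("digitisation produces equal-count, rank-invariant labels", {
  g <- small_genome(1, 100)
  tr <- binned_track(g, c(1, 2, 3, 4, rnorm(96) + 10))
  lab <- track_values(digitize_track(tr, 2, trim_fraction = 0))
  expect_equal(lab[1:4], c(1, 1, 1, 1))
  set.seed(1)
  tr2 <- binned_track(g, rnorm(100))
  for (Q in c(4, 7)) {
    l <- track_values(digitize_track(tr2, Q, trim_fraction = 0))
    sizes <- table(l)
    expect_lte(diff(range(sizes)), 1)
    # monotone transform leaves labels unchanged
    l2 <- track_values(digitize_track(binned_track(g, track_values(tr2)^3), Q,
                                      trim_fraction = 0))
    expect_equal(l, l2)
  }
  trimmed <- track_values(digitize_track(tr2, 4, trim_fraction = 0.1))
  expect_equal(sum(is.na(trimmed)), 20)
  expect_error(digitize_track(tr2, 20), "at least 200")
})

test_that("a flat O/E map yields a flat saddle with strength one", {
  g <- small_genome(1, 100)
  m <- matrix(1, 100, 100); diag(m) <- NA
  oe <- contact_matrix("chr1", 50e3, m, mask = rep(TRUE, 100), balanced = TRUE, oe = TRUE)
  set.seed(2)
  lab <- digitize_track(binned_track(g, rnorm(100)), 5, trim_fraction = 0)
  s <- saddle_matrix(list(oe), lab)
  expect_equal(unname(s$saddle[!is.na(s$saddle)]), rep(1, sum(!is.na(s$saddle))))
  expect_equal(compartment_strength(s), 1)
})

test_that("the noiseless block model reproduces exp(4 delta) to float precision", {
  p <- noiseless_oe_panel(delta = 0.25)
  lab <- digitize_track(p$rt, 10)
  s <- saddle_matrix(p$oe, lab)
  expect_equal(compartment_strength(s), exp(1), tolerance = 1e-6)
  # independent brute-force corner averaging agrees
  brute <- brute_corner_strength(p$oe, lab)
  expect_equal(compartment_strength(s), brute, tolerance = 1e-9)
})

test_that("reversing the ranking flips the saddle antidiagonally", {
  p <- noiseless_oe_panel(seed = 3)
  # a tie-free ranking: with distinct values the quantile partition of the
  # negated track is the exact reversal of the original one
  cont <- make_rt_track(p$seg, 0.05, seed = 3)
  lab <- digitize_track(cont, 4, trim_fraction = 0)
  rev_lab <- digitize_track(binned_track(p$genome, -track_values(cont)), 4,
                            trim_fraction = 0)
  s <- saddle_matrix(p$oe, lab)
  sr <- saddle_matrix(p$oe, rev_lab)
  expect_equal(sr$saddle, s$saddle[4:1, 4:1])
  expect_equal(sr$pair_counts, s$pair_counts[4:1, 4:1])
})

test_that("analytic mixing makes strength strictly decreasing in lambda", {
  strengths <- sapply(c(0, 0.4, 0.8), function(lam) {
    p <- noiseless_oe_panel(seed = 4, delta = 0.5, lambda = lam)
    compartment_strength(saddle_matrix(p$oe, digitize_track(p$rt, 10)))
  })
  expect_true(all(diff(strengths) < 0))
  closed_form <- function(lam) ((1 - lam) * exp(0.5) + lam)^2 / ((1 - lam) * exp(-0.5) + lam)^2
  expect_equal(strengths, sapply(c(0, 0.4, 0.8), closed_form), tolerance = 1e-6)
})

test_that("strength is stable across saddle resolutions on block models", {
  p <- noiseless_oe_panel(seed = 5, delta = 0.5)
  st <- sapply(c(5, 10, 20), function(Q)
    compartment_strength(saddle_matrix(p$oe, digitize_track(p$rt, Q))))
  expect_lt(diff(range(st)) / mean(st), 0.1)
})

test_that("empty saddle cells propagate as missing, never zero", {
  g <- small_genome(1, 100)
  # quantile 1 confined to one end, far from quantile 4: with a tight
  # max_dist the (1,4) cell has no pairs
  vals <- sort(rnorm(100))
  lab <- digitize_track(binned_track(g, vals), 4, trim_fraction = 0)
  m <- matrix(1, 100, 100); diag(m) <- NA
  oe <- contact_matrix("chr1", 50e3, m, mask = rep(TRUE, 100), balanced = TRUE, oe = TRUE)
  s <- saddle_matrix(list(oe), lab, max_dist = 10 * 50e3)
  expect_true(is.na(s$saddle[1, 4]))
  expect_equal(s$pair_counts[1, 4], 0)
  expect_error(compartment_strength(s, corner_fraction = 0.25), "missing")
})

test_that("distance-stratified strength is flat for distance-free structure", {
  p <- noiseless_oe_panel(seed = 6, delta = 0.25, len = 200)
  lab <- digitize_track(p$rt, 10)
  bands <- list(c(1e6, 3e6), c(3e6, 6e6), c(6e6, 9e6))
  curve <- strength_by_distance(p$oe, lab, bands)
  expect_equal(nrow(curve), 3)
  expect_lt(diff(range(curve$strength)), 1e-6)
  expect_equal(curve$strength[1], exp(1), tolerance = 1e-6)
  # a band beyond the chromosome is missing
  far <- strength_by_distance(p$oe, lab, list(c(50e6, 60e6)))
  expect_true(is.na(far$strength))
  expect_error(strength_by_distance(p$oe, lab, list(c(1e6, 3e6), c(2e6, 4e6))),
               "disjoint")
})

test_that("differential saddles are zero on identity and negate on swap", {
  p <- noiseless_oe_panel(seed = 7, delta = 0.5, lambda = 0)
  p2 <- list(oe = structured_oe_expectation(p$seg, 0.5, 0.8))
  lab <- digitize_track(p$rt, 8)
  s1 <- saddle_matrix(p$oe, lab)
  s2 <- saddle_matrix(p2$oe, lab)
  expect_equal(max(abs(differential_saddle(s1, s1)), na.rm = TRUE), 0)
  expect_equal(differential_saddle(s1, s2), -differential_saddle(s2, s1))
  # weakened structure loses same-quantile contacts and gains cross ones
  d <- differential_saddle(s2, s1)
  expect_lt(d[1, 1], 0); expect_lt(d[8, 8], 0)
  expect_gt(d[1, 8], 0)
  s3 <- saddle_matrix(p$oe, digitize_track(p$rt, 5))
  expect_error(differential_saddle(s1, s3), "mismatch")
})

test_that("a random ranking nulls the saddle", {
  g <- small_genome(2, 200)
  seg <- segment_genome(g, 40, seed = 8)
  gt <- genotype_spec("x", 0, coverage = 100, seed = 8)
  oe <- lapply(simulate_hic(seg, gt, delta = 0.5), function(m)
    observed_over_expected(balance_matrix(m)))
  set.seed(8)
  lab <- digitize_track(binned_track(g, rnorm(400)), 5, trim_fraction = 0)
  s <- saddle_matrix(oe, lab)
  expect_lt(max(abs(s$saddle - 1), na.rm = TRUE), 0.12)
  expect_lt(abs(compartment_strength(s) - 1), 0.05)
})
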