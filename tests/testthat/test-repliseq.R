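test_that("RPM normalisation scales to a million and rejects empty input", {
  g <- small_genome(1, 10)
  tr <- binned_track(g, c(2, 2, rep(0, 8)))
  out <- track_values(rpm_normalize(tr))
  expect_equal(out[1:2], c(5e5, 5e5))
  tr2 <- binned_track(g, c(1, 3, rep(0, 8)))
  expect_equal(track_values(rpm_normalize(tr2))[1:2], c(2.5e5, 7.5e5))
  expect_equal(sum(track_values(rpm_normalize(binned_track(g, runif(10))))), 1e6,
               tolerance = 1e-9)
  expect_error(rpm_normalize(binned_track(g, rep(0, 10))), "all-zero")
})

test_that("bin exclusion masks chromosomes and low-coverage bins in place", {
  g <- small_genome(2, 10)
  counts <- binned_track(g, c(5, 0, 3, 1, 9, 2, rep(6, 14)))
  masked <- exclude_bins(counts, min_count = 2)
  expect_equal(sum(is.na(track_values(masked))), 2)
  expect_equal(which(is.na(track_values(masked))), c(2L, 4L))
  chrmasked <- exclude_bins(counts, excluded_chromosomes = "chr2")
  expect_true(all(is.na(track_values(chrmasked)[11:20])))
  expect_error(exclude_bins(counts, excluded_chromosomes = "chrX"), "chrX")
  same <- exclude_bins(counts, excluded_chromosomes = c("chrX", "chrY"), strict = FALSE)
  expect_equal(track_values(same), track_values(counts))
  expect_equal(track_values(exclude_bins(counts, min_count = 0)),
               track_values(counts))
})

test_that("RT scores are the log2 ratio with pseudocount-bounded edge cases", {
  g <- small_genome(1, 10)
  e <- binned_track(g, c(4, 8, 0, rep(5, 7)))
  l <- binned_track(g, c(4, 2, 0, rep(5, 7)))
  rt <- track_values(compute_rt_profile(e, l, pseudocount = 1e-9))
  expect_equal(rt[1], 0)
  expect_equal(rt[2], 2, tolerance = 1e-8)
  expect_equal(rt[3], 0)  # pseudocount over pseudocount
  e2 <- binned_track(g, c(NA, 8, rep(5, 8)))
  rt2 <- track_values(compute_rt_profile(e2, l))
  expect_true(is.na(rt2[1]))
  expect_error(compute_rt_profile(e, binned_track(small_genome(1, 12), rep(1, 12))),
               "different genomes")
})

test_that("RPM + log2 ratio is invariant to rescaling either fraction's counts", {
  g <- small_genome(1, 100)
  set.seed(42)
  e <- binned_track(g, rpois(100, 50))
  l <- binned_track(g, rpois(100, 50))
  base <- track_values(compute_rt_profile(rpm_normalize(e), rpm_normalize(l)))
  e7 <- binned_track(g, track_values(e) * 7)
  scaled <- track_values(compute_rt_profile(rpm_normalize(e7), rpm_normalize(l)))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("RT histograms integrate to one and expose planted bimodality", {
  g <- small_genome(1, 10)
  h <- rt_distribution(binned_track(g, rep(1.3, 10)), n_hist_bins = 20)
  expect_equal(sum(h$density > 0), 1)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
  gg <- default_genome()
  seg <- segment_genome(gg, 40, seed = 8)
  rt <- make_rt_track(seg, 0.2, seed = 8)
  h2 <- rt_distribution(rt, n_hist_bins = 40)
  d_at <- function(x) h2$density[which.min(abs(h2$mids - x))]
  expect_gt(d_at(-1.5), d_at(0))
  expect_gt(d_at(1.5), d_at(0))
  expect_error(rt_distribution(binned_track(g, c(1, rep(NA, 9)))), "at least 2")
})

test_that("degenerate and unimodal inputs are not called bimodal", {
  g <- small_genome(1, 200)
  expect_equal(bimodality(binned_track(g, rep(0, 200))),
               list(score = 0, is_bimodal = FALSE, means = c(0, 0), sds = c(0, 0)))
  set.seed(2)
  uni <- binned_track(default_genome(), rnorm(4000, 0, 0.8))
  expect_false(bimodality(uni)$is_bimodal)
})

test_that("profile correlations have exact self/negation limits and a tight null", {
  g <- default_genome()
  set.seed(3)
  a <- binned_track(g, rnorm(4000), name = "a")
  b <- binned_track(g, rnorm(4000), name = "b")
  cc <- correlate_profiles(list(a, b, binned_track(g, -track_values(a), name = "nega")))
  expect_equal(diag(cc), c(a = 1, b = 1, nega = 1))
  expect_equal(cc["a", "nega"], -1)
  expect_lt(abs(cc["a", "b"]), 0.06)
  # affine invariance
  a2 <- binned_track(g, 3.2 * track_values(a) + 0.7, name = "a2")
  cc2 <- correlate_profiles(list(a, a2, b))
  expect_equal(cc2["a", "a2"], 1)
  expect_equal(cc2["a2", "b"], cc["a", "b"], tolerance = 1e-12)
})

test_that("correlation masking uses jointly unmasked bins only", {
  g <- small_genome(1, 20)
  v1 <- c(NA, rnorm(19)); v2 <- c(rnorm(19), NA)
  cc <- correlate_profiles(list(binned_track(g, v1), binned_track(g, v2)))
  expect_equal(cc[1, 2], cor(v1[2:19], v2[2:19]))
  expect_error(correlate_profiles(list(binned_track(g, c(1, rep(NA, 19))),
                                       binned_track(g, c(1, rep(NA, 19))))),
               "fewer than 2")
})

test_that("replica clustering separates planted groups and has exact small cases", {
  g <- default_genome()
  seg_a <- segment_genome(g, 40, seed = 1)
  seg_b <- reprogram_rt(seg_a, 1, seed = 99)
  tracks <- c(
    lapply(1:3, function(r) make_rt_track(seg_a, 0.3, seed = r)),
    lapply(1:3, function(r) make_rt_track(seg_b, 0.3, seed = 10 + r))
  )
  cc <- correlate_profiles(tracks, labels = paste0(rep(c("a", "b"), each = 3), 1:3))
  cl <- cluster_profiles(cc)
  expect_equal(mclust::adjustedRandIndex(cl$clusters, rep(1:2, each = 3)), 1)
  # two tracks: single merge at 1 - r
  cc2 <- correlate_profiles(tracks[c(1, 4)], labels = c("x", "y"))
  cl2 <- cluster_profiles(cc2)
  expect_equal(cl2$hclust$height, 1 - cc2[1, 2])
  # identical tracks: merge heights all ~0
  cc3 <- correlate_profiles(tracks[c(1, 1, 1)], labels = c("i1", "i2", "i3"))
  expect_lt(max(cluster_profiles(cc3)$hclust$height), 1e-12)
  expect_true(grepl("^\\(", cl$newick))
  asym <- cc; asym[1, 2] <- 0.5
  expect_error(cluster_profiles(asym), "symmetric")
})

test_that("timing-change classification follows the sign/threshold rule", {
  g <- small_genome(1, 10)
  a <- binned_track(g, rep(1, 10))
  res <- classify_rt_changes(a, a)
  expect_equal(unname(res$fractions["stable"]), 1)
  b <- binned_track(g, rep(-1, 10))
  res2 <- classify_rt_changes(a, b, 0.5, 0.25)
  expect_true(all(res2$table$category == "EtoL"))
  res3 <- classify_rt_changes(b, a, 0.5, 0.25)
  expect_true(all(res3$table$category == "LtoE"))
  # toward / away from zero
  res4 <- classify_rt_changes(binned_track(g, rep(1, 10)), binned_track(g, rep(0.5, 10)))
  expect_true(all(res4$table$category == "toward_zero"))
  res5 <- classify_rt_changes(binned_track(g, rep(0.5, 10)), binned_track(g, rep(1, 10)))
  expect_true(all(res5$table$category == "away_from_zero"))
  expect_error(classify_rt_changes(a, b, 0.2, 0.25), "at least")
})

test_that("a planted 10% sign-flip is recovered as the switch fraction", {
  g <- default_genome()
  set.seed(6)
  base <- sample(c(-1.2, 1.2), 4000, replace = TRUE) + rnorm(4000, 0, 0.1)
  flip <- sample(4000, 400)
  after <- base; after[flip] <- -after[flip]
  res <- classify_rt_changes(binned_track(g, base), binned_track(g, after), 0.5, 0.25)
  sw <- sum(res$fractions[c("EtoL", "LtoE")])
  expect_lt(abs(sw - 0.1), 0.01)
})

test_that("no operation unmasks a masked bin", {
  g <- small_genome(1, 50)
  v <- rpois(50, 20); v[7] <- NA
  tr <- binned_track(g, v)
  expect_true(is.na(track_values(rpm_normalize(tr))[7]))
  expect_true(is.na(track_values(exclude_bins(tr, min_count = 1))[7]))
  rt <- compute_rt_profile(rpm_normalize(tr), rpm_normalize(binned_track(g, rpois(50, 20))))
  expect_true(is.na(track_values(rt)[7]))
  expect_true(is.na(track_values(median_center(rt))[7]))
})
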