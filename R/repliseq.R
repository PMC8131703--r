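# Replication-timing profiles from binned early/late Repli-seq counts and
# their structure: RPM normalisation, bin exclusion, log2 ratio scoring,
# distribution shape, replica correlation/clustering, and between-condition
# timing-change classification.

#' Reads-per-million normalisation
#'
#' @param counts A `binned_track` of non-negative counts.
#' @return A `binned_track` whose unmasked values sum to 1e6.
#' @export
rpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "binned_track"))
  v <- counts$values
  if (any(v < 0, na.rm = TRUE)) stop("counts must be non-negative")
  tot <- sum(v, na.rm = TRUE)
  if (tot <= 0) stop("cannot RPM-normalise an all-zero track")
  binned_track(counts$genome, v * 1e6 / tot, name = counts$name)
}

#' Mask excluded chromosomes and low-coverage bins
#'
#' Bins on excluded chromosomes (e.g. chrX/chrY) and bins whose raw count
#' falls below `min_count` are masked, never dropped, so bin coordinates
#' stay aligned across tracks.
#'
#' @param track A `binned_track` of raw counts.
#' @param excluded_chromosomes Chromosome names to mask.
#' @param min_count Bins with value below this are masked.
#' @param strict If `TRUE` (default), naming a chromosome absent from the
#'   genome is an error.
#' @return A `binned_track` with additional masked bins.
#' @export
exclude_bins <- function(track, excluded_chromosomes = character(), min_count = 0,
                         strict = TRUE) {
  stopifnot(inherits(track, "binned_track"))
  g <- track$genome
  unknown <- setdiff(excluded_chromosomes, g$chrom)
  if (length(unknown) && strict)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  v <- track$values
  for (ch in intersect(excluded_chromosomes, g$chrom)) v[chrom_slice(g, ch)] <- NA_real_
  v[!is.na(v) & v < min_count] <- NA_real_
  binned_track(g, v, name = track$name)
}

#' Replication-timing score from early/late RPM tracks
#'
#' `rt = log2((early + pseudocount) / (late + pseudocount))` per bin; bins
#' masked in either input stay masked.
#'
#' @param early,late RPM-normalised `binned_track`s on the same genome.
#' @param pseudocount Positive pseudocount in RPM units (default 0.1),
#'   bounding the score on empty bins.
#' @return A `binned_track` of RT scores.
#' @export
compute_rt_profile <- function(early, late, pseudocount = 0.1) {
  stopifnot(inherits(early, "binned_track"), inherits(late, "binned_track"))
  if (!same_genome(early$genome, late$genome))
    stop("early and late tracks are on different genomes")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  rt <- log2((early$values + pseudocount) / (late$values + pseudocount))
  rt[is.na(early$values) | is.na(late$values)] <- NA_real_
  binned_track(early$genome, rt, name = "rt")
}

#' Density histogram of RT scores
#'
#' @param rt A `binned_track` with at least 2 unmasked values.
#' @param n_hist_bins Number of histogram bins.
#' @return A list with `breaks`, `mids`, and `density` (integrating to 1).
#' @export
rt_distribution <- function(rt, n_hist_bins = 50) {
  stopifnot(inherits(rt, "binned_track"))
  v <- rt$values[!is.na(rt$values)]
  if (length(v) < 2) stop("need at least 2 unmasked RT values")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_hist_bins + 1),
                      plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, density = h$density)
}

#' Bimodality of an RT distribution
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances) to the
#' unmasked RT values and scores bimodality as the BIC improvement of the
#' two-component model, `BIC(1) - BIC(2)` in the standard
#' smaller-is-better convention. The distribution is called bimodal when the
#' improvement exceeds 10 and the fitted component means are separated by
#' more than the larger component standard deviation -- the guard stops a
#' heavy-tailed unimodal fit from being called bimodal.
#'
#' @param rt A `binned_track` with at least 100 unmasked bins.
#' @return A list: `score` (BIC improvement), `is_bimodal`, and the fitted
#'   2-component `means` and `sds`.
#' @export
bimodality <- function(rt) {
  stopifnot(inherits(rt, "binned_track"))
  v <- rt$values[!is.na(rt$values)]
  if (length(v) < 100) stop("need at least 100 unmasked bins")
  if (stats::sd(v) == 0)
    return(list(score = 0, is_bimodal = FALSE, means = rep(v[1], 2), sds = c(0, 0)))
  # Mclust initialises on a random subsample for large n; pin the stream so
  # the fit is a pure function of the data
  fits <- withr::with_seed(271828L, {
    f1 <- mclust::Mclust(v, G = 1, modelNames = "V", verbose = FALSE)
    f2 <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(f2))
      f2 <- mclust::Mclust(v, G = 2, modelNames = "E", verbose = FALSE)
    list(f1, f2)
  })
  f1 <- fits[[1]]; f2 <- fits[[2]]
  if (is.null(f1) || is.null(f2))
    return(list(score = 0, is_bimodal = FALSE, means = rep(mean(v), 2), sds = rep(stats::sd(v), 2)))
  # mclust reports BIC as 2 loglik - k log n (larger is better), so the
  # standard BIC(1) - BIC(2) equals f2$bic - f1$bic
  score <- f2$bic - f1$bic
  mu <- as.numeric(f2$parameters$mean)
  sg <- sqrt(f2$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  list(score = score,
       is_bimodal = score > 10 && abs(diff(mu)) > max(sg),
       means = mu, sds = sg)
}

#' Pearson correlation matrix of genome-wide profiles
#'
#' Correlations are computed over bins unmasked in every track, so the
#' matrix is a proper correlation matrix of a common support.
#'
#' @param tracks List of at least 2 `binned_track`s on one genome.
#' @param labels Optional sample names (defaults to track names).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlate_profiles <- function(tracks, labels = NULL) {
  if (length(tracks) < 2) stop("need at least 2 tracks")
  g <- tracks[[1]]$genome
  for (t in tracks) {
    stopifnot(inherits(t, "binned_track"))
    if (!same_genome(t$genome, g)) stop("tracks are on different genomes")
  }
  if (is.null(labels)) labels <- vapply(tracks, function(t) t$name, "")
  mat <- sapply(tracks, track_values)
  ok <- rowSums(is.na(mat)) == 0
  if (sum(ok) < 2) stop("fewer than 2 jointly unmasked bins")
  cc <- stats::cor(mat[ok, , drop = FALSE])
  dimnames(cc) <- list(labels, labels)
  cc
}

#' Hierarchical clustering of profile correlations
#'
#' Agglomerative clustering with distance `1 - r` and average linkage, the
#' standard recipe for replica dendrograms of genome-wide profiles.
#'
#' @param corr Symmetric correlation matrix (e.g. from
#'   [correlate_profiles()]).
#' @param k Number of flat clusters to cut (default 2).
#' @return A list: `hclust` (the merge tree), `clusters` (flat assignment),
#'   `newick` (the dendrogram as a Newick string).
#' @export
cluster_profiles <- function(corr, k = 2) {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = "average")
  clusters <- stats::cutree(hc, k = k)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, clusters = clusters, newick = newick)
}

#' Classify replication-timing changes between two conditions
#'
#' Per jointly unmasked bin with `delta = rt_b - rt_a`:
#' * `EtoL` -- early in a (`rt_a > change_threshold`), late in b
#'   (`rt_b < -change_threshold`), and `|delta| >= switch_threshold`;
#' * `LtoE` -- the mirror switch;
#' * `toward_zero` / `away_from_zero` -- `|delta| >= change_threshold`,
#'   split by whether `|rt_b|` shrinks below `|rt_a|`;
#' * `stable` -- everything else; masked bins are `masked`.
#'
#' @param rt_a,rt_b RT `binned_track`s on the same genome (a = reference).
#' @param switch_threshold Minimum `|delta|` for a switch (default 0.5).
#' @param change_threshold Minimum `|delta|` for a change, and the
#'   early/late sign threshold (default 0.25); must not exceed
#'   `switch_threshold`.
#' @return A list: `table` (tibble with per-bin `category` and `delta_rt`)
#'   and `fractions` (genome fraction per category over unmasked bins).
#' @export
classify_rt_changes <- function(rt_a, rt_b, switch_threshold = 0.5,
                                change_threshold = 0.25) {
  stopifnot(inherits(rt_a, "binned_track"), inherits(rt_b, "binned_track"))
  if (!same_genome(rt_a$genome, rt_b$genome)) stop("tracks are on different genomes")
  if (switch_threshold < change_threshold)
    stop("switch_threshold must be at least change_threshold")
  a <- rt_a$values; b <- rt_b$values
  delta <- b - a
  cat_ <- rep("stable", length(a))
  chg <- abs(delta) >= change_threshold
  cat_[chg & abs(b) < abs(a)] <- "toward_zero"
  cat_[chg & abs(b) >= abs(a)] <- "away_from_zero"
  sw <- abs(delta) >= switch_threshold
  cat_[sw & a > change_threshold & b < -change_threshold] <- "EtoL"
  cat_[sw & a < -change_threshold & b > change_threshold] <- "LtoE"
  cat_[is.na(a) | is.na(b)] <- "masked"
  lv <- c("EtoL", "LtoE", "toward_zero", "away_from_zero", "stable", "masked")
  cat_ <- factor(cat_, levels = lv)
  unm <- cat_ != "masked"
  fr <- as.numeric(table(cat_[unm])[lv[1:5]]) / max(1, sum(unm))
  names(fr) <- lv[1:5]
  list(
    table = tibble::tibble(chrom = genome_bins(rt_a$genome)$chrom,
                           bin = genome_bins(rt_a$genome)$bin,
                           category = cat_, delta_rt = delta),
    fractions = fr
  )
}
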