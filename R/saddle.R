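# Track-conditioned saddle statistics: quantile digitisation, O/E
# aggregation over quantile pairs, corner compartment strength, strength by
# distance, and differential saddles against a reference genotype.

#' Digitise a track into equal-count quantile groups
#'
#' The lowest and highest `trim_fraction` of values are masked as an
#' outlier guard; remaining bins are assigned to `n_quantiles` equal-count
#' groups (label 1 = lowest values), ties broken by stable bin order, so a
#' monotone transform of the track leaves labels unchanged.
#'
#' @param track A `binned_track`.
#' @param n_quantiles Number of groups Q (>= 2); needs at least 10*Q
#'   unmasked bins.
#' @param trim_fraction Fraction trimmed from each tail, in \[0, 0.1\].
#' @return A `binned_track` of integer labels (NA = masked/trimmed) with
#'   attribute `n_quantiles`.
#' @export
digitize_track <- function(track, n_quantiles, trim_fraction = 0.02) {
  stopifnot(inherits(track, "binned_track"))
  if (n_quantiles < 2) stop("n_quantiles must be at least 2")
  if (trim_fraction < 0 || trim_fraction > 0.1) stop("trim_fraction must lie in [0, 0.1]")
  v <- track$values
  ok <- which(!is.na(v))
  if (length(ok) < 10 * n_quantiles)
    stop("need at least ", 10 * n_quantiles, " unmasked bins")
  r <- rank(v[ok], ties.method = "first")
  n <- length(ok)
  ntrim <- floor(trim_fraction * n)
  keep <- r > ntrim & r <= n - ntrim
  r2 <- rank(v[ok][keep], ties.method = "first")
  lab <- floor((r2 - 1) * n_quantiles / length(r2)) + 1
  out <- rep(NA_real_, length(v))
  out[ok[keep]] <- lab
  res <- binned_track(track$genome, out, name = paste0(track$name, "_q", n_quantiles))
  attr(res, "n_quantiles") <- as.integer(n_quantiles)
  res
}

#' Saddle matrix: mean O/E over quantile pairs
#'
#' `S[p, q]` is the mean of unmasked cis O/E entries over all pairs with
#' quantile labels p and q (both orders pooled, so S is symmetric) whose
#' genomic separation lies in `[min_dist, max_dist]`, pooled across
#' chromosomes and across replicate matrices weighted by pair counts.
#'
#' @param oe_list O/E `contact_matrix` list; replicate matrices of the same
#'   chromosome may simply be included multiple times.
#' @param labels A digitised track from [digitize_track()].
#' @param min_dist Minimum separation in bp (default 2 bins).
#' @param max_dist Maximum separation in bp (`NULL` = none).
#' @return A `saddle_result`: `saddle` (QxQ mean O/E, `NA` where no pairs),
#'   `pair_counts`, `track_name`, `n_quantiles`.
#' @export
saddle_matrix <- function(oe_list, labels, min_dist = NULL, max_dist = NULL) {
  stopifnot(inherits(labels, "binned_track"))
  Q <- attr(labels, "n_quantiles")
  if (is.null(Q)) stop("labels must come from digitize_track()")
  g <- labels$genome
  oe_list <- as_matrix_list(oe_list)
  if (is.null(min_dist)) min_dist <- 2 * oe_list[[1]]$bin_size
  if (min_dist < 2 * oe_list[[1]]$bin_size)
    stop("min_dist must be at least 2 bins")
  if (is.null(max_dist)) max_dist <- Inf
  sums <- matrix(0, Q, Q)
  cnts <- matrix(0, Q, Q)
  for (m in oe_list) {
    if (!m$oe) stop("saddle_matrix requires O/E matrices")
    sl <- chrom_slice(g, m$chrom)
    if (length(sl) != nrow(m$mat)) stop("matrix for ", m$chrom, " does not match label genome")
    lab <- labels$values[sl]
    n <- nrow(m$mat)
    ut <- upper.tri(m$mat)
    v <- m$mat[ut]
    i <- row(m$mat)[ut]; j <- col(m$mat)[ut]
    dbp <- (j - i) * m$bin_size
    li <- lab[i]; lj <- lab[j]
    ok <- !is.na(v) & !is.na(li) & !is.na(lj) & dbp >= min_dist & dbp <= max_dist
    if (!any(ok)) next
    key <- (li[ok] - 1) * Q + lj[ok]
    s <- rowsum(v[ok], key)
    cn <- rowsum(rep(1, sum(ok)), key)
    kk <- as.integer(rownames(s))
    pi <- (kk - 1) %/% Q + 1
    pj <- (kk - 1) %% Q + 1
    sums[cbind(pi, pj)] <- sums[cbind(pi, pj)] + s
    cnts[cbind(pi, pj)] <- cnts[cbind(pi, pj)] + cn
  }
  # pool both orders; every unordered pair contributes twice (once per
  # orientation), also on the diagonal, so cell weights stay comparable
  sums <- sums + t(sums)
  cnts <- cnts + t(cnts)
  S <- ifelse(cnts > 0, sums / cnts, NA_real_)
  structure(
    list(saddle = S, pair_counts = cnts, track_name = labels$name,
         n_quantiles = Q),
    class = "saddle_result"
  )
}

#' @export
print.saddle_result <- function(x, ...) {
  cat(sprintf("<saddle_result> %dx%d over '%s', %g pairs\n",
              x$n_quantiles, x$n_quantiles, x$track_name, sum(x$pair_counts) / 2))
  invisible(x)
}

#' Corner compartment strength of a saddle
#'
#' With k = `max(1, floor(corner_fraction * Q))`, AA is the pair-count
#' weighted mean of the saddle over the top-k x top-k corner, BB over the
#' bottom-k x bottom-k corner, and AB over the two cross corners; strength
#' is `(AA * BB) / AB^2`. A structureless map has strength 1; the noiseless
#' block model with log-preference delta has strength `exp(4 * delta)`.
#'
#' @param s A `saddle_result`.
#' @param corner_fraction Corner size as a fraction of Q, in (0, 0.5\]
#'   (default 0.2).
#' @return Strength (positive scalar).
#' @export
compartment_strength <- function(s, corner_fraction = 0.2) {
  stopifnot(inherits(s, "saddle_result"))
  if (corner_fraction <= 0 || corner_fraction > 0.5)
    stop("corner_fraction must lie in (0, 0.5]")
  Q <- s$n_quantiles
  k <- max(1, floor(corner_fraction * Q))
  top <- (Q - k + 1):Q
  bot <- 1:k
  wmean <- function(rows, cols) {
    v <- s$saddle[rows, cols, drop = FALSE]
    w <- s$pair_counts[rows, cols, drop = FALSE]
    ok <- !is.na(v) & w > 0
    if (!any(ok)) stop("saddle corner entirely missing")
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  aa <- wmean(top, top)
  bb <- wmean(bot, bot)
  ab <- wmean(top, bot)
  (aa * bb) / ab^2
}

#' Compartment strength stratified by genomic distance
#'
#' Applies [saddle_matrix()] + [compartment_strength()] within each distance
#' band; a band with an empty saddle corner is reported as missing.
#'
#' @param oe_list O/E `contact_matrix` list.
#' @param labels A digitised track.
#' @param bands List of `c(lo, hi)` bp intervals, disjoint and increasing.
#' @param corner_fraction Corner size (see [compartment_strength()]).
#' @return A tibble: `band_lo`, `band_hi`, `strength` (NA = missing),
#'   `n_pairs`.
#' @export
strength_by_distance <- function(oe_list, labels, bands, corner_fraction = 0.2) {
  bm <- do.call(rbind, lapply(bands, function(b) as.numeric(b)))
  if (ncol(bm) != 2 || any(bm[, 1] >= bm[, 2])) stop("bands must be (lo, hi) intervals")
  if (nrow(bm) > 1) {
    o <- order(bm[, 1])
    if (any(bm[o, 1][-1] < bm[o, 2][-nrow(bm)])) stop("bands must be disjoint")
  }
  res <- lapply(seq_len(nrow(bm)), function(i) {
    s <- saddle_matrix(oe_list, labels,
                       min_dist = max(bm[i, 1], 2 * as_matrix_list(oe_list)[[1]]$bin_size),
                       max_dist = bm[i, 2])
    st <- tryCatch(compartment_strength(s, corner_fraction), error = function(e) NA_real_)
    tibble::tibble(band_lo = bm[i, 1], band_hi = bm[i, 2], strength = st,
                   n_pairs = sum(s$pair_counts) / 2)
  })
  do.call(rbind, res)
}

#' Differential saddle against a reference
#'
#' Entry-wise `log2(S / S_ref)`; missing where either saddle is missing;
#' antisymmetric under swapping the arguments.
#'
#' @param s,reference `saddle_result`s with the same Q.
#' @return A QxQ signed matrix.
#' @export
differential_saddle <- function(s, reference) {
  stopifnot(inherits(s, "saddle_result"), inherits(reference, "saddle_result"))
  if (s$n_quantiles != reference$n_quantiles) stop("saddle Q mismatch")
  log2(s$saddle / reference$saddle)
}
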