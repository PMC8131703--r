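# A/B compartment calling from O/E matrices and cross-sample PCA of
# compartment profiles.

#' A/B compartment eigenvector of O/E matrices
#'
#' Per chromosome: the Pearson correlation matrix of unmasked O/E columns is
#' computed (pairwise-complete, since near-diagonal entries are masked) and
#' its leading eigenvector taken. The eigenvector is scaled by the square
#' root of its eigenvalue share, so its amplitude reflects how coherent the
#' checkerboard is, and its sign is fixed so that it correlates positively
#' with the orientation track (replication timing by default: A = early =
#' positive eigenvector).
#'
#' @param oe_list O/E `contact_matrix` list (one per chromosome) covering
#'   the orientation track's genome.
#' @param orientation A `binned_track` on the same bins (e.g. an RT score).
#' @param min_bins Chromosomes with fewer unmasked bins are fully masked,
#'   with a warning.
#' @return A `compartment_profile`: `e1` (`binned_track`), `labels`
#'   (per-bin `"A"`/`"B"`/`NA`), `orientation_track_name`, and per-chromosome
#'   `variance_share` of the leading eigenvalue.
#' @export
compartment_eigenvector <- function(oe_list, orientation, min_bins = 20) {
  stopifnot(inherits(orientation, "binned_track"))
  g <- orientation$genome
  oe_list <- as_matrix_list(oe_list)
  e1 <- rep(NA_real_, n_bins(g))
  share <- stats::setNames(rep(NA_real_, length(oe_list)),
                           vapply(oe_list, function(m) m$chrom, ""))
  for (m in oe_list) {
    if (!m$oe) stop("compartment_eigenvector requires O/E matrices")
    sl <- chrom_slice(g, m$chrom)
    if (length(sl) != nrow(m$mat))
      stop("matrix for ", m$chrom, " does not match the orientation genome")
    valid <- m$mask
    if (sum(valid) < min_bins) {
      warning("chromosome ", m$chrom, " has fewer than ", min_bins,
              " unmasked bins; masking it entirely")
      next
    }
    sub <- m$mat[valid, valid, drop = FALSE]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    v <- eg$vectors[, 1]
    lam <- pmax(eg$values, 0)
    sh <- lam[1] / sum(lam)
    v <- v * sqrt(sh)
    ref <- orientation$values[sl][valid]
    s <- suppressWarnings(stats::cor(v, ref, use = "complete.obs"))
    if (!is.na(s) && s < 0) v <- -v
    e1[sl[valid]] <- v
    share[m$chrom] <- sh
  }
  labels <- ifelse(is.na(e1), NA_character_, ifelse(e1 > 0, "A", "B"))
  structure(
    list(e1 = binned_track(g, e1, name = "E1"),
         labels = labels,
         orientation_track_name = orientation$name,
         variance_share = share),
    class = "compartment_profile"
  )
}

#' @export
print.compartment_profile <- function(x, ...) {
  n <- sum(!is.na(x$labels))
  cat(sprintf("<compartment_profile> %d labelled bins (A: %d, B: %d), oriented by '%s'\n",
              n, sum(x$labels == "A", na.rm = TRUE), sum(x$labels == "B", na.rm = TRUE),
              x$orientation_track_name))
  invisible(x)
}

#' A and B compartment fractions
#'
#' @param profile A `compartment_profile`.
#' @return Named list `a_fraction`, `b_fraction` (summing to 1 over
#'   unmasked bins).
#' @export
ab_fraction <- function(profile) {
  stopifnot(inherits(profile, "compartment_profile"))
  lab <- profile$labels[!is.na(profile$labels)]
  if (!length(lab)) stop("all bins are masked")
  list(a_fraction = mean(lab == "A"), b_fraction = mean(lab == "B"))
}

#' Cross-sample PCA of compartment profiles
#'
#' Samples are observations and per-bin eigenvector values are features
#' (restricted to bins unmasked in every sample, centred across samples).
#' The first two principal coordinates summarise how compartment
#' organisation varies across a genotype panel.
#'
#' @param profiles List of at least 3 `compartment_profile`s on one genome.
#' @param labels Sample names.
#' @return A list: `coords` (tibble with `sample`, `PC1`, `PC2`) and
#'   `variance_share` (length-2 numeric).
#' @export
compartment_pca <- function(profiles, labels = NULL) {
  if (length(profiles) < 3) stop("need at least 3 samples")
  if (is.null(labels)) labels <- paste0("sample", seq_along(profiles))
  mat <- sapply(profiles, function(p) {
    stopifnot(inherits(p, "compartment_profile"))
    track_values(p$e1)
  })
  ok <- rowSums(is.na(mat)) == 0
  if (sum(ok) < 3) stop("fewer than 3 jointly unmasked bins")
  x <- t(mat[ok, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  k <- min(2, ncol(pc$x))
  coords <- tibble::tibble(
    sample = labels,
    PC1 = pc$x[, 1],
    PC2 = if (k >= 2) pc$x[, 2] else 0
  )
  list(coords = coords, variance_share = share[1:2])
}
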