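# Contact-matrix plumbing: the container, iterative-correction balancing,
# expected-by-distance, O/E, distance-decay curves, range fractions and
# differential maps. Coordinates are 0-based half-open: entry (i, j) covers
# [i*bs, (i+1)*bs) x [j*bs, (j+1)*bs).

#' Symmetric cis contact matrix for one chromosome
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param mat Symmetric non-negative numeric matrix (counts, balanced
#'   frequencies, or O/E values). Masked rows/columns are `NA`.
#' @param mask Logical vector of valid bins; defaults to bins with any
#'   non-`NA` entry.
#' @param balanced Whether the matrix has been balanced.
#' @param weights Per-bin balancing weights (present iff balanced by
#'   [balance_matrix()]).
#' @param oe Whether entries are on the observed/expected scale.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(chrom, bin_size, mat, mask = NULL,
                           balanced = FALSE, weights = NULL, oe = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  sym_dev <- max(abs(mat - t(mat)), na.rm = TRUE)
  if (is.finite(sym_dev) && sym_dev > 1e-8 * max(1, max(abs(mat), na.rm = TRUE)))
    stop("contact matrix must be symmetric")
  if (is.null(mask)) mask <- apply(mat, 1, function(r) any(!is.na(r) & r != 0))
  mat[!mask, ] <- NA_real_
  mat[, !mask] <- NA_real_
  structure(
    list(chrom = chrom, bin_size = as.numeric(bin_size), mat = mat,
         mask = as.logical(mask), balanced = isTRUE(balanced),
         weights = weights, oe = isTRUE(oe)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %s bp, %d masked%s%s\n",
              x$chrom, nrow(x$mat), format(x$bin_size, big.mark = ","),
              sum(!x$mask),
              if (x$balanced) ", balanced" else "",
              if (x$oe) ", O/E" else ""))
  invisible(x)
}

bin_dist <- function(n) abs(outer(seq_len(n), seq_len(n), "-"))

as_matrix_list <- function(x) {
  if (inherits(x, "contact_matrix")) list(x) else x
}

#' Balance a contact matrix by iterative correction
#'
#' Masks bins with zero marginal or whose log marginal falls more than
#' `mad_max` robust deviations below the median (a one-sided low-coverage
#' filter, with the robust scale floored at half a log2 unit so noiseless
#' marginals cannot collapse the threshold), then iteratively
#' rescales rows/columns until all unmasked marginals agree with their mean
#' to within `tol` (relative). Balanced entries are
#' `raw[i,j] * weights[i] * weights[j]`, scaled so unmasked marginals
#' average 1.
#'
#' @param mat A raw-count `contact_matrix`.
#' @param tol Relative convergence tolerance on marginals.
#' @param max_iter Maximum iterations.
#' @param mad_max MAD cutoff for the marginal filter.
#' @return A balanced `contact_matrix` with per-bin `weights`.
#' @export
balance_matrix <- function(mat, tol = 1e-5, max_iter = 1000, mad_max = 5) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (tol <= 0) stop("tol must be positive")
  m <- mat$mat
  m[is.na(m)] <- 0
  marg <- rowSums(m)
  valid <- mat$mask & marg > 0
  if (any(valid)) {
    # one-sided low-coverage filter: only unusually empty bins are dropped.
    # The robust scale is floored at half a log2 unit so that on maps with
    # near-noiseless marginals (where the MAD collapses) ordinary structural
    # variation is not mistaken for dropout.
    lm <- log(marg[valid])
    dev <- lm - stats::median(lm)
    madv <- max(stats::median(abs(dev)), 0.5 * log(2))
    valid[valid] <- dev >= -mad_max * madv
  }
  if (!any(valid)) stop("all bins masked; nothing to balance")
  sub <- m[valid, valid, drop = FALSE]
  b <- rep(1, nrow(sub))
  for (it in seq_len(max_iter)) {
    s <- rowSums(sub / outer(b, b))
    s <- s / mean(s)
    b <- b * sqrt(s)
    if (max(abs(s - 1)) < tol) break
  }
  bal_sub <- sub / outer(b, b)
  scale <- mean(rowSums(bal_sub))
  bal_sub <- bal_sub / scale
  w_sub <- 1 / (b * sqrt(scale))
  n <- nrow(m)
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- bal_sub
  weights <- rep(NA_real_, n)
  weights[valid] <- w_sub
  contact_matrix(mat$chrom, mat$bin_size, out, mask = valid,
                 balanced = TRUE, weights = weights)
}

#' Expected contact value by bin distance
#'
#' The expected at distance `d` is the mean of unmasked entries on the d-th
#' diagonal. Diagonals with fewer than `min_pairs` unmasked pairs are pooled
#' within geometric distance bins (shared sums over counts), and a still-
#' sparse geometric bin is merged with its nearest populated neighbour.
#'
#' @param mat A balanced `contact_matrix`.
#' @param min_pairs Minimum unmasked pairs for a diagonal to stand alone.
#' @param bins_per_decade Geometric pooling resolution.
#' @return A list with `dist` (bins), `expected`, and `n_pairs`.
#' @export
expected_by_distance <- function(mat, min_pairs = 10, bins_per_decade = 8) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (!mat$balanced) stop("expected_by_distance requires a balanced matrix")
  n <- nrow(mat$mat)
  d <- bin_dist(n)
  ut <- upper.tri(mat$mat)
  v <- mat$mat[ut]
  dd <- d[ut]
  ok <- !is.na(v)
  sums <- rep(0, n - 1)
  cnts <- rep(0, n - 1)
  s <- tapply(v[ok], dd[ok], sum)
  cn <- tapply(rep(1, sum(ok)), dd[ok], sum)
  idx <- as.integer(names(s))
  sums[idx] <- s
  cnts[idx] <- cn
  expected <- ifelse(cnts > 0, sums / cnts, NA_real_)
  sparse <- cnts < min_pairs | sums == 0
  if (any(sparse)) {
    gbin <- floor(log10(seq_len(n - 1)) * bins_per_decade)
    gs <- tapply(sums, gbin, sum)
    gc <- tapply(cnts, gbin, sum)
    gmean <- gs / pmax(gc, 1)
    pop <- which(gc >= min_pairs)
    for (dd2 in which(sparse)) {
      gb <- as.character(gbin[dd2])
      gi <- match(gb, names(gs))
      if (!(gi %in% pop) && length(pop)) gi <- pop[which.min(abs(pop - gi))]
      expected[dd2] <- gmean[gi]
    }
  }
  list(dist = seq_len(n - 1), expected = as.numeric(expected), n_pairs = as.numeric(cnts))
}

#' Observed/expected contact matrix
#'
#' Divides each entry by the expected at its bin distance. The diagonal and
#' the first `exclude_diags - 1` off-diagonals are masked (short-range
#' ligation artefact convention; configurable).
#'
#' @param mat A balanced `contact_matrix`.
#' @param exclude_diags Smallest bin distance retained (default 2).
#' @param min_pairs,bins_per_decade Passed to [expected_by_distance()].
#' @return An O/E-flagged `contact_matrix`.
#' @export
observed_over_expected <- function(mat, exclude_diags = 2, min_pairs = 10,
                                   bins_per_decade = 8) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (!mat$balanced) stop("observed_over_expected requires a balanced matrix")
  exp_d <- expected_by_distance(mat, min_pairs = min_pairs, bins_per_decade = bins_per_decade)
  n <- nrow(mat$mat)
  d <- bin_dist(n)
  if (any(exp_d$expected == 0 & exp_d$n_pairs > 0, na.rm = TRUE))
    stop("zero expected value at an occupied distance")
  ev <- c(NA_real_, exp_d$expected)[d + 1]
  oe <- mat$mat / ev
  oe[d < exclude_diags] <- NA_real_
  contact_matrix(mat$chrom, mat$bin_size, oe, mask = mat$mask,
                 balanced = TRUE, weights = mat$weights, oe = TRUE)
}

#' Contact-frequency distance-decay curve
#'
#' Aggregates balanced contact frequencies in geometric distance bins across
#' chromosomes, normalises each sample's curve to unit area in log10
#' distance (so samples of different total signal are comparable), and
#' reports the per-distance median and standard deviation across replicas.
#'
#' @param samples One replica (a list of balanced `contact_matrix`) or a
#'   list of replicas.
#' @param bins_per_decade Geometric distance bins per decade.
#' @return A tibble: `dist_bp` (geometric bin centre), `freq` (median across
#'   replicas), `freq_sd`, `n_pairs`.
#' @export
contact_scaling <- function(samples, bins_per_decade = 8) {
  if (inherits(samples, "contact_matrix") ||
      (is.list(samples) && length(samples) && inherits(samples[[1]], "contact_matrix")))
    samples <- list(as_matrix_list(samples))
  bs <- unique(unlist(lapply(samples, function(s) vapply(s, function(m) m$bin_size, 0))))
  if (length(bs) != 1) stop("all matrices must share one bin size")
  one_curve <- function(mats) {
    sums <- list(); cnts <- list()
    for (m in mats) {
      if (!m$balanced) stop("contact_scaling requires balanced matrices")
      n <- nrow(m$mat)
      ut <- upper.tri(m$mat)
      v <- m$mat[ut]; dd <- bin_dist(n)[ut]
      ok <- !is.na(v) & dd >= 1
      gb <- floor(log10(dd[ok] * bs) * bins_per_decade)
      sums[[length(sums) + 1]] <- tapply(v[ok], gb, sum)
      cnts[[length(cnts) + 1]] <- tapply(rep(1, sum(ok)), gb, sum)
    }
    keys <- sort(unique(as.integer(unlist(lapply(sums, names)))))
    s <- c_by_key(sums, keys); cn <- c_by_key(cnts, keys)
    freq <- s / cn
    centre <- 10^((keys + 0.5) / bins_per_decade)
    width <- 1 / bins_per_decade
    area <- sum(freq * width)
    list(keys = keys, freq = freq / area, n = cn, centre = centre)
  }
  curves <- lapply(samples, one_curve)
  keys <- sort(unique(unlist(lapply(curves, `[[`, "keys"))))
  fm <- sapply(curves, function(cu) cu$freq[match(keys, cu$keys)])
  fm <- matrix(fm, nrow = length(keys))
  np <- rowSums(sapply(curves, function(cu) {
    x <- cu$n[match(keys, cu$keys)]; ifelse(is.na(x), 0, x)
  }))
  tibble::tibble(
    dist_bp = 10^((keys + 0.5) / bins_per_decade),
    freq = apply(fm, 1, stats::median, na.rm = TRUE),
    freq_sd = apply(fm, 1, stats::sd),
    n_pairs = np
  )
}

c_by_key <- function(lst, keys) {
  out <- rep(0, length(keys))
  for (x in lst) {
    i <- match(as.integer(names(x)), keys)
    out[i] <- out[i] + as.numeric(x)
  }
  out
}

#' Short- and long-range contact fractions
#'
#' Fractions of the total unmasked cis signal at genomic separation at most
#' `short_max` (intra-TAD scale) and at least `long_min` (long range).
#'
#' @param mats A balanced `contact_matrix` or list of them (pooled).
#' @param short_max Short-range cutoff in bp (default 0.3 Mb).
#' @param long_min Long-range cutoff in bp (default 10 Mb).
#' @return Named list: `short_fraction`, `mid_fraction`, `long_fraction`
#'   (they sum to 1).
#' @export
range_fractions <- function(mats, short_max = 0.3e6, long_min = 10e6) {
  if (short_max >= long_min) stop("short_max must be below long_min")
  mats <- as_matrix_list(mats)
  tot <- short <- long <- 0
  for (m in mats) {
    if (!m$balanced) stop("range_fractions requires balanced matrices")
    n <- nrow(m$mat)
    ut <- upper.tri(m$mat)
    v <- m$mat[ut]; dbp <- bin_dist(n)[ut] * m$bin_size
    ok <- !is.na(v) & dbp >= m$bin_size
    tot <- tot + sum(v[ok])
    short <- short + sum(v[ok & dbp <= short_max])
    long <- long + sum(v[ok & dbp >= long_min])
  }
  if (tot <= 0) stop("no unmasked cis signal")
  list(short_fraction = short / tot,
       mid_fraction = (tot - short - long) / tot,
       long_fraction = long / tot)
}

#' Differential contact map against a reference
#'
#' Both matrices are rescaled to unit mean unmasked signal, then the map is
#' `log((sample + pseudo) / (reference + pseudo))`. Antisymmetric under
#' swapping the arguments.
#'
#' @param sample,reference Balanced `contact_matrix` objects on the same
#'   chromosome and binning.
#' @param pseudo Positive pseudocount on the rescaled values.
#' @return A `contact_matrix` of signed log ratios (masked where either
#'   input is masked).
#' @export
differential_map <- function(sample, reference, pseudo = 1e-6) {
  stopifnot(inherits(sample, "contact_matrix"), inherits(reference, "contact_matrix"))
  if (pseudo <= 0) stop("pseudo must be positive")
  if (!sample$balanced || !reference$balanced) stop("both matrices must be balanced")
  if (!identical(dim(sample$mat), dim(reference$mat)) ||
      !identical(sample$chrom, reference$chrom) ||
      !isTRUE(all.equal(sample$bin_size, reference$bin_size)))
    stop("sample and reference must share chromosome and binning")
  rescale <- function(m) m$mat / mean(m$mat[upper.tri(m$mat)], na.rm = TRUE)
  s <- rescale(sample); r <- rescale(reference)
  out <- log((s + pseudo) / (r + pseudo))
  mask <- sample$mask & reference$mask
  contact_matrix(sample$chrom, sample$bin_size, out, mask = mask, balanced = TRUE)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums raw counts over `factor` x `factor` blocks. Apply before balancing.
#'
#' @param mat A raw-count `contact_matrix`.
#' @param factor Positive integer coarsening factor.
#' @return A `contact_matrix` at `bin_size * factor`.
#' @export
coarsen_matrix <- function(mat, factor) {
  stopifnot(inherits(mat, "contact_matrix"))
  factor <- as.integer(factor)
  if (mat$balanced || mat$oe) stop("coarsen raw counts, then balance")
  m <- mat$mat
  m[is.na(m)] <- 0
  n <- nrow(m)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  agg <- rowsum(m, grp)
  agg <- t(rowsum(t(agg), grp))
  contact_matrix(mat$chrom, mat$bin_size * factor, agg)
}

#' Write a contact matrix as coordinate-list text
#'
#' Tab-separated `chrom bin_i bin_j count` (0-based bins, upper triangle
#' including the diagonal, zero entries omitted), with a header line.
#'
#' @param mat A `contact_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(mat, path) {
  stopifnot(inherits(mat, "contact_matrix"))
  m <- mat$mat
  keep <- upper.tri(m, diag = TRUE) & !is.na(m) & m != 0
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(chrom = mat$chrom, bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = m[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coordinate-list text contact matrix
#'
#' @param path File written by [write_contacts()].
#' @param n_bins Number of bins on the chromosome.
#' @param bin_size Bin size in bp.
#' @return A `contact_matrix` of raw counts.
#' @export
read_contacts <- function(path, n_bins, bin_size) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$count
  m[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$count
  contact_matrix(df$chrom[1], bin_size, m)
}
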