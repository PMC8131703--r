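#' One value per genomic bin
#'
#' The universal 1-D currency of the package: replication-timing scores,
#' early/late read counts, RIF1 association scores, compartment eigenvectors
#' and quantile labels are all binned tracks. Missing bins are `NA`, never
#' silently zero, so masking survives every downstream operation.
#'
#' @param genome A [genome_spec()].
#' @param values Numeric vector, one value per bin in genome order; `NA`
#'   marks a masked bin.
#' @param name Optional track name (used for labelling outputs).
#' @return A `binned_track` object.
#' @export
binned_track <- function(genome, values, name = "track") {
  stopifnot(inherits(genome, "genome_spec"))
  if (length(values) != n_bins(genome))
    stop("track length (", length(values), ") does not match genome bins (", n_bins(genome), ")")
  structure(
    list(genome = genome, values = as.numeric(values), name = as.character(name)),
    class = "binned_track"
  )
}

#' @export
print.binned_track <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<binned_track> '%s': %d bins (%d masked), range [%.3g, %.3g]\n",
    x$name, length(v), sum(is.na(v)),
    suppressWarnings(min(v, na.rm = TRUE)), suppressWarnings(max(v, na.rm = TRUE))
  ))
  invisible(x)
}

#' @export
as.data.frame.binned_track <- function(x, ...) {
  cbind(as.data.frame(genome_bins(x$genome)), value = x$values)
}

#' Track values as a plain numeric vector
#' @param track A `binned_track`.
#' @return Numeric vector with `NA` at masked bins.
#' @export
track_values <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  track$values
}

#' Coarsen a track to a larger bin size
#'
#' Each coarse bin takes the mean of its constituent unmasked fine bins;
#' a coarse bin whose fine bins are all masked stays masked.
#'
#' @param track A `binned_track`.
#' @param factor Positive integer coarsening factor.
#' @return A `binned_track` on [coarsen_genome()] bins.
#' @export
coarsen_track <- function(track, factor) {
  stopifnot(inherits(track, "binned_track"))
  g <- track$genome
  cg <- coarsen_genome(g, factor)
  out <- numeric(0)
  for (ch in g$chrom) {
    v <- track$values[chrom_slice(g, ch)]
    grp <- (seq_along(v) - 1L) %/% factor
    m <- tapply(v, grp, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    out <- c(out, as.numeric(m))
  }
  binned_track(cg, out, name = track$name)
}

#' Centre a track on its genome-wide median
#'
#' Removes the additive offset left by unequal sequencing depths of the two
#' Repli-seq fractions before profiles are compared across samples.
#'
#' @param track A `binned_track`.
#' @return A `binned_track` with median (over unmasked bins) subtracted.
#' @export
median_center <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  binned_track(track$genome, track$values - stats::median(track$values, na.rm = TRUE),
               name = track$name)
}

#' Write a track as bedGraph
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open
#' coordinates, no header. Masked bins are omitted.
#'
#' @param track A `binned_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)
  df <- df[!is.na(df$value), c("chrom", "start", "end", "value")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a genome's bins
#'
#' Intervals must coincide with the genome's bins; bins absent from the file
#' are masked.
#'
#' @param path bedGraph file (chrom, start, end, value; no header).
#' @param genome A [genome_spec()] giving the binning.
#' @param name Track name.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, genome, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  bad <- setdiff(unique(df$chrom), genome$chrom)
  if (length(bad)) stop("bedGraph contains unknown chromosome(s): ", paste(bad, collapse = ", "))
  vals <- rep(NA_real_, n_bins(genome))
  bin <- df$start / genome$bin_size
  if (any(bin != round(bin)) || any(df$end - df$start != genome$bin_size & df$end - df$start <= 0))
    stop("bedGraph intervals do not align with the genome's bins")
  idx <- genome$offset[df$chrom] + bin + 1
  if (any(bin < 0) || any(bin + 1 > genome$length_bins[df$chrom]))
    stop("bedGraph interval outside chromosome bounds")
  vals[idx] <- df$value
  binned_track(genome, vals, name = name)
}
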