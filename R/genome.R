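#' Define a binned genome
#'
#' A genome here is an ordered set of chromosomes, each a run of fixed-size
#' bins. All tracks and contact matrices in the package refer back to such a
#' specification, so bin coordinates stay aligned across samples.
#'
#' @param length_bins Named integer vector: bins per chromosome, in genome
#'   order. Names are chromosome names and must be unique; every chromosome
#'   must have at least 10 bins.
#' @param bin_size Bin size in bp (positive integer).
#' @return A `genome_spec` object.
#' @examples
#' g <- genome_spec(c(chr1 = 400, chr2 = 400), bin_size = 50e3)
#' n_bins(g)
#' @export
genome_spec <- function(length_bins, bin_size) {
  if (length(length_bins) == 0) stop("genome must contain at least one chromosome")
  nm <- names(length_bins)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("chromosome names must be present and unique")
  length_bins <- as.integer(length_bins)
  if (any(is.na(length_bins)) || any(length_bins < 10))
    stop("every chromosome needs at least 10 bins")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a positive number")
  offsets <- cumsum(c(0L, length_bins[-length(length_bins)]))
  structure(
    list(
      chrom = nm,
      length_bins = stats::setNames(length_bins, nm),
      offset = stats::setNames(as.integer(offsets), nm),
      bin_size = as.numeric(bin_size)
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %d chromosome(s), %d bins of %s bp\n",
    length(x$chrom), n_bins(x), format(x$bin_size, big.mark = ",")
  ))
  invisible(x)
}

#' Total number of bins in a genome
#' @param genome A `genome_spec`.
#' @return Integer, total bins across chromosomes.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  sum(genome$length_bins)
}

#' Per-bin coordinate table
#'
#' @param genome A `genome_spec`.
#' @return A tibble with one row per bin: `chrom`, `bin` (0-based index within
#'   the chromosome), `start`, `end` (bp, 0-based half-open).
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  chrom <- rep(genome$chrom, genome$length_bins)
  bin <- unlist(lapply(genome$length_bins, function(n) seq_len(n) - 1L), use.names = FALSE)
  tibble::tibble(
    chrom = chrom,
    bin = bin,
    start = bin * genome$bin_size,
    end = (bin + 1) * genome$bin_size
  )
}

#' Indices of a chromosome's bins within the genome-wide order
#' @param genome A `genome_spec`.
#' @param chrom Chromosome name.
#' @return Integer vector of positions into a genome-wide track.
#' @export
chrom_slice <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!chrom %in% genome$chrom) stop("unknown chromosome: ", chrom)
  genome$offset[[chrom]] + seq_len(genome$length_bins[[chrom]])
}

#' Coarsen a genome to a larger bin size
#'
#' Groups of `factor` consecutive bins become one bin; a trailing partial
#' group becomes a (shorter-than-nominal) final bin.
#'
#' @param genome A `genome_spec`.
#' @param factor Positive integer coarsening factor.
#' @return A `genome_spec` at `bin_size * factor`.
#' @export
coarsen_genome <- function(genome, factor) {
  stopifnot(inherits(genome, "genome_spec"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  genome_spec(ceiling(genome$length_bins / factor), genome$bin_size * factor)
}

same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) &&
    identical(a$length_bins, b$length_bins) &&
    isTRUE(all.equal(a$bin_size, b$bin_size))
}
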