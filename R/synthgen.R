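# Synthetic genomes with planted replication-timing and compartment structure.
# Every operation is a pure function of (inputs, seed): randomness is drawn
# inside withr::with_seed(seed + op-specific constant), so repeated calls with
# the same arguments reproduce byte-identical output and the caller's RNG
# state is untouched.

SEED_SEGMENT <- 101L
SEED_RT <- 211L
SEED_REPLISEQ <- 307L
SEED_RIF1 <- 401L
SEED_HIC <- 503L
SEED_RELABEL <- 601L

#' Two-component replication-timing mixture parameters
#'
#' Domain-level RT scores are drawn from a two-component Gaussian mixture:
#' the early component for A-compartment domains and the late component for
#' B-compartment domains. The defaults plant a clearly bimodal genome
#' (modes at +/-1.5 RT units).
#'
#' @param mu_early,mu_late Component means (RT units, log2 early/late);
#'   `mu_early > mu_late` required.
#' @param sigma Common component standard deviation (> 0).
#' @param p_early Marginal weight of the early component in (0, 1); with the
#'   default label process compartments are balanced, so 0.5.
#' @return A list of mixture parameters.
#' @export
rt_mixture <- function(mu_early = 1.5, mu_late = -1.5, sigma = 0.3, p_early = 0.5) {
  if (!(mu_early > mu_late)) stop("mu_early must exceed mu_late")
  if (sigma <= 0) stop("sigma must be positive")
  if (p_early <= 0 || p_early >= 1) stop("p_early must lie in (0, 1)")
  list(mu_early = mu_early, mu_late = mu_late, sigma = sigma, p_early = p_early)
}

#' Synthetic genotype parameter bundle
#'
#' Encodes one member of a genotype dose series. `lambda_mix` linearly mixes
#' the planted compartment structure toward a structure-free null on the
#' observed/expected scale: 0 keeps the full checkerboard, 1 erases it.
#' `rt_pattern` controls the planted replication-timing landscape:
#' `"shared"` uses the genome's reference landscape, `"reprogrammed"` draws a
#' fresh landscape (same domains, new timing) with mixture means scaled by
#' `rt_scale` -- emulating genotypes whose timing programme is lost and whose
#' RT distribution collapses toward zero.
#'
#' @param name Genotype name.
#' @param lambda_mix Mixing toward the structure-free null, in \[0, 1\].
#' @param coverage Expected-count scale: expected contacts at unit distance
#'   per bin pair (> 0).
#' @param repliseq_depth Total reads per Repli-seq fraction (> 0).
#' @param seed Integer seed for this genotype's random draws.
#' @param rt_pattern `"shared"` or `"reprogrammed"` (see above).
#' @param rt_scale Multiplier applied to the mixture means when the landscape
#'   is reprogrammed.
#' @return A `genotype_spec` object.
#' @export
genotype_spec <- function(name, lambda_mix, coverage = 100, repliseq_depth = 2e6,
                          seed = 1L, rt_pattern = c("shared", "reprogrammed"),
                          rt_scale = 1) {
  if (lambda_mix < 0 || lambda_mix > 1) stop("lambda_mix must lie in [0, 1]")
  if (coverage <= 0) stop("coverage must be positive")
  if (repliseq_depth <= 0) stop("repliseq_depth must be positive")
  structure(
    list(name = name, lambda_mix = lambda_mix, coverage = coverage,
         repliseq_depth = repliseq_depth, seed = as.integer(seed),
         rt_pattern = match.arg(rt_pattern), rt_scale = rt_scale),
    class = "genotype_spec"
  )
}

#' Segment a genome into replication domains
#'
#' Domain lengths are geometric with the stated mean (support starting at 2
#' bins), truncated to the remaining chromosome length; a tail shorter than 2
#' bins is absorbed into the previous domain, and a chromosome whose length
#' does not exceed the target mean becomes a single domain. Each domain gets
#' a compartment label (alternating with probability 0.7, otherwise an
#' independent fair draw) and a domain-level RT score from the mixture
#' component matching its label (A = early, B = late).
#'
#' @param genome A [genome_spec()].
#' @param mean_domain_bins Target mean domain length in bins (>= 2).
#' @param seed Integer seed.
#' @param mixture Mixture parameters from [rt_mixture()].
#' @param p_alternate Probability that adjacent domains alternate labels.
#' @return A `domain_segmentation`: tibble of domains (`chrom`, `start_bin`,
#'   `end_bin`, half-open; `label` in A/B; `rt_value`) with the genome
#'   attached as an attribute.
#' @export
segment_genome <- function(genome, mean_domain_bins, seed,
                           mixture = rt_mixture(), p_alternate = 0.7) {
  stopifnot(inherits(genome, "genome_spec"))
  if (mean_domain_bins < 2) stop("mean_domain_bins must be at least 2")
  withr::with_seed(seed + SEED_SEGMENT, {
    doms <- lapply(genome$chrom, function(ch) {
      n <- genome$length_bins[[ch]]
      if (mean_domain_bins >= n) {
        lens <- n
      } else {
        lens <- integer(0); left <- n
        while (left > 0) {
          d <- 2L + stats::rgeom(1, 1 / (mean_domain_bins - 1))
          d <- min(d, left)
          if (left - d < 2L) d <- left
          lens <- c(lens, d); left <- left - d
        }
      }
      k <- length(lens)
      lab <- character(k)
      lab[1] <- sample(c("A", "B"), 1)
      if (k > 1) for (i in 2:k) {
        lab[i] <- if (stats::runif(1) < p_alternate) setdiff(c("A", "B"), lab[i - 1]) else sample(c("A", "B"), 1)
      }
      mu <- ifelse(lab == "A", mixture$mu_early, mixture$mu_late)
      tibble::tibble(
        chrom = ch,
        start_bin = cumsum(c(0L, lens[-k])),
        end_bin = cumsum(lens),
        label = lab,
        rt_value = stats::rnorm(k, mu, mixture$sigma)
      )
    })
  })
  seg <- do.call(rbind, doms)
  structure(seg, genome = genome, class = c("domain_segmentation", class(seg)))
}

seg_genome <- function(seg) attr(seg, "genome")

#' Expand a segmentation to a per-bin vector
#'
#' @param seg A `domain_segmentation`.
#' @param field `"rt_value"` for the domain RT score or `"label"` for the
#'   compartment label (+1 for A, -1 for B).
#' @return Numeric vector over all genome bins.
#' @export
segmentation_bins <- function(seg, field = c("rt_value", "label")) {
  field <- match.arg(field)
  lens <- seg$end_bin - seg$start_bin
  if (field == "rt_value") rep(seg$rt_value, lens) else rep(ifelse(seg$label == "A", 1, -1), lens)
}

#' Reassign a fraction of B domains to the A compartment
#'
#' Emulates an expansion of the A compartment: a random fraction of B
#' domains flips label (and redraws its RT score from the early component).
#'
#' @param seg A `domain_segmentation`.
#' @param fraction Fraction of B domains to flip, in \[0, 1\].
#' @param seed Integer seed.
#' @param mixture Mixture used to redraw flipped domains' RT.
#' @return A `domain_segmentation`.
#' @export
reassign_labels <- function(seg, fraction, seed, mixture = rt_mixture()) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  b <- which(seg$label == "B")
  withr::with_seed(seed + SEED_RELABEL, {
    flip <- sample(b, round(fraction * length(b)))
    seg$label[flip] <- "A"
    seg$rt_value[flip] <- stats::rnorm(length(flip), mixture$mu_early, mixture$sigma)
  })
  seg
}

#' Redraw a segmentation's timing landscape
#'
#' Keeps the domain structure and compartment labels but draws fresh
#' domain-level RT values, independent of both the previous landscape and
#' the compartment labels, from a mixture with means scaled by `rt_scale`.
#' Models a genotype whose replication-timing programme is reprogrammed and
#' compressed toward zero while its compartments persist.
#'
#' @param seg A `domain_segmentation`.
#' @param rt_scale Multiplier on the mixture means (1 = full amplitude).
#' @param seed Integer seed.
#' @param mixture Reference mixture whose means are scaled.
#' @return A `domain_segmentation` with new `rt_value`s.
#' @export
reprogram_rt <- function(seg, rt_scale, seed, mixture = rt_mixture()) {
  k <- nrow(seg)
  withr::with_seed(seed + SEED_RT + 7L, {
    comp <- stats::runif(k) < mixture$p_early
    mu <- ifelse(comp, mixture$mu_early, mixture$mu_late) * rt_scale
    seg$rt_value <- stats::rnorm(k, mu, mixture$sigma * abs(rt_scale))
  })
  seg
}

#' Per-bin replication-timing track from a segmentation
#'
#' Bins inherit their domain's RT score plus i.i.d. Gaussian bin noise.
#'
#' @param seg A `domain_segmentation`.
#' @param bin_noise_sd Non-negative noise standard deviation.
#' @param seed Integer seed.
#' @return A `binned_track` of planted RT scores.
#' @export
make_rt_track <- function(seg, bin_noise_sd, seed) {
  if (bin_noise_sd < 0) stop("bin_noise_sd must be non-negative")
  g <- seg_genome(seg)
  base <- segmentation_bins(seg, "rt_value")
  vals <- withr::with_seed(seed + SEED_RT, base + stats::rnorm(length(base), 0, bin_noise_sd))
  binned_track(g, vals, name = "rt_planted")
}

#' Simulate early/late Repli-seq counts from an RT track
#'
#' Inverse model of the RT estimator: each bin's early-fraction weight is the
#' logistic `2^rt / (1 + 2^rt)`, and each fraction's reads are multinomial
#' over bins with probabilities proportional to the weights. The downstream
#' log2(early/late) RPM score then recovers the planted RT up to sampling
#' noise and a genome-wide additive offset.
#'
#' @param rt A `binned_track` of RT scores (masked bins receive no reads).
#' @param depth Total reads per fraction (> 0).
#' @param seed Integer seed.
#' @return List with `early` and `late` count tracks.
#' @export
simulate_repliseq_counts <- function(rt, depth, seed) {
  stopifnot(inherits(rt, "binned_track"))
  if (depth <= 0) stop("depth must be positive")
  v <- rt$values
  w <- 2^v / (1 + 2^v)
  w[is.na(w)] <- 0
  lw <- ifelse(is.na(v), 0, 1 - 2^v / (1 + 2^v))
  counts <- withr::with_seed(seed + SEED_REPLISEQ, {
    list(
      early = as.numeric(stats::rmultinom(1, size = depth, prob = w)),
      late = as.numeric(stats::rmultinom(1, size = depth, prob = lw))
    )
  })
  counts$early[is.na(v)] <- NA_real_
  counts$late[is.na(v)] <- NA_real_
  list(
    early = binned_track(rt$genome, counts$early, name = "early_counts"),
    late = binned_track(rt$genome, counts$late, name = "late_counts")
  )
}

#' Simulate a RIF1-association track
#'
#' RIF1 occupancy anti-correlates with replication timing: the track is the
#' negated RT score plus Gaussian noise, so contiguous high stretches over
#' late-replicating domains emulate RIF1-associated domains (RADs).
#'
#' @param rt A `binned_track` of RT scores.
#' @param noise_sd Non-negative noise standard deviation.
#' @param seed Integer seed.
#' @return A `binned_track` of RIF1 scores.
#' @export
simulate_rif1_track <- function(rt, noise_sd, seed) {
  stopifnot(inherits(rt, "binned_track"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  vals <- withr::with_seed(seed + SEED_RIF1,
                           -rt$values + stats::rnorm(length(rt$values), 0, noise_sd))
  binned_track(rt$genome, vals, name = "rif1")
}

# O/E-scale structure factor for bins i, j given +/-1 labels:
# (1 - lambda) * exp(delta * c_i * c_j) + lambda
structure_factor <- function(ci, delta, lambda_mix) {
  (1 - lambda_mix) * exp(delta * outer(ci, ci)) + lambda_mix
}

#' Simulate cis Hi-C contact matrices
#'
#' For bins i < j on one chromosome with compartment signs `c` (+1 for A,
#' -1 for B), the expected count is
#' `coverage * |i-j|^(-decay_alpha) * ((1-lambda) * exp(delta c_i c_j) + lambda)`;
#' observed counts are Poisson around that expectation (or the expectation
#' itself with `noise = "none"`), symmetrised, with a zero, masked diagonal.
#'
#' @param seg A `domain_segmentation` supplying compartment labels.
#' @param genotype A [genotype_spec()] (supplies `lambda_mix`, `coverage`,
#'   and the seed).
#' @param decay_alpha Power-law distance-decay exponent (> 0).
#' @param delta Non-negative log-scale compartment preference.
#' @param noise `"poisson"` for sampled counts, `"none"` for the expectation.
#' @return List of `contact_matrix` (raw counts), one per chromosome.
#' @export
simulate_hic <- function(seg, genotype, decay_alpha = 1, delta = 0.5,
                         noise = c("poisson", "none")) {
  stopifnot(inherits(genotype, "genotype_spec"))
  noise <- match.arg(noise)
  if (delta < 0) stop("delta must be non-negative")
  if (decay_alpha <= 0) stop("decay_alpha must be positive")
  g <- seg_genome(seg)
  signs <- segmentation_bins(seg, "label")
  mats <- vector("list", length(g$chrom))
  names(mats) <- g$chrom
  for (k in seq_along(g$chrom)) {
    ch <- g$chrom[k]
    ci <- signs[chrom_slice(g, ch)]
    n <- length(ci)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    lam <- genotype$coverage * ifelse(d > 0, d^(-decay_alpha), 0) *
      structure_factor(ci, delta, genotype$lambda_mix)
    if (noise == "poisson") {
      m <- matrix(0, n, n)
      ut <- upper.tri(lam)
      m[ut] <- withr::with_seed(genotype$seed + SEED_HIC + k,
                                stats::rpois(sum(ut), lam[ut]))
      m <- m + t(m)
    } else {
      m <- lam
    }
    mats[[k]] <- contact_matrix(ch, g$bin_size, m)
  }
  mats
}

#' Noiseless observed/expected expectation of the block model
#'
#' Returns the generative structure factor
#' `(1-lambda) * exp(delta c_i c_j) + lambda` as O/E-scale matrices -- the
#' exact expectation of the observed/expected map relative to the pure
#' power-law decay. The saddle corner strength of these matrices has the
#' closed form `((1-lambda) e^delta + lambda)^2 / ((1-lambda) e^-delta + lambda)^2`,
#' which reduces to `exp(4 delta)` at `lambda = 0`.
#'
#' @param seg A `domain_segmentation`.
#' @param delta Non-negative log-scale compartment preference.
#' @param lambda_mix Mixing toward the structure-free null in \[0, 1\].
#' @return List of O/E-flagged `contact_matrix` objects, one per chromosome.
#' @export
structured_oe_expectation <- function(seg, delta, lambda_mix = 0) {
  if (delta < 0) stop("delta must be non-negative")
  if (lambda_mix < 0 || lambda_mix > 1) stop("lambda_mix must lie in [0, 1]")
  g <- seg_genome(seg)
  signs <- segmentation_bins(seg, "label")
  mats <- lapply(g$chrom, function(ch) {
    ci <- signs[chrom_slice(g, ch)]
    m <- structure_factor(ci, delta, lambda_mix)
    diag(m) <- NA_real_
    contact_matrix(ch, g$bin_size, m, oe = TRUE, balanced = TRUE)
  })
  names(mats) <- g$chrom
  mats
}

#' Observed/expected against the generative decay law
#'
#' Divides raw simulated counts by the structure-free expectation
#' `coverage * d^(-alpha)`. Because the null decay is known exactly for
#' synthetic data, the result is an unbiased (up to Poisson noise) estimate
#' of the planted structure factor -- the estimator used for
#' planted-parameter recovery checks, free of the finite-size attenuation of
#' the empirical per-diagonal expected.
#'
#' @param mat A raw-count `contact_matrix` from [simulate_hic()].
#' @param coverage Generator coverage.
#' @param decay_alpha Generator decay exponent.
#' @return An O/E-flagged `contact_matrix`.
#' @export
model_oe <- function(mat, coverage, decay_alpha = 1) {
  stopifnot(inherits(mat, "contact_matrix"))
  n <- nrow(mat$mat)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  oe <- mat$mat / (coverage * ifelse(d > 0, d^(-decay_alpha), NA_real_))
  contact_matrix(mat$chrom, mat$bin_size, oe, mask = mat$mask, oe = TRUE, balanced = TRUE)
}

#' Default synthetic experiment configuration
#'
#' The study conditions: a 10-chromosome genome of 400 bins of 50 kb
#' (20 Mb chromosomes), megabase-scale replication domains (mean 2 Mb),
#' a strongly bimodal RT mixture, unit power-law decay and a compartment
#' preference `delta = 0.5`, with a wild-type-like / hemizygous-like /
#' knockout-like dose series at `lambda_mix` 0 / 0.4 / 0.8. The
#' knockout-like genotype additionally carries a reprogrammed, compressed
#' timing landscape whose amplitude (5% of wild type) keeps the
#' mean-of-replicates RT distribution analytically unimodal: the mode
#' separation stays below twice the component standard deviation once the
#' per-replicate bin noise is attenuated by sqrt(n_replicates) in the mean
#' profile.
#'
#' @param genome A [genome_spec()].
#' @param mean_domain_bins Mean domain length in bins.
#' @param mixture Mixture parameters from [rt_mixture()].
#' @param decay_alpha Power-law decay exponent.
#' @param delta_compartment Compartment preference on the log O/E scale.
#' @param rt_bin_noise_sd Per-bin RT noise sd.
#' @param rif1_noise_sd RIF1 track noise sd.
#' @param coverage Hi-C coverage scale.
#' @param repliseq_depth Reads per Repli-seq fraction.
#' @param n_replicates Replicates per genotype.
#' @param ko_rt_scale RT amplitude retained by the knockout-like landscape.
#' @param seed Global seed; per-genotype and per-replicate seeds derive
#'   from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(genome = genome_spec(stats::setNames(rep(400L, 10), paste0("chr", 1:10)), 50e3),
                         mean_domain_bins = 40,
                         mixture = rt_mixture(),
                         decay_alpha = 1,
                         delta_compartment = 0.5,
                         rt_bin_noise_sd = 0.2,
                         rif1_noise_sd = 0.5,
                         coverage = 100,
                         repliseq_depth = 2e6,
                         n_replicates = 3,
                         ko_rt_scale = 0.05,
                         seed = 1L) {
  structure(
    list(genome = genome, mean_domain_bins = mean_domain_bins, mixture = mixture,
         decay_alpha = decay_alpha, delta_compartment = delta_compartment,
         rt_bin_noise_sd = rt_bin_noise_sd, rif1_noise_sd = rif1_noise_sd,
         coverage = coverage, repliseq_depth = repliseq_depth,
         n_replicates = n_replicates, ko_rt_scale = ko_rt_scale,
         seed = as.integer(seed),
         lambda_series = c("WT-like" = 0, "hem-like" = 0.4, "KO-like" = 0.8)),
    class = "synth_config"
  )
}
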