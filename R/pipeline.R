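# End-to-end orchestration: generate a synthetic genotype panel, run the
# Repli-seq and Hi-C analyses per genotype, and collect the panel-by-panel
# result bundle.

#' Experiment configuration
#'
#' Bundles the generator configuration with the analysis parameters: the
#' compartment/saddle analysis resolution (250 kb, by coarsening the
#' generation-resolution bins), saddle quantiles and corner fraction,
#' distance bands for strength-by-distance, and the timing-change
#' thresholds.
#'
#' @param synth A [synth_config()].
#' @param compartment_bin_size Analysis resolution for compartments and
#'   saddles (bp).
#' @param n_quantiles Saddle quantiles Q.
#' @param corner_fraction Saddle corner fraction.
#' @param trim_fraction Digitisation trim.
#' @param bands Distance bands (bp) for strength-by-distance.
#' @param switch_threshold,change_threshold Timing-change thresholds
#'   (RT units).
#' @param pseudocount RT pseudocount (RPM).
#' @param reference Name of the reference genotype for differential
#'   analyses.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(),
                              compartment_bin_size = 250e3,
                              n_quantiles = 20,
                              corner_fraction = 0.2,
                              trim_fraction = 0.02,
                              bands = list(c(1e6, 3e6), c(3e6, 6e6), c(6e6, 10e6), c(10e6, 20e6)),
                              switch_threshold = 0.5,
                              change_threshold = 0.25,
                              pseudocount = 0.1,
                              reference = "WT-like") {
  structure(
    list(synth = synth, compartment_bin_size = compartment_bin_size,
         n_quantiles = n_quantiles, corner_fraction = corner_fraction,
         trim_fraction = trim_fraction, bands = bands,
         switch_threshold = switch_threshold, change_threshold = change_threshold,
         pseudocount = pseudocount, reference = reference),
    class = "experiment_config"
  )
}

rep_seed <- function(base, g_idx, r) base + 1000L * g_idx + 100L * r

mean_oe_matrices <- function(oe_reps) {
  # element-wise mean of replicate O/E matrices for one chromosome
  out <- oe_reps[[1]]
  if (length(oe_reps) > 1) {
    arr <- simplify2array(lapply(oe_reps, function(m) m$mat))
    mu <- apply(arr, c(1, 2), function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    mask <- Reduce(`|`, lapply(oe_reps, function(m) m$mask))
    out <- contact_matrix(out$chrom, out$bin_size, mu, mask = mask,
                          balanced = TRUE, oe = TRUE)
  }
  out
}

#' Run the full synthetic experiment
#'
#' Generates the genotype panel (shared replication-domain segmentation and
#' compartment labels; the knockout-like genotype carries a reprogrammed,
#' compressed timing landscape), simulates Repli-seq and Hi-C per replicate,
#' and runs every analysis stage: RT profiles, distribution/bimodality,
#' replica correlation and clustering, timing changes versus the reference,
#' contact scaling and range fractions, differential-map summaries,
#' compartment eigenvectors, A/B fractions, cross-sample PCA, and
#' RT-/RIF1-/E1-ranked saddles with global and distance-stratified
#' compartment strength. Deterministic given the configuration.
#'
#' @param config An [experiment_config()].
#' @param outdir Optional directory: tracks are written as bedGraph, tables
#'   as TSV, and a manifest of all parameters and seeds as YAML.
#' @return A `result_bundle` list (see Details in the package vignette).
#' @export
run_experiment <- function(config = experiment_config(), outdir = NULL) {
  sc <- config$synth
  g <- sc$genome
  factor <- as.integer(config$compartment_bin_size / g$bin_size)
  seg <- segment_genome(g, sc$mean_domain_bins, sc$seed, mixture = sc$mixture)
  seg_ko <- reprogram_rt(seg, sc$ko_rt_scale, sc$seed, mixture = sc$mixture)

  genotype_names <- names(sc$lambda_series)
  genos <- list()
  for (gi in seq_along(sc$lambda_series)) {
    nm <- genotype_names[gi]
    genos[[nm]] <- list(
      lambda = sc$lambda_series[[gi]],
      seg = if (nm == "KO-like") seg_ko else seg,
      idx = gi
    )
  }

  rt_profiles <- list()   # per replicate, median-centred
  oe_fine <- list()       # per replicate: list of balanced 50 kb matrices
  oe_coarse <- list()     # per replicate: list of O/E matrices at analysis res
  sample_names <- character(0)
  sample_geno <- character(0)

  for (nm in genotype_names) {
    ge <- genos[[nm]]
    for (r in seq_len(sc$n_replicates)) {
      sd <- rep_seed(sc$seed, ge$idx, r)
      rt_true <- make_rt_track(ge$seg, sc$rt_bin_noise_sd, sd)
      cnts <- simulate_repliseq_counts(rt_true, sc$repliseq_depth, sd)
      prof <- median_center(compute_rt_profile(
        rpm_normalize(cnts$early), rpm_normalize(cnts$late),
        pseudocount = config$pseudocount))
      gt <- genotype_spec(nm, ge$lambda, coverage = sc$coverage,
                          repliseq_depth = sc$repliseq_depth, seed = sd)
      raw <- simulate_hic(seg, gt, decay_alpha = sc$decay_alpha,
                          delta = sc$delta_compartment)
      bal <- lapply(raw, balance_matrix)
      coarse <- lapply(raw, function(m) observed_over_expected(balance_matrix(coarsen_matrix(m, factor))))
      key <- paste0(nm, "_rep", r)
      sample_names <- c(sample_names, key)
      sample_geno <- c(sample_geno, nm)
      rt_profiles[[key]] <- prof
      oe_fine[[key]] <- bal
      oe_coarse[[key]] <- coarse
    }
  }

  ref <- config$reference
  ref_keys <- sample_names[sample_geno == ref]

  # --- Repli-seq side -------------------------------------------------------
  corr <- correlate_profiles(rt_profiles, labels = sample_names)
  clust <- cluster_profiles(corr, k = 2)
  mean_profile <- function(keys) {
    m <- rowMeans(sapply(keys, function(k) track_values(rt_profiles[[k]])))
    binned_track(g, m, name = "rt_mean")
  }
  geno_mean_rt <- lapply(genotype_names, function(nm) mean_profile(sample_names[sample_geno == nm]))
  names(geno_mean_rt) <- genotype_names
  bimod <- lapply(geno_mean_rt, bimodality)
  rt_dist <- lapply(geno_mean_rt, rt_distribution)
  rt_changes <- lapply(genotype_names, function(nm) {
    if (nm == ref) NULL else
      classify_rt_changes(geno_mean_rt[[ref]], geno_mean_rt[[nm]],
                          switch_threshold = config$switch_threshold,
                          change_threshold = config$change_threshold)
  })
  names(rt_changes) <- genotype_names

  # --- Hi-C first-order side ------------------------------------------------
  scaling <- lapply(genotype_names, function(nm)
    contact_scaling(unname(oe_fine[sample_names[sample_geno == nm]])))
  names(scaling) <- genotype_names
  fractions <- lapply(genotype_names, function(nm)
    range_fractions(unlist(unname(oe_fine[sample_names[sample_geno == nm]]), recursive = FALSE)))
  names(fractions) <- genotype_names
  # long-range gain versus the reference: log ratio of the long-range share
  # of total cis signal (an entry-wise mean of log ratios would be dominated
  # by the bimodal within/between-compartment split and miss the net gain)
  diff_longrange <- lapply(genotype_names, function(nm) {
    if (nm == ref) return(0)
    keys <- sample_names[sample_geno == nm]
    vals <- sapply(seq_along(keys), function(ri) {
      fs <- range_fractions(oe_fine[[keys[ri]]])
      fr <- range_fractions(oe_fine[[ref_keys[ri]]])
      log(fs$long_fraction / fr$long_fraction)
    })
    mean(vals)
  })
  names(diff_longrange) <- genotype_names

  # --- Compartments and saddles (analysis resolution) -----------------------
  cg <- coarsen_genome(g, factor)
  wt_rt_coarse <- coarsen_track(geno_mean_rt[[ref]], factor)
  wt_rt_coarse$name <- "rt"
  rif1_fine <- simulate_rif1_track(make_rt_track(genos[[ref]]$seg, sc$rt_bin_noise_sd,
                                                 rep_seed(sc$seed, genos[[ref]]$idx, 1L)),
                                   sc$rif1_noise_sd, sc$seed)
  rif1_coarse <- coarsen_track(rif1_fine, factor)

  profiles <- lapply(sample_names, function(k)
    compartment_eigenvector(oe_coarse[[k]], wt_rt_coarse))
  names(profiles) <- sample_names
  wt_pooled_oe <- lapply(cg$chrom, function(ch)
    mean_oe_matrices(lapply(ref_keys, function(k) oe_coarse[[k]][[ch]])))
  names(wt_pooled_oe) <- cg$chrom
  wt_e1 <- compartment_eigenvector(wt_pooled_oe, wt_rt_coarse)$e1
  wt_e1$name <- "E1"

  ab <- lapply(genotype_names, function(nm) {
    fr <- sapply(sample_names[sample_geno == nm], function(k) unlist(ab_fraction(profiles[[k]])))
    list(a_fraction = mean(fr["a_fraction", ]), b_fraction = mean(fr["b_fraction", ]))
  })
  names(ab) <- genotype_names
  pca <- compartment_pca(profiles, labels = sample_names)

  rankings <- list(rt = wt_rt_coarse, rif1 = rif1_coarse, e1 = wt_e1)
  digit <- lapply(rankings, digitize_track, n_quantiles = config$n_quantiles,
                  trim_fraction = config$trim_fraction)
  saddles <- list(); strengths <- list(); strength_dist <- list()
  for (nm in genotype_names) {
    pooled <- unlist(unname(oe_coarse[sample_names[sample_geno == nm]]), recursive = FALSE)
    saddles[[nm]] <- lapply(digit, function(dg) saddle_matrix(pooled, dg))
    strengths[[nm]] <- vapply(saddles[[nm]], compartment_strength,
                              corner_fraction = config$corner_fraction, 0)
    strength_dist[[nm]] <- strength_by_distance(pooled, digit$rt, config$bands,
                                                corner_fraction = config$corner_fraction)
  }
  diff_saddles <- lapply(genotype_names, function(nm)
    if (nm == ref) NULL else
      lapply(names(rankings), function(rk)
        differential_saddle(saddles[[nm]][[rk]], saddles[[ref]][[rk]])))
  names(diff_saddles) <- genotype_names

  bundle <- structure(
    list(config = config, genotypes = genotype_names, reference = ref,
         sample_names = sample_names, sample_genotype = sample_geno,
         segmentation = seg, segmentation_ko = seg_ko,
         rt_profiles = rt_profiles, genotype_mean_rt = geno_mean_rt,
         correlation = corr, clustering = clust,
         bimodality = bimod, rt_distribution = rt_dist, rt_changes = rt_changes,
         scaling = scaling, range_fractions = fractions,
         differential_longrange = diff_longrange,
         compartment_profiles = profiles, ab_fractions = ab, pca = pca,
         rankings = rankings, saddles = saddles, strengths = strengths,
         strength_by_distance = strength_dist, differential_saddles = diff_saddles),
    class = "result_bundle"
  )
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Summarise a result bundle
#'
#' One row per genotype: bimodality score and verdict, mean within-genotype
#' replica correlation, long-range contact fraction, A-compartment fraction,
#' RT-ranked compartment strength, mean PC1 coordinate, and the RT switch
#' fraction versus the reference.
#'
#' @param bundle A `result_bundle` from [run_experiment()].
#' @return A tibble with one row per genotype.
#' @export
summarize_experiment <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  need <- c("bimodality", "correlation", "range_fractions", "ab_fractions",
            "strengths", "pca", "rt_changes")
  missing <- need[!vapply(need, function(f) !is.null(bundle[[f]]), TRUE)]
  if (length(missing)) stop("incomplete bundle; missing: ", paste(missing, collapse = ", "))
  rows <- lapply(bundle$genotypes, function(nm) {
    keys <- bundle$sample_names[bundle$sample_genotype == nm]
    cc <- bundle$correlation[keys, keys]
    ch <- bundle$rt_changes[[nm]]
    sw <- if (is.null(ch)) 0 else sum(ch$fractions[c("EtoL", "LtoE")])
    tibble::tibble(
      genotype = nm,
      bimodality_score = bundle$bimodality[[nm]]$score,
      is_bimodal = bundle$bimodality[[nm]]$is_bimodal,
      mean_replica_correlation = mean(cc[upper.tri(cc)]),
      long_range_fraction = bundle$range_fractions[[nm]]$long_fraction,
      a_fraction = bundle$ab_fractions[[nm]]$a_fraction,
      strength_rt = bundle$strengths[[nm]][["rt"]],
      pc1 = mean(bundle$pca$coords$PC1[bundle$sample_genotype == nm]),
      switch_fraction_vs_ref = sw
    )
  })
  do.call(rbind, rows)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  for (nm in bundle$genotypes) {
    write_bedgraph(bundle$genotype_mean_rt[[nm]],
                   file.path(outdir, paste0("rt_mean_", gsub("[^A-Za-z0-9]", "_", nm), ".bedgraph")))
  }
  utils::write.table(bundle$correlation, file.path(outdir, "replica_correlation.tsv"),
                     sep = "\t", quote = FALSE)
  writeLines(bundle$clustering$newick, file.path(outdir, "rt_dendrogram.nwk"))
  utils::write.table(as.data.frame(summarize_experiment(bundle)),
                     file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in bundle$genotypes) {
    utils::write.table(as.data.frame(bundle$scaling[[nm]]),
                       file.path(outdir, paste0("scaling_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(bundle$strength_by_distance[[nm]]),
                       file.path(outdir, paste0("strength_by_distance_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(bundle$pca$coords), file.path(outdir, "pca_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "rtcompart",
    seed = cfg$synth$seed,
    genome = list(chromosomes = as.list(cfg$synth$genome$length_bins),
                  bin_size = cfg$synth$genome$bin_size),
    generator = cfg$synth[c("mean_domain_bins", "decay_alpha", "delta_compartment",
                            "rt_bin_noise_sd", "rif1_noise_sd", "coverage",
                            "repliseq_depth", "n_replicates", "ko_rt_scale")],
    mixture = cfg$synth$mixture,
    lambda_series = as.list(cfg$synth$lambda_series),
    analysis = cfg[c("compartment_bin_size", "n_quantiles", "corner_fraction",
                     "trim_fraction", "switch_threshold", "change_threshold",
                     "pseudocount", "reference")]
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
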