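# rtcompart

Joint analysis of **Repli-seq replication timing** and **Hi-C A/B
compartmentalisation** across genotypes, built around a synthetic
block-model generator with planted, dose-tunable structure.

## The problem

Replication timing (RT) and 3D chromatin compartmentalisation are tightly
coupled genome-wide: early-replicating chromatin overlaps the A
compartment, late-replicating chromatin the B compartment. Proteins such
as RIF1 sit at the interface, and genotype series (wild type → hemizygous
→ knockout / interaction mutants) can *dissociate* the two readouts:
compartment strength weakens progressively with dose while the
replication-timing programme collapses only on complete loss of function.
Quantifying that dissociation takes a pipeline of standard but
fiddly-to-get-right steps on both sides. This package implements them as
tested, reusable functions for analysts working with binned Repli-seq
counts and cis contact matrices:

* **Repli-seq** — RPM normalisation, masking rules, per-bin
  `RT = log2(early/late)`, distribution shape and Gaussian-mixture
  bimodality (ΔBIC with a mean-separation guard), replica correlation and
  average-linkage clustering, and timing-change classification
  (EtoL / LtoE switches, toward/away-from-zero changes) between
  conditions.
* **Hi-C** — iterative-correction balancing, expected-by-distance and O/E,
  distance-decay scaling curves (unit area in log distance), short/long
  range signal fractions, differential maps; A/B compartment eigenvectors
  (leading eigenvector of the per-chromosome O/E correlation matrix,
  oriented by RT), compartment fractions and cross-sample PCA; and
  track-conditioned **saddle plots** with the corner compartment-strength
  statistic

  `strength = (AA · BB) / AB²`,

  globally, per distance band, and differentially against a reference
  genotype.
* **Generator** — replication domains with geometric lengths, bimodal RT,
  anti-correlated RIF1 occupancy, multinomial early/late counts, and
  Poisson Hi-C counts with power-law decay multiplicatively modulated by
  planted compartments:

  `Λ(i,j) = coverage · |i−j|^(−α) · [(1−λ)·exp(δ·c_i·c_j) + λ]`.

  The exponential structure factor gives the saddle corner strength the
  closed form `exp(4δ)` at `λ = 0`, so the whole analysis stack is
  validated against planted truth; `λ` mixes toward a structure-free null
  and encodes the genotype dose series.

## Worked example

```r
library(rtcompart)

genome <- genome_spec(c(chr1 = 400, chr2 = 400), bin_size = 50e3)
seg    <- segment_genome(genome, mean_domain_bins = 40, seed = 42)

# Repli-seq: simulate counts, score RT, test bimodality
rt     <- make_rt_track(seg, bin_noise_sd = 0.2, seed = 42)
counts <- simulate_repliseq_counts(rt, depth = 2e6, seed = 42)
profile <- compute_rt_profile(rpm_normalize(counts$early), rpm_normalize(counts$late))
profile
#> <binned_track> 'rt': 800 bins (0 masked), range [-2.22, 2.3]
bimodality(profile)$score
#> [1] 1556.6   # >> 10: clearly bimodal, distinct early and late genome

# Hi-C: simulate, balance, O/E, saddle, corner strength
gt <- genotype_spec("WT-like", lambda_mix = 0, coverage = 100, seed = 42)
oe <- lapply(simulate_hic(seg, gt, delta = 0.5),
             \(m) observed_over_expected(balance_matrix(m)))
lab <- digitize_track(profile, n_quantiles = 10)
compartment_strength(saddle_matrix(oe, lab))
#> [1] 5.854    # planted exp(4*0.5) = 7.39, attenuated by the empirical
#>              # expected on short chromosomes (see the vignette)

gt_ko <- genotype_spec("KO-like", lambda_mix = 0.8, coverage = 100, seed = 42)
oe_ko <- lapply(simulate_hic(seg, gt_ko, delta = 0.5),
                \(m) observed_over_expected(balance_matrix(m)))
compartment_strength(saddle_matrix(oe_ko, lab))
#> [1] 1.378    # 80% mixing toward the null: compartments nearly gone
```

A strength of 1 means no compartment preference; the WT-like map shows
strong same-compartment preference, the KO-like map barely any, with the
RT ranking shared so the two are directly comparable.

The full experiment — three genotypes × three replicates, every analysis
stage, written tables and a YAML manifest — is one call:

```r
bundle <- run_experiment(experiment_config(synth = synth_config(seed = 1)))
summarize_experiment(bundle)
```

The numbered drivers under `analysis/` run the same workflow piecewise and
narrate the findings (`01_simulate_panel.R`, `02_replication_timing.R`,
`03_contact_scaling.R`, `04_compartments_saddles.R`), writing tables under
`results/`.

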