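---
title: "Replication timing and chromatin compartmentalisation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication timing and chromatin compartmentalisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcompart)
```

# What this package measures

Two genome-wide readouts of nuclear organisation are analysed jointly:

* **Replication timing (RT)** — the temporal order in which the genome
  replicates, scored per fixed-size bin as
  `RT = log2(early RPM / late RPM)` from the read counts of early- and
  late-S-phase Repli-seq fractions. Megabase-scale *replication domains*
  replicate as units, and in wild-type cells the genome-wide RT
  distribution is bimodal: distinct early and late compartments of the
  genome.
* **A/B compartmentalisation** — the checkerboard pattern of cis Hi-C
  contact maps. After balancing and removal of distance decay
  (observed/expected), the leading eigenvector of the per-chromosome
  correlation matrix assigns bins to the A (early-replicating-like) or B
  compartment, and *saddle plots* — mean O/E over quantile pairs of a
  ranking track — quantify the preference of same-compartment over
  cross-compartment contacts.

The scientific setting is a genotype dose series: architectural proteins
such as RIF1 weaken compartmentalisation in a dose-dependent way while
leaving the replication-timing programme untouched until function is lost
entirely. The package's synthetic panel encodes exactly this dissociation
so that every analysis stage can be validated against planted truth.

# The synthetic generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions used throughout the tests and the acceptance script.

## Genome and replication domains

A genome of 10 chromosomes x 400 bins of 50 kb (20 Mb chromosomes,
200 Mb total). Domain lengths are geometric with mean `mean_domain_bins`
(default 40 bins = 2 Mb, the megabase scale of replication domains),
support starting at 2 bins, truncated to the remaining chromosome; a tail
shorter than 2 bins is absorbed into the previous domain, and a chromosome
not exceeding the target mean is a single domain. Labels alternate between
A and B with probability 0.7 (otherwise an independent fair draw), giving
balanced compartments with occasional same-label runs, as in real genomes.

## Replication timing

Domain-level RT values come from a two-component Gaussian mixture —
early `N(+1.5, 0.3)` for A domains, late `N(-1.5, 0.3)` for B domains (RT
units, log2 early/late) — plus i.i.d. per-bin noise (sd 0.2). These values
plant a clearly bimodal genome: mode separation 3.0 against a component sd
of ~0.36.

Repli-seq counts invert the RT estimator: bin weights
`w = 2^RT / (1 + 2^RT)` for the early fraction (and `1 - w` for the late
fraction) are sampled multinomially at `repliseq_depth` reads per fraction
(default 2e6, scaled to the 200 Mb genome from typical genome-wide
depths). The logistic weight makes the downstream `log2` RPM ratio an
unbiased estimator of planted RT up to a genome-wide additive offset,
which median-centering removes before profiles are compared.

The RIF1-association track is `-RT` plus Gaussian noise (sd 0.5),
planting the anti-correlation between RIF1 occupancy and timing and,
through the domain structure, contiguous RIF1-associated-domain-like
stretches over late domains.

## Hi-C block model

For bins i < j with compartment signs `c in {+1, -1}`, expected counts are

```
Lambda(i,j) = coverage * |i-j|^(-alpha) * [ (1-lambda) * exp(delta c_i c_j) + lambda ]
```

with Poisson observation noise. Defaults: `alpha = 1` (the classical cis
decay exponent), `delta = 0.5`, `coverage = 100` (= 50 expected counts at
the 2-bin separation where analysis starts). The multiplicative
exponential structure factor is chosen so that the saddle corner strength
`(AA*BB)/AB^2` has the closed form `exp(4*delta)` on the noiseless
expectation — a clean, independent oracle for the whole saddle stack.

`lambda` mixes the structure linearly toward a structure-free null on the
O/E scale and is the single dose dial: the genotype presets are WT-like
(`lambda = 0`), hem-like (`lambda = 0.4`) and KO-like (`lambda = 0.8`),
for which the closed-form corner strengths are `e^2 ~ 7.39`, 3.30 and
1.50. Trans contacts are not simulated; every analysis here is cis-only.

## The knockout-like timing landscape

The KO-like genotype must reproduce two phenomena at once: its RT
distribution collapses to unimodality, and its replicas form their own
cluster in a correlation dendrogram, away from wild type. Pure
multiplicative shrinkage of the wild-type landscape can do neither job:
Pearson correlation is scale-free, so a shrunk profile still correlates
almost perfectly with wild type (for shrinkage `s < 1` the shrunk-vs-WT
correlation always exceeds the correlation between two shrunk replicas),
and moderate shrinkage leaves the mode separation many component sds wide.

The preset therefore *reprograms* timing: domain RT values are re-drawn,
independently of both the wild-type values and the compartment labels,
from a mixture whose means are compressed to `rt_scale = 0.05` of the
wild-type amplitude. Compartment labels — and hence the Hi-C structure —
are untouched: compartments persist, weakened only through `lambda`.
The compression magnitude follows from requiring the *panel-level*
distribution (the mean of `n = 3` replicate profiles, which is what the
distribution figure shows) to be analytically unimodal:
`3 * s * 1.5 <= 2 * sqrt((0.3 s)^2 + (0.2/sqrt(3))^2)`, i.e. `s <= 0.078`;
0.05 satisfies the bound with margin. Replicates share one planted
landscape and differ in bin noise, Repli-seq sampling and Hi-C Poisson
draws — matching the observation that knockout clones still cluster
together, which implies shared residual structure.

# Analysis methods and their numerical choices

## Repli-seq

* **RPM** normalisation per fraction, then
  `RT = log2((early + p) / (late + p))` with pseudocount `p = 0.1` RPM,
  bounding scores on empty bins (`0/0 -> 0`).
* **Masking** is explicit (`NA`), never silent zeroing: excluded
  chromosomes (e.g. sex chromosomes) and bins below a count threshold stay
  in place so coordinates remain aligned; no operation unmasks a bin.
* **Bimodality**: one- against two-component Gaussian mixture
  (unequal variances, `mclust`), scored as the BIC improvement
  `BIC(1) - BIC(2)`; bimodal requires improvement > 10 *and* fitted means
  separated by more than the larger component sd — the guard stops a
  heavy-tailed unimodal fit from being called bimodal. `mclust`
  initialises on a random subsample for large n, so the fit is pinned to
  an internal fixed seed and is a pure function of the data.
* **Replica clustering**: Pearson correlation over jointly unmasked bins,
  distance `1 - r`, average linkage. Correlation is invariant to the
  affine offsets that depth differences create, so no further
  normalisation is needed.
* **Timing changes** between conditions: switches (EtoL / LtoE) need sign
  thresholds `+/-0.25` on both profiles and `|delta RT| >= 0.5`; smaller
  movements of at least 0.25 are classified toward / away from zero;
  everything else is stable. Thresholds are in RT units and configurable.
* No smoothing is applied to RT profiles by default; the estimator
  consistency checks operate on raw binned scores.

## Hi-C

* **Balancing** is iterative correction to equal marginals (tol `1e-5` on
  the relative marginal deviation, max 1000 iterations). The low-coverage
  filter is one-sided: bins whose log marginal falls more than `mad_max`
  (default 5) robust deviations *below* the median are masked. The robust
  scale is floored at half a log2 unit: on synthetic maps there is no
  technical dropout, the marginal MAD collapses to ~0.04, and an unfloored
  two-sided filter would mask entire minority compartments on
  label-imbalanced chromosomes.
* **Expected by distance** is the mean of unmasked entries per diagonal;
  diagonals with fewer than 10 unmasked pairs (or zero signal) borrow a
  pooled estimate from geometric distance bins (8 per decade). O/E
  excludes the diagonal and first off-diagonal (short-range ligation
  artefact convention; configurable).
* **Scaling curves** aggregate balanced frequencies in geometric distance
  bins (8 per decade) and are normalised to unit area in log10 distance so
  genotypes with different totals are comparable; replicas are combined by
  the per-distance median with an sd band. Short/long-range fractions use
  0.3 Mb (median TAD scale) and 10 Mb cutoffs.
* **Compartment eigenvector**: per chromosome, the leading eigenvector of
  the Pearson correlation matrix of O/E columns
  (pairwise-complete over the masked near-diagonal), scaled by the square
  root of its eigenvalue share so amplitude reflects checkerboard
  coherence, and sign-fixed to correlate positively with an orientation
  track — replication timing by default, so A = early = positive.
  Chromosomes with fewer than 20 unmasked bins are masked entirely.
  Compartment analysis runs at 250 kb by coarsening 50 kb counts (sums)
  and tracks (means) before balancing.
* **Saddles**: ranking tracks are trimmed by 2% per tail (outlier guard)
  and digitised into Q = 20 equal-count quantiles (ties broken by stable
  bin order, so labels are rank-invariant). Mean O/E is pooled across
  chromosomes and replicates weighted by pair counts, at separations of at
  least 2 bins. Empty cells propagate as missing, never zero. Strength is
  `(AA*BB)/AB^2` over 20% corners, pair-count weighted; 1 means no
  compartmentalisation. In the genotype panel all genotypes are ranked by
  the *reference* genotype's tracks, because differential saddles against
  the reference require a common ranking.

## Known estimator properties

Two deliberate properties of the full empirical pipeline are worth
knowing, both documented by the test suite:

* **Finite-size attenuation.** The empirical per-diagonal expected absorbs
  part of the compartment signal at separations comparable to the domain
  length, because a 20 Mb chromosome holds only ~10 domains and the label
  composition per diagonal co-fluctuates with the expected. On the default
  genome the recovered strength runs at roughly 0.94/0.83/0.75 of
  `exp(4*delta)` for `delta = 0.1/0.25/0.5`; a minimum-distance cutoff
  does not remove the effect. Planted-parameter recovery is therefore
  validated against the generator's own decay law (`model_oe()`), which
  recovers `exp(4*delta)` within ~1% under Poisson noise, while the
  empirical pipeline is validated for what it must deliver: a strictly
  monotone, well-separated dose response.
* **Self-ranking selection.** E1-ranked saddles run ~20% stronger than
  RT- or RIF1-ranked ones (which agree within a few percent): the
  eigenvector is derived from the same maps, so its extreme quantiles
  select the purest compartment bins. The same effect makes
  eigenvector-ranked saddles look sharpest in real analyses.

## Cross-sample PCA

Compartment profiles (eigenvector tracks) of all replicates enter a PCA as
observations, on bins unmasked in every sample, features centred across
samples. PC1 orders the panel by compartment-strength dose, with
hemizygous-like replicates falling strictly between the wild-type-like and
knockout-like groups.

# What the generator does and does not emulate

It emulates: domain-scale RT structure with bimodal scores; early/late
counts whose ratio encodes RT; RIF1 occupancy anti-correlated with RT;
power-law cis decay multiplicatively modulated by planted compartments;
Poisson sampling; a genotype dose series as linear mixing toward a
structure-free null; optional A-compartment expansion by relabelling a
fraction of B domains (`reassign_labels()`), since no quantitative rule
for expansion is available.

It does not emulate: TADs, loops or insulation (all claims here are
compartment-level); trans contacts; mappability/GC visibility bias (so
balancing weights are near-uniform by construction); sub-compartments;
S-phase fraction deconvolution; read-level artefacts (duplicates, sex
chromosomes are handled as masking rules upstream of these analyses).
Passing tests therefore demonstrate correctness of the estimators under
this generative model, not robustness to every artefact of real data.

# Problem sizes and determinism

All randomness flows from integer seeds through a fixed derivation rule
(seed + operation-specific constant), so every operation — and the whole
experiment — is a pure function of its configuration; re-running writes
byte-identical tables. The default panel (3 genotypes x 3 replicates,
200 Mb at 50 kb, compartments at 250 kb) runs in well under a minute;
seeded repetitions used for rate estimates (10-20 seeds) keep the complete
validation suite in the minutes range. Domain-level RT recovery is checked
at 1e7 reads per fraction; Poissonized strength recovery at coverage 100,
i.e. >= 50 expected counts per near-diagonal pair.

# Limitations

* The compartment-strength statistic is corner- and Q-dependent; defaults
  (Q = 20, 20% corners) are stated and configurable, and strength is
  stable within ~10% across Q in {5, 10, 20} on block models.
* The dose dial is a uniform mixing parameter; real dosage effects may mix
  uniform weakening with A-expansion, for which only the relabelling
  mechanism is provided.
* Chromosomes are short (20 Mb) relative to mammalian genomes; the
  finite-size attenuation above is correspondingly larger than it would be
  on 100-200 Mb chromosomes.
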