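---
title: "Methods: un-mixing and causal network analysis of aging yeast populations"
author: "agemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: un-mixing and causal network analysis of aging yeast populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemix)
```

# The problem

Replicatively aging budding yeast mothers are vastly outnumbered by their
daughters, so bulk harvests of an aging cohort are mixtures of mother,
daughter and dead cells. `agemix` implements a complete analysis chain for
such experiments: it recovers pure cell-type molecular profiles from
mixed-sample measurements by solving a composition-weighted linear system
("mathematical un-mixing"), processes the recovered time courses into a
unified proteome and transcriptome dataset, and quantifies the aging
phenotypes of interest — divergence from the young state, uncoupling of
protein from transcript levels, loss of protein-complex stoichiometry, and
a directional gene network that ranks co-expression clusters from causal
to responsive. A synthetic-data generator emulates the experimental design
with planted ground truth, so every stage is testable.

# Mathematical un-mixing

At each harvest, three mixed samples are measured whose mother, daughter
and dead-cell fractions `W` (rows on the simplex) are known from flow
cytometry. For each gene the measured mixed abundances satisfy
`W a = a_mix`, a square linear system solved exactly per gene
(`unmix_timepoint()`). The solve is deliberately unconstrained: a negative
solved component is physically impossible and is flagged *unsolvable*
rather than truncated, and a composition matrix with condition number
above `1e8` flags the whole harvest. Genes with fewer than five solvable
time points are removed; remaining gaps are linearly interpolated from the
neighbouring solved times, with boundary gaps taking the nearest solved
value (`finalize_series()`). Each time point is then normalized to a total
of 10^6.

Two regimes need care:

* **Early harvests contain no dead cells.** The three-unknown system is
  then rank-deficient in the dead direction, so those time points are
  solved as a 2×2 system in (mother, daughter) using the most
  mother-enriched and most daughter-enriched mixes, with the two
  composition rows re-normalized over the live cell types.
* **Mother/dead collinearity at late harvests.** Dead cells are mostly
  former mothers and co-enrich with them, so the mother and dead columns
  of `W` are nearly collinear unless the dead:mother ratio differs across
  mixes. Single-time-point mother estimates at late harvests therefore
  amplify measurement noise by roughly an order of magnitude; the
  downstream analyses never use a single noisy solve directly but the
  LOESS-fused replicates (below). Dead-cell profiles are treated as
  nuisance estimates throughout.

The method is validated as the original experiment validated it: three
pure populations with distinct signatures are mixed in known, distinct
proportions — each validation mix dominated by one population — measured
with multiplicative lognormal noise (CV 0.10), and un-mixed
(`unmixing_validation()`). Pure profiles share a per-gene baseline
(lognormal, sdlog 1.5) times population-specific lognormal factors
(sdlog 0.5), reproducing the strong cross-population correlation of real
pure samples; with these conditions the mean relative recovery error is
about 13%, inside the 16% bound the validation is expected to meet. The
error would not be meaningful for an arbitrary ill-conditioned mixing
design: with compositions like the aging run's own (mother-enriched,
wash, effluent), noise amplification through `W^-1` alone exceeds the
bound, which is precisely why the experiment solves two unknowns early
and why validation requires designed mixtures.

# Preprocessing

* **Bead correction.** The iron beads used to retain mothers cause a
  reproducible protein-specific signal loss. The correction factor per
  protein is the ratio of its mean abundance without beads to its mean
  with beads, applied multiplicatively to bead-containing samples only
  (`bead_correction_factors()`, `apply_bead_correction()`); re-application
  is refused.
* **Young reference.** Profiles are expressed as log2 fold changes versus
  the first harvest (default 7.8 h); the offset between that reference
  and an unprocessed sample is stored as metadata so recovery from the
  labeling procedure is not mistaken for aging
  (`standardize_reference()`).
* **Replicate fusion.** The two replicate campaigns are pooled per gene
  and fitted with LOESS (degree 2, span 0.75 — the standard span),
  resampled at the experimental harvest times (`fit_profiles()`). Fitting
  is done in linear abundance space by default (log-space by
  configuration); genes whose fitted curve crosses zero are removed by
  default (clamping to a small floor, `1e-6` of the median, is the
  alternative), and genes with fewer than four pooled points are flagged
  unfittable.
* **Reproducibility filter.** Per gene, the coefficient of variation
  across replicates (sample SD with the n−1 denominator, so `|a−b|/√2`
  for two replicates) is computed at each shared time point and averaged
  over time; genes with mean CV strictly below 0.3 are retained
  (`cv_filter()`). The per-time-point-then-average definition was chosen
  because it is symmetric in the replicates and testable in closed form;
  time points with zero mean are excluded from the average.

# Coupling analyses

All coupling statistics operate on the fused fold-change tables.
`divergence_from_young()` correlates each time point with the reference;
`crosslevel_correlation()` correlates proteome against transcriptome per
time point with Spearman, Kendall, and Pearson on raw or log2 values —
the rank statistics are primary, raw-scale Pearson being dominated by the
few most abundant genes. `quadrant_map()` classifies genes by the signs
of their final protein and transcript fold changes (Q1/Q3 coupled, Q2
protein-overabundant, Q4 the reverse); genes with an exactly zero fold
change lie on an axis and are excluded from quadrant fractions with a
reported count — with continuous data this is a measure-zero tie rule.
`overabundance_series()` computes protein minus transcript log2 fold
change per gene and time, with per-quadrant sums fixed at the final-time
assignment, and `foldchange_census()` counts genes crossing the twofold
threshold per time point, distinguishing new crossings from repeats and
reporting the fraction of final changers presaged at an earlier time.

# Complex stoichiometry

The stoichiometry loss of a complex at a time point is the interquartile
range of its members' log2 fold changes (`stoichiometry_loss()`): zero
for perfectly coordinated change, translation-invariant, and linear under
scaling. Quantiles use linear interpolation between order statistics
(type 7), the common scientific-computing default; the convention is
configurable since box-plot quartiles admit several definitions.
Complexes with fewer than two quantified members are skipped rather than
scored zero. Level and population comparisons
(`compare_stoichiometry()`) restrict to genes shared between the two
datasets before scoring, as fold-change dispersions are only comparable
on a common gene set.

# Directional network

The network stage turns fold-change time courses into a ranked causal map:

1. **Profile filter.** Each profile is scored by the log marginal
   likelihood ratio of a smooth Gaussian-process model (squared
   exponential temporal covariance plus independent noise, hyperparameters
   maximized over a small fixed grid) against a noise-only model
   (`profile_signal_filter()`). The default threshold of 1.0 was
   calibrated on simulated white-noise profiles (≥95% removed); strong
   trends score an order of magnitude higher.
2. **Shrinkage correlation.** With 12 time points and hundreds of genes
   the sample correlation is singular, so the correlation matrix is shrunk
   toward the identity with the analytic variance-minimizing intensity
   (`shrink_correlation()`), giving a positive definite estimate whose
   intensity vanishes as time points accumulate.
3. **Partial-correlation edges.** Edges connect gene pairs whose partial
   correlation (from the scaled inverse of the shrunk correlation) exceeds
   a cutoff in magnitude; indirectly related profiles are thereby
   disconnected, and isolated nodes are dropped. Because the magnitude
   scale of shrunk partial correlations depends on the data, default
   cutoffs are specified as quantiles of the off-diagonal `|pcor|`
   distribution.
4. **Orientation.** Each node's standardized partial variance (SPV) is
   the fraction of its variance left unexplained by regression on its
   strongest network neighbours (capped at four so the regression stays
   overdetermined at 12 time points; ridge-regularized and flagged in the
   degenerate case). An edge points from the higher-SPV (predictive,
   poorly explained) node to the lower-SPV (explained, responsive) node;
   edges with `|log SPV ratio|` under 0.6 — the 95th percentile on
   simulated exchangeable edges, i.e. a 5% false-orientation rate — stay
   undirected and are excluded from causal counts. In a Gaussian
   graphical model the neighbour set is the Markov blanket, so the
   whole-model SPV `1/(R*^-1)_ii` is the regularized equivalent; it is
   retained (`standardized_partial_variance()`) and the two agree exactly
   on small unshrunk systems, but with hundreds of genes and 12 time
   points the whole-model version compresses toward a constant, so the
   neighbour regression is the default.
5. **Clustering and ranking.** Clusters maximize modularity of the
   undirected skeleton — exactly (exhaustive over partitions) for graphs
   of up to 8 nodes, greedily beyond. Directed inter-cluster arrows are
   tallied in a direction matrix, each cluster's causal ratio is outgoing
   over incoming arrows (no incoming: ranked first among such by outgoing
   count), and clusters are ranked by descending ratio.
6. **Sensitivity sweep.** The full network is recomputed across a cutoff
   grid; cluster rankings at adjacent cutoffs are compared after matching
   clusters by maximal node overlap (`sensitivity_sweep()`). Ranking
   stability is high on the dense side of the grid and degrades as the
   network fragments into small clusters whose arrow counts are dominated
   by chance; the default grid (quantiles 0.93–0.99, and 0.85–0.95 for
   the planted benchmark below) covers the stable plateau.

## What the planted benchmark does and does not show

The causal-recovery benchmark (`generate_driver_responder()`) plants 50
driver profiles and 150 responders, each responder a noisy linear map of
driver *activity*. Two modelling choices matter and are deliberate:

* **Drivers transmit only part of their variance** (default 0.5). If
  responders copied the full driver profile, the many children of each
  driver would jointly reconstruct it better than its few parents explain
  any responder, and partial-variance orientation would point backwards —
  an intrinsic property of linear Gaussian systems with more responders
  than drivers, not an implementation artifact. A regulator whose
  measured abundance contains variation its targets never inherit is
  also the biologically realistic picture.
* **Responder noise is smooth** (drawn from the same temporal process),
  because the profiles entering the real network stage are LOESS fits;
  white noise would make responders look spuriously unexplained in the
  low-rank 12-point regime.

Under these conditions edge orientation is excellent (on the canonical
benchmark roughly 450 driver→responder arrows against 15 reversed, at
every cutoff in the default grid) and the top-ranked cluster is
consistently enriched in drivers. What the benchmark does *not* show is a
clean two-community split into a driver block and a responder block:
causal edges run between the blocks, so modularity communities are
necessarily mixtures of drivers and their responders, and the ranking
separates *more* causal from *more* responsive mixtures rather than pure
roles. Conclusions about real data should be read the same way: a
top-ranked cluster is a module enriched in predictive profiles, not a set
of proven causes.

# The synthetic-data generator

`simulate_cohort()` models each founder mother as a homogeneous Poisson
division process with per-cell rate drawn from a gamma distribution
(mean 0.5 h⁻¹, CV 0.2) — reproducing the widening of the cohort age
distribution over time that motivates exponentially spaced harvests
(`harvest_schedule()`; 12 points from 7.8 h to 72 h by default). The
wording of the underlying model admits two readings (heterogeneous rates
versus a pure event process); rate heterogeneity is the default and
`rate_cv = 0` gives the pure process. Death, which the original cohort
simulation did not model, is additive and configurable: each cell draws a
replicative lifespan limit from a logistic distribution (location 34
divisions, scale 4), calibrated so population viability at 72 h lands
near the observed ~42%.

`generate_molecular_truth()` plants per-gene trajectories by archetype —
the four co-expression quadrants plus flat — with terminal log2 fold
changes of 0.5–2.5 in magnitude, daughters following mothers at half the
log2 trend (partial rejuvenation), a fixed dead-cell signature, per-gene
log protein and transcript baselines correlated at 0.75 (the young-state
coupling), protein-specific bead retention factors in [0.5, 1], and
complexes that are either coordinated (equal member slopes) or drifting
(a fan of slopes). `compose_mixed_samples()` mixes the pure profiles by
the design compositions, multiplies lognormal noise (default CV 0.10,
which keeps most replicate CVs under the 0.3 filter), applies bead losses
to protein channels of bead-containing mixes, and perturbs measured
compositions on the simplex by a Dirichlet draw. The default mix design
has a mother-enriched fraction declining from 99% to 60% mothers, an
intermediate wash, a daughter-dominated effluent, and dead fractions that
are exactly zero over the first harvests and grow to (0.30, 0.35, 0.10)
across the three mixes, with the dead:mother ratio varying across mixes
(detached dead cells in the wash, dead daughters in the effluent) so that
the late three-unknown systems remain solvable.

What the generator does not emulate: count noise and missingness
structure of sequencing or MS detection (noise is purely multiplicative
lognormal and every gene is observed in every sample), batch effects
beyond the bead artifact, compositional coupling between genes, and any
feedback of molecular state onto division or death. Passing tests
demonstrate correct and robust computation under the planted model, not
performance guarantees on real measurements.

# Problem sizes and numerical choices

The test suite and analysis scripts run the full pipeline on 600–800
genes with two replicates over 12 harvests, the network benchmark on 200
profiles, and validations on 1000 genes; these sizes keep every planted
property measurable with comfortable margins while the whole suite runs
in well under a minute. Tolerances worth knowing: un-mixing flags
condition numbers above `1e8`; the oracle identity (mix then un-mix) is
asserted at `1e-9` relative error; interpolation uses `stats::approx`
with boundary rule 2; LOESS uses the direct surface so fits are exact,
deterministic functions of the input; quantile type 7 throughout; all
stochastic stages take explicit integer seeds and are bit-reproducible.
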