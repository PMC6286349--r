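---
title: "Methods: stratifying gut microbiota, diet and health associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying gut microbiota, diet and health associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstrat)
```

## The analysis model

`microstrat` implements the downstream statistics of a two-time-point
prospective gut-microbiome cohort: community stratification, co-abundance
structure, diet clustering, and the associations among microbiota,
inflammation and phenotype. The guiding picture is that a child's gut
community occupies one of a small number of *steady states* — recurrent
whole-community configurations distinguishable by genus-level composition
and biodiversity — and that diet and inflammatory status align with the
dominant axis of community variation.

### Community stratification

Steady states are found by hierarchical Ward clustering (`ward.D2`,
squared-distance update; `ward.D` available behind a flag for legacy
comparability) of the inter-sample Spearman correlation of OTU
proportions. OTUs seen in fewer than 20% of samples are discarded first
(`prevalence_min = 0.20`): rare OTUs contribute rank noise without
stabilising the correlation. Correlations map to distances as
`(1 - rho)/2`, taking [-1, 1] to [1, 0]; the alternative `1 - |rho|` is
exposed (`distance_mode = "abs"`) because the protocol this follows is
ambiguous about the mapping, but the shifted form is the default since
anti-correlated samples should be *far* apart, not near. Because the
distance is rank-based, the labels are invariant to per-sample scaling
and to sample order (asserted in the test suite).

The cluster count is **not** hard-coded: `k = "auto"` maximises the mean
silhouette width over k = 2..8 on the same distance. A study that has
settled on a k (e.g. 4 microbiota states, 5 diet groups) can fix it. Two
verifications accompany the labels: (a) per cluster, the fraction of
intra-cluster sample pairs whose positive Spearman correlation survives
Benjamini-Hochberg correction across all intra-cluster tests (Spearman
p-values use the t approximation, adequate for the feature counts
involved); (b) a PERMANOVA of the labels against the correlation
distance.

### Diversity and ordination

Shannon entropy uses log base 2 (the convention of the usual 16S
toolchains; the base is an argument). Faith's PD includes the branch path
to the supplied root ("whole tree" convention; switchable). No
rarefaction is applied — the package warns when library sizes vary more
than 10-fold instead of silently resampling, because rarefaction discards
data and the downstream statistics are rank- or proportion-based.

UniFrac is computed from an edge-by-tip incidence decomposition of the
rooted tree; multifurcations are handled naturally since the sums run
over all branches. The unweighted form is the fraction of branch length
leading exclusively to tips observed in one sample of the pair; the
weighted form sums branch lengths times absolute differences in the
proportion of reads descending through the branch. Whether "weighted
UniFrac" should be normalized is ambiguous in common usage, so both are
exposed; `"weighted"` resolves to the normalized variant (the Lozupone
normalizer, the maximum attainable raw value for the pair). The
implementation is checked against a brute-force per-branch oracle (50
random 10-tip trees, tolerance 1e-10) and against phyloseq.

PCoA performs Gower double-centering `B = -1/2 J D^2 J` and an
eigendecomposition; axes with negative eigenvalues (non-Euclidean input)
are dropped and their magnitudes reported, with the Cailliez correction
behind a flag — dropping matches the default behaviour of the toolchain
this emulates. Proportions explained are taken over the positive
eigenvalues only. Eigenvector signs are fixed by making the
largest-magnitude loading positive, so coordinates are reproducible
across linear-algebra backends. Correspondence analysis follows the
standard SVD of standardized residuals; its total inertia equals the
independence chi-square over the grand total, which the tests assert to
1e-10.

### Permutation inference

PERMANOVA uses the pseudo-F built from the sum-of-squared-distance
decomposition and permutes labels; all permutation p-values use the
add-one convention `(#{stat* >= stat} + 1)/(B + 1)` and therefore are
never zero. Permutation counts default to 999 and every seeded function
takes an explicit `seed`. One subtlety: in tiny, perfectly separated
designs a permutation can reproduce the observed partition exactly, tying
the observed statistic, so the attainable minimum p is `(ties + 1)/(B + 1)`
rather than `1/(B + 1)`; the test suite accounts for this. Vector fitting
(`fit_env_vectors`) regresses each centered variable on the chosen axes,
reports r² and the unit direction, permutes the variable for inference,
and applies Benjamini-Hochberg across variables when two or more are
fitted — the correction is unnamed in the protocol this mirrors, and BH
is chosen for consistency with the rest of the pipeline.

### Co-abundance groups

Genera are aggregated from taxonomy (OTUs unclassified at genus pool into
a reserved `Unclassified` feature that is excluded from CAG analysis),
filtered at relative abundance > 0.1% in at least 2 samples, and
correlated by Kendall tau-b with normal-approximation p-values
(exact enumeration is neither feasible nor necessary with ties at n in
the hundreds). Multiplicity is controlled by Storey q-values with fixed
lambda = 0.5 (`pi0 = #{p > 0.5} / (0.5 m)` capped at 1, scaling the BH
step-up values), with plain BH behind a flag. Network edges keep pairs
with q ≤ 0.05. Clustering uses the Spearman-correlation distance between
genus profiles by default; a Kendall-derived distance is exposed because
the source protocol can be read either way. Each CAG is named for its
dominant genus — the highest cohort-wide mean relative abundance within
the group — and Wiggum over-abundance ratios (cluster mean / cohort mean)
are exported per (state, genus) for network rendering; cluster-size
weighted ratios average to 1 per genus by construction.

### Diet, HFD and macronutrients

FFQ categories convert to daily consumption frequencies: point
frequencies directly ("2 times per day" → 2), weekly ranges by the
midpoint divided by 7 ("1-3 times per week" → 2/7), with declared floor
("never or less than once a week" → 0) and ceiling ("4 or more times per
day" → 4); unknown category strings are an error listing them, and the
dialect table is replaceable. Dietary groups come from Ward/Euclidean
clustering of the *first* CA axis only — a deliberately one-dimensional
view justified when that axis carries the dietary signal, which the
synthetic generator reproduces and the CA inertia share makes checkable.
Groups are renamed D1..Dm by ascending mean axis-1 score.

The Healthy Food Diversity index is the health-value-weighted Berry
index, `HFD = (sum hv_i s_i)(1 - sum s_i^2)` over consumption shares
`s_i`: zero for single-food diets, bounded by `1 - 1/n`, invariant to
rescaling all consumptions. The functional form follows the published
index construction it is named after; the per-food health values in
`food_reference()` (50 items, values in [0, 1]) are package defaults
intended for simulation and teaching, and should be replaced with
instrument-specific values for real studies. Macronutrient summaries use
Atwater factors 4/9/4 kcal/g and report fibre as g per 1000 kcal; the
packaged composition table guarantees shares sum to ≤ 100%, with the
remainder reported as unassigned energy.

### Clinical associations

Markers regress on ordination axes at the median (quantile tau = 0.5),
adjusted for age as a linear covariate — median regression is preferred
over least squares because inflammatory markers are heavy-tailed. The
fit is the exact Barrodale-Roberts solution (via quantreg). Coefficients
are reported on two scales: `rc_range` (coefficient × axis span) and
`rc_sd` (coefficient × axis standard deviation); both share the
coefficient's sign and their ratio is the span/sd ratio by construction.
Inference defaults to a seeded xy-pair bootstrap (2000 resamples): the
centred resampling distribution of the axis coefficient gives a basic
bootstrap test of zero. A Wald alternative with the `nid` sandwich
standard error is provided instead of rank-score inversion — quantreg
exposes rank-based confidence intervals but not p-values, and inverting
them adds complexity without user benefit. The bootstrap p-value is
well calibrated at cohort-scale n (the test suite verifies uniformity
under the null at n = 140 over 500 simulations); at n below ~50 it is
conservative, which is the safe direction. A constant age covariate is
dropped rather than left to alias the intercept, and degenerate
(noiseless) Wald fits return `p = NA` with a warning.

Combination enrichment works at the **subject** level: a subject is "in"
a (state-set × diet-set) combination if any of its samples satisfies both
simultaneously, and the resulting phenotype × membership table goes to
Fisher's exact test (two-sided by minimum-likelihood summation with 1e-7
relative slack; odds ratio with Haldane 0.5 correction when a cell is
zero). The subject, not the sample, is the exchangeable unit — printed
p-values from analyses whose unit of analysis is unclear cannot be
compared directly, and this package states its unit explicitly. Group
tests of taxon abundances use Wilcoxon rank-sum, the paired signed-rank
when a subject map pairs two groups, or Kruskal-Wallis for three or more,
after the same 20% prevalence filter, with BH adjustment across features;
zero-variance features are flagged rather than tested.

The within-subject pairing statistic counts subjects whose two samples
are mutual rank-1 neighbours in the correlation distance, with a
permutation null over subject assignments. This is a stated substitute
for a dendrogram-adjacency test whose original construction is not
reproducible from its description; the mutual-nearest-neighbour criterion
is stricter and has an exact null mean (`n_subjects × M / C(n, 2)`, with
M the number of mutual-NN pairs), which the tests exploit.

## The synthetic cohort generator

The generator emulates the study conditions the analysis is designed for:
70 subjects × 2 time points (140 samples), a discrete number of latent
community states with a biodiversity gradient, latent diet groups coupled
to state, and metadata whose inflammatory markers track the community
gradient. Defaults were chosen once, at design time:

- `n_otus = 300`, `n_genera = 40`: scaled down from the tens of
  thousands of OTUs of a real run to keep the suite fast while preserving
  a realistic OTU-per-genus multiplicity; the 40 genus names and lineages
  are real gut taxa (`gut_genus_reference()`).
- `reads_per_sample = 5000` with lognormal library sizes at
  `library_size_cv = 0.395` — the coefficient of variation implied by a
  mean of roughly 56,000 ± 22,000 reads, at a scaled-down mean.
- `state_diversity_gradient = c(1, 2, 4, 8)`: per-state Dirichlet shape
  scalars; a state's genus profile is drawn with this shape, so larger
  values give more even profiles and strictly higher expected Shannon
  diversity, giving the monotone diversity gradient across states that
  the analysis should recover.
- `dirichlet_concentration = 100`: per-sample Dirichlet-multinomial
  overdispersion around the state profile (not a plain multinomial),
  emulating 16S compositional noise while keeping states well separated —
  the stated regime for the recovery properties.
- `state_persistence = 0.75`: probability the second sample stays in the
  subject's first state. The underlying study does not report
  within-subject state stability; this is a free parameter, not an
  estimate.
- `cag_sd = 0.4`: shared lognormal per-sample factors over `n_cags = 4`
  genus blocks induce within-block positive correlation — the ground
  truth for co-abundance detection.
- `subject_sd = 0.8`: a per-subject, per-genus lognormal signature shared
  by a subject's samples, so that a minority of subjects cluster by
  individual rather than by state — mirroring the observation that some
  children's two samples are each other's closest neighbours while most
  are not. Raising it trades state recovery for individuality.
- Diet templates sit at evenly spaced positions along a single food
  "healthiness" gradient (`diet_sharpness = 1.2`, idiosyncratic per-food
  deviations `diet_idiosyncrasy = 0.15`, per-sample lognormal consumption
  noise `ffq_noise_sd = 0.35`), so the first CA axis carries the diet
  signal — the one-dimensional structure the diet clustering relies on. A
  row-stochastic confusion matrix couples diet group to community state
  (`diet_state_coupling = 0.6` on the mapped group by default; an
  identity matrix makes diet a deterministic function of state).
- Markers equal a baseline plus `inflammation_effect` × (standardized
  state gradient score, higher in low-diversity states) × marker scale,
  plus Gaussian noise, truncated at zero and rounded to the instrument's
  3 decimals; excessive weight gain at the second time point is enriched
  in subjects ending in low-diversity states via a logistic link.

What the generator does **not** emulate: sequencing error, chimeras and
taxonomy misassignment (upstream of this package's scope); longitudinal
age trends in the microbiota; covariance between diet and library size;
non-lognormal library-size tails; and any real food-composition data —
the packaged 50-item table is synthetic-but-plausible. Passing the
recovery tests therefore demonstrates that the algorithms identify the
structure they are designed for when it is present at realistic
signal-to-noise, not that real cohorts contain such structure.

## Numerical choices and degenerate inputs

- Zero-total samples are an error naming the sample (relative abundance,
  HFD, macronutrients); empty samples are rejected by UniFrac.
- Constant genus profiles get correlation 0 (mid-distance) instead of NA;
  constant envfit variables return r² = 0, p = 1 with a warning.
- PCoA/CA rank cut-offs are relative (1e-9, 1e-8 of the leading
  eigenvalue/singular value) with an absolute floor so exactly-rank-1
  tables report zero inertia instead of numerical dust.
- Cluster labels are renamed deterministically (states by decreasing
  size, CAGs by decreasing dominant-genus abundance, diet groups by
  ascending axis-1 mean), so outputs are stable across runs.
- All writers stamp a config hash and seed as comment headers; two runs
  of the pipeline with the same configuration are byte-identical
  (asserted by checksum in the tests).

## Problem sizes in the test suite

The suite runs the full default cohort (140 samples × 300 OTUs) for
recovery checks over 10 independent seeds, 500-simulation calibrations
for the PERMANOVA type-I error and the bootstrap null (n = 140, 199
resamples per simulation — the bootstrap p is a discrete grid at
(B+1)⁻¹ resolution, which the uniformity test tolerates), 20 replicates
for the CAG false-edge rate, and exhaustive enumeration for Fisher's
exact test over every 2×2 table with total ≤ 60. These sizes are the
package's own choice of a thorough-but-quick regime; all scale up by
argument.

## Known limitations

- UniFrac is O(samples² × edges); at a few hundred samples this is
  seconds, but very large cohorts would want a compiled implementation.
- The silhouette-based k selection inherits silhouette's preference for
  compact, balanced clusters; gradient-like data may select k = 2.
- Storey's pi0 estimate with a single fixed lambda is coarse for small
  p-value sets; the BH fallback is the conservative alternative.
- The bootstrap median-regression p is conservative below n ≈ 50.
- Diet clustering deliberately uses only CA axis 1; diets varying along
  orthogonal axes are invisible to it by design.
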