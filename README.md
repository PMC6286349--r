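# microstrat

Downstream analysis toolkit for prospective gut-microbiome cohort studies,
built around the question of how children's gut community configurations,
dietary habits and inflammatory status jointly relate to the development of
obesity. Given an OTU count table with taxonomy, a rooted phylogeny, a
food-frequency questionnaire (FFQ) and clinical metadata, the package

- stratifies samples into **microbiota steady states** — recurrent
  whole-community configurations — by Ward linkage clustering of
  inter-sample Spearman correlations of OTU proportions (distance
  `(1 - rho)/2`, prevalence filter ≥ 20%), with two built-in
  verifications: the fraction of intra-cluster sample pairs with
  BH-significant positive correlation, and a PERMANOVA of the labels
  against the correlation distance;
- derives **co-abundance groups (CAGs)** of genera from all-pairs Kendall
  tau-b correlations with Storey q-value FDR control (edges at q ≤ 0.05),
  Ward clustering of genus profiles, and **Wiggum over-abundance ratios**
  (cluster mean relative abundance / cohort mean) for network rendering;
- computes **alpha diversity** (Shannon in log base 2, observed features,
  Faith's PD including the root path) and **unweighted / weighted UniFrac**
  distances, and ordinates them by **PCoA** (Gower double-centering,
  negative eigenvalues reported and dropped);
- clusters FFQ profiles into **dietary groups** by Ward/Euclidean
  clustering of the first **correspondence-analysis** axis, and scores each
  diet with the **Healthy Food Diversity index**
  `HFD = (sum hv_i s_i) * (1 - sum s_i^2)` — a health-value-weighted Berry
  diversity of the consumption shares — plus macronutrient summaries
  (4/9/4 kcal/g shares, fibre per 1000 kcal);
- associates clinical markers with the ordination by **age-adjusted median
  (quantile tau = 0.5) regression**, reporting coefficients scaled to the
  full axis range (RC range) and to one axis standard deviation (RC sd)
  with seeded xy-bootstrap inference, and fits food vectors onto the
  ordination with permutation tests (envfit-style r²);
- tests **diet × microbiota combinations** for enrichment in a binary
  phenotype at the subject level with Fisher's exact test, and compares
  taxon abundances across groups with Wilcoxon / Mann-Whitney /
  Kruskal-Wallis tests under Benjamini-Hochberg correction.

A fully parameterised **synthetic cohort generator** (70 subjects × 2 time
points by default, latent community states with a diversity gradient,
latent diet groups coupled to state, inflammatory markers tracking the
community gradient, per-subject microbial signatures) provides ground truth
so that every stage is testable without access to cohort data.

## Worked example

```r
library(microstrat)

cohort <- generate_cohort(synthetic_config(seed = 42))
#> synthetic_cohort: 70 subjects x 2 time points, 300 OTUs (40 genera),
#> 4 states, 5 diet groups, seed 42

states <- identify_steady_states(cohort$otu_table, k = 4, seed = 42)
#> steady states: 4 clusters over 140 samples (C1=47, C2=44, C3=28, C4=21)
#>   PERMANOVA pseudo-F = 20.343, p = 0.001

diets <- identify_diet_groups(cohort$ffq, m = 5)
#> diet groups: 5 groups over 140 samples (D1=34, D2=27, D3=42, D4=24,
#> D5=13); CA axis 1 explains 61.7%

hfd <- hfd_index(cohort$ffq)
round(tapply(hfd, diets$labels, mean), 3)
#>    D1    D2    D3    D4    D5
#> 0.241 0.340 0.510 0.673 0.768

mclust::adjustedRandIndex(states$labels, cohort$truth$state)
#> [1] 0.9874612
```

The pseudo-F of 20.3 with the minimal permutation p (0.001 at 999
permutations) says the four clusters are strongly separated in the
Spearman-correlation geometry; the adjusted Rand index of 0.99 against the
generator's truth confirms the clustering recovers the latent states. The
HFD means rise monotonically across diet groups because the synthetic diet
templates sit along a single food-healthiness gradient that the first CA
axis captures (61.7% of inertia).

The whole pipeline — normalization, diversity, UniFrac, PCoA, steady
states, CAGs, diet groups, HFD, envfit, median regressions, group tests,
combination enrichment, provenance-stamped artifacts and a run report — is
one call:

```r
report <- run_pipeline(pipeline_config(synthetic = TRUE,
                                       outdir = "out", seed = 42))
```

or, from a shell, `inst/scripts/microstrat run --seed 42 --outdir out`
(subcommand `simulate` writes just a cohort; exit codes: 0 success, 2
validation error, 1 runtime failure).

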