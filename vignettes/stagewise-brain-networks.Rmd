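---
title: "Stage-wise analysis of mutual-information brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise analysis of mutual-information brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`adnetworks` implements a pipeline for comparing resting-state functional
brain networks across clinical stage groups (healthy subjects, amnestic
mild cognitive impairment, and dementia at CDR 0.5 / 1 / 2):

1. **Connectivity.** For each subject, pairwise mutual information (MI)
   between the time series of 90 cerebral regions (AAL parcellation),
   estimated by the plug-in histogram formula
   $MI = \sum_{a,b} p(a,b)\,\log_2 \frac{p(a,b)}{p(a)\,p(b)}$
   in bits. MI is chosen over Pearson correlation because it also captures
   non-linear dependence.
2. **Network construction.** Each MI matrix is binarized by keeping the
   top-ranked entries up to a fixed edge density
   $d = 2E / (N(N-1))$, default 7%, so every subject's graph has the same
   number of edges (280 for 90 nodes) and topological measures are
   comparable across subjects and groups.
3. **Graph measures.** Seven whole-network measures — characteristic path
   length, clustering coefficient, global efficiency, local efficiency,
   betweenness centrality, degree assortativity, and modularity — plus
   their nodal forms and averages within ten lobe-by-hemisphere cells.
4. **Rich-club analysis.** $\Phi(k) = 2E_{\ge k} / (N_{\ge k}(N_{\ge k}-1))$
   over a range of degree thresholds, normalized by the mean over a
   degree-preserving rewiring null ensemble, with a permutation p-value.
5. **Group statistics.** One-way ANOVA with Tukey–Kramer post-hoc
   comparisons for each measure (whole brain and per lobar cell), and
   Pearson correlations between measures and clinical scores within each
   group and pooled.

A synthetic cohort generator drives end-to-end validation, since no
resting-state dataset is distributed with the package.

## The synthetic cohort model

Each subject's series is a stationary zero-mean multivariate normal over
the 90 regions with a block-modular correlation structure, one module per
lobe. Two parameters control it:

* `within_base` (default 0.6) — the correlation between regions of the
  same module;
* `coupling_by_group[group]` $\in [0,1)$ — the **integration coupling**: the
  between-module correlation is `coupling * within_base`.

The coupling is the stage-dependent parameter. This parameterization is a
deliberate design choice: at a fixed edge density the network's topology is
governed by how well the between-module MI values compete with the
within-module ones for the fixed edge budget. When the coupling is low the
budget concentrates inside modules and the graph fragments into lobe-sized
components (low global efficiency); as the coupling rises, cross-module
edges enter the graph, paths shorten, and global efficiency rises
monotonically. Making the *within*-module correlation the stage parameter
would invert this relationship (a stronger module soaks up the whole edge
budget), and could not reproduce a cohort in which the stage ordering of
couplings is mirrored by the ordering of group-mean efficiency. With
integration as the parameter, the generator expresses the disconnection
view of dementia directly: disease stages differ in long-range,
between-lobe integration.

Default group couplings are HS 0.55, aMCI 0.85, CDR0.5 0.40, CDR1 0.70,
CDR2 0.25 — non-monotonic across the stage sequence
(HS < aMCI > CDR0.5 < CDR1 > CDR2), emulating a cohort whose efficiency
and betweenness are elevated in the aMCI and CDR 1 stages relative to
their neighbours. The values were placed on the responsive part of the
coupling–efficiency curve (couplings below about 0.3 sit on a flat,
fully-fragmented plateau) with gaps large enough that group-mean orderings
are stable at the default group sizes (31/50/25/36/10, total 152). Each
subject's realized coupling adds Gaussian jitter (`coupling_jitter_sd`,
default 0.06) around the group value, which creates within-group variance
in both network measures and clinical scores.

Clinical scores are `baseline + clinical_effect * coupling + noise`, with
baselines and noise SDs taken from typical healthy-subject values of a
standard dementia battery (MMSE, SVLT delayed recall, COWAT, Stroop, and
so on). The default `clinical_effect` is −25 points per unit coupling:
within a group, subjects with higher realized integration score *worse*,
mirroring the negative metric–score correlations such cohorts show in
prodromal stages. The scores are plausible in location and spread but are
not calibrated to reproduce any published group table.

What the generator deliberately omits: hemodynamics, temporal
autocorrelation (an optional AR(1) filter, `ar_coef`, is available but
defaults to 0 because MI ranking and thresholding do not depend on it),
motion and physiological artifacts, and spatial heterogeneity within
modules. Passing tests on this cohort therefore demonstrates that the
*pipeline* recovers planted group structure; it says nothing about
preprocessing choices on real fMRI.

## Numerical and statistical choices

* **Binning.** Marginal equiprobable (quantile) binning with
  `ceiling(sqrt(T/5))` bins clamped to [4, 16] (5 bins at T = 120). Values
  equal to a boundary go to the lower bin; boundaries are type-7
  (linear-interpolation) quantiles. Quantile binning makes MI invariant to
  monotone signal transforms. No bias correction is applied: thresholding
  uses only the rank order of MI values, which the uniform plug-in bias
  does not disturb. MI is reported in bits; the log base cannot change the
  edge ranking either.
* **Edge budget.** `round(d * N(N-1)/2)` with half away from zero. Ties at
  the cutoff are broken lexicographically by (row, column) index —
  deterministic and order-stable. Thresholding is scale-invariant and edge
  sets nest across densities in the absence of cutoff ties.
* **Subject screen.** The degree screen thresholds each subject's MI
  matrix at an absolute value (`screen_tau`, default 0.8 — a config value,
  since its natural scale depends on the MI estimator's units) and flags
  total degrees outside the Tukey fences Q1 − 1.5 IQR and Q3 + 1.5 IQR.
* **Disconnected graphs.** Path length averages over reachable pairs only
  (the count of unreachable pairs is attached to the result); efficiency
  measures use $1/\infty = 0$ and need no special handling — one reason
  they are the headline measures at sparse densities.
* **Betweenness normalization** divides by $(N-1)(N-2)/2$, the number of
  pairs excluding the node, the standard convention for undirected graphs.
* **Assortativity** is undefined on degree-regular graphs and returns NA
  with a warning rather than a number.
* **Modularity** is the best Newman Q found by the multilevel (Louvain)
  heuristic over 20 seeded restarts. The heuristic is the definition of
  the operation: on small graphs it can sit slightly below the exhaustive
  optimum, which is why validation checks its Q against the Newman formula
  on the partition it returns, bounded by the exhaustive maximum, rather
  than asserting equality with brute-force search.
* **Rich club.** Degrees are measured once in the full graph and nodes
  with degree ≥ k are retained (no iterative re-peeling: the coefficient's
  formula references a single removal step). The null model performs
  double-edge swaps until 10 × E successful swaps per network; the
  reference ensemble size is 1000 networks, and $\Phi_{random}$ is the
  ensemble mean. The permutation p-value uses the add-one form
  $(1 + \#\{\Phi_{null} \ge \Phi\}) / (1 + n_{defined})$ so it can never
  be exactly zero. Thresholds where either quantity is undefined are
  flagged, never dropped.
* **Group networks.** How a group-level network should be aggregated from
  subject matrices is genuinely open; the package averages the subjects'
  connectivity matrices element-wise and thresholds the mean to the same
  density. This keeps group networks on the subject networks' density
  footing and is labelled in the network's provenance field.
* **Statistics.** ANOVA and Tukey–Kramer come from R's `aov`/`TukeyHSD`
  (the Kramer form handles the unequal group sizes and is conservative);
  correlations from `cor.test`. Correlation p-values are uncorrected by
  default, with an optional Benjamini–Hochberg flag; lobar tests run
  per-cell without correction, treating lobes as independent. Missing
  clinical items are deleted pairwise.

## Validation scales

The shipped validation suite runs the generator end to end at the full
cohort scale (152 subjects, 90 regions, 120 time points) across 50 seeds
for the ordering-recovery check; brute-force oracle comparisons use 200
random graphs of up to 8 nodes, where exhaustive enumeration (Floyd–
Warshall distances, explicit shortest-path enumeration, all set
partitions) is feasible; rewiring nulls use ensembles of 100–200 networks
in tests, with 1000 as the analysis default.

## Worked example

```{r, eval = FALSE}
library(adnetworks)

spec <- cohort_spec(seed = 1)
cohort <- generate_cohort(spec)
res <- run_group_pipeline(cohort, list(n_random = 100, seed = 1))

# non-monotonic stage profile of global efficiency
tapply(res$subject_metrics$global_efficiency,
       res$subject_metrics$group, mean)

# rich-club curve of the healthy-subject group network
res$rich_club$HS
```

## Known limitations

* The MI estimator's absolute values depend on the binning scheme; only
  rank-based downstream quantities (edge sets, densities) are comparable
  across estimator settings. Exact numeric parity with connectivity
  matrices produced by other toolchains is not a goal.
* The generator's Gaussian, temporally white signal model cannot probe
  preprocessing-sensitive behaviour (autocorrelation-induced MI bias,
  motion artifacts).
* Group-level rich-club results depend on the mean-matrix aggregation
  choice above.
* The AAL region-to-lobe assignment is a convention and user-overridable;
  lobar results depend on it.
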