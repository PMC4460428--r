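# adnetworks

Stage-wise graph analysis of mutual-information functional brain networks.

## The problem

In progressive dementia, resting-state functional connectivity between
brain regions reorganizes with clinical stage — and not necessarily
monotonically: prodromal stages can show *higher* network efficiency than
both healthy subjects and later stages. Detecting such stage-specific
topology requires a pipeline in which every subject's network is built the
same way, has the same size, and is summarized by comparable graph
measures. `adnetworks` provides that pipeline for region-by-time
resting-state data (90-region AAL parcellation), aimed at researchers
comparing network topology across clinical groups.

## The method

For each subject with region time series $X_1, \dots, X_{90}$:

1. **Connectivity** — pairwise mutual information from the joint histogram
   under marginal equiprobable binning,
   $MI(X,Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}$ (bits),
   which captures non-linear as well as linear coupling.
2. **Fixed-density network** — keep the top-ranked MI pairs up to density
   $d = 2E/(N(N-1)) = 7\%$: every subject's binary graph has exactly 280
   of the 4005 possible edges, so measures are comparable across subjects.
3. **Graph measures** — characteristic path length, clustering
   coefficient, global and local efficiency, betweenness centrality,
   degree assortativity, and Newman modularity; whole-brain, nodal, and
   averaged within ten lobe-by-hemisphere cells.
4. **Rich club** — $\Phi(k) = 2E_{\ge k}/(N_{\ge k}(N_{\ge k}-1))$, the edge
   density among nodes of degree ≥ k, normalized by its mean over a
   degree-preserving double-edge-swap null ensemble
   ($\Phi_{norm} = \Phi / \Phi_{random}$, permutation p-value).
5. **Group statistics** — one-way ANOVA + Tukey–Kramer post-hoc per
   measure, and Pearson correlations (p / R² / r) between measures and
   clinical scores, per group and pooled.

A synthetic five-group cohort generator (block-modular Gaussian series
whose between-lobe integration varies by stage, with clinical scores
linearly coupled to each subject's realized integration) makes the whole
pipeline testable without imaging data. See the vignette
(`vignettes/stagewise-brain-networks.Rmd`) for the model and all numerical
conventions.

## Worked example

A reduced cohort (8 subjects per group) through the full pipeline:

```r
library(adnetworks)

spec <- cohort_spec(group_sizes = c(HS = 8L, aMCI = 8L, CDR0.5 = 8L,
                                    CDR1 = 8L, CDR2 = 8L), seed = 1)
cohort <- generate_cohort(spec)
res <- run_group_pipeline(cohort, list(n_random = 100, seed = 1))

round(tapply(res$subject_metrics$global_efficiency,
             res$subject_metrics$group, mean), 3)
#>   aMCI CDR0.5   CDR1   CDR2     HS
#>  0.383  0.156  0.309  0.131  0.232
```

Group-mean global efficiency reproduces the generator's non-monotonic
stage profile (CDR2 < CDR0.5 < HS < CDR1 < aMCI): the prodromal (aMCI) and
CDR 1 stages sit *above* their neighbours. The post-hoc contrast between
aMCI and CDR 0.5 is strongly significant:

```r
subset(res$comparisons, metric_name == "global_efficiency" &
       group_a == "CDR0.5" & group_b == "aMCI")
#>          metric_name anova_F  anova_p group_a group_b mean_diff adjusted_p significant_at_05
#>    global_efficiency      42 6.81e-13  CDR0.5    aMCI    -0.226    1.1e-10              TRUE
```

The healthy-subject group network shows rich-club organization over a band
of degree thresholds:

```r
as.data.frame(res$rich_club$HS)[6:10, ]
#>     k n_nodes n_edges   phi phi_random phi_norm perm_p defined
#> 6   6      41     171 0.209      0.188     1.11 0.0099    TRUE
#> 7   7      33     149 0.282      0.227     1.24 0.0099    TRUE
#> 8   8      31     135 0.290      0.237     1.22 0.0099    TRUE
#> 9   9      27     121 0.345      0.258     1.34 0.0099    TRUE
#> 10 10      20     101 0.532      0.301     1.76 0.0099    TRUE
```

`phi` is the observed rich-club coefficient, `phi_random` its mean over
100 rewired null networks, `phi_norm` their ratio (> 1 indicates a rich
club), and `perm_p` the add-one permutation p-value (0.0099 is the
smallest value attainable with 100 nulls).

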