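# cellmeth

Bayesian model selection for cell-specific DNA methylation in sorted blood
cells.

Whole-blood methylation signal is dominated by cell-type composition.
Given cell-sorted beta-value matrices (probes × samples) with a sample
sheet mapping samples to subject, cell type and sex, `cellmeth` identifies,
for every CpG probe, *which* cell types carry a distinct methylation level
— single cell types or lineage-coherent groups (all T cells, all
lymphocytes, the myeloid branch) — and whether those cell-specific levels
differ between females and males. It is aimed at analysts of Illumina
450K-style cell-sorted methylation studies and at anyone building
reference panels for cell-mixture deconvolution.

## The model

Cell lineage is inferred by hierarchical clustering of cell-type mean
profiles; each dendrogram leaf and internal node defines a candidate
partition of the J cell types (members get their own mean, non-members
pool into a reference partition), plus the null and saturated models —
twelve candidates for the six standard blood cell types. For CpG *k*, sex
*s* and model *m* with design matrix X<sub>m</sub>:

- likelihood: y<sub>iks</sub> ~ N<sub>J</sub>(X<sub>m</sub> μ, σ² I), i = 1…n<sub>s</sub>
- g-prior: μ | g, σ² ~ N(b₀𝟙, (g σ²/n<sub>s</sub>) (X<sub>m</sub>ᵀX<sub>m</sub>)⁻¹), with p(σ²) ∝ 1/σ²

The marginal likelihood p(y | m, g) is available in closed form, so
posterior model probabilities Pr(m | y<sub>k</sub>) follow by normalisation
(equal model priors). The shrinkage factor g is estimated per sex by an
empirical-Bayes EM algorithm maximising the model-averaged marginal
likelihood. Marker panels per model are selected at a 5% Bayes FDR (largest
probability-ranked set whose mean (1 − probability) stays below the level);
differential methylation and female-vs-male differences are summarised by
closed-form normal posteriors. A synthetic-data generator with recorded
truth makes every stage testable without downloads. See
`vignettes/cellmeth-methods.Rmd` for derivations, defaults and caveats.

## Worked example

```r
library(cellmeth)

cfg <- sim_config(K = 2000, seed = 42,
                  sex_shift = list(delta = 0.2, prob = 0.05))
sim <- simulate_dataset(cfg)

fit_f <- fit_models(sim$F, sim$models)  # EM estimate of g per sex
fit_m <- fit_models(sim$M, sim$models)
glance(fit_f)
#> # A tibble: 1 × 8
#>   sex   n_probes n_models n_subjects    b0     g em_converged em_iterations
#>   <chr>    <int>    <int>      <int> <dbl> <dbl> <lgl>                <int>
#> 1 F         2000       12          5 0.516 1988. TRUE                     4
```

2,000 probes were fit against the twelve candidate models with 5 female
subjects; the EM estimate ĝ ≈ 1988 means the data dominate the prior
(shrinkage weight g/(1+g) ≈ 0.9995) while the Occam factor ½·log(1+ĝ) per
extra partition strongly favours parsimonious models.

```r
panel_f <- select_markers(fit_f, "CD56_NK", fdr_level = 0.05)
panel_m <- select_markers(fit_m, "CD56_NK", fdr_level = 0.05)
panel_f
#> <marker_panel> model CD56_NK: 21 probes at Bayes FDR <= 0.05 (realized 0.04092)

common <- common_markers(panel_f, panel_m)
length(common)
#> [1] 16
```

21 probes show NK-specific methylation in females at an estimated Bayes
FDR of 4.1%; 16 of them are also selected in males (common markers).

```r
diffs <- differential_posterior(fit_f, "CD56_NK", probes = common)
head(dplyr::select(diffs, probe_id, partition, posterior_mean,
                   ci_low, ci_high, state))
#> # A tibble: 6 × 6
#>   probe_id partition posterior_mean ci_low ci_high state
#>   <chr>    <chr>              <dbl>  <dbl>   <dbl> <chr>
#> 1 cg001536 CD56_NK           -0.104 -0.120 -0.0877 hypomethylated
#> 2 cg000407 CD56_NK           -0.290 -0.307 -0.273  hypomethylated
#> 3 cg001031 CD56_NK            0.290  0.274  0.306  hypermethylated
#> 4 cg000044 CD56_NK           -0.310 -0.327 -0.293  hypomethylated
#> 5 cg001949 CD56_NK            0.280  0.266  0.294  hypermethylated
#> 6 cg000423 CD56_NK            0.294  0.278  0.310  hypermethylated
```

Each row is the posterior of the NK-minus-reference methylation
difference with its 95% credible interval; the recovered magnitudes match
the simulated effect size of 0.3 (cg001536's smaller difference reflects a
simulated female-only shift partially cancelling its effect).

```r
sex <- sex_effect_posterior(fit_f, fit_m, "CD56_NK", probes = common)
dplyr::count(sex, declared)
#> # A tibble: 2 × 2
#>   declared     n
#>   <lgl>    <int>
#> 1 FALSE       15
#> 2 TRUE         1
dplyr::filter(sex, declared) |>
  dplyr::select(probe_id, posterior_mean, posterior_sd, prob_effect)
#> # A tibble: 1 × 4
#>   probe_id posterior_mean posterior_sd prob_effect
#>   <chr>             <dbl>        <dbl>       <dbl>
#> 1 cg001536          0.199       0.0117           1
```

One common marker is declared sex-specific: its female-minus-male NK
difference of 0.199 (the simulated shift was 0.2) has posterior
probability ≈ 1 of exceeding 0.10 in absolute value.

`plot_posterior_probs()`, `plot_differential()` and `plot_sex_effects()`
give ggplot views of the same objects, and `tidy()` methods return long
tibbles for downstream work. A command-line wrapper over these functions
(subcommands `simulate`, `fit`, `markers`, `diff`, `sex-effects`,
`validate`, `features`) is installed at
`system.file("cli", "cellmeth.R", package = "cellmeth")`.

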