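# resorb

Tools for analysing **community-level leaf nitrogen and phosphorus
resorption** along ecological transects, aimed at plant and ecosystem
ecologists working with paired mature/senesced leaf chemistry and
resin-core soil incubations (e.g. grassland or permafrost transect
campaigns).

The package computes, for each site of a transect:

* **Resorption efficiency** `NuRE = (Nu_mat − Nu_sen)/Nu_mat × 100` and
  absolute resorption `Nu_mat − Nu_sen` (g kg⁻¹), for N and P;
* **Resorption proficiency**: the senesced concentration against the
  complete-resorption boundary (< 0.4 g kg⁻¹ for P);
* **Mass-loss harmonisation** of literature values,
  `NuRE = (1 − (1 − NuRE_m)·MLCF) × 100`, with the five growth-form MLCF
  constants (0.780, 0.784, 0.745, 0.640, 0.713) and its algebraic inverse;
* the three classical **control-strategy diagnostics** via log10–log10
  power-law regressions: concentration control (`Nu_sen = a·Nu_mat^b`,
  slope *b* tested against 1), stoichiometry control (NRE–PRE correlation
  plus resorbed N:P vs mature N:P), and limitation control
  (`resorbed N:P = ε·(leaf N:P)^λ`, exponent λ tested against 1);
* **net soil mineralization rates** from resin-core budgets,
  `(post_soil + resin − pre_soil)/(π(d/2)²·days)` in ng cm⁻² d⁻¹;
* the **resorption–supply trade-off**: linear fits of efficiency on
  mineralization rate, with an effect-size-gated significance rule
  (P < 0.05 **and** |Cohen's d| > 0.2) for the group comparisons.

A synthetic transect generator (`simulate_transect()`) with a stored
ground-truth record emulates a 30-site × 3-replicate campaign, so the whole
chain is validated by parameter recovery without any data download.

## Worked example

```r
library(resorb)

sim   <- simulate_transect(synthetic_config(seed = 42))
pairs <- pair_site_periods(sim$leaf)
sites <- site_resorption(pairs)

paired_t(sites$pre, sites$nre)
#> estimate = 19.3847, t = 12.810, df = 29, P = 1.82e-13
#> Cohen's d = 2.339, 95% CI [16.290, 22.480], power = 1.000
#> significant (P < 0.05 and |d| > 0.2): TRUE
```

P resorption exceeds N resorption by ~19 percentage points across the 30
sites (mean NRE 55.9 ± 1.7%, mean PRE 75.3 ± 1.1%): the transect conserves
P more tightly than N.

```r
limitation_control_test(sites)
#> Strategy: limitation_control ( N relative to P )
#>   criterion: slope lambda of log10(resorbed N:P) on log10(mature N:P) < 1 (one-sided P = 0.00189)
#>   supported: TRUE at alpha = 0.05
```

The fitted exponent λ is significantly below 1: as leaf N:P rises (P
limitation worsens), P is resorbed preferentially.

```r
rates <- aggregate_rates(net_mineralization_rate(sim$incubation))
fit_tradeoff(sites$nre, rates$n_rate,
             response_name = "NRE", predictor_name = "N mineralization")
#> Trade-off fit: NRE ~ N mineralization  [site_means]
#>   slope = -0.07141 (SE 0.01789), intercept = 73.5
#>   R2 = 0.3628, n = 30, df = 28, P = 0.000428
#>   negative trade-off: TRUE
```

Sites with faster soil N supply resorb leaf N less efficiently — the
trade-off — while the same fit for P (`fit_tradeoff(sites$pre,
rates$p_rate)`) comes out flat (P = 0.16), reproducing the N/P asymmetry
the generator imposes.

`run_pipeline(run_config(leaf_csv, incubation_csv))` executes the whole
chain from CSV inputs (schemas documented in `?read_leaf_table` and
`?read_incubation_table`) and writes per-stage CSVs plus a key/value run
report.

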