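# ecostoich

Community-level ecological stoichiometry along environmental gradients, for
plot-based vegetation surveys: who is limited by what, how much N and P
plants pull back before leaf fall, and how tightly leaf chemistry is
regulated against the soil.

Field studies of this kind record, per plot, species biomass and green-leaf
C/N/P, senesced-leaf N/P, and soil chemistry along an elevation gradient.
`ecostoich` turns those three tables into the standard community-level
quantities and tests:

* **Community-weighted traits** — LTC/LTN/LTP as biomass-proportion-weighted
  means `CWM = Σ pᵢ tᵢ`, their C:N, C:P and N:P ratios, plus Shannon
  diversity `H' = −Σ pᵢ ln pᵢ` and Pielou evenness `E = H'/ln S`.
* **Nutrient resorption** — `NuRE = (1 − senesced/green × MLCF) × 100` with
  a mass loss correction factor (default 0.762), and the ratio of absolute
  resorbed amounts `(LTN − LTNₛ·MLCF)/(LTP − LTPₛ·MLCF)`.
* **Resorption control strategy** — a power law
  `resorbed N:P = ω·(N:P)^λ` fitted on log10–log10 axes plus a linear fit on
  the raw scale; 95% CIs on both slopes classify the community as
  *stoichiometric control* (both CIs contain 1), *nutrient limitation
  control* (power-law CI excludes 1) or *joint regulation*.
* **Stoichiometric homeostasis** — `lg y = lg c + lg x/H` regressed on
  plot-paired soil values; `H = 1/slope`, classified on Persson's bands
  (H ≥ 4 steady state … H < 1.33 sensitive state; non-significant
  regressions are an *absolute steady state*).
* **Nutrient limitation** — leaf N:P thresholds, Güsewell 10/20 and
  Koerselman–Meuleman 14/16.
* **Elevation gradients** — polynomial trends of order 1–3 with AICc model
  selection, and Pearson/Spearman correlation screening with BH-adjusted
  p-values.
* **Synthetic communities** — `generate_dataset()` builds full
  survey/litter/soil triplets with known λ, ω, H and resorption targets, so
  every stage is testable by parameter recovery without field data.

See `vignettes/community-stoichiometry.Rmd` for the models, defaults and
verification strategy.

## Worked example

```r
library(ecostoich)

sim <- generate_dataset(simulation_config(seed = 1))   # 6 sites x 4 plots
tr  <- community_traits(sim$survey, elevations = sim$soil)
rs  <- resorption_table(tr, sim$litter, survey = sim$survey)
control_strategy(tr$ratio_NP[match(rs$plot_id, tr$plot_id)], rs$resorbed_NP)
#> Nutrient resorption control strategy
#>   power law : resorbed N:P = 1.172 * (N:P)^0.9584
#>   lambda    : 0.9584  [0.5033, 1.4135]  R^2 = 0.464
#>   lin slope : 0.9645  [0.4944, 1.4345]  R^2 = 0.451
#>   n used = 24, excluded = 0
#>   strategy  : stoichiometric control
```

Both slope CIs contain 1, so N and P are resorbed in proportion to
green-leaf stoichiometry — the generator's truth here was λ = 0.912, a
regime indistinguishable from proportionality at 24 plots.

```r
homeostasis_table(tr, sim$soil)
#>   trait        H         c      slope      p_value  r_squared  n                 label
#> 1     N      Inf 26.403055 0.04840600 1.753168e-01 0.08185431 24 absolute steady state
#> 2     P 17.74229  1.984411 0.05636251 1.851153e-03 0.36253615 24          steady state
#> 3   N:P 18.78775 13.340390 0.05322618 1.236725e-06 0.66423546 24          steady state
```

Leaf N:P barely moves across a wide soil N:P range (slope 0.053, H ≈ 18.8):
strong homeostasis, as configured (H_true = 16.34). Mean resorption on this
dataset is NRE = 79.5% and PRE = 75.7%, and every plot's leaf N:P falls in
the 10–20 co-limitation band of the Güsewell scheme
(`limitation_table(tr)`).

The end-to-end pipeline, writing one CSV per stage plus `warnings.csv` and a
JSON run manifest:

```r
run_all("results/", sim = sim)            # or survey=/litter=/soil= file paths
```

A command-line front end lives in `inst/scripts/ecostoich.R`
(`simulate` and `run-all` subcommands).

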