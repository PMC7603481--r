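# patchties

Detecting and testing **long-term social ties** between individually
marked animals that breed in ephemeral patches within colonies.

In many colonial seabirds, breeding happens in discrete patches that
turn over almost annually (mean occupancy on the order of 1.5 seasons),
so two birds found side by side in successive years cannot be explained
by each returning to a fixed site. The question this package answers
from resighting records is: do particular *pairs* of individuals keep
breeding together across years and across different patches — social
ties — and does that cohesion survive a perturbation regime?

`patchties` is aimed at behavioural ecologists working with long-term
individual mark–resight programmes. It provides a tidyverse-style
pipeline:

* **Association** — period-level dyadic sociomatrices with ternary
  states (*together* / *apart* / *missing*: a missed individual is
  missing data, not evidence of separation), and the half-weight
  association index
  `HWI = x / (x + y_ab + 0.5 (y_a + y_b))` for weighted network export.
* **Persistence tests** — the 3×3 dyad table cross-classifying an
  earlier and a later period, a Pearson chi-square (df = 1, no
  continuity correction) on its fully observed 2×2 core, and
  power-matched subsampling for comparing phases of unequal size.
* **Network regression** — a Bayesian symmetric binary-probit
  social-relations model fitted by Gibbs sampling,

  `z_ij = β0 + β_dyad · x_ij + a_i + a_j + ε_ij,  y_ij = 1(z_ij > 0)`,

  with one additive random effect per individual (`a_i ~ N(0, σ²_a)`),
  the previous period's together-indicator `x_ij` as the lagged dyadic
  predictor, and missing dyads imputed inside the MCMC under the
  missing-at-random assumption. Coefficients are reported as posterior
  mean (`pmean`), posterior SD (`psd`), `z = pmean/psd`, and
  `p = 2(1 − Φ(|z|))`.
* **Permutation null** — within each year, individuals are rearranged
  among patches keeping every patch's size fixed; the observed statistic
  (chi-square or the `.dyad` coefficient) is located in the null
  distribution with the add-one two-sided estimator.
* **Synthetic colony** — a seeded simulator (latent social groups,
  annual patch turnover, imperfect detection, perturbation regimes) with
  known ground truth, so the whole chain is testable end to end.

## Worked example

A small synthetic resighting table ships with the package (40 birds, 10
seasons, strong group fidelity):

```r
library(patchties)

recs <- read_resightings(
  system.file("extdata", "example_resightings_synthetic.csv", package = "patchties"))
#> read 129 resightings of 38 individuals (129 kept after validation)

rep <- run_phase_analysis(recs, 2002:2006, 2007:2011,
                          mcmc = mcmc_config(seed = 1), n_perm = 199,
                          seed = 1, quiet = TRUE)
rep
#> <phase_report> predictor 2002-2006, outcome 2007-2011
#> chi-square(1) = 20.1152, P = 7.291e-06 (n = 120 complete-case dyads)
#> <ame_fit> 703 dyads among 38 individuals (72.5% of outcomes imputed)
#>   intercept  pmean   -0.849  psd   0.211  z   -4.015  P 0.000
#>   .dyad      pmean    1.252  psd   0.262  z    4.770  P 0.000
#> <permutation_result> chi_square = 20.1152 vs 199 within-year permutations
#>   extremeness 0.0050 at level 0.05 -> evidence of non-random association
```

Reading the output: dyads that bred together in 2002–2006 are far more
likely to breed together in 2007–2011 than independence predicts
(chi-square 20.1 on 120 fully observed dyads), the dyadic regression
coefficient is strongly positive (`.dyad` posterior mean 1.25, z = 4.8)
after absorbing individual gregariousness in the additive effects, and
the observed chi-square sits beyond all 199 patch-size-preserving
permutations (extremeness 0.005) — ties between particular individuals,
not site fidelity or general sociability.

`tidy()`, `glance()` and `autoplot()` methods expose every result as
tibbles and ggplots; `run_full_study()` chains two phases (stable vs
perturbed) with power-matched subsampling, and `export_edges()` /
`write_graphml()` produce weighted networks for external layout tools.

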