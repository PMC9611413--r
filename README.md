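# popmix

Population variability in concentration addition for chemical mixtures.

## The problem

Component-based mixture risk assessment leans on **concentration addition
(CA)**: the assumption that the effective concentration of a mixture for any
effect size is the fraction-weighted harmonic sum of its components'
effective concentrations,

```
1 / EC_x,CA = Σ_k  f_k / EC_x,k .
```

When a mixture is tested across a *population* of genetically distinct
individuals (e.g. a panel of lymphoblastoid cell lines from ~150 donors),
CA can be applied in several non-equivalent ways, differing in how they
assume individual sensitivity correlates across components. `popmix`
implements the full analysis chain needed to ask how accurate each variant
is — for the typical individual, for the sensitive tail of the population,
and for the ratio between the two:

1. **Hierarchical Bayesian Hill fits** per substance: each individual's
   concentration–response follows a downward Hill curve
   `y = y0 / (1 + (x/x0)^n)` with Student-t(5) residuals; individual
   `ln EC10` and `ln ñ` (Hill coefficient `n = 1 + ñ ≥ 1`) are lognormal
   random effects with uncertain population geometric mean (GM) and
   geometric standard deviation (GSD). Sampling runs in JAGS with a
   split-chain Rhat ≤ 1.2 gate and a chain-doubling protocol
   (4000 → 16,000 iterations).
2. **Points of departure**: per posterior draw, the population-median EC10
   (= GM), the sensitive 1st-percentile EC10 (= GM·GSD^−2.326) and the
   **toxicodynamic variability factor** TDVF01 = GSD^2.326, with the
   3×-top-concentration inactivity rule.
3. **Three population-level CA schemes**: `CA_Indiv` (CA per individual,
   then a censored-lognormal population fit), `CA_LNSum` (lognormal-sum
   approximation, assuming uncorrelated sensitivity) and `CA_Default`
   (quantile-wise CA, assuming perfectly correlated sensitivity).
4. **Loewe Additivity Index**: LAI = measured / CA-predicted, draw-wise;
   LAI < 1 flags greater-than-additive (synergistic) mixtures for which CA
   is not protective.
5. **Reporting**: two-way η² variance decomposition of log10 LAI (mixtures
   versus individuals), within-10-fold accuracy fractions, hierarchical
   clustering, and `10^{median [lo, hi]}`-style summary tables.

A synthetic-population generator with known ground truth — including an
interaction multiplier λ that plants exact additivity (λ = 1), synergy
(λ < 1) or antagonism (λ > 1) — makes the whole chain testable end to end:
the pipeline should recover λ as the LAI.

## Worked example

Twelve cell lines, three chemicals, and one mixture that is truly 3-fold
more potent than CA predicts (interaction multiplier 1/3):

```r
library(popmix)
mix <- mixture_spec("mixA", c(benzo = 0.5, cadmo = 0.3, pyri = 0.2),
                    interaction_multiplier = 1/3)
design <- study_design(sprintf("LCL%02d", 1:12), c("benzo", "cadmo", "pyri"),
                       list(mix))
truth <- sample_population_truth(design,
                                 gm_ec10 = c(benzo = 3, cadmo = 10, pyri = 25),
                                 gsd_ec10 = 1.8, rho = 0.5, sigma = 0.05,
                                 seed = 42)
dataset <- simulate_responses(truth, design, seed = 43)

cfg <- fit_config(initial_iterations = 2000, max_iterations = 8000, seed = 44)
post_benzo <- fit_hill_population(dataset, "benzo", cfg)
post_mix   <- fit_hill_population(dataset, "mixA", cfg)
print(post_benzo)
#> <hill_posterior> benzo: 4000 draws (4 chains, 2000 iter/chain), 12 individuals
#>   GM EC10 3.338 uM, GSD 2.417, converged: TRUE (max Rhat 1.175)

derive_pod_draws(post_mix)
#> <pod_summary> mixA:
#>   EC10 median  1.482 [0.9095, 2.418] uM
#>   EC10 1%      0.3008 [0.1002, 0.6704] uM
#>   TDVF         4.991 [2.445, 12.7] (default UF 3.16)

posts <- list(benzo = post_benzo,
              cadmo = fit_hill_population(dataset, "cadmo", cfg),
              pyri  = fit_hill_population(dataset, "pyri", cfg))
pred <- ca_indiv(posts, mix, censor_limit = 3 * design$c_max_uM,
                 n_draws = 300, seed = 45)
print(pred)
#> <ca_prediction> mixA by CA_Indiv (300 draws)
#>   EC10 median 5.231 [4.132, 8.051] uM; TDVF 4.729 [1.904, 7.48]

lai_levels(derive_pod_draws(post_mix), pred)$median
#> <lai_result> mixA / CA_Indiv / median: LAI = 10^-0.56 [-0.80, -0.29] (n = 300 draws)
```

Reading the output: the measured mixture median EC10 (1.5 µM) is about
3.5-fold below the CA prediction (5.2 µM), so LAI ≈ 10^−0.56 ≈ 0.28 — the
pipeline recovers the planted 1/3 interaction multiplier, flagging the
mixture as more potent than additivity predicts. The measured TDVF of ~5
exceeds the default uncertainty factor of 3.16 printed alongside it.

`run_pipeline(popmix_config(...))` chains all of the above (simulate → fit
→ POD → CA ×3 → LAI → report) and writes CSV/JSON artifacts plus a
provenance manifest; see `?run_pipeline`.

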