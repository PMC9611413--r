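---
title: "Population variability in mixture additivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population variability in mixture additivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`popmix` asks a quantitative question about component-based mixture risk
assessment: when a defined chemical mixture is tested across a genetically
diverse population of human cell lines, how accurately does concentration
addition (CA) predict the mixture's potency — for the typical individual,
for the sensitive tail of the population, and for the ratio between the
two? This vignette documents the models, the assumptions, the tunable
parameters and the numerical choices, in the order the pipeline applies
them.

## 1. The concentration–response model

Each substance (single chemical or whole mixture) and individual is
assumed to follow a *downward Hill* curve for normalized viability $y$ at
concentration $x$ (µM):

$$y = \frac{y_0}{1 + (x/x_0)^n} + \epsilon,$$

with baseline $y_0$ (fitted rather than fixed at 1, to absorb residual
drift after vehicle-control normalization), midpoint $x_0$ (EC50, µM), and
Hill coefficient $n$. Residuals are scaled Student-t,
$\epsilon = \sigma t(\nu)$ with $\nu = 5$ by default, which keeps the fit
robust to the occasional outlying well. The benchmark response is a 10%
viability decrement; the EC10 relates to the midpoint through
$x_0 = EC_{10}\,9^{1/n}$, and the sampler parameterizes the curve directly
in (EC10, $n$) so the quantity of interest carries no transformation error.

Two restrictions reflect prior biology: $n \ge 1$ (enforced exactly by
writing $n = 1 + \tilde n$ with $\tilde n \ge 0$), excluding implausibly
shallow curves, and $y_0 > 0$.

### Population structure

Individual-level parameters are lognormal random effects:
$\ln EC_{10,i} \sim N(\ln GM, (\ln GSD)^2)$ and similarly for
$\ln \tilde n_i$. The population geometric mean (GM, µM) and geometric
standard deviation (GSD, dimensionless $\ge 1$) of EC10 are the targets of
inference: GM is the population-median EC10 and GSD controls the spread of
individual sensitivity.

### Priors

The priors are weakly informative on the tested-concentration scale, and
all are exposed in `fit_config()`:

| parameter | prior | default | rationale |
|---|---|---|---|
| $\ln GM_{EC10}$ | Normal(mean, 4) | mean $= \ln c_{max}$ | centred at the top tested concentration, spanning many decades |
| $\ln GSD_{EC10}$, $\ln GSD_{\tilde n}$ | Half-Normal(ln 10 / 2) | — | population GSDs well above 10 remain reachable |
| $\ln GM_{\tilde n}$ | Normal(ln 0.5, 1) | — | Hill slopes near 1.5, weakly held |
| $\sigma$ | Half-Normal(0.3) | — | residual scale on the normalized-viability axis |
| $y_0$ | Normal(1, 0.2), truncated $> 0$ | — | baselines near 1 after normalization |

One $y_0$ is shared across the individuals of a substance. The data rarely
identify per-individual baselines at screening density (one replicate per
concentration), and a shared baseline keeps the per-curve parameter count
at two; this is an assumption, not a finding.

### Sampling and convergence

Sampling runs in JAGS (4 chains by default) with a non-centered
parameterization of the random effects — the scaled-deviate form avoids
the funnel geometry that centered hierarchies develop when the GSD is
small; a centered option exists behind `parameterization = "centered"`.
Chains start at 4000 iterations, the first half of every chain is
discarded as warm-up (JAGS adapts during at most the first 1000 of those),
and convergence is assessed with the split-chain potential scale reduction
factor implemented in `rhat()`. While any monitored parameter exceeds
$\hat R = 1.2$, the chain length doubles and the model reruns from
scratch, capping at 16,000 iterations per chain; the posterior carries a
`converged` flag either way. The monitored set is the population-level
quantities — the two GM/GSD pairs, $y_0$, $\sigma$ — not the per-individual
effects: with hundreds of individual parameters, gating on every one
makes the gate's false-alarm rate grow with population size while the
inferential targets are the population hyperparameters.

## 2. Points of departure and the variability factor

For each posterior draw, `derive_pod_draws()` computes

$$EC_{10,median} = GM, \qquad
  EC_{10,1\%} = GM \cdot GSD^{-2.326}, \qquad
  TDVF_{01} = GSD^{2.326},$$

where $2.326 = |\Phi^{-1}(0.01)|$ is computed by `quantile_constant()`,
not hard-coded, and the percentile level is a parameter (5% gives 1.645).
Repeating the arithmetic per draw propagates estimation uncertainty into
the POD and TDVF distributions. The conventional default toxicodynamic
uncertainty factor $10^{1/2} \approx 3.16$ is likewise computed
(`default_td_uf()`) and reported alongside measured TDVFs for comparison.

A substance is classified *inactive* when the posterior median of its GM
exceeds 3× the top tested concentration — such a fit extrapolates beyond
the tested range. The posterior median feeds the rule by default
(configurable to the mean; the choice of functional is not dictated by the
rule itself), and a tie at exactly 3× counts as active since the exclusion
is a strict inequality. The rule is applied to mixtures as well as
components, and the flag travels with every output table.

## 3. Three ways to apply CA to a population

All three schemes share the harmonic-sum kernel (`ca_harmonic()`) and
differ only in what they assume about how an individual's sensitivity
correlates across components:

* **`ca_indiv()`** applies CA within each individual,
  $1/EC_{10,CA,m,i} = \sum_k f_{k,m}/EC_{10,k,i}$, then fits the resulting
  per-individual EC10s to a right-censored lognormal to obtain the
  predicted population GM/GSD. It propagates the *empirical* cross-component
  correlation. Censoring (at 3× the top tested mixture concentration by
  default) prevents extrapolated individual CA values from distorting the
  population fit.
* **`ca_lnsum()`** uses only the component GM/GSD pairs and assumes
  sensitivities are *uncorrelated* across components: the CA denominator is
  a sum of independent lognormal terms with
  $\mu_{k,m} = \ln(f_{k,m}/GM_k)$, $\sigma_{k,m} = \ln GSD_k$, approximated
  as lognormal by zero-correlation moment matching (`lognormal_sum()`):
  with $E_k = e^{\mu_k + \sigma_k^2/2}$ and $S = \sum E_k$,
  $\sigma_S^2 = \sum \sigma_k^2 E_k^2 / S^2$ and
  $\mu_S = \ln S - \sigma_S^2/2$. The approximation preserves the
  arithmetic mean of the sum exactly — an identity the tests assert — and
  its error against brute-force simulation is well under a percent on the
  GM/GSD scale for the mixture sizes and spreads used here (up to ten
  components, $\sigma \le \ln 2$). Note that the natural scale for judging
  this approximation is the exponentiated one: relative error on the
  log-scale location $\mu$ depends on where zero is.
* **`ca_default()`** mirrors hazard-index practice and assumes *perfectly
  correlated* sensitivity: CA is applied separately to the component
  medians and to the component 1st-percentile EC10s, and the predicted
  TDVF is their ratio.

On synthetic populations the three schemes order as the correlation
structure dictates: quantile-wise CA is the $\rho = 1$ limit of
individual-wise CA (exactly so when components share one GSD — with
unequal GSDs the quantile-wise construction is no longer the distribution
of any individual-wise quantity, even at perfect rank correlation, which
is why the limiting-case tests fix a common GSD), the lognormal-sum scheme
is the $\rho = 0$ limit, and intermediate correlation lands in between:
$TDVF_{CA\_Default} \ge TDVF_{CA\_Indiv} \ge TDVF_{CA\_LNSum}$.

### Draw handling

Substances are fitted independently, so posterior draws carry no joint
structure across substances; predictions pair draws by pooled draw index
and subsample a configurable number (default 500) before the per-draw
censored-lognormal fits, which dominate `ca_indiv()`'s cost. The pairing
is arbitrary but deterministic given the seed, so reruns reproduce
identical tables. When measured and predicted draw vectors differ in
length, `lai()` aligns them by even-index subsampling of the longer.

### Inactive components

Components classified inactive contribute no term to any CA sum — their
EC10 is treated as infinite — and their fraction is *not* reassigned to the
remaining components. Renormalizing would silently change the mixture
being predicted; the un-renormalized convention keeps the prediction
interpretable as "the active portion of the dosed mixture".

## 4. The accuracy score

The Loewe Additivity Index is the measured-to-predicted ratio,
$LAI = EC_{10,measured}/EC_{10,CA}$, computed draw-wise at each population
level (and per individual from point estimates). $LAI < 1$ means the
mixture is more potent than CA predicts, so CA is not health-protective.
Summaries are the median and equal-tailed 95% interval of $\log_{10} LAI$,
formatted as $10^{m\,[lo,\,hi]}$. Pooled summaries weight mixtures
equally (each mixture's draws are evenly subsampled to the smallest count
before pooling), so a mixture with more retained draws does not dominate
the table.

LAI is invariant to per-chemical bioavailability: rescaling every
concentration at which chemical $k$ acts by a factor $b_k$ (component
EC10s $\to EC10/b_k$, fractions reweighted by $1/b_k$ and renormalized)
multiplies measured and predicted mixture EC10s by the same constant and
cancels from the ratio. The test suite asserts this identity, which means
LAI comparisons are meaningful even when absolute in-well bioavailability
differs across chemicals — as long as it is constant across concentrations
and mixtures.

## 5. The synthetic-population generator

`sample_population_truth()` + `simulate_responses()` emulate the structure
of a population-based cytotoxicity screen: ~146 cell lines × ~42 chemicals
× ~8 defined mixtures, five 10-fold serial dilutions (0.01–100 µM, top
concentration 100 µM), one replicate per (individual, substance,
concentration) cell by default, all configurable.

Generator defaults and what they represent:

* `gsd_ec10 = 2` — population variability of EC10 around its GM; 2 is a
  typical magnitude for cell-line panels (TDVF01 ≈ 5).
* `gm_ntilde = 0.5`, `gsd_ntilde = 1.5` — Hill offsets giving slopes
  mostly between 1.2 and 2.5.
* `sigma = 0.08` — residual scale on the normalized-viability axis, with
  $t(5)$ tails; a realistic screening noise level.
* `rho` — exchangeable cross-chemical correlation of individual
  sensitivity, $z_{k,i} = \sqrt{\rho}\,u_i + \sqrt{1-\rho}\,e_{k,i}$. The
  single-$\rho$ exchangeable family is deliberately the simplest structure
  that spans the two limiting assumptions of the CA schemes ($\rho = 1$
  and $\rho = 0$); richer correlation matrices are out of scope.
* `interaction_multiplier` ($\lambda_m$) — the planted truth for mixture
  $m$: its true per-individual EC10 is $\lambda_m$ times the exact CA
  value, so the pipeline's LAI should recover $\lambda_m$. With
  $\lambda_m = 1$ the truth satisfies CA to machine precision, an identity
  the tests assert.
* Default component GMs are log-spaced within the tested range (0.3–30
  µM) so every substance is active and informative at the default design.
* Mixture Hill offsets are drawn from the same $\tilde n$ population as
  chemicals: under CA the mixture curve is not exactly Hill, so the
  generator treats the mixture as its own Hill "substance" — consistent
  with how the analysis fits mixtures.

What the generator does **not** emulate: plate/edge effects,
normalization drift beyond the fitted baseline, toxicokinetics (nominal
concentration is the exposure metric), concentration-dependent
bioavailability, and upward or biphasic responses. Passing tests therefore
demonstrate correctness of the statistical machinery under its own
assumptions — not robustness of CA to the biology those phenomena
introduce in real screens.

## 6. Numerical choices

* **Censored lognormal fit**: values above the censor limit enter as
  right-censored; with no censoring the fit is the exact closed-form MLE
  (population-variance convention), and with censoring the likelihood is
  maximised by `fitdistrplus::fitdistcens` with a direct `optim` fallback.
  The fitted log-SD is floored at $\ln(1 + 10^{-9})$ so degenerate
  zero-spread inputs yield GSD $= 1 + 10^{-9}$ and downstream ratios stay
  finite. An all-censored input is a hard error, not a fit.
* **`rhat()`** splits each chain in half (dropping the middle draw of
  odd-length chains) and returns 1 for the all-constant degenerate case.
* **Exactly noise-free data** ($\sigma = 0$) make the $\sigma$-posterior
  degenerate and MCMC cannot mix on them; the noise-free *identities* are
  tested deterministically (exact Hill inversion of a $\sigma = 0$
  dataset), while likelihood-based recovery is tested at a small positive
  $\sigma$ where the posterior concentrates at truth.
* **Seeds** are explicit arguments everywhere; generator draws, chain
  initialisation, and draw subsampling all derive from them, and
  `run_pipeline()` derives per-stage seeds from the master seed so reruns
  are byte-identical at the CSV level.
* **Problem sizes**: the test suite and acceptance script exercise the
  chain at reduced sizes chosen to keep full runs in minutes — 8–30
  individuals and 600–2000 initial iterations for MCMC checks, $10^4$
  individuals for law-of-large-numbers checks on the generator,
  $2\times 10^4$ for the scheme-ordering comparisons, and $10^6$-draw
  Monte-Carlo oracles for the closed-form approximations. The statistical
  structure (five-concentration design, priors, convergence protocol) is
  identical at every size.

## 7. Known limitations

* Independent action (response additivity) is intentionally not
  implemented; the package quantifies the accuracy of CA only.
* Interaction is a generator input ($\lambda_m$), never estimated; the
  package scores departure from additivity but does not fit synergy
  models.
* The two-way η² decomposition assumes one value per (mixture,
  individual) cell and main effects only — with a single observation per
  cell there are no degrees of freedom for an interaction term.
* Mixture fractions are abstract weights summing to one; whether they are
  molar or mass fractions is the caller's convention, and results are
  interpretable as long as concentrations are expressed consistently.
* Posterior draw pairing across independently fitted substances is a
  bookkeeping convention; it induces no artificial correlation beyond
  seed determinism, but draw-level joint statements across substances
  have no extra meaning.
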