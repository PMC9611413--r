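test_that("ca_harmonic computes the weighted harmonic combination", {
  expect_equal(ca_harmonic(c(a = 1), c(a = 7)), 7)
  expect_equal(ca_harmonic(c(0.5, 0.5), c(1, 3)), 1.5)
  ## inactive component contributes no term, fraction not renormalized
  expect_equal(ca_harmonic(c(0.5, 0.5), c(1, Inf)), 2)
  expect_error(ca_harmonic(c(0.5, 0.4), c(1, 2)), "sum to 1")
  expect_error(ca_harmonic(c(0.5, 0.5), c(Inf, Inf)), "no active")
})

test_that("ca_harmonic never exceeds the harmonic-sum bound", {
  set.seed(81)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    f <- stats::runif(k); f <- f / sum(f)
    e <- exp(stats::rnorm(k, 0, 2))
    expect_lte(ca_harmonic(f, e), min(e / f) + 1e-12)
  }
})

test_that("lognormal_sum identities: single term, constants, exact mean", {
  expect_equal(lognormal_sum(0.3, 0.7), c(mu = 0.3, sigma = 0.7))
  expect_equal(lognormal_sum(c(0, 0), c(0, 0)), c(mu = log(2), sigma = 0))
  set.seed(82)
  for (rep in 1:20) {
    k <- sample(1:8, 1)
    mus <- stats::rnorm(k); sigmas <- abs(stats::rnorm(k, 0, 0.5))
    s <- lognormal_sum(mus, sigmas)
    ## arithmetic mean of the sum is preserved exactly
    expect_equal(exp(s[["mu"]] + s[["sigma"]]^2 / 2),
                 sum(exp(mus + sigmas^2 / 2)), tolerance = 1e-12)
  }
  expect_error(lognormal_sum(numeric(0), numeric(0)), "one term")
  expect_error(lognormal_sum(c(0, 0), c(0.1, -0.1)), ">= 0")
})

test_that("lognormal_sum matches a brute-force Monte-Carlo oracle", {
  set.seed(83)
  k <- 5
  sums <- rowSums(matrix(exp(stats::rnorm(1e6 * k, 0, log(1.5))), ncol = k))
  emp_mu <- mean(log(sums)); emp_sigma <- stats::sd(log(sums))
  ap <- lognormal_sum(rep(0, k), rep(log(1.5), k))
  ## compared on the GM/GSD (exponentiated) scale, where relative error is
  ## well defined for a log-scale location
  expect_equal(exp(ap[["mu"]]), exp(emp_mu), tolerance = 0.03)
  expect_equal(exp(ap[["sigma"]]), exp(emp_sigma), tolerance = 0.03)
})

test_that("a collapsed population gives floor GSD and unit TDVF", {
  ids <- sprintf("i%02d", 1:6)
  comp <- list(a = matrix(2, 3, 6, dimnames = list(NULL, ids)),
               b = matrix(6, 3, 6, dimnames = list(NULL, ids)))
  pred <- ca_indiv(comp, c(a = 0.5, b = 0.5), censor_limit = 1e6)
  expect_equal(unname(pred$indiv[1, ]),
               rep(ca_harmonic(c(0.5, 0.5), c(2, 6)), 6))
  expect_equal(pred$draws$gsd, rep(1 + 1e-9, 3), tolerance = 1e-10)
  expect_equal(pred$draws$tdvf, rep(1, 3), tolerance = 1e-6)
})

test_that("ca_indiv point mode equals the harmonic sum of posterior medians", {
  ids <- c("i1", "i2", "i3", "i4")
  set.seed(84)
  mk <- function(center) matrix(exp(log(center) + 0.05 * stats::rnorm(200 * 4)),
                                200, 4, dimnames = list(NULL, ids))
  comp <- list(a = mk(1), b = mk(4))
  pred <- ca_indiv(comp, c(a = 0.5, b = 0.5), censor_limit = 1e6,
                   mode = "point")
  med_a <- apply(comp$a, 2, stats::median)
  med_b <- apply(comp$b, 2, stats::median)
  manual <- 1 / (0.5 / med_a + 0.5 / med_b)
  expect_equal(pred$indiv, manual)
})

test_that("ca_indiv rejects unmatched individuals, naming them", {
  comp <- list(a = matrix(1, 2, 3, dimnames = list(NULL, c("i1", "i2", "i3"))),
               b = matrix(1, 2, 4,
                          dimnames = list(NULL, c("i1", "i2", "i3", "i4"))))
  expect_error(ca_indiv(comp, c(a = 0.5, b = 0.5), censor_limit = 100),
               "i4.*missing from.*a")
  expect_error(ca_indiv(comp["a"], c(a = 0.5, b = 0.5), censor_limit = 100),
               "missing from 'components': b")
})

test_that("ca_lnsum reduces to the harmonic sum for deterministic components", {
  comp <- list(a = c(gm = 1, gsd = 1), b = c(gm = 3, gsd = 1))
  pred <- ca_lnsum(comp, c(a = 0.5, b = 0.5))
  expect_equal(pred$draws$ec10_median, 1.5, tolerance = 1e-12)
  expect_equal(pred$draws$gsd, 1, tolerance = 1e-12)
  expect_equal(pred$draws$tdvf, 1, tolerance = 1e-12)
})

test_that("ca_lnsum matches a simulated-population oracle", {
  set.seed(85)
  gms <- c(1, 2, 4, 8, 16)
  f <- rep(0.2, 5)
  e <- sapply(gms, function(g) exp(log(g) + log(2) * stats::rnorm(1e6)))
  ca_pop <- 1 / rowSums(sweep(1 / e, 2, f, "*"))
  emp_gm <- exp(mean(log(ca_pop))); emp_gsd <- exp(stats::sd(log(ca_pop)))
  comp <- lapply(setNames(gms, paste0("c", 1:5)),
                 function(g) c(gm = g, gsd = 2))
  pred <- ca_lnsum(comp, setNames(f, paste0("c", 1:5)))
  expect_equal(pred$draws$gm, emp_gm, tolerance = 0.03)
  expect_equal(pred$draws$gsd, emp_gsd, tolerance = 0.03)
})

test_that("ca_default evaluates the quantile-wise sums", {
  comp <- list(a = data.frame(ec10_median = 1, ec10_p = 0.5),
               b = data.frame(ec10_median = 3, ec10_p = 1.5))
  pred <- ca_default(comp, c(a = 0.5, b = 0.5))
  expect_equal(pred$draws$ec10_median, 1.5)
  expect_equal(pred$draws$ec10_p, 0.75)
  expect_equal(pred$draws$tdvf, 2)
})

test_that("shared component GSD cancels into an exact CA_Default TDVF", {
  z <- quantile_constant(0.01)
  g <- 2.2
  comp <- list(a = truth_pod_draws(1, g), b = truth_pod_draws(5, g),
               c = truth_pod_draws(20, g))
  pred <- ca_default(comp, c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(pred$draws$tdvf, g^z, tolerance = 1e-12)
  ## GSD = 1 everywhere: median and percentile predictions coincide
  comp1 <- lapply(comp, function(d) truth_pod_draws(d$ec10_median[1], 1))
  pred1 <- ca_default(comp1, c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(pred1$draws$ec10_median, pred1$draws$ec10_p)
  expect_equal(pred1$draws$tdvf, 1)
})

test_that("a single-component mixture reproduces the component PODs", {
  post <- fake_posterior(gm = exp(stats::rnorm(500, log(8), 0.2)),
                         gsd = exp(abs(stats::rnorm(500, 0, 0.3))),
                         individual_ids = sprintf("i%02d", 1:10))
  set.seed(86)
  post$ec10 <- matrix(exp(log(8) + 0.5 * stats::rnorm(500 * 10)), 500,
                      dimnames = list(NULL, sprintf("i%02d", 1:10)))
  pod <- derive_pod_draws(post)
  one <- c(chemX = 1)

  def <- ca_default(list(chemX = pod), one, n_draws = 500)
  expect_equal(def$draws$ec10_median, pod$draws$ec10_median,
               tolerance = 1e-12)
  expect_equal(def$draws$tdvf, pod$draws$tdvf, tolerance = 1e-12)

  lns <- ca_lnsum(list(chemX = post), one, n_draws = 500)
  expect_equal(lns$draws$ec10_median, pod$draws$ec10_median,
               tolerance = 1e-12)
  expect_equal(lns$draws$tdvf, pod$draws$tdvf, tolerance = 1e-12)

  ind <- ca_indiv(list(chemX = post), one, censor_limit = 1e9, n_draws = 200)
  ## refitted from 10 individuals: statistical, not exact
  expect_equal(stats::median(ind$draws$ec10_median),
               stats::median(pod$draws$ec10_median), tolerance = 0.35)
})

test_that("limiting cases: CA_Indiv meets CA_Default at rho = 1 and
           CA_LNSum at rho = 0, with the ordering in between", {
  gms <- c(c1 = 2, c2 = 8, c3 = 20)
  gsd <- 1.8
  fr <- c(c1 = 0.4, c2 = 0.3, c3 = 0.3)
  d <- study_design(sprintf("i%05d", 1:20000), names(gms),
                    list(mixture_spec("m", fr)))
  tdvf_indiv <- function(rho) {
    tr <- sample_population_truth(d, gm_ec10 = gms, gsd_ec10 = gsd,
                                  rho = rho, seed = 87)
    pred <- ca_indiv(truth_components(tr, names(gms)), fr,
                     censor_limit = Inf)
    pred$draws$tdvf
  }
  comp_pod <- lapply(gms, truth_pod_draws, gsd = gsd)
  tdvf_def <- ca_default(comp_pod, fr)$draws$tdvf
  comp_gg <- lapply(gms, function(g) c(gm = g, gsd = gsd))
  tdvf_lns <- ca_lnsum(comp_gg, fr)$draws$tdvf

  expect_equal(tdvf_indiv(1), tdvf_def, tolerance = 0.02)
  expect_equal(tdvf_indiv(0), tdvf_lns, tolerance = 0.10)
  mid <- tdvf_indiv(0.5)
  expect_gte(tdvf_def * 1.02, mid)
  expect_gte(mid * 1.02, tdvf_lns)
})

test_that("LAI is invariant to per-chemical potency rescaling", {
  fr <- c(chemA = 0.3, chemB = 0.7)
  spec <- mixture_spec("m", fr, interaction_multiplier = 0.3)
  d <- quick_design(n_ind = 50, mixtures = list(spec))
  tr <- sample_population_truth(d, gm_ec10 = c(chemA = 1, chemB = 10),
                                gsd_ec10 = 2, rho = 0.5, seed = 88)
  lai_of <- function(truth, spec) {
    measured <- compose_mixture_truth(truth, spec)
    pred <- ca_indiv(truth_components(truth, names(spec$fractions)),
                     spec, censor_limit = Inf)
    list(indiv = measured / pred$indiv[1, names(measured)],
         median = fit_censored_lognormal(measured, Inf)[["gm"]] /
           pred$draws$ec10_median)
  }
  base <- lai_of(tr, spec)

  b <- c(chemA = 3.7, chemB = 0.2)   # per-chemical bioavailability factors
  tr2 <- tr
  tr2$ec10[, names(b)] <- sweep(tr$ec10[, names(b)], 2, b, "/")
  w <- fr / b
  spec2 <- mixture_spec("m", w / sum(w), interaction_multiplier = 0.3)
  resc <- lai_of(tr2, spec2)

  expect_equal(resc$indiv, base$indiv, tolerance = 1e-9)
  expect_equal(resc$median, base$median, tolerance = 1e-9)
})

test_that("inactive components are dropped without renormalization", {
  ids <- c("i1", "i2", "i3")
  comp <- list(a = matrix(c(1, 2, 4), 1, dimnames = list(NULL, ids)))
  pred <- ca_indiv(comp, c(a = 0.5, b = 0.5), censor_limit = 1e6,
                   inactive = "b")
  expect_equal(unname(pred$indiv[1, ]), c(1, 2, 4) / 0.5)
})

test_that("lai scores identity, scaling, and planted interaction", {
  r <- lai(rep(3, 50), rep(3, 50))
  expect_equal(r$summary$log10_lai_median, 0)
  expect_equal(r$summary$log10_lai_lo95, 0)
  expect_equal(r$summary$log10_lai_hi95, 0)
  r2 <- lai(rep(2, 50), rep(1, 50))
  expect_equal(unique(r2$lai), 2)
  expect_error(lai(c(1, -1), c(1, 1)), "positive")
  expect_error(lai(numeric(0), 1), "empty")
  ## unequal draw counts are aligned deterministically
  r3 <- lai(rep(2, 100), rep(1, 37))
  expect_equal(length(r3$lai), 37)
})

test_that("truth-level LAI recovers the planted interaction multiplier", {
  fr <- c(chemA = 0.5, chemB = 0.5)
  spec <- mixture_spec("m", fr, interaction_multiplier = 0.1)
  d <- quick_design(n_ind = 40, mixtures = list(spec))
  tr <- sample_population_truth(d, gsd_ec10 = 2, rho = 0.3, seed = 89)
  measured <- compose_mixture_truth(tr, spec)
  pred <- ca_indiv(truth_components(tr, names(fr)), fr, censor_limit = Inf)
  ratio <- measured / pred$indiv[1, names(measured)]
  expect_equal(unname(ratio), rep(0.1, 40), tolerance = 1e-9)
})
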