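test_that("zero-variance populations collapse to the geometric mean", {
  d <- quick_design(n_ind = 8)
  tr <- sample_population_truth(d, gm_ec10 = c(chemA = 5, chemB = 12),
                                gsd_ec10 = 1, seed = 1)
  expect_equal(unname(tr$ec10[, "chemA"]), rep(5, 8))
  expect_equal(unname(tr$ec10[, "chemB"]), rep(12, 8))
})

test_that("rho = 1 makes individual rank order identical across chemicals", {
  d <- quick_design(n_ind = 25)
  tr <- sample_population_truth(d, gm_ec10 = c(chemA = 1, chemB = 30),
                                gsd_ec10 = 2, rho = 1, seed = 2)
  expect_equal(order(tr$ec10[, "chemA"]), order(tr$ec10[, "chemB"]))
})

test_that("sampled populations recover GM and GSD at large n", {
  d <- quick_design(n_ind = 10000)
  tr <- sample_population_truth(d, gm_ec10 = 10, gsd_ec10 = 2, rho = 0,
                                seed = 3)
  lv <- log(tr$ec10[, "chemA"])
  expect_equal(exp(mean(lv)), 10, tolerance = 0.02)
  expect_equal(exp(stats::sd(lv)), 2, tolerance = 0.02)
  ## marginals are unaffected by the correlation structure
  tr2 <- sample_population_truth(d, gm_ec10 = 10, gsd_ec10 = 2, rho = 0.7,
                                 seed = 3)
  lv2 <- log(tr2$ec10[, "chemB"])
  expect_equal(exp(mean(lv2)), 10, tolerance = 0.02)
  expect_equal(exp(stats::sd(lv2)), 2, tolerance = 0.02)
})

test_that("generator rejects invalid hyperparameters", {
  d <- quick_design()
  expect_error(sample_population_truth(d, gm_ec10 = -1), "positive")
  expect_error(sample_population_truth(d, gsd_ec10 = 0.5), ">= 1")
  expect_error(sample_population_truth(d, rho = 1.2), "rho")
})

test_that("mixture truth composition follows the scaled harmonic sum", {
  d <- quick_design(n_ind = 5)
  tr <- sample_population_truth(d, gm_ec10 = c(chemA = 1, chemB = 3),
                                gsd_ec10 = 1, seed = 1)
  one <- mixture_spec("m", c(chemA = 1))
  expect_equal(unname(compose_mixture_truth(tr, one)), rep(1, 5))
  half <- mixture_spec("m", c(chemA = 0.5, chemB = 0.5))
  expect_equal(unname(compose_mixture_truth(tr, half)), rep(1.5, 5))
  syn <- mixture_spec("m", c(chemA = 0.5, chemB = 0.5),
                      interaction_multiplier = 0.1)
  expect_equal(unname(compose_mixture_truth(tr, syn)), rep(0.15, 5))
  bad <- mixture_spec("m", c(chemZ = 1))
  expect_error(compose_mixture_truth(tr, bad), "chemZ")
})

test_that("additive truth satisfies the CA identity at machine precision", {
  fr <- c(chemA = 0.3, chemB = 0.7)
  d <- quick_design(n_ind = 12, mixtures = list(mixture_spec("m", fr)))
  for (rho in c(0, 0.5, 1)) {
    tr <- sample_population_truth(d, gsd_ec10 = 2.5, rho = rho, seed = 9)
    lhs <- 1 / tr$ec10[, "m"]
    rhs <- fr["chemA"] / tr$ec10[, "chemA"] + fr["chemB"] / tr$ec10[, "chemB"]
    expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  }
})

test_that("noise-free responses are exact and invertible at any concentration", {
  d <- quick_design(n_ind = 4, conc = c(0.01, 0.1, 1, 10, 100))
  tr <- sample_population_truth(d, gm_ec10 = 1, gsd_ec10 = 1, sigma = 0,
                                y0 = 1, seed = 5)
  ds <- simulate_responses(tr, d, seed = 6)
  ## conc = EC10 = 1 gives exactly 90% of baseline
  expect_equal(ds$viability[ds$substance_id == "chemA" & ds$conc_uM == 1],
               rep(0.9, 4))
  ## every record inverts back to its concentration through the true curve
  sub <- ds[ds$substance_id == "chemA", ]
  i <- match(sub$individual_id, rownames(tr$ec10))
  n <- 1 + tr$ntilde[cbind(i, match("chemA", colnames(tr$ntilde)))]
  x0 <- ec10_to_x0(tr$ec10[cbind(i, match("chemA", colnames(tr$ec10)))], n)
  expect_equal(hill_inverse(sub$viability, 1, x0, n), sub$conc_uM,
               tolerance = 1e-9)
})

test_that("response simulation is reproducible from its seed", {
  d <- quick_design(n_ind = 4)
  tr <- sample_population_truth(d, seed = 1)
  a <- simulate_responses(tr, d, seed = 10)
  b <- simulate_responses(tr, d, seed = 10)
  c <- simulate_responses(tr, d, seed = 11)
  expect_identical(a$viability, b$viability)
  expect_false(identical(a$viability, c$viability))
})

test_that("dataset CSV round-trips and enforces its invariants", {
  d <- quick_design(n_ind = 4)
  tr <- sample_population_truth(d, seed = 1)
  ds <- simulate_responses(tr, d, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  expect_identical(readLines(f, n = 1),
                   "individual_id,substance_id,conc_uM,viability")
  back <- read_dataset(f)
  expect_equal(back$viability, ds$viability, tolerance = 1e-14)
  expect_equal(back$conc_uM, ds$conc_uM)

  ## empty dataset: header-only file, reads back empty
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(as_response_dataset(ds[0, ]), f2)
  expect_equal(nrow(read_dataset(f2)), 0L)

  ## corrupt file: negative concentration flagged with its row
  lines <- readLines(f)
  lines[3] <- sub("^([^,]*,[^,]*,)[^,]*", "\\1-5", lines[3])
  writeLines(lines, f)
  expect_error(read_dataset(f), "row\\(s\\) 2")
})

test_that("coverage invariant: fewer than 4 concentrations is rejected", {
  d <- quick_design(n_ind = 4)
  tr <- sample_population_truth(d, seed = 1)
  ds <- simulate_responses(tr, d, seed = 2)
  thin <- ds[ds$conc_uM > 0.5, ]   # leaves only 3 distinct concentrations
  expect_error(as_response_dataset(thin), "4 distinct")
})

test_that("mixture CSV and truth JSON round-trip", {
  specs <- list(mixture_spec("m1", c(a = 0.25, b = 0.75)),
                mixture_spec("m2", c(b = 0.6, c = 0.4)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_mixtures(specs, f)
  back <- read_mixtures(f)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(back$m1$fractions, specs[[1]]$fractions)

  d <- quick_design(n_ind = 3)
  tr <- sample_population_truth(d, gsd_ec10 = 1.7, rho = 0.4, seed = 8)
  fj <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, fj)
  tr2 <- read_truth(fj)
  expect_equal(tr2$ec10, tr$ec10, tolerance = 1e-12)
  expect_equal(tr2$rho, tr$rho)
  expect_equal(tr2$gm_ec10, tr$gm_ec10)
})

test_that("design and mixture constructors enforce their invariants", {
  expect_error(mixture_spec("m", c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(mixture_spec("m", c(a = -0.5, b = 1.5)), "> 0")
  expect_error(mixture_spec("m", c(a = 0.5, b = 0.5), -1),
               "interaction_multiplier")
  expect_error(quick_design(n_ind = 1), "2 unique individual")
  expect_error(study_design("i1", "c1", list()), "2 unique individual")
  expect_error(quick_design(conc = c(1, 1, 2, 3, 4)), "increasing")
  d <- quick_design(conc = c(0.1, 1, 10, 50))
  expect_equal(d$c_max_uM, 50)
})
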