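## Balanced two-factor table with exactly scaled planted effects.
planted_lai_table <- function(n_mix = 8, n_ind = 100,
                              v_mix = 0.6, v_ind = 0.2, v_noise = 0.2,
                              seed = 91) {
  set.seed(seed)
  scale_to <- function(x, v) {
    x <- x - mean(x)
    if (v == 0) return(x * 0)
    x * sqrt(v / mean(x^2))
  }
  a <- scale_to(stats::rnorm(n_mix), v_mix)
  b <- scale_to(stats::rnorm(n_ind), v_ind)
  e <- scale_to(stats::rnorm(n_mix * n_ind), v_noise)
  g <- expand.grid(mixture_id = sprintf("m%02d", seq_len(n_mix)),
                   individual_id = sprintf("i%03d", seq_len(n_ind)),
                   stringsAsFactors = FALSE)
  g$log10_lai <- a[match(g$mixture_id, unique(g$mixture_id))] +
    b[match(g$individual_id, unique(g$individual_id))] + e
  g
}

test_that("one-factor structure yields a pure mixture effect", {
  tab <- planted_lai_table(v_mix = 1, v_ind = 0, v_noise = 0, n_mix = 4,
                           n_ind = 10)
  dec <- anova_eta2(tab)
  expect_equal(dec$eta2_mixture, 1, tolerance = 1e-9)
  expect_equal(dec$eta2_individual, 0, tolerance = 1e-9)
  expect_equal(dec$r_squared, 1, tolerance = 1e-9)
})

test_that("planted variance fractions are recovered", {
  dec <- anova_eta2(planted_lai_table())
  expect_lt(abs(dec$eta2_mixture - 0.6), 0.05)
  expect_lt(abs(dec$eta2_individual - 0.2), 0.05)
  expect_lt(abs(dec$r_squared - 0.8), 0.05)
  expect_equal(dec$n_cells, 800)
})

test_that("sums of squares are conserved on balanced layouts", {
  for (seed in 92:94) {
    dec <- anova_eta2(planted_lai_table(n_mix = 5, n_ind = 20, seed = seed))
    ss <- dec$ss
    expect_equal(ss[["mixture"]] + ss[["individual"]] + ss[["residual"]],
                 ss[["total"]], tolerance = 1e-8)
    expect_equal(dec$eta2_mixture + dec$eta2_individual, dec$r_squared,
                 tolerance = 1e-8)
  }
})

test_that("degenerate ANOVA inputs are rejected", {
  tab <- planted_lai_table(n_mix = 3, n_ind = 5)
  tab$log10_lai <- 0.7
  expect_error(anova_eta2(tab), "no variation")
  one <- planted_lai_table(n_mix = 3, n_ind = 5)
  expect_error(anova_eta2(one[one$mixture_id == "m01", ]), "2 levels")
  unb <- planted_lai_table(n_mix = 3, n_ind = 6)[-1, ]
  expect_warning(anova_eta2(unb), "unbalanced")
})

test_that("within_fold_fraction counts fold boundaries symmetrically", {
  expect_equal(within_fold_fraction(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(within_fold_fraction(c(1, 1, 1), c(1, 20, 5)), 2 / 3)
  ## boundary pair counts as within
  expect_equal(within_fold_fraction(1, 10), 1)
  expect_equal(within_fold_fraction(1, 10.0001), 0)
  set.seed(95)
  m <- exp(stats::rnorm(100)); p <- exp(stats::rnorm(100, 0, 2))
  expect_equal(within_fold_fraction(m, p), within_fold_fraction(p, m))
  expect_error(within_fold_fraction(numeric(0), numeric(0)), "empty")
})

test_that("clustering merges identical rows first and finds planted blocks", {
  set.seed(96)
  base <- matrix(stats::rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("m", 1:5), paste0("i", 1:10)))
  base["m2", ] <- base["m1", ]
  cl <- cluster_lai(base)
  first <- cl$row_hclust$merge[1, ]
  expect_setequal(rownames(base)[-first], c("m1", "m2"))
  expect_equal(cl$row_hclust$height[1], 0)

  ## two planted mixture blocks separate at the top split
  block <- rbind(matrix(stats::rnorm(3 * 12, mean = 0), 3, 12),
                 matrix(stats::rnorm(3 * 12, mean = 6), 3, 12))
  rownames(block) <- paste0("m", 1:6)
  colnames(block) <- paste0("i", 1:12)
  cl2 <- cluster_lai(block)
  top <- stats::cutree(cl2$row_hclust, k = 2)
  expect_equal(length(unique(top[1:3])), 1L)
  expect_equal(length(unique(top[4:6])), 1L)
  expect_false(top[1] == top[4])
})

test_that("clustering is invariant to row permutation and constant shifts", {
  set.seed(97)
  m <- matrix(stats::rnorm(6 * 8), 6, 8,
              dimnames = list(paste0("m", 1:6), paste0("i", 1:8)))
  cl <- cluster_lai(m)
  perm <- sample(nrow(m))
  cl_p <- cluster_lai(m[perm, ])
  d1 <- as.matrix(stats::cophenetic(cl$row_hclust))
  d2 <- as.matrix(stats::cophenetic(cl_p$row_hclust))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)
  cl_s <- cluster_lai(m + 5)
  d3 <- as.matrix(stats::cophenetic(cl_s$row_hclust))
  expect_equal(d3, d1, tolerance = 1e-12)
  ## missing values: error unless imputation requested
  m[2, 3] <- NA
  expect_error(cluster_lai(m), "missing")
  expect_true(cluster_lai(m, impute = TRUE)$imputed)
})

test_that("summarize_lai reports log10 medians with equal mixture weight", {
  row <- summarize_lai(rep(0.5, 100))
  expect_equal(row$log10_lai_median, log10(0.5))
  expect_equal(row$formatted, "10^-0.30 [-0.30, -0.30]")

  set.seed(98)
  draws <- 10^stats::rnorm(1e5, -0.26, 0.36)
  row2 <- summarize_lai(draws)
  expect_equal(row2$log10_lai_median, -0.26, tolerance = 0.01)

  ## equal weight per mixture despite unequal draw counts
  row3 <- summarize_lai(list(m1 = rep(10, 1000), m2 = rep(0.1, 50)))
  expect_equal(row3$log10_lai_median, 0, tolerance = 1e-9)
  expect_equal(row3$n_mixtures, 2)
  expect_error(summarize_lai(list(m1 = numeric(0))), "no draws")
})
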