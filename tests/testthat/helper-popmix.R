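## Shared fixtures and independent oracles for the test suite.

## Small two-chemical design with one equal-fraction mixture.
quick_design <- function(n_ind = 10, chems = c("chemA", "chemB"),
                         mixtures = NULL, conc = 10^(-2:2), reps = 1) {
  if (is.null(mixtures)) {
    fr <- setNames(rep(1 / length(chems), length(chems)), chems)
    mixtures <- list(mixture_spec("mix1", fr))
  }
  study_design(sprintf("i%03d", seq_len(n_ind)), chems, mixtures,
               concentrations_uM = conc, replicates_per_conc = reps)
}

## Fast Bayesian fit settings for unit tests (no doubling).
quick_fit_config <- function(iter = 1000, seed = 1, ...) {
  fit_config(initial_iterations = iter, max_iterations = iter,
             seed = seed, ...)
}

## Synthetic posterior with known GM/GSD draws, bypassing MCMC, for
## operations that only consume posterior draws.
fake_posterior <- function(gm, gsd, substance_id = "chemX", c_max = 100,
                           individual_ids = c("i1", "i2", "i3"),
                           ec10 = NULL, converged = TRUE) {
  n <- max(length(gm), length(gsd))
  gm <- rep_len(gm, n); gsd <- rep_len(gsd, n)
  if (is.null(ec10))
    ec10 <- matrix(rep(gm, length(individual_ids)), n,
                   dimnames = list(NULL, individual_ids))
  structure(
    list(substance_id = substance_id,
         individual_ids = colnames(ec10),
         draws = data.frame(chain = 1L, lnGM_EC10 = log(gm),
                            lnGSD_EC10 = log(gsd),
                            lnGM_ntilde = log(0.5), lnGSD_ntilde = log(1.5),
                            y0 = 1, sigma = 0.05),
         ec10 = ec10,
         ntilde = matrix(0.5, n, ncol(ec10),
                         dimnames = dimnames(ec10)),
         rhat = c(lnGM_EC10 = 1, lnGSD_EC10 = 1, lnGM_ntilde = 1,
                  lnGSD_ntilde = 1, y0 = 1, sigma = 1),
         iterations_used = 1000L, converged = converged, c_max = c_max,
         n_chains = 2L, seed = 1L),
    class = "hill_posterior")
}

## Independent textbook implementation of the split-chain potential scale
## reduction factor, written with explicit loops (oracle for rhat()).
oracle_split_rhat <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  h <- floor(n / 2)
  seqs <- list()
  for (j in seq_len(m)) {
    seqs[[length(seqs) + 1]] <- mat[1:h, j]
    seqs[[length(seqs) + 1]] <- mat[(n - h + 1):n, j]
  }
  M <- length(seqs)
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- h / (M - 1) * sum((means - mean(means))^2)
  sqrt(((h - 1) / h * W + B / h) / W)
}

## Truth-level component list for the CA functions (single "draw" each).
truth_components <- function(truth, chems = truth$chemical_ids) {
  lapply(setNames(chems, chems), function(k)
    matrix(truth$ec10[, k], nrow = 1,
           dimnames = list(NULL, rownames(truth$ec10))))
}

## Truth-level POD draws (one draw) from known GM/GSD.
truth_pod_draws <- function(gm, gsd, p = 0.01) {
  z <- abs(stats::qnorm(p))
  data.frame(ec10_median = gm, ec10_p = gm * gsd^(-z), tdvf = gsd^z,
             gm = gm, gsd = gsd)
}
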