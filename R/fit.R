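#' Configuration for the hierarchical Bayesian Hill fit
#'
#' Bundles sampler settings and prior scales for [fit_hill_population()].
#' Priors are weakly informative on the tested-concentration scale: the
#' population log-geometric-mean EC10 gets a normal prior centred (by
#' default) at the log of the top tested concentration with SD 4 (spanning
#' many orders of magnitude), the log-GSDs get half-normal priors with scale
#' `log(10)/2` (allowing population GSDs well above 10), the residual scale a
#' half-normal with SD 0.3 on the normalized-viability scale, and the shared
#' baseline a positive-truncated normal around 1.
#'
#' The convergence protocol: chains of `initial_iterations` are run (first
#' half discarded as warm-up); if any monitored parameter has split-chain
#' Rhat above `rhat_threshold`, chain length is doubled and the model rerun,
#' capping at `max_iterations`. Monitored (gate) parameters are the
#' population hyperparameters, baseline and residual scale; per-individual
#' parameters are excluded from the gate.
#'
#' @param n_chains Number of MCMC chains (default 4).
#' @param initial_iterations Total iterations per chain in the first attempt
#'   (default 4000, half used as warm-up).
#' @param max_iterations Cap on iterations per chain for the doubling
#'   protocol (default 16000).
#' @param rhat_threshold Convergence threshold for the potential scale
#'   reduction factor (default 1.2).
#' @param t_dof Degrees of freedom of the Student-t residual distribution
#'   (default 5).
#' @param parameterization `"noncentered"` (default; random effects expressed
#'   as scaled standard-normal deviates, avoiding funnel pathologies at small
#'   GSD) or `"centered"`.
#' @param prior_lnGM_EC10 `c(mean, sd)` of the normal prior on ln GM(EC10);
#'   `mean = NA` (default) resolves to `log(c_max)` at fit time.
#' @param prior_lnGSD_EC10,prior_lnGSD_ntilde `c(sd)` of half-normal priors
#'   on the log-GSDs.
#' @param prior_lnGM_ntilde `c(mean, sd)` of the normal prior on ln GM of the
#'   Hill offset.
#' @param prior_sigma `c(sd)` of the half-normal prior on the residual scale.
#' @param prior_y0 `c(mean, sd)` of the positive-truncated normal prior on
#'   the baseline.
#' @param monitor_gate Parameters entering the convergence gate.
#' @param seed Integer seed controlling chain initialisation.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_chains = 4L,
                       initial_iterations = 4000L,
                       max_iterations = 16000L,
                       rhat_threshold = 1.2,
                       t_dof = 5,
                       parameterization = c("noncentered", "centered"),
                       prior_lnGM_EC10 = c(mean = NA, sd = 4),
                       prior_lnGSD_EC10 = c(sd = log(10) / 2),
                       prior_lnGM_ntilde = c(mean = log(0.5), sd = 1),
                       prior_lnGSD_ntilde = c(sd = log(10) / 2),
                       prior_sigma = c(sd = 0.3),
                       prior_y0 = c(mean = 1, sd = 0.2),
                       monitor_gate = c("lnGM_EC10", "lnGSD_EC10",
                                        "lnGM_ntilde", "lnGSD_ntilde",
                                        "y0", "sigma"),
                       seed = 1L) {
  parameterization <- match.arg(parameterization)
  n_chains <- as.integer(n_chains)
  initial_iterations <- as.integer(initial_iterations)
  max_iterations <- as.integer(max_iterations)
  if (n_chains < 2L) stop("need at least 2 chains", call. = FALSE)
  if (initial_iterations < 4L) stop("'initial_iterations' too small", call. = FALSE)
  if (max_iterations < initial_iterations)
    stop("'max_iterations' must be >= 'initial_iterations'", call. = FALSE)
  stop_if_not_scalar_number(rhat_threshold, "rhat_threshold", positive = TRUE)
  stop_if_not_scalar_number(t_dof, "t_dof", positive = TRUE)
  structure(
    list(n_chains = n_chains,
         initial_iterations = initial_iterations,
         max_iterations = max_iterations,
         rhat_threshold = rhat_threshold,
         t_dof = t_dof,
         parameterization = parameterization,
         prior_lnGM_EC10 = prior_lnGM_EC10,
         prior_lnGSD_EC10 = prior_lnGSD_EC10,
         prior_lnGM_ntilde = prior_lnGM_ntilde,
         prior_lnGSD_ntilde = prior_lnGSD_ntilde,
         prior_sigma = prior_sigma,
         prior_y0 = prior_y0,
         monitor_gate = monitor_gate,
         seed = as.integer(seed)),
    class = "fit_config")
}

## JAGS model source for the hierarchical downward Hill model.
hill_model_string <- function(config, lnGM_mean) {
  re <- if (config$parameterization == "noncentered") "
    z_e[i] ~ dnorm(0, 1)
    z_n[i] ~ dnorm(0, 1)
    lnEC10[i] <- lnGM_EC10 + lnGSD_EC10 * z_e[i]
    ln_ntilde[i] <- lnGM_ntilde + lnGSD_ntilde * z_n[i]" else "
    lnEC10[i] ~ dnorm(lnGM_EC10, pow(lnGSD_EC10 + 1.0E-9, -2))
    ln_ntilde[i] ~ dnorm(lnGM_ntilde, pow(lnGSD_ntilde + 1.0E-9, -2))"
  sprintf("
model {
  for (j in 1:N) {
    ratio[j] <- pow(conc[j] / x0[ind[j]], hilln[ind[j]])
    mu[j] <- y0 / (1 + ratio[j])
    y[j] ~ dt(mu[j], tau, nu)
  }
  for (i in 1:I) {%s
    EC10[i] <- exp(lnEC10[i])
    ntilde[i] <- exp(ln_ntilde[i])
    hilln[i] <- 1 + ntilde[i]
    x0[i] <- EC10[i] * pow(9, 1 / hilln[i])
  }
  lnGM_EC10 ~ dnorm(%.10g, %.10g)
  lnGSD_EC10 ~ dnorm(0, %.10g) T(0,)
  lnGM_ntilde ~ dnorm(%.10g, %.10g)
  lnGSD_ntilde ~ dnorm(0, %.10g) T(0,)
  sigma ~ dnorm(0, %.10g) T(0,)
  tau <- pow(sigma, -2)
  y0 ~ dnorm(%.10g, %.10g) T(0,)
}",
    re,
    lnGM_mean, config$prior_lnGM_EC10[["sd"]]^-2,
    config$prior_lnGSD_EC10[["sd"]]^-2,
    config$prior_lnGM_ntilde[["mean"]], config$prior_lnGM_ntilde[["sd"]]^-2,
    config$prior_lnGSD_ntilde[["sd"]]^-2,
    config$prior_sigma[["sd"]]^-2,
    config$prior_y0[["mean"]], config$prior_y0[["sd"]]^-2)
}

#' Fit the hierarchical Bayesian Hill model for one substance
#'
#' Fits the random-effects downward Hill model to all individuals'
#' concentration-response data for a single substance. Individual
#' `ln(EC10)` and `ln(ntilde)` (Hill coefficient `n = 1 + ntilde >= 1`) are
#' normal random effects with uncertain population geometric mean (GM) and
#' geometric standard deviation (GSD); the sampler draws EC10 and `ntilde`
#' directly and derives the Hill midpoint `x0` via [ec10_to_x0()]. Residuals
#' are scaled Student-t with `t_dof` degrees of freedom. One baseline `y0` is
#' shared across individuals of a substance.
#'
#' Sampling runs in JAGS. Convergence is assessed with the split-chain
#' potential scale reduction factor ([rhat()]) on the gate parameters; while
#' any exceeds the threshold, chain length is doubled (up to the cap), the
#' model is rerun from scratch, and the final `converged` flag records
#' whether the gate was met. The first half of every chain is discarded as
#' warm-up; post-warm-up draws are pooled across chains.
#'
#' @param dataset A `response_dataset` (may contain several substances).
#' @param substance_id Substance to fit; may be omitted when the dataset
#'   contains exactly one.
#' @param config A [fit_config()].
#' @param c_max Top tested concentration (µM) for this substance; defaults to
#'   the maximum concentration present in the data. Used for the default
#'   prior location and stored for downstream activity classification.
#' @return An object of class `hill_posterior` with elements:
#'   `draws` (data.frame of pooled post-warm-up draws of `lnGM_EC10`,
#'   `lnGSD_EC10`, `lnGM_ntilde`, `lnGSD_ntilde`, `y0`, `sigma` with chain
#'   index), `ec10` and `ntilde` (draw x individual matrices), `rhat`
#'   (gate diagnostics), `iterations_used`, `converged`, `c_max`.
#' @export
fit_hill_population <- function(dataset, substance_id = NULL,
                                config = fit_config(), c_max = NULL) {
  stopifnot(inherits(dataset, "response_dataset") || is.data.frame(dataset))
  if (is.null(substance_id)) {
    substance_id <- unique(dataset$substance_id)
    if (length(substance_id) != 1L)
      stop("dataset has multiple substances; give 'substance_id'", call. = FALSE)
  }
  sub <- dataset[dataset$substance_id == substance_id, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records for substance '", substance_id, "'", call. = FALSE)
  if (any(!is.finite(sub$viability)))
    stop("non-finite viability values for '", substance_id, "'", call. = FALSE)
  individuals <- sort(unique(sub$individual_id))
  if (length(individuals) < 2L)
    stop("need at least 2 individuals to fit the population model", call. = FALSE)
  nconc <- tapply(sub$conc_uM, sub$individual_id,
                  function(x) length(unique(x)))
  if (any(nconc < 4))
    stop("each individual needs >= 4 distinct concentrations; offending: ",
         paste(head(names(nconc)[nconc < 4], 5), collapse = ", "),
         call. = FALSE)
  if (is.null(c_max)) c_max <- max(sub$conc_uM)

  lnGM_mean <- config$prior_lnGM_EC10[["mean"]]
  if (is.na(lnGM_mean)) lnGM_mean <- log(c_max)
  model_src <- hill_model_string(config, lnGM_mean)
  data_list <- list(N = nrow(sub), I = length(individuals),
                    conc = sub$conc_uM,
                    ind = match(sub$individual_id, individuals),
                    y = sub$viability, nu = config$t_dof)

  total_iter <- config$initial_iterations
  repeat {
    run <- run_hill_jags(model_src, data_list, config, total_iter)
    gate <- run$rhat[config$monitor_gate]
    converged <- all(is.finite(gate)) && all(gate <= config$rhat_threshold)
    if (converged || total_iter >= config$max_iterations) break
    total_iter <- min(2L * total_iter, config$max_iterations)
  }
  if (!converged)
    warning("'", substance_id, "': Rhat above ", config$rhat_threshold,
            " after ", total_iter, " iterations/chain", call. = FALSE)

  mat <- run$draws
  scl <- c("lnGM_EC10", "lnGSD_EC10", "lnGM_ntilde", "lnGSD_ntilde",
           "y0", "sigma")
  ec10_cols <- paste0("EC10[", seq_along(individuals), "]")
  nt_cols <- paste0("ntilde[", seq_along(individuals), "]")
  ec10 <- mat[, ec10_cols, drop = FALSE]
  ntilde <- mat[, nt_cols, drop = FALSE]
  colnames(ec10) <- colnames(ntilde) <- individuals

  structure(
    list(substance_id = substance_id,
         individual_ids = individuals,
         draws = data.frame(chain = run$chain, mat[, scl, drop = FALSE]),
         ec10 = ec10,
         ntilde = ntilde,
         rhat = run$rhat[config$monitor_gate],
         iterations_used = total_iter,
         converged = converged,
         c_max = c_max,
         n_chains = config$n_chains,
         seed = config$seed),
    class = "hill_posterior")
}

## One JAGS run at a fixed chain length; returns pooled draws + diagnostics.
run_hill_jags <- function(model_src, data_list, config, total_iter) {
  warmup <- total_iter %/% 2L
  n_adapt <- min(1000L, warmup)
  n_burn <- warmup - n_adapt
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (config$seed %% 1000003L) * 100L + ch)
  })
  con <- textConnection(model_src)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data_list,
                          inits = inits, n.chains = config$n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  monitor <- c("lnGM_EC10", "lnGSD_EC10", "lnGM_ntilde", "lnGSD_ntilde",
               "y0", "sigma", "EC10", "ntilde")
  sm <- rjags::coda.samples(jm, monitor, n.iter = total_iter - warmup,
                            progress.bar = "none")
  vars <- colnames(sm[[1]])
  rh <- vapply(vars, function(v)
    rhat(sapply(sm, function(ch) as.numeric(ch[, v]))), numeric(1))
  pooled <- do.call(rbind, lapply(sm, as.matrix))
  chain <- rep(seq_along(sm), each = nrow(sm[[1]]))
  list(draws = pooled, chain = chain, rhat = rh)
}

#' @export
print.hill_posterior <- function(x, ...) {
  gm <- stats::median(gm_draws(x)); gsd <- stats::median(gsd_draws(x))
  cat("<hill_posterior> ", x$substance_id, ": ", nrow(x$draws), " draws (",
      x$n_chains, " chains, ", x$iterations_used, " iter/chain), ",
      length(x$individual_ids), " individuals\n",
      "  GM EC10 ", signif(gm, 4), " uM, GSD ", signif(gsd, 4),
      ", converged: ", x$converged,
      " (max Rhat ", signif(max(x$rhat), 4), ")\n", sep = "")
  invisible(x)
}

#' Extract posterior draws from a Hill population fit
#'
#' `gm_draws()`/`gsd_draws()` return the population geometric mean (µM) and
#' geometric standard deviation of EC10; `ec10_draws()` the draw x individual
#' matrix of per-individual EC10s.
#'
#' @param posterior A `hill_posterior`.
#' @return Numeric vector (or matrix for `ec10_draws()`), one entry per
#'   pooled post-warm-up draw.
#' @export
gm_draws <- function(posterior) {
  stopifnot(inherits(posterior, "hill_posterior"))
  exp(posterior$draws$lnGM_EC10)
}

#' @rdname gm_draws
#' @export
gsd_draws <- function(posterior) {
  stopifnot(inherits(posterior, "hill_posterior"))
  exp(posterior$draws$lnGSD_EC10)
}

#' @rdname gm_draws
#' @export
ec10_draws <- function(posterior) {
  stopifnot(inherits(posterior, "hill_posterior"))
  posterior$ec10
}

#' Persist / restore a posterior as CSV plus JSON diagnostics
#'
#' Writes the pooled draws (scalar parameters and per-individual EC10 and
#' `ntilde` columns, keyed by chain and draw index) to
#' `<prefix>.csv` and the diagnostics (Rhat per gate parameter, iterations,
#' convergence flag, `c_max`) to `<prefix>_diag.json`.
#'
#' @param posterior A `hill_posterior`.
#' @param prefix Path prefix (no extension).
#' @return `read_posterior()` restores the `hill_posterior`;
#'   `write_posterior()` returns `prefix` invisibly.
#' @export
write_posterior <- function(posterior, prefix) {
  stopifnot(inherits(posterior, "hill_posterior"))
  df <- cbind(substance_id = posterior$substance_id,
              draw = seq_len(nrow(posterior$draws)),
              posterior$draws,
              setNames(as.data.frame(posterior$ec10),
                       paste0("ec10.", colnames(posterior$ec10))),
              setNames(as.data.frame(posterior$ntilde),
                       paste0("ntilde.", colnames(posterior$ntilde))))
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE, quote = FALSE)
  diag <- list(substance_id = posterior$substance_id,
               individual_ids = posterior$individual_ids,
               rhat = as.list(posterior$rhat),
               iterations_used = posterior$iterations_used,
               converged = posterior$converged,
               c_max = posterior$c_max,
               n_chains = posterior$n_chains,
               seed = posterior$seed)
  jsonlite::write_json(diag, paste0(prefix, "_diag.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  diag <- jsonlite::read_json(paste0(prefix, "_diag.json"),
                              simplifyVector = TRUE)
  ids <- diag$individual_ids
  ec10 <- as.matrix(df[, paste0("ec10.", ids), drop = FALSE])
  ntilde <- as.matrix(df[, paste0("ntilde.", ids), drop = FALSE])
  colnames(ec10) <- colnames(ntilde) <- ids
  scl <- c("lnGM_EC10", "lnGSD_EC10", "lnGM_ntilde", "lnGSD_ntilde",
           "y0", "sigma")
  structure(
    list(substance_id = diag$substance_id,
         individual_ids = ids,
         draws = df[, c("chain", scl)],
         ec10 = ec10, ntilde = ntilde,
         rhat = unlist(diag$rhat),
         iterations_used = diag$iterations_used,
         converged = diag$converged,
         c_max = diag$c_max,
         n_chains = diag$n_chains,
         seed = diag$seed),
    class = "hill_posterior")
}
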