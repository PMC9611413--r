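#' Sample ground-truth population parameters
#'
#' Draws a synthetic population with the statistical structure assumed by the
#' hierarchical concentration-response model: per-chemical lognormal
#' population distributions of individual EC10s (geometric mean `gm_ec10`,
#' geometric standard deviation `gsd_ec10`) and of the Hill-coefficient
#' offset `ntilde` (the Hill coefficient is `n = 1 + ntilde`, so curves are
#' never shallower than `n = 1`).
#'
#' Cross-chemical correlation of individual sensitivity is exchangeable with
#' a single parameter `rho`: the standard-normal deviate of individual `i`
#' for chemical `k` is \eqn{z_{k,i} = \sqrt\rho\, u_i + \sqrt{1-\rho}\,
#' e_{k,i}} with independent `u`, `e`. `rho = 1` makes every individual's
#' sensitivity rank identical across chemicals (the assumption implicit in
#' quantile-wise concentration addition), `rho = 0` makes sensitivities
#' independent (the lognormal-sum assumption), and intermediate values
#' interpolate.
#'
#' For every mixture in the design the true per-individual mixture EC10 is
#' composed from the component EC10s via [compose_mixture_truth()], i.e.
#' concentration addition times the mixture's interaction multiplier; mixture
#' Hill offsets are drawn from the same `ntilde` population.
#'
#' @param design A [study_design()].
#' @param gm_ec10 Per-chemical geometric mean EC10 (µM); scalar or named
#'   vector over `design$chemical_ids`. Default: a log-spaced series between
#'   0.3 and 30 µM, inside the tested concentration range.
#' @param gsd_ec10 Per-chemical geometric standard deviation of EC10
#'   (`>= 1`); scalar or named vector.
#' @param gm_ntilde,gsd_ntilde Population geometric mean / GSD of the Hill
#'   offset `ntilde` (defaults 0.5 and 1.5).
#' @param rho Exchangeable cross-chemical sensitivity correlation in `[0, 1]`.
#' @param y0 True baseline viability (dimensionless, default 1).
#' @param sigma True residual scale on the normalized-viability scale
#'   (default 0.08).
#' @param seed Integer seed; the draw is fully reproducible from
#'   `(seed, design)`.
#' @return An object of class `population_truth` with matrices `ec10` and
#'   `ntilde` (individuals x substances, mixtures included as columns) and
#'   the hyperparameters used.
#' @export
sample_population_truth <- function(design,
                                    gm_ec10 = NULL,
                                    gsd_ec10 = 2,
                                    gm_ntilde = 0.5,
                                    gsd_ntilde = 1.5,
                                    rho = 0,
                                    y0 = 1,
                                    sigma = 0.08,
                                    seed = 1) {
  stopifnot(inherits(design, "study_design"))
  chems <- design$chemical_ids
  inds <- design$individual_ids
  K <- length(chems); I <- length(inds)
  if (is.null(gm_ec10))
    gm_ec10 <- 10^seq(log10(0.3), log10(30), length.out = K)
  gm_ec10 <- expand_named(gm_ec10, chems, "gm_ec10")
  gsd_ec10 <- expand_named(gsd_ec10, chems, "gsd_ec10")
  if (any(gm_ec10 <= 0)) stop("'gm_ec10' must be positive", call. = FALSE)
  if (any(gsd_ec10 < 1)) stop("'gsd_ec10' must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(gm_ntilde, "gm_ntilde", positive = TRUE)
  stop_if_not_scalar_number(gsd_ntilde, "gsd_ntilde")
  if (gsd_ntilde < 1) stop("'gsd_ntilde' must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(rho, "rho")
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]", call. = FALSE)
  stop_if_not_scalar_number(y0, "y0", positive = TRUE)
  stop_if_not_scalar_number(sigma, "sigma")
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)

  with_preserved_seed(seed, {
    u <- rnorm(I)                                  # shared sensitivity deviate
    e <- matrix(rnorm(I * K), I, K)
    z <- sqrt(rho) * u + sqrt(1 - rho) * e
    ln_ec10 <- sweep(sweep(z, 2, log(gsd_ec10), "*"), 2, log(gm_ec10), "+")
    ec10_chem <- exp(ln_ec10)
    ntilde_chem <- exp(log(gm_ntilde) +
                       log(gsd_ntilde) * matrix(rnorm(I * K), I, K))
    dimnames(ec10_chem) <- dimnames(ntilde_chem) <- list(inds, chems)

    truth <- structure(
      list(individual_ids = inds,
           chemical_ids = chems,
           mixture_ids = names(design$mixtures),
           gm_ec10 = gm_ec10, gsd_ec10 = gsd_ec10,
           gm_ntilde = gm_ntilde, gsd_ntilde = gsd_ntilde,
           rho = rho, y0 = y0, sigma = sigma, seed = seed,
           lambda = vapply(design$mixtures,
                           function(m) m$interaction_multiplier, numeric(1)),
           ec10 = ec10_chem,
           ntilde = ntilde_chem),
      class = "population_truth")

    M <- length(design$mixtures)
    if (M > 0) {
      ec10_mix <- vapply(design$mixtures,
                         function(m) compose_mixture_truth(truth, m),
                         numeric(I))
      ntilde_mix <- exp(log(gm_ntilde) +
                        log(gsd_ntilde) * matrix(rnorm(I * M), I, M))
      dimnames(ec10_mix) <- dimnames(ntilde_mix) <-
        list(inds, names(design$mixtures))
      truth$ec10 <- cbind(ec10_chem, ec10_mix)
      truth$ntilde <- cbind(ntilde_chem, ntilde_mix)
    }
    truth
  })
}

expand_named <- function(x, ids, name) {
  if (length(x) == 1L) x <- rep(x, length(ids))
  if (length(x) != length(ids))
    stop("'", name, "' must be scalar or one value per chemical", call. = FALSE)
  if (is.null(names(x))) names(x) <- ids
  if (!setequal(names(x), ids))
    stop("'", name, "' names must match the design's chemical ids", call. = FALSE)
  x[ids]
}

#' @export
print.population_truth <- function(x, ...) {
  cat("<population_truth> ", length(x$individual_ids), " individuals, ",
      length(x$chemical_ids), " chemicals, ", length(x$mixture_ids),
      " mixtures (rho = ", x$rho, ", sigma = ", x$sigma, ")\n", sep = "")
  invisible(x)
}

#' True per-individual mixture EC10 under concentration addition
#'
#' Composes the ground-truth mixture EC10 for each individual from the
#' component truth:
#' \deqn{EC_{10,m,i} = \lambda_m \Big/ \sum_k f_{k,m} / EC_{10,k,i},}
#' the weighted harmonic combination of component EC10s scaled by the
#' mixture's interaction multiplier \eqn{\lambda_m}. With
#' \eqn{\lambda_m = 1} the generated truth satisfies concentration addition
#' exactly, so a correct analysis pipeline should recover
#' \eqn{\lambda_m} as the Loewe Additivity Index.
#'
#' @param truth A `population_truth` object (mixture columns not required).
#' @param spec A [mixture_spec()]; every component must be a chemical present
#'   in `truth`.
#' @return Named numeric vector of per-individual mixture EC10s (µM).
#' @export
compose_mixture_truth <- function(truth, spec) {
  stopifnot(inherits(truth, "population_truth"), inherits(spec, "mixture_spec"))
  fr <- spec$fractions
  missing <- setdiff(names(fr), truth$chemical_ids)
  if (length(missing))
    stop("mixture '", spec$mixture_id, "': component(s) not in truth: ",
         paste(missing, collapse = ", "), call. = FALSE)
  comp <- truth$ec10[, names(fr), drop = FALSE]
  spec$interaction_multiplier /
    rowSums(sweep(1 / comp, 2, fr, "*"))
}

#' Simulate a noisy concentration-response dataset
#'
#' Generates viability records for every (individual, substance,
#' concentration, replicate) cell of the design. The mean response follows
#' the downward Hill curve with the individual's true EC10 and Hill
#' coefficient (midpoint from [ec10_to_x0()]); additive residual noise is
#' scaled Student-t with 5 degrees of freedom, `sigma * t(5)`, the
#' heavy-tailed error model the Bayesian fit assumes. Mixture concentrations
#' are total (nominal) mixture concentrations.
#'
#' @param truth A `population_truth` from [sample_population_truth()].
#' @param design The [study_design()] the truth was sampled for.
#' @param seed Integer seed (noise only; deterministic given seed).
#' @param t_dof Degrees of freedom of the Student-t noise (default 5).
#' @return A `response_dataset`: a data.frame with columns `individual_id`,
#'   `substance_id`, `conc_uM`, `viability`, carrying provenance attributes
#'   (`seed`, `design_hash`).
#' @export
simulate_responses <- function(truth, design, seed = 1, t_dof = 5) {
  stopifnot(inherits(truth, "population_truth"),
            inherits(design, "study_design"))
  subs <- colnames(truth$ec10)
  need <- c(design$chemical_ids, names(design$mixtures))
  if (!all(need %in% subs))
    stop("truth does not cover all substances in the design: ",
         paste(setdiff(need, subs), collapse = ", "), call. = FALSE)
  if (!identical(truth$individual_ids, design$individual_ids))
    stop("truth and design disagree on individuals", call. = FALSE)

  grid <- expand.grid(
    rep = seq_len(design$replicates_per_conc),
    conc_uM = design$concentrations_uM,
    individual_id = design$individual_ids,
    substance_id = need,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i_idx <- match(grid$individual_id, truth$individual_ids)
  s_idx <- match(grid$substance_id, colnames(truth$ec10))
  ec10 <- truth$ec10[cbind(i_idx, s_idx)]
  n <- 1 + truth$ntilde[cbind(i_idx, s_idx)]
  mu <- hill_response(grid$conc_uM, y0 = truth$y0,
                      x0 = ec10_to_x0(ec10, n), n = n)
  y <- with_preserved_seed(seed, mu + truth$sigma * rt(nrow(grid), df = t_dof))
  out <- data.frame(individual_id = grid$individual_id,
                    substance_id = grid$substance_id,
                    conc_uM = grid$conc_uM,
                    viability = y,
                    stringsAsFactors = FALSE)
  as_response_dataset(out, seed = seed, design_hash = digest::digest(design))
}

#' Construct / validate a response dataset
#'
#' A `response_dataset` is a long-form data.frame with one viability record
#' per row: columns `individual_id`, `substance_id`, `conc_uM` (positive, µM)
#' and `viability` (dimensionless fraction; values may exceed 1 or fall below
#' 0 because of noise, but must be finite). Every (individual, substance)
#' pair must cover at least 4 distinct concentrations so that the
#' four-parameter-per-curve Hill model is identifiable.
#'
#' @param df A data.frame with the four required columns.
#' @param seed,design_hash Optional provenance recorded as attributes.
#' @return The validated data.frame with class `response_dataset`.
#' @export
as_response_dataset <- function(df, seed = NA_integer_, design_hash = NA_character_) {
  req <- c("individual_id", "substance_id", "conc_uM", "viability")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("dataset must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- df[, req]
  df$individual_id <- as.character(df$individual_id)
  df$substance_id <- as.character(df$substance_id)
  bad <- which(!is.finite(df$conc_uM) | df$conc_uM <= 0)
  if (length(bad))
    stop("non-positive or missing concentration at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$viability))
  if (length(bad))
    stop("non-finite viability at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  if (nrow(df) > 0) {
    nconc <- tapply(df$conc_uM,
                    paste(df$individual_id, df$substance_id, sep = "\r"),
                    function(x) length(unique(x)))
    if (any(nconc < 4))
      stop("every (individual, substance) pair needs >= 4 distinct ",
           "concentrations; offending pair(s): ",
           paste(head(gsub("\r", " / ", names(nconc)[nconc < 4]), 5),
                 collapse = "; "), call. = FALSE)
  }
  structure(df, seed = seed, design_hash = design_hash,
            class = c("response_dataset", "data.frame"))
}
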