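#' Concentration addition: weighted harmonic combination of component EC10s
#'
#' The effective concentration of a mixture under concentration addition
#' (CA) is the fraction-weighted harmonic combination of the component
#' effective concentrations:
#' \deqn{\frac{1}{EC_{X,CA}} = \sum_k \frac{f_k}{EC_{X,k}}.}
#' Components excluded as inactive contribute no term; pass `Inf` for their
#' EC10 (their fraction is retained, i.e. fractions are not renormalized).
#' The result is monotone increasing in every component EC10 and never
#' exceeds \eqn{\min_k EC_{10,k}/f_k}.
#'
#' @param fractions Positive fractions summing to 1 (tolerance `1e-6`). If
#'   both arguments are named, they are aligned by name.
#' @param ec10s Positive component EC10s (µM); `Inf` marks an inactive
#'   component.
#' @return The CA-combined EC10 (µM).
#' @export
#' @examples
#' ca_harmonic(c(0.5, 0.5), c(1, 3))   # 1.5
ca_harmonic <- function(fractions, ec10s) {
  if (length(fractions) != length(ec10s))
    stop("'fractions' and 'ec10s' must have the same length", call. = FALSE)
  if (!is.null(names(fractions)) && !is.null(names(ec10s))) {
    if (!setequal(names(fractions), names(ec10s)))
      stop("names of 'fractions' and 'ec10s' differ", call. = FALSE)
    ec10s <- ec10s[names(fractions)]
  }
  if (any(fractions <= 0)) stop("fractions must be > 0", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1 (got ",
         format(sum(fractions), digits = 10), ")", call. = FALSE)
  if (any(ec10s <= 0)) stop("EC10s must be positive", call. = FALSE)
  if (all(is.infinite(ec10s)))
    stop("no active components (all EC10s infinite)", call. = FALSE)
  1 / sum(fractions / ec10s)
}

#' Moment-matched lognormal approximation to a sum of lognormals
#'
#' A sum of independent lognormal terms \eqn{\sum_k \exp(N(\mu_k,
#' \sigma_k^2))} has no closed-form distribution; the common approximation
#' treats the sum as lognormal with parameters matched as follows. With
#' term means \eqn{E_k = \exp(\mu_k + \sigma_k^2/2)} and
#' \eqn{S_+ = \sum_k E_k},
#' \deqn{\sigma_S^2 = \frac{1}{S_+^2} \sum_k \sigma_k^2 E_k^2, \qquad
#'       \mu_S = \ln S_+ - \sigma_S^2 / 2}
#' (the zero-correlation form). The approximation preserves the arithmetic
#' mean exactly: \eqn{\exp(\mu_S + \sigma_S^2/2) = S_+}.
#'
#' @param mus Log-scale means of the terms (length >= 1).
#' @param sigmas Log-scale standard deviations (`>= 0`, same length).
#' @return Named vector `c(mu, sigma)` of the approximating lognormal.
#' @export
#' @examples
#' lognormal_sum(0, 0.5)                  # single term: identity
#' lognormal_sum(c(0, 0), c(0, 0))        # two constants: mu = log 2
lognormal_sum <- function(mus, sigmas) {
  if (length(mus) < 1L) stop("need at least one term", call. = FALSE)
  if (length(mus) != length(sigmas))
    stop("'mus' and 'sigmas' must have the same length", call. = FALSE)
  if (any(sigmas < 0)) stop("'sigmas' must be >= 0", call. = FALSE)
  E <- exp(mus + sigmas^2 / 2)
  S <- sum(E)
  s2 <- sum(sigmas^2 * E^2) / S^2
  c(mu = log(S) - s2 / 2, sigma = sqrt(s2))
}

## ---- input coercion helpers --------------------------------------------

mixture_fractions <- function(mixture) {
  if (inherits(mixture, "mixture_spec")) return(mixture$fractions)
  if (is.numeric(mixture) && !is.null(names(mixture))) {
    if (abs(sum(mixture) - 1) > 1e-6)
      stop("mixture fractions must sum to 1", call. = FALSE)
    return(mixture)
  }
  stop("'mixture' must be a mixture_spec or a named fraction vector",
       call. = FALSE)
}

mixture_label <- function(mixture) {
  if (inherits(mixture, "mixture_spec")) mixture$mixture_id else "mixture"
}

## Per-individual EC10 draws: hill_posterior, draws x individuals matrix,
## or a named per-individual vector (treated as one draw).
as_ec10_matrix <- function(x, what = "component") {
  if (inherits(x, "hill_posterior")) return(x$ec10)
  if (is.matrix(x)) {
    if (is.null(colnames(x)))
      stop(what, ": EC10 matrix needs individual ids as column names",
           call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && !is.null(names(x)))
    return(matrix(x, nrow = 1, dimnames = list(NULL, names(x))))
  stop(what, ": cannot interpret as per-individual EC10 draws", call. = FALSE)
}

## Population GM/GSD draws: hill_posterior, data.frame(gm, gsd), or c(gm, gsd).
as_gmgsd_draws <- function(x, what = "component") {
  if (inherits(x, "hill_posterior"))
    return(data.frame(gm = gm_draws(x), gsd = gsd_draws(x)))
  if (is.data.frame(x) && all(c("gm", "gsd") %in% names(x)))
    return(x[, c("gm", "gsd")])
  if (is.numeric(x) && all(c("gm", "gsd") %in% names(x)))
    return(data.frame(gm = x[["gm"]], gsd = x[["gsd"]]))
  stop(what, ": cannot interpret as GM/GSD draws", call. = FALSE)
}

## POD draws (ec10_median, ec10_p): pod_summary, hill_posterior, data.frame.
as_pod_draws <- function(x, p = 0.01, what = "component") {
  if (inherits(x, "pod_summary")) return(x$draws)
  if (inherits(x, "hill_posterior"))
    return(pod_from_gmgsd(gm_draws(x), gsd_draws(x), p))
  if (is.data.frame(x) && all(c("ec10_median", "ec10_p") %in% names(x)))
    return(x)
  stop(what, ": cannot interpret as POD draws", call. = FALSE)
}

## Deterministic draw subsampling, common across components.
subsample_idx <- function(n_avail, n_draws, seed) {
  if (n_avail <= n_draws) return(seq_len(n_avail))
  with_preserved_seed(seed, sort(sample.int(n_avail, n_draws)))
}

active_components <- function(fractions, inactive) {
  unknown <- setdiff(inactive, names(fractions))
  if (length(unknown))
    stop("'inactive' names not in the mixture: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  active <- setdiff(names(fractions), inactive)
  if (!length(active))
    stop("no active components remain for the mixture", call. = FALSE)
  active
}

new_ca_prediction <- function(mixture_id, method, p, draws, ...) {
  structure(c(list(mixture_id = mixture_id, method = method, p = p,
                   draws = draws,
                   summary = summarize_pod_draws(draws)),
              list(...)),
            class = "ca_prediction")
}

#' @export
print.ca_prediction <- function(x, ...) {
  s <- x$summary
  cat("<ca_prediction> ", x$mixture_id, " by ", x$method, " (",
      nrow(x$draws), " draws)\n", sep = "")
  cat(sprintf("  EC10 median %.4g [%.4g, %.4g] uM; TDVF %.4g [%.4g, %.4g]\n",
              s["ec10_median", 1], s["ec10_median", 2], s["ec10_median", 3],
              s["tdvf", 1], s["tdvf", 2], s["tdvf", 3]))
  invisible(x)
}

## ---- the three CA schemes ----------------------------------------------

#' Concentration addition applied per individual (CA_Indiv)
#'
#' Applies the CA harmonic sum to each individual's component EC10s,
#' treating every cell line as its own experiment:
#' \deqn{1/EC_{10,CA,m,i} = \sum_k f_{k,m} / EC_{10,k,i}.}
#' The per-individual CA EC10s are then fitted across individuals to a
#' right-censored lognormal ([fit_censored_lognormal()], censored at
#' `censor_limit`) to estimate the predicted population GM and GSD, from
#' which the predicted median EC10, sensitive-percentile EC10 and TDVF are
#' derived. This scheme propagates the empirically observed cross-component
#' correlation of individual sensitivity.
#'
#' In `"draws"` mode the whole procedure is repeated for each retained
#' posterior draw (draws are paired across components by pooled draw index
#' and subsampled to `n_draws`), propagating estimation uncertainty. In
#' `"point"` mode it is applied once to the per-individual posterior-median
#' EC10s, the form used for individual-level scatter and heatmap displays.
#'
#' @param components Named list (chemical id -> `hill_posterior`, a draws x
#'   individuals EC10 matrix, or a named per-individual EC10 vector). All
#'   listed active components must share the same individuals.
#' @param mixture A [mixture_spec()] or named fraction vector summing to 1.
#' @param censor_limit Right-censoring ceiling for the population fit
#'   (conventionally 3x the top tested mixture concentration).
#' @param mode `"draws"` (default) or `"point"`; see Details.
#' @param n_draws Number of posterior draws retained in `"draws"` mode.
#' @param p Sensitive-percentile level (default 0.01).
#' @param seed Seed for the deterministic draw subsample.
#' @param inactive Character vector of component ids classified inactive;
#'   their fraction is kept but contributes no term (EC10 treated as
#'   infinite), with no renormalization.
#' @return A `ca_prediction` (method `"CA_Indiv"`) with draw-level
#'   `ec10_median`, `ec10_p`, `tdvf`, `gm`, `gsd`, and the per-individual
#'   predicted EC10s (`indiv`: a draws x individuals matrix, or a vector in
#'   point mode).
#' @export
ca_indiv <- function(components, mixture, censor_limit,
                     mode = c("draws", "point"), n_draws = 500, p = 0.01,
                     seed = 1, inactive = character()) {
  mode <- match.arg(mode)
  fr <- mixture_fractions(mixture)
  active <- active_components(fr, inactive)
  missing <- setdiff(active, names(components))
  if (length(missing))
    stop("components missing from 'components': ",
         paste(missing, collapse = ", "), call. = FALSE)
  mats <- lapply(setNames(active, active), function(k)
    as_ec10_matrix(components[[k]], what = k))

  ids_all <- lapply(mats, colnames)
  shared <- Reduce(intersect, ids_all)
  if (length(shared) < 3L)
    stop("need >= 3 individuals shared across all active components",
         call. = FALSE)
  not_shared <- setdiff(unique(unlist(ids_all)), shared)
  if (length(not_shared)) {
    where <- vapply(not_shared, function(id) {
      lacking <- names(mats)[!vapply(ids_all, function(v) id %in% v,
                                     logical(1))]
      paste0(id, " (missing from ", paste(lacking, collapse = ", "), ")")
    }, character(1))
    stop("individuals not matchable across components: ",
         paste(where, collapse = "; "), call. = FALSE)
  }
  mats <- lapply(mats, function(m) m[, shared, drop = FALSE])
  w <- fr[active]  # inactive fractions contribute no term, no renormalization

  ca_over_individuals <- function(ec10_rows) {
    ## ec10_rows: K x I matrix of component EC10s for one draw
    1 / colSums(ec10_rows^-1 * w)
  }

  if (mode == "point") {
    med <- do.call(rbind, lapply(mats, function(m) apply(m, 2, median)))
    ca_i <- ca_over_individuals(med)
    fit <- fit_censored_lognormal(ca_i, censor_limit)
    draws <- pod_from_gmgsd(fit[["gm"]], fit[["gsd"]], p)
    return(new_ca_prediction(mixture_label(mixture), "CA_Indiv", p, draws,
                             indiv = ca_i, censor_limit = censor_limit,
                             individual_ids = shared, mode = mode))
  }

  idx <- subsample_idx(min(vapply(mats, nrow, integer(1))), n_draws, seed)
  indiv <- matrix(NA_real_, length(idx), length(shared),
                  dimnames = list(NULL, shared))
  gm <- gsd <- numeric(length(idx))
  for (d in seq_along(idx)) {
    rows <- do.call(rbind, lapply(mats, function(m) m[idx[d], ]))
    ca_i <- ca_over_individuals(rows)
    indiv[d, ] <- ca_i
    fit <- fit_censored_lognormal(ca_i, censor_limit)
    gm[d] <- fit[["gm"]]; gsd[d] <- fit[["gsd"]]
  }
  draws <- pod_from_gmgsd(gm, gsd, p)
  new_ca_prediction(mixture_label(mixture), "CA_Indiv", p, draws,
                    indiv = indiv, censor_limit = censor_limit,
                    individual_ids = shared, mode = mode)
}

#' Concentration addition via the lognormal-sum approximation (CA_LNSum)
#'
#' Uses only the population summary statistics (GM and GSD of EC10) of each
#' component and assumes individual sensitivities are uncorrelated across
#' components, so the per-individual CA denominator
#' \eqn{\sum_k f_{k,m}/EC_{10,k,i}} is a sum of independent lognormal terms
#' with \eqn{\mu_{k,m} = \ln(f_{k,m}/GM_k)} and
#' \eqn{\sigma_{k,m} = \ln GSD_k}. The sum is approximated as lognormal via
#' [lognormal_sum()] and inverted:
#' \eqn{GM_{CA,m} = 1/\exp(\mu_{CA,m})}, \eqn{GSD_{CA,m} =
#' \exp(\sigma_{CA,m})}; the predicted median EC10, sensitive-percentile
#' EC10 and TDVF follow as in [derive_pod_draws()]. Applied per posterior
#' draw of the component GM/GSD pairs.
#'
#' @param components Named list (chemical id -> `hill_posterior`,
#'   `data.frame(gm, gsd)` of draws, or `c(gm =, gsd =)`).
#' @inheritParams ca_indiv
#' @return A `ca_prediction` (method `"CA_LNSum"`).
#' @export
ca_lnsum <- function(components, mixture, n_draws = 500, p = 0.01,
                     seed = 1, inactive = character()) {
  fr <- mixture_fractions(mixture)
  active <- active_components(fr, inactive)
  missing <- setdiff(active, names(components))
  if (length(missing))
    stop("components missing from 'components': ",
         paste(missing, collapse = ", "), call. = FALSE)
  dr <- lapply(setNames(active, active), function(k)
    as_gmgsd_draws(components[[k]], what = k))
  idx <- subsample_idx(min(vapply(dr, nrow, integer(1))), n_draws, seed)

  G <- sapply(dr, function(d) d$gm[idx])    # draws x K
  S <- sapply(dr, function(d) log(d$gsd[idx]))
  if (is.null(dim(G))) { G <- matrix(G, nrow = 1); S <- matrix(S, nrow = 1) }
  w <- fr[active]
  ## vectorized lognormal_sum over draws: terms exp(N(log(f/GM), log(GSD)^2))
  E <- sweep(exp(S^2 / 2) / G, 2, w, "*")
  Ssum <- rowSums(E)
  s2 <- rowSums(S^2 * E^2) / Ssum^2
  mu_ca <- log(Ssum) - s2 / 2
  gm_ca <- exp(-mu_ca)
  gsd_ca <- exp(sqrt(s2))
  draws <- pod_from_gmgsd(gm_ca, gsd_ca, p)
  new_ca_prediction(mixture_label(mixture), "CA_LNSum", p, draws)
}

#' Quantile-wise concentration addition (CA_Default)
#'
#' Mirrors default component-based risk assessment: the mixture's median and
#' sensitive-percentile EC10s are obtained by applying the CA harmonic sum
#' separately to the component medians and to the component
#' sensitive-percentile EC10s,
#' \deqn{1/EC_{10,CA,median} = \sum_k f_{k,m}/EC_{10,median,k}, \qquad
#'       1/EC_{10,CA,p} = \sum_k f_{k,m}/EC_{10,p,k},}
#' and the predicted TDVF is their ratio. This implicitly assumes the same
#' individuals occupy the same population quantile for every component
#' (perfectly correlated sensitivity). Applied per posterior draw.
#'
#' @param components Named list (chemical id -> `pod_summary`,
#'   `hill_posterior`, or data.frame with `ec10_median` and `ec10_p` draws).
#' @inheritParams ca_indiv
#' @return A `ca_prediction` (method `"CA_Default"`).
#' @export
ca_default <- function(components, mixture, n_draws = 500, p = 0.01,
                       seed = 1, inactive = character()) {
  fr <- mixture_fractions(mixture)
  active <- active_components(fr, inactive)
  missing <- setdiff(active, names(components))
  if (length(missing))
    stop("components missing from 'components': ",
         paste(missing, collapse = ", "), call. = FALSE)
  dr <- lapply(setNames(active, active), function(k)
    as_pod_draws(components[[k]], p = p, what = k))
  idx <- subsample_idx(min(vapply(dr, nrow, integer(1))), n_draws, seed)

  MED <- sapply(dr, function(d) d$ec10_median[idx])  # draws x K
  P <- sapply(dr, function(d) d$ec10_p[idx])
  if (is.null(dim(MED))) { MED <- matrix(MED, nrow = 1); P <- matrix(P, nrow = 1) }
  w <- fr[active]
  med_ca <- 1 / rowSums(sweep(1 / MED, 2, w, "*"))
  p_ca <- 1 / rowSums(sweep(1 / P, 2, w, "*"))
  draws <- data.frame(ec10_median = med_ca,
                      ec10_p = p_ca,
                      tdvf = med_ca / p_ca,
                      gm = med_ca, gsd = (med_ca / p_ca)^(1 / quantile_constant(p)))
  new_ca_prediction(mixture_label(mixture), "CA_Default", p, draws)
}
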