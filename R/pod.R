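#' Magnitude of a standard-normal tail quantile
#'
#' Returns \eqn{|\Phi^{-1}(p)|}, the number of log-GSD units separating the
#' population median from the `p`-th percentile of a lognormal population.
#' At `p = 0.01` this is 2.326 (3 d.p.), the exponent relating GSD to the
#' toxicodynamic variability factor.
#'
#' @param p Tail probability, `0 < p <= 0.5`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' quantile_constant(0.01)   # 2.326
#' quantile_constant(0.5)    # 0
quantile_constant <- function(p) {
  stop_if_not_scalar_number(p, "p")
  if (p <= 0 || p > 0.5)
    stop("'p' must be in (0, 0.5]", call. = FALSE)
  abs(qnorm(p))
}

#' Default toxicodynamic uncertainty factor
#'
#' The conventional default uncertainty factor for human toxicodynamic
#' variability, one half of a log-decade: \eqn{10^{1/2} \approx 3.16}.
#' Computed, not hard-coded, so it can serve as a benchmark alongside
#' data-derived variability factors.
#'
#' @return Scalar, `10^0.5`.
#' @export
default_td_uf <- function() 10^(1 / 2)

#' Classify a substance as active or inactive
#'
#' A substance is "inactive" when its population geometric-mean EC10 exceeds
#' `multiplier` times the top tested concentration (default 3x, e.g. 300 µM
#' when the top concentration is 100 µM) -- the fit is then an extrapolation
#' beyond the tested range and the substance is excluded from downstream
#' component sets. The rule is applied to a posterior point summary (median
#' by default, configurable to the mean); a tie at exactly the threshold
#' counts as active (the exclusion is a strict inequality).
#'
#' @param posterior A `hill_posterior`.
#' @param c_max Top tested concentration (µM); defaults to the value stored
#'   in the posterior.
#' @param multiplier Threshold multiplier (default 3).
#' @param statistic Posterior functional fed to the rule.
#' @return `TRUE` if active.
#' @export
classify_active <- function(posterior, c_max = posterior$c_max,
                            multiplier = 3,
                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stop_if_not_scalar_number(c_max, "c_max", positive = TRUE)
  gm <- gm_draws(posterior)
  point <- if (statistic == "median") median(gm) else mean(gm)
  point <= multiplier * c_max
}

#' Derive point-of-departure and variability-factor draws
#'
#' For each posterior draw `d` of the population geometric mean `GM(d)` and
#' geometric standard deviation `GSD(d)` of EC10:
#' \deqn{EC_{10,median}(d) = GM(d), \quad
#'       EC_{10,p}(d) = GM(d)\,GSD(d)^{-z_p}, \quad
#'       TDVF_p(d) = GSD(d)^{z_p},}
#' with \eqn{z_p} from [quantile_constant()] (2.326 at the default
#' `p = 0.01`). Repeating the calculation per draw propagates parameter
#' uncertainty into the POD and TDVF distributions. The per-draw identity
#' `EC10_median / EC10_p = TDVF` holds to machine precision.
#'
#' @param posterior A `hill_posterior` (a warning is issued when it did not
#'   pass the convergence gate).
#' @param p Sensitive-percentile level (default 0.01, the 1st percentile).
#' @param c_max Top tested concentration, for the activity rule and the
#'   censoring limit (`3 * c_max`) recorded in the result.
#' @return An object of class `pod_summary` with draw-level `ec10_median`,
#'   `ec10_p` and `tdvf`, point summaries (posterior median, 95% CI), the
#'   activity flag and the censoring limit.
#' @export
derive_pod_draws <- function(posterior, p = 0.01, c_max = posterior$c_max) {
  stopifnot(inherits(posterior, "hill_posterior"))
  if (nrow(posterior$draws) == 0L) stop("posterior has no draws", call. = FALSE)
  if (!isTRUE(posterior$converged))
    warning("posterior for '", posterior$substance_id,
            "' did not meet the convergence gate; PODs may be unreliable",
            call. = FALSE)
  draws <- pod_from_gmgsd(gm_draws(posterior), gsd_draws(posterior), p)
  structure(
    list(substance_id = posterior$substance_id,
         p = p,
         draws = draws,
         summary = summarize_pod_draws(draws),
         active = classify_active(posterior, c_max = c_max),
         censor_limit = 3 * c_max),
    class = "pod_summary")
}

## Draw-level POD arithmetic shared by measured and CA-predicted summaries.
pod_from_gmgsd <- function(gm, gsd, p = 0.01) {
  if (any(gm <= 0)) stop("'gm' must be positive", call. = FALSE)
  if (any(gsd < 1)) stop("'gsd' must be >= 1", call. = FALSE)
  z <- quantile_constant(p)
  data.frame(ec10_median = gm,
             ec10_p = gm * gsd^(-z),
             tdvf = gsd^z,
             gm = gm, gsd = gsd)
}

summarize_pod_draws <- function(draws) {
  q <- function(x) quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  out <- rbind(ec10_median = q(draws$ec10_median),
               ec10_p = q(draws$ec10_p),
               tdvf = q(draws$tdvf))
  colnames(out) <- c("median", "lo95", "hi95")
  as.data.frame(out)
}

#' @export
print.pod_summary <- function(x, ...) {
  cat("<pod_summary> ", x$substance_id,
      if (!x$active) " [inactive]", ":\n", sep = "")
  s <- x$summary
  cat(sprintf("  EC10 median  %.4g [%.4g, %.4g] uM\n",
              s["ec10_median", 1], s["ec10_median", 2], s["ec10_median", 3]))
  cat(sprintf("  EC10 %g%%      %.4g [%.4g, %.4g] uM\n", 100 * x$p,
              s["ec10_p", 1], s["ec10_p", 2], s["ec10_p", 3]))
  cat(sprintf("  TDVF         %.4g [%.4g, %.4g] (default UF %.3g)\n",
              s["tdvf", 1], s["tdvf", 2], s["tdvf", 3], default_td_uf()))
  invisible(x)
}

#' Tabulate POD summaries across substances
#'
#' @param pods List of `pod_summary` objects.
#' @return A data.frame with one row per substance: activity flag, posterior
#'   median and 95% CI of the median EC10, sensitive-percentile EC10 and
#'   TDVF, the censoring limit, and the computed default toxicodynamic
#'   uncertainty factor for comparison.
#' @export
pod_table <- function(pods) {
  if (inherits(pods, "pod_summary")) pods <- list(pods)
  stopifnot(all(vapply(pods, inherits, logical(1), "pod_summary")))
  do.call(rbind, lapply(pods, function(x) {
    s <- x$summary
    data.frame(substance_id = x$substance_id,
               active = x$active,
               ec10_median_med = s["ec10_median", "median"],
               ec10_median_lo95 = s["ec10_median", "lo95"],
               ec10_median_hi95 = s["ec10_median", "hi95"],
               ec10_p01_med = s["ec10_p", "median"],
               ec10_p01_lo95 = s["ec10_p", "lo95"],
               ec10_p01_hi95 = s["ec10_p", "hi95"],
               tdvf01_med = s["tdvf", "median"],
               tdvf01_lo95 = s["tdvf", "lo95"],
               tdvf01_hi95 = s["tdvf", "hi95"],
               censor_limit = x$censor_limit,
               default_td_uf = default_td_uf(),
               stringsAsFactors = FALSE)
  }))
}
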