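#' Loewe Additivity Index
#'
#' The accuracy score for concentration addition: the ratio of a measured to
#' a CA-predicted quantity,
#' \deqn{LAI = \frac{\text{measured}}{\text{CA-predicted}},}
#' computed draw-wise so that its distribution reflects estimation
#' uncertainty. `LAI < 1` means the mixture is more potent than CA predicts
#' (greater-than-additive, "synergy", CA not protective); `LAI > 1` means
#' less-than-additive ("antagonism", CA protective). Summaries are reported
#' as the median and equal-tailed 95% interval of `log10(LAI)`.
#'
#' When the two draw vectors have different lengths, the longer one is
#' deterministically subsampled at evenly spaced indices to align them
#' (pairing is by draw index; the quantities are estimated independently, so
#' the pairing is arbitrary but reproducible).
#'
#' @param measured,predicted Positive draw vectors of the same quantity
#'   (e.g. the mixture's measured and CA-predicted median EC10, or TDVF).
#' @param mixture_id,method,level Optional labels stored in the result
#'   (`level` conventionally one of `"individual"`, `"median"`, `"p01"`,
#'   `"tdvf"`).
#' @return An object of class `lai_result`: draw-level `lai`, the labels,
#'   and `summary` with `log10_lai_median`, `log10_lai_lo95`,
#'   `log10_lai_hi95`.
#' @export
#' @examples
#' r <- lai(rep(2, 100), rep(1, 100))
#' r$summary$log10_lai_median   # log10(2)
lai <- function(measured, predicted, mixture_id = NA_character_,
                method = NA_character_, level = NA_character_) {
  if (length(measured) == 0L || length(predicted) == 0L)
    stop("empty draw vector", call. = FALSE)
  if (any(!is.finite(measured)) || any(!is.finite(predicted)) ||
      any(measured <= 0) || any(predicted <= 0))
    stop("measured and predicted values must be positive and finite",
         call. = FALSE)
  n <- min(length(measured), length(predicted))
  measured <- even_subsample(measured, n)
  predicted <- even_subsample(predicted, n)
  ratio <- measured / predicted
  ld <- log10(ratio)
  q <- quantile(ld, c(0.5, 0.025, 0.975), names = FALSE)
  structure(
    list(mixture_id = mixture_id, method = method, level = level,
         lai = ratio,
         summary = data.frame(log10_lai_median = q[1],
                              log10_lai_lo95 = q[2],
                              log10_lai_hi95 = q[3])),
    class = "lai_result")
}

even_subsample <- function(x, n) {
  if (length(x) == n) return(x)
  x[round(seq(1, length(x), length.out = n))]
}

#' @export
print.lai_result <- function(x, ...) {
  s <- x$summary
  cat("<lai_result> ", x$mixture_id, " / ", x$method, " / ", x$level,
      sprintf(": LAI = 10^%.2f [%.2f, %.2f] (n = %d draws)\n",
              s$log10_lai_median, s$log10_lai_lo95, s$log10_lai_hi95,
              length(x$lai)), sep = "")
  invisible(x)
}

#' LAI at the population levels of a CA prediction
#'
#' Convenience wrapper computing the draw-wise [lai()] of a measured mixture
#' POD against one CA prediction at the three population levels: median
#' EC10, sensitive-percentile EC10, and TDVF.
#'
#' @param measured_pod `pod_summary` of the measured (directly fitted)
#'   mixture.
#' @param prediction A `ca_prediction` for the same mixture.
#' @return Named list of `lai_result` objects (`median`, `p01`, `tdvf`).
#' @export
lai_levels <- function(measured_pod, prediction) {
  stopifnot(inherits(measured_pod, "pod_summary"),
            inherits(prediction, "ca_prediction"))
  mk <- function(col, level)
    lai(measured_pod$draws[[col]], prediction$draws[[col]],
        mixture_id = prediction$mixture_id, method = prediction$method,
        level = level)
  list(median = mk("ec10_median", "median"),
       p01 = mk("ec10_p", "p01"),
       tdvf = mk("tdvf", "tdvf"))
}

#' Per-individual LAI from point estimates
#'
#' Individual-level accuracy of CA: the ratio of each individual's measured
#' mixture EC10 (posterior median) to the CA-predicted EC10 from a
#' point-mode [ca_indiv()] call. Individuals are aligned by name.
#'
#' @param measured Named vector of measured per-individual mixture EC10s.
#' @param predicted Named vector of CA-predicted per-individual EC10s (e.g.
#'   the `indiv` element of a point-mode `ca_prediction`).
#' @param mixture_id Optional label.
#' @return A data.frame with `individual_id`, `measured`, `predicted`,
#'   `lai`, `log10_lai`.
#' @export
lai_indiv <- function(measured, predicted, mixture_id = NA_character_) {
  if (is.null(names(measured)) || is.null(names(predicted)))
    stop("'measured' and 'predicted' must be named by individual",
         call. = FALSE)
  shared <- intersect(names(measured), names(predicted))
  if (!length(shared)) stop("no shared individuals", call. = FALSE)
  m <- measured[shared]; p <- predicted[shared]
  if (any(m <= 0) || any(p <= 0))
    stop("EC10 values must be positive", call. = FALSE)
  data.frame(mixture_id = mixture_id,
             individual_id = shared,
             measured = as.numeric(m),
             predicted = as.numeric(p),
             lai = as.numeric(m / p),
             log10_lai = log10(as.numeric(m / p)),
             row.names = NULL, stringsAsFactors = FALSE)
}
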