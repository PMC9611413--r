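#' Potential scale reduction factor (split-chain Rhat)
#'
#' Convergence diagnostic comparing between- and within-chain variability.
#' Each chain is split in half (first and last `floor(n/2)` iterations; the
#' middle draw of an odd-length chain is dropped), giving `2m` sequences of
#' length `n/2`. With within-chain variance `W` (mean of per-sequence sample
#' variances) and between-chain variance `B` (`n/2` times the variance of the
#' sequence means),
#' \deqn{\hat R = \sqrt{\frac{(n/2 - 1)/(n/2)\, W + B/(n/2)}{W}}.}
#' Values near 1 indicate that the chains are mixing over the same
#' distribution; values above about 1.2 are treated as non-converged by
#' [fit_hill_population()].
#'
#' Chains that are all constant and identical have `W = B = 0`; by convention
#' the function returns 1 for that degenerate case. Chains shorter than 4
#' draws are not split.
#'
#' @param draws A matrix (iterations x chains), a list of equal-length
#'   numeric vectors, or a [coda::mcmc.list] of a single variable.
#' @return The scalar potential scale reduction factor (`>= 1` up to floating
#'   point for non-degenerate input).
#' @export
#' @examples
#' set.seed(1)
#' rhat(matrix(rnorm(2000), 500, 4))            # ~1
#' rhat(cbind(rnorm(100), rnorm(100) + 100))    # >> 1.2
rhat <- function(draws) {
  if (inherits(draws, "mcmc.list"))
    draws <- sapply(draws, as.numeric)
  if (is.list(draws)) {
    if (length(unique(lengths(draws))) != 1L)
      stop("all chains must have the same length", call. = FALSE)
    draws <- do.call(cbind, draws)
  }
  if (!is.matrix(draws) || ncol(draws) < 2L)
    stop("need draws from at least 2 chains", call. = FALSE)
  n <- nrow(draws)
  if (n < 2L) stop("need at least 2 draws per chain", call. = FALSE)
  if (any(!is.finite(draws))) stop("non-finite draws", call. = FALSE)

  if (n >= 4L) {
    h <- floor(n / 2)
    draws <- cbind(draws[seq_len(h), , drop = FALSE],
                   draws[seq.int(n - h + 1, n), , drop = FALSE])
    n <- h
  }
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}
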