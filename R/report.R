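#' Two-way variance decomposition of log10 LAI
#'
#' Quantifies how much of the variation in CA accuracy is attributable to
#' mixture composition versus to individuals, by a two-way main-effects
#' ANOVA on `log10(LAI)` with one value per (mixture, individual) cell.
#' Effect sizes are reported as \eqn{\eta^2 = SS_{factor}/SS_{total}};
#' `r_squared = 1 - SS_residual/SS_total`. On a balanced layout all
#' sums-of-squares types coincide and
#' `eta2_mixture + eta2_individual = r_squared` exactly; unbalanced layouts
#' trigger a warning and use the sequential (additive-model) decomposition.
#' The residual spread is reported as a fold-change, `10^s` with `s` the
#' residual standard error.
#'
#' @param lai_table Data.frame with columns `mixture_id`, `individual_id`,
#'   `log10_lai` (one row per cell).
#' @return An object of class `variance_decomposition`: `r_squared`,
#'   `eta2_mixture`, `eta2_individual`, `residual_se_fold`, `n_cells`, and
#'   the underlying `ss` vector.
#' @export
anova_eta2 <- function(lai_table) {
  req <- c("mixture_id", "individual_id", "log10_lai")
  if (!is.data.frame(lai_table) || !all(req %in% names(lai_table)))
    stop("'lai_table' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  mx <- factor(lai_table$mixture_id)
  id <- factor(lai_table$individual_id)
  y <- lai_table$log10_lai
  if (any(!is.finite(y))) stop("non-finite log10 LAI values", call. = FALSE)
  if (nlevels(mx) < 2L || nlevels(id) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0)
    stop("no variation in log10 LAI; decomposition undefined", call. = FALSE)
  if (length(unique(table(mx, id))) != 1L)
    warning("unbalanced layout: using sequential (additive-model) ",
            "sums of squares", call. = FALSE)
  ## sequential sums of squares from nested fits (all types coincide when
  ## the layout is balanced)
  rss_mx <- sum(lm(y ~ mx)$residuals^2)
  fit <- lm(y ~ mx + id)
  rss_full <- sum(fit$residuals^2)
  ss <- c(mixture = ss_total - rss_mx,
          individual = rss_mx - rss_full,
          residual = rss_full,
          total = ss_total)
  structure(
    list(r_squared = 1 - ss[["residual"]] / ss[["total"]],
         eta2_mixture = ss[["mixture"]] / ss[["total"]],
         eta2_individual = ss[["individual"]] / ss[["total"]],
         residual_se_fold = 10^sqrt(rss_full / fit$df.residual),
         n_cells = length(y),
         ss = ss),
    class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<variance_decomposition> R2 = %.3f ",
                     "(mixtures eta2 = %.3f, individuals eta2 = %.3f), ",
                     "residual SE 10^%.3f, n = %d\n"),
              x$r_squared, x$eta2_mixture, x$eta2_individual,
              log10(x$residual_se_fold), x$n_cells))
  invisible(x)
}

#' Fraction of predictions within a fold boundary
#'
#' The proportion of paired (measured, predicted) values whose ratio lies
#' within `fold` in either direction, i.e.
#' `|log10(measured/predicted)| <= log10(fold)`. A pair exactly on the
#' boundary counts as within (the comparison is `<=`). The measure is
#' symmetric in its two arguments.
#'
#' @param measured,predicted Positive paired vectors.
#' @param fold Fold boundary (default 10).
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' within_fold_fraction(c(1, 1, 1), c(1, 20, 5))  # 2/3
within_fold_fraction <- function(measured, predicted, fold = 10) {
  if (length(measured) == 0L) stop("empty input", call. = FALSE)
  if (length(measured) != length(predicted))
    stop("'measured' and 'predicted' must be paired", call. = FALSE)
  if (any(measured <= 0) || any(predicted <= 0))
    stop("values must be positive", call. = FALSE)
  stop_if_not_scalar_number(fold, "fold", positive = TRUE)
  mean(abs(log10(measured / predicted)) <= log10(fold))
}

#' Hierarchical clustering of a log10 LAI matrix
#'
#' Agglomerative clustering of mixtures (rows) and individuals (columns) of
#' a `log10(LAI)` matrix, as used for heatmap displays that reveal groups of
#' mixtures with similar departure from additivity and consistently
#' sensitive or resistant individuals. Deterministic given the distance and
#' linkage (defaults: Euclidean, complete).
#'
#' @param mat Numeric matrix (mixtures x individuals) of log10 LAI values.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param impute If `TRUE`, missing cells are replaced by the grand mean
#'   (flagged in the output); otherwise missing values are an error.
#' @return An object of class `lai_clustering`: `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order`, the (possibly imputed) `matrix`, and
#'   `imputed`.
#' @export
cluster_lai <- function(mat, distance = "euclidean", linkage = "complete",
                        impute = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("'mat' must be a numeric matrix", call. = FALSE)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  imputed <- FALSE
  if (any(is.na(mat))) {
    if (!impute)
      stop("matrix contains missing values (set impute = TRUE to ",
           "mean-impute)", call. = FALSE)
    mat[is.na(mat)] <- mean(mat, na.rm = TRUE)
    imputed <- TRUE
  }
  rh <- hclust(dist(mat, method = distance), method = linkage)
  ch <- hclust(dist(t(mat), method = distance), method = linkage)
  structure(
    list(row_hclust = rh, col_hclust = ch,
         row_order = rownames(mat)[rh$order] %||% rh$order,
         col_order = colnames(mat)[ch$order] %||% ch$order,
         matrix = mat, imputed = imputed,
         distance = distance, linkage = linkage),
    class = "lai_clustering")
}

#' Summary-table rows for LAI distributions
#'
#' Pools LAI draws across mixtures (equal weight per mixture: each mixture's
#' draws are evenly subsampled to the smallest count before pooling) and
#' reports the posterior median and equal-tailed 95% interval of
#' `log10(LAI)`, formatted in the conventional `10^{median [lo, hi]}` style.
#'
#' @param lai_draws A single positive draw vector, a named list of draw
#'   vectors (one per mixture), or a list of `lai_result` objects.
#' @param method,level Optional labels for the output row.
#' @return A one-row data.frame: `method`, `level`, `n_mixtures`,
#'   `log10_lai_median`, `log10_lai_lo95`, `log10_lai_hi95`, `formatted`.
#' @export
#' @examples
#' summarize_lai(rep(0.5, 100))$formatted   # "10^-0.30 [-0.30, -0.30]"
summarize_lai <- function(lai_draws, method = NA_character_,
                          level = NA_character_) {
  if (inherits(lai_draws, "lai_result")) lai_draws <- list(lai_draws)
  if (is.numeric(lai_draws)) lai_draws <- list(lai_draws)
  draws_list <- lapply(lai_draws, function(x)
    if (inherits(x, "lai_result")) x$lai else x)
  if (!length(draws_list) || any(lengths(draws_list) == 0L))
    stop("no draws to summarize", call. = FALSE)
  if (any(vapply(draws_list, function(x) any(x <= 0), logical(1))))
    stop("LAI draws must be positive", call. = FALSE)
  m <- min(lengths(draws_list))
  pooled <- unlist(lapply(draws_list, even_subsample, n = m))
  ld <- log10(pooled)
  q <- quantile(ld, c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(method = method, level = level,
             n_mixtures = length(draws_list),
             log10_lai_median = q[1],
             log10_lai_lo95 = q[2],
             log10_lai_hi95 = q[3],
             formatted = sprintf("10^%.2f [%.2f, %.2f]", q[1], q[2], q[3]),
             stringsAsFactors = FALSE)
}

#' Diagnostic figures for a measured-versus-predicted comparison
#'
#' `plot_lai_scatter()` draws the standard accuracy display: measured
#' against CA-predicted EC10 on log-log axes with the equality line and
#' 10-fold guide lines. `plot_lai_heatmap()` renders the clustered log10
#' LAI matrix. Both write to `file` when given (PDF) and return the plot
#' object invisibly.
#'
#' @param comparison Data.frame with columns `measured`, `predicted` and
#'   optionally `mixture_id` (used for colour).
#' @param fold Guide-line fold (default 10).
#' @param file Optional output path.
#' @return The ggplot object (scatter) or pheatmap object, invisibly.
#' @export
plot_lai_scatter <- function(comparison, fold = 10, file = NULL) {
  stopifnot(all(c("measured", "predicted") %in% names(comparison)))
  has_mix <- "mixture_id" %in% names(comparison)
  p <- ggplot2::ggplot(comparison,
                       ggplot2::aes(x = predicted, y = measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = log10(fold),
                         linetype = "dotted", colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = -log10(fold),
                         linetype = "dotted", colour = "grey50") +
    (if (has_mix)
       ggplot2::geom_point(ggplot2::aes(colour = mixture_id),
                           alpha = 0.7)
     else ggplot2::geom_point(alpha = 0.7)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "CA-predicted EC10 (uM)", y = "Measured EC10 (uM)")
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}

#' @rdname plot_lai_scatter
#' @param clustering A `lai_clustering` from [cluster_lai()].
#' @export
plot_lai_heatmap <- function(clustering, file = NULL) {
  stopifnot(inherits(clustering, "lai_clustering"))
  ph <- pheatmap::pheatmap(
    clustering$matrix,
    cluster_rows = clustering$row_hclust,
    cluster_cols = clustering$col_hclust,
    silent = TRUE)
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 4)
    grid::grid.newpage()
    grid::grid.draw(ph$gtable)
    grDevices::dev.off()
  }
  invisible(ph)
}
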