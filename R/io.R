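#' Read and write response datasets as CSV
#'
#' The on-disk format is a UTF-8 CSV with fixed header
#' `individual_id,substance_id,conc_uM,viability` and "." as the decimal
#' separator. Values round-trip at full printed precision (15 significant
#' digits). Malformed files fail with an error naming the offending row.
#'
#' @param dataset A `response_dataset` (see [as_response_dataset()]).
#' @param path File path.
#' @return `read_dataset()` returns a validated `response_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "response_dataset"))
  df <- as.data.frame(dataset)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(individual_id = "character",
                                substance_id = "character"))
  req <- c("individual_id", "substance_id", "conc_uM", "viability")
  if (!all(req %in% names(df)))
    stop("malformed dataset CSV (expected header ",
         paste(req, collapse = ","), "): ", path, call. = FALSE)
  if (nrow(df) == 0L) {
    df$conc_uM <- numeric(0)
    df$viability <- numeric(0)
    return(as_response_dataset(df))
  }
  if (!is.numeric(df$conc_uM) || !is.numeric(df$viability)) {
    suppressWarnings({
      cn <- as.numeric(df$conc_uM); vn <- as.numeric(df$viability)
    })
    bad <- which(is.na(cn) | is.na(vn))
    stop("non-numeric value(s) at data row(s) ",
         paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
  }
  bad <- which(!is.finite(df$conc_uM) | df$conc_uM <= 0)
  if (length(bad))
    stop("non-positive concentration at data row(s) ",
         paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
  as_response_dataset(df)
}

#' Read and write mixture definitions as CSV
#'
#' Long format with header `mixture_id,chemical_id,fraction`; one row per
#' mixture component. Fractions of each mixture must sum to 1. The
#' interaction multiplier is a generator-side parameter and is not part of
#' this exchange format; mixtures read from CSV get multiplier 1.
#'
#' @param mixtures A list of [mixture_spec()] objects.
#' @param path File path.
#' @return `read_mixtures()` returns a named list of `mixture_spec`;
#'   `write_mixtures()` returns `path` invisibly.
#' @export
write_mixtures <- function(mixtures, path) {
  if (inherits(mixtures, "mixture_spec")) mixtures <- list(mixtures)
  stopifnot(all(vapply(mixtures, inherits, logical(1), "mixture_spec")))
  rows <- do.call(rbind, lapply(mixtures, function(m) {
    data.frame(mixture_id = m$mixture_id,
               chemical_id = names(m$fractions),
               fraction = as.numeric(m$fractions),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mixtures
#' @export
read_mixtures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(mixture_id = "character",
                                chemical_id = "character"))
  req <- c("mixture_id", "chemical_id", "fraction")
  if (!all(req %in% names(df)))
    stop("malformed mixture CSV (expected header ",
         paste(req, collapse = ","), "): ", path, call. = FALSE)
  out <- lapply(split(df, df$mixture_id), function(d) {
    mixture_spec(d$mixture_id[1], setNames(d$fraction, d$chemical_id))
  })
  out[unique(df$mixture_id)]
}

#' Dump / restore ground-truth population parameters as JSON
#'
#' Serializes a full `population_truth` (hyperparameters plus the
#' per-individual EC10 and Hill-offset matrices) so that test fixtures and
#' pipeline runs can be reproduced without rerunning the generator.
#'
#' @param truth A `population_truth`.
#' @param path File path ending in `.json`.
#' @return `read_truth()` returns the restored `population_truth`;
#'   `write_truth()` returns `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "population_truth"))
  x <- unclass(truth)
  ## named vectors serialize as JSON objects so names survive the round trip
  x$gm_ec10 <- as.list(x$gm_ec10)
  x$gsd_ec10 <- as.list(x$gsd_ec10)
  x$lambda <- as.list(x$lambda)
  x$ec10 <- mat_to_list(truth$ec10)
  x$ntilde <- mat_to_list(truth$ntilde)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ec10 <- list_to_mat(x$ec10, x$individual_ids)
  x$ntilde <- list_to_mat(x$ntilde, x$individual_ids)
  x$gm_ec10 <- unlist(x$gm_ec10)
  x$gsd_ec10 <- unlist(x$gsd_ec10)
  x$lambda <- unlist(x$lambda)
  structure(x, class = "population_truth")
}

mat_to_list <- function(m) {
  c(list(.individuals = rownames(m)),
    lapply(as.data.frame(m), identity))
}

list_to_mat <- function(l, individuals) {
  cols <- setdiff(names(l), ".individuals")
  m <- do.call(cbind, lapply(l[cols], unlist))
  rownames(m) <- individuals
  m
}
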