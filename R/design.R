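#' Define a mixture by its component fractions
#'
#' A mixture is described by the fraction each component contributes to the
#' total (nominal) concentration, plus an interaction multiplier used only by
#' the synthetic-data generator: `interaction_multiplier = 1` makes the true
#' mixture potency exactly concentration-additive, values `< 1` make the
#' mixture more potent than additive (synergy) and values `> 1` less potent
#' (antagonism). Downstream Loewe Additivity Index estimates should recover
#' this multiplier.
#'
#' Fractions are treated as abstract weights summing to 1 (whether they are
#' molar or mass fractions is up to the user, as long as concentrations are
#' expressed consistently).
#'
#' @param mixture_id Character label.
#' @param fractions Named positive numeric vector (names are chemical ids);
#'   must sum to 1 within `1e-9`.
#' @param interaction_multiplier Positive scalar; see Description.
#' @return An object of class `mixture_spec`.
#' @export
#' @examples
#' mixture_spec("mixA", c(chemA = 0.5, chemB = 0.5))
mixture_spec <- function(mixture_id, fractions, interaction_multiplier = 1) {
  if (!is.character(mixture_id) || length(mixture_id) != 1L || !nzchar(mixture_id))
    stop("'mixture_id' must be a non-empty string", call. = FALSE)
  if (!is.numeric(fractions) || length(fractions) < 1L)
    stop("'fractions' must be a named numeric vector", call. = FALSE)
  nm <- names(fractions)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("'fractions' must have unique non-empty names (chemical ids)", call. = FALSE)
  if (any(fractions <= 0))
    stop("all mixture fractions must be > 0", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mixture '", mixture_id, "': fractions must sum to 1 (got ",
         format(sum(fractions), digits = 12), ")", call. = FALSE)
  stop_if_not_scalar_number(interaction_multiplier, "interaction_multiplier",
                            positive = TRUE)
  structure(
    list(mixture_id = mixture_id,
         fractions = fractions,
         interaction_multiplier = interaction_multiplier),
    class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture_spec> ", x$mixture_id, ": ", length(x$fractions),
      " components, interaction multiplier ", x$interaction_multiplier, "\n",
      sep = "")
  invisible(x)
}

#' Describe a population concentration-response study design
#'
#' Captures the layout of a population-based in vitro screen: which
#' individuals (cell lines) and chemicals are tested, which defined mixtures,
#' at which concentrations and with how many replicates. The default
#' concentration series is the five-point 10-fold dilution series
#' 0.01, 0.1, 1, 10, 100 µM typical of such screens.
#'
#' The design does not cross-check mixture component names against
#' `chemical_ids`; that validation is performed by
#' [compose_mixture_truth()] and by the `validate` stage of
#' [run_pipeline()], so that malformed configurations fail fast with a
#' stage-named error rather than at construction time.
#'
#' @param individual_ids Character vector of at least 2 individual labels.
#' @param chemical_ids Character vector of at least 2 chemical labels.
#' @param mixtures List of [mixture_spec()] objects (at least 1).
#' @param concentrations_uM Strictly increasing positive concentrations (µM).
#' @param replicates_per_conc Positive integer; replicates per
#'   (individual, substance, concentration) cell.
#' @return An object of class `study_design`; its `c_max_uM` element is the
#'   top tested concentration.
#' @export
#' @examples
#' d <- study_design(
#'   individual_ids = paste0("ind", 1:10),
#'   chemical_ids = c("chemA", "chemB"),
#'   mixtures = list(mixture_spec("mix1", c(chemA = 0.5, chemB = 0.5))))
#' d$c_max_uM
study_design <- function(individual_ids, chemical_ids, mixtures,
                         concentrations_uM = 10^(-2:2),
                         replicates_per_conc = 1L) {
  individual_ids <- as.character(individual_ids)
  chemical_ids <- as.character(chemical_ids)
  if (length(individual_ids) < 2L || anyDuplicated(individual_ids))
    stop("need at least 2 unique individual_ids", call. = FALSE)
  if (length(chemical_ids) < 2L || anyDuplicated(chemical_ids))
    stop("need at least 2 unique chemical_ids", call. = FALSE)
  if (inherits(mixtures, "mixture_spec")) mixtures <- list(mixtures)
  if (!is.list(mixtures) || length(mixtures) < 1L ||
      !all(vapply(mixtures, inherits, logical(1), "mixture_spec")))
    stop("'mixtures' must be a list of at least one mixture_spec", call. = FALSE)
  mixture_ids <- vapply(mixtures, function(m) m$mixture_id, character(1))
  if (anyDuplicated(mixture_ids)) stop("duplicate mixture ids", call. = FALSE)
  if (any(mixture_ids %in% chemical_ids))
    stop("mixture ids must not collide with chemical ids", call. = FALSE)
  if (!is.numeric(concentrations_uM) || length(concentrations_uM) < 2L ||
      any(concentrations_uM <= 0) || any(diff(concentrations_uM) <= 0))
    stop("'concentrations_uM' must be strictly increasing and positive",
         call. = FALSE)
  replicates_per_conc <- as.integer(replicates_per_conc)
  if (is.na(replicates_per_conc) || replicates_per_conc < 1L)
    stop("'replicates_per_conc' must be a positive integer", call. = FALSE)
  names(mixtures) <- mixture_ids
  structure(
    list(individual_ids = individual_ids,
         chemical_ids = chemical_ids,
         mixtures = mixtures,
         concentrations_uM = as.numeric(concentrations_uM),
         replicates_per_conc = replicates_per_conc,
         c_max_uM = max(concentrations_uM)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", length(x$individual_ids), " individuals x ",
      length(x$chemical_ids), " chemicals x ", length(x$mixtures),
      " mixtures; ", length(x$concentrations_uM),
      " concentrations (top ", x$c_max_uM, " uM), ",
      x$replicates_per_conc, " replicate(s)\n", sep = "")
  invisible(x)
}

#' Generate random mixture definitions
#'
#' Convenience generator for test layouts emulating defined-mixture screens:
#' each mixture uses all (or a subset of) chemicals with fractions drawn from
#' a lognormal and normalized to sum to 1, reflecting the orders-of-magnitude
#' spread of component concentrations in exposure- or hazard-based mixture
#' designs.
#'
#' @param chemical_ids Chemicals to draw components from.
#' @param n_mixtures Number of mixtures.
#' @param components_per_mixture Number of components per mixture (default all).
#' @param fraction_gsd Geometric standard deviation of the unnormalized
#'   lognormal fraction weights (1 gives equal fractions).
#' @param interaction_multipliers Numeric vector recycled across mixtures
#'   (default 1 = exact concentration addition).
#' @param seed Integer seed.
#' @return A list of [mixture_spec()] objects named by mixture id.
#' @export
random_mixture_specs <- function(chemical_ids, n_mixtures,
                                 components_per_mixture = length(chemical_ids),
                                 fraction_gsd = 3,
                                 interaction_multipliers = 1,
                                 seed = 1) {
  chemical_ids <- as.character(chemical_ids)
  stopifnot(n_mixtures >= 1, components_per_mixture >= 1,
            components_per_mixture <= length(chemical_ids), fraction_gsd >= 1)
  lam <- rep_len(interaction_multipliers, n_mixtures)
  with_preserved_seed(seed, {
    specs <- lapply(seq_len(n_mixtures), function(m) {
      comp <- if (components_per_mixture == length(chemical_ids)) chemical_ids
              else sort(sample(chemical_ids, components_per_mixture))
      w <- exp(log(fraction_gsd) * rnorm(length(comp)))
      mixture_spec(sprintf("mix%02d", m), setNames(w / sum(w), comp),
                   interaction_multiplier = lam[m])
    })
    names(specs) <- vapply(specs, function(s) s$mixture_id, character(1))
    specs
  })
}
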