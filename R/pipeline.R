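#' Configuration for an end-to-end analysis run
#'
#' Collects everything [run_pipeline()] needs: either a [study_design()] plus
#' generator parameters (simulation mode) or paths to an existing dataset
#' and mixture table, the Bayesian fit settings, the concentration-addition
#' options, reporting options, an output directory and a master seed. All
#' per-stage seeds are derived deterministically from the master seed, so a
#' rerun with the same configuration reproduces identical tables.
#'
#' @param design A [study_design()] (simulation mode), or `NULL` when
#'   reading data from files.
#' @param dataset_path,mixtures_path CSV paths (data mode; see
#'   [read_dataset()], [read_mixtures()]).
#' @param truth_params Named list of generator parameters passed to
#'   [sample_population_truth()] (e.g. `gm_ec10`, `gsd_ec10`, `rho`,
#'   `sigma`).
#' @param fit A [fit_config()].
#' @param ca_methods Concentration-addition schemes to run.
#' @param ca_n_draws Posterior draws retained per CA prediction.
#' @param censor_multiplier Censoring ceiling as a multiple of the top
#'   tested concentration (default 3).
#' @param percentile Sensitive-percentile level (default 0.01).
#' @param report_fold Fold boundary for the accuracy fraction (default 10).
#' @param figures Whether the report stage writes PDF figures.
#' @param output_dir Output directory (created if absent).
#' @param seed Master seed.
#' @return A list of class `popmix_config`.
#' @export
popmix_config <- function(design = NULL,
                          dataset_path = NULL, mixtures_path = NULL,
                          truth_params = list(),
                          fit = fit_config(),
                          ca_methods = c("CA_Indiv", "CA_LNSum", "CA_Default"),
                          ca_n_draws = 500,
                          censor_multiplier = 3,
                          percentile = 0.01,
                          report_fold = 10,
                          figures = TRUE,
                          output_dir,
                          seed = 1L) {
  simulate <- !is.null(design)
  if (simulate && !inherits(design, "study_design"))
    stop("'design' must be a study_design", call. = FALSE)
  if (!simulate && (is.null(dataset_path) || is.null(mixtures_path)))
    stop("give either 'design' or both 'dataset_path' and 'mixtures_path'",
         call. = FALSE)
  stopifnot(inherits(fit, "fit_config"))
  ca_methods <- match.arg(ca_methods,
                          c("CA_Indiv", "CA_LNSum", "CA_Default"),
                          several.ok = TRUE)
  if (missing(output_dir)) stop("'output_dir' is required", call. = FALSE)
  structure(
    list(design = design,
         dataset_path = dataset_path, mixtures_path = mixtures_path,
         truth_params = truth_params,
         fit = fit,
         ca_methods = ca_methods,
         ca_n_draws = as.integer(ca_n_draws),
         censor_multiplier = censor_multiplier,
         percentile = percentile,
         report_fold = report_fold,
         figures = isTRUE(figures),
         output_dir = output_dir,
         seed = as.integer(seed),
         simulate = simulate),
    class = "popmix_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Deserializes a configuration file into a [popmix_config()]. Nested keys
#' mirror the function arguments; a `fit` block is passed to [fit_config()]
#' and a `design` block (with `individual_ids`, `chemical_ids`,
#' `concentrations_uM`, `replicates_per_conc` and a `mixtures` list of
#' `{mixture_id, fractions, interaction_multiplier}` entries) to
#' [study_design()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param output_dir,seed Optional overrides of the file's values.
#' @return A `popmix_config`.
#' @export
read_config <- function(path, output_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$design)) {
    d <- raw$design
    mixes <- lapply(d$mixtures, function(m)
      mixture_spec(m$mixture_id, unlist(m$fractions),
                   m$interaction_multiplier %||% 1))
    raw$design <- study_design(
      d$individual_ids, d$chemical_ids, mixes,
      concentrations_uM = unlist(d$concentrations_uM) %||% 10^(-2:2),
      replicates_per_conc = d$replicates_per_conc %||% 1L)
  }
  raw$fit <- if (is.null(raw$fit)) fit_config()
             else do.call(fit_config, raw$fit)
  if (!is.null(output_dir)) raw$output_dir <- output_dir
  if (!is.null(seed)) raw$seed <- seed
  do.call(popmix_config, raw[intersect(names(raw),
                                       names(formals(popmix_config)))])
}

#' Validate a dataset / mixture combination
#'
#' Checks the structural assumptions the analysis relies on and returns a
#' machine-readable issue list rather than stopping: mixture fractions
#' summing to 1, concentration positivity, finite viability, mixture
#' components present in the dataset, and individual coverage (an
#' individual tested on a mixture should be tested on every component).
#'
#' @param dataset A `response_dataset` (or data.frame with its columns).
#' @param mixtures List of [mixture_spec()] objects.
#' @return Data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `scope`, `id`, `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(dataset, mixtures) {
  issues <- list()
  add <- function(severity, scope, id, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, scope = scope, id = id, message = message,
      stringsAsFactors = FALSE)
  if (inherits(mixtures, "mixture_spec")) mixtures <- list(mixtures)

  bad <- which(!is.finite(dataset$conc_uM) | dataset$conc_uM <= 0)
  if (length(bad))
    add("error", "dataset", "conc_uM",
        paste0("non-positive concentration at row(s) ",
               paste(head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(dataset$viability))
  if (length(bad))
    add("error", "dataset", "viability",
        paste0("non-finite viability at row(s) ",
               paste(head(bad, 5), collapse = ", ")))

  subs <- unique(dataset$substance_id)
  for (m in mixtures) {
    fs <- sum(m$fractions)
    if (abs(fs - 1) > 1e-9)
      add("error", "mixture", m$mixture_id,
          sprintf("fractions sum to %.6g, not 1", fs))
    missing <- setdiff(names(m$fractions), subs)
    if (length(missing))
      add("error", "mixture", m$mixture_id,
          paste0("component(s) absent from dataset: ",
                 paste(missing, collapse = ", ")))
    if (m$mixture_id %in% subs) {
      mix_ind <- unique(dataset$individual_id[dataset$substance_id ==
                                                m$mixture_id])
      for (k in intersect(names(m$fractions), subs)) {
        comp_ind <- unique(dataset$individual_id[dataset$substance_id == k])
        orphan <- setdiff(mix_ind, comp_ind)
        if (length(orphan))
          add("warning", "coverage", m$mixture_id,
              paste0("individual(s) tested on mixture but not on ", k, ": ",
                     paste(head(orphan, 5), collapse = ", ")))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(), scope = character(),
                  id = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Run the full population mixture-additivity analysis
#'
#' Orchestrates the end-to-end chain: (optionally) simulate a synthetic
#' population dataset, fit the hierarchical Hill model per substance, derive
#' PODs and activity flags, predict each mixture's EC10 distribution under
#' the configured concentration-addition schemes, score accuracy with the
#' Loewe Additivity Index, and write the report bundle. Every stage persists
#' its outputs under `config$output_dir`:
#'
#' * `dataset.csv`, `mixtures.csv`, `truth.json` (simulation mode)
#' * `posteriors/<substance>.csv` + `_diag.json`
#' * `pod_table.csv`
#' * `ca_predictions.csv` (mixture x method x level)
#' * `lai_summary.csv`, `lai_individual.csv`
#' * `variance_report.json`, `lai_table.csv`, figures (PDF, optional)
#' * `manifest.json` (config hash, seed, stage timings, file list)
#'
#' Any stage failure halts the run with an error naming the stage; the
#' manifest of completed stages up to that point is still written. Reruns
#' with the same configuration and seed produce identical CSV content.
#'
#' @param config A [popmix_config()].
#' @return Invisibly, a list with the in-memory stage products (`dataset`,
#'   `posteriors`, `pods`, `ca`, `lai`, `report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "popmix_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "posteriors"), showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("popmix")),
                   seed = config$seed,
                   config_hash = digest::digest(config[setdiff(names(config),
                                                               "output_dir")]),
                   stages = list())
  t_all <- Sys.time()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[name]] <<- list(status = "ok", seconds = round(dt, 2))
    message(sprintf("[%s] done in %.1fs", name, dt))
    res
  }

  ## ---- validate ---------------------------------------------------------
  inputs <- run_stage("validate", {
    if (config$simulate) {
      design <- config$design
      bad <- unlist(lapply(design$mixtures, function(m)
        setdiff(names(m$fractions), design$chemical_ids)))
      if (length(bad))
        stop("mixture component(s) not among the design's chemicals: ",
             paste(unique(bad), collapse = ", "))
      list(design = design)
    } else {
      dataset <- read_dataset(config$dataset_path)
      mixtures <- read_mixtures(config$mixtures_path)
      issues <- validate_inputs(dataset, mixtures)
      if (any(issues$severity == "error"))
        stop(paste(issues$message[issues$severity == "error"],
                   collapse = "; "))
      if (nrow(issues)) for (msg in issues$message) warning(msg, call. = FALSE)
      list(dataset = dataset, mixtures = mixtures)
    }
  })

  ## ---- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", {
    if (!config$simulate) {
      list(dataset = inputs$dataset, mixtures = inputs$mixtures,
           truth = NULL)
    } else {
      design <- inputs$design
      truth <- do.call(sample_population_truth,
                       c(list(design = design), config$truth_params,
                         list(seed = config$seed)))
      dataset <- simulate_responses(truth, design, seed = config$seed + 1L,
                                    t_dof = config$fit$t_dof)
      write_dataset(dataset, file.path(out, "dataset.csv"))
      write_mixtures(design$mixtures, file.path(out, "mixtures.csv"))
      write_truth(truth, file.path(out, "truth.json"))
      list(dataset = dataset, mixtures = design$mixtures, truth = truth)
    }
  })

  substances <- unique(sim$dataset$substance_id)
  mixture_ids <- vapply(sim$mixtures, function(m) m$mixture_id, character(1))
  chem_ids <- setdiff(substances, mixture_ids)

  ## ---- fit --------------------------------------------------------------
  posteriors <- run_stage("fit", {
    ps <- lapply(seq_along(substances), function(si) {
      s <- substances[si]
      cfg <- config$fit
      cfg$seed <- config$seed + 100L + si
      post <- fit_hill_population(sim$dataset, s, cfg)
      write_posterior(post, file.path(out, "posteriors", s))
      post
    })
    names(ps) <- substances
    ps
  })

  ## ---- pod --------------------------------------------------------------
  pods <- run_stage("pod", {
    pd <- lapply(posteriors, derive_pod_draws, p = config$percentile)
    write.csv(pod_table(pd), file.path(out, "pod_table.csv"),
              row.names = FALSE, quote = FALSE)
    pd
  })

  ## ---- ca ---------------------------------------------------------------
  ca <- run_stage("ca", {
    inactive_chems <- chem_ids[!vapply(pods[chem_ids],
                                       function(x) x$active, logical(1))]
    preds <- list()
    for (m in sim$mixtures) {
      mid <- m$mixture_id
      comp_ids <- names(m$fractions)
      inact <- intersect(comp_ids, inactive_chems)
      c_max_mix <- max(sim$dataset$conc_uM[sim$dataset$substance_id == mid])
      censor <- config$censor_multiplier * c_max_mix
      for (meth in config$ca_methods) {
        pred <- switch(meth,
          CA_Indiv = ca_indiv(posteriors[comp_ids], m, censor_limit = censor,
                              n_draws = config$ca_n_draws,
                              p = config$percentile,
                              seed = config$seed + 7L, inactive = inact),
          CA_LNSum = ca_lnsum(posteriors[comp_ids], m,
                              n_draws = config$ca_n_draws,
                              p = config$percentile,
                              seed = config$seed + 7L, inactive = inact),
          CA_Default = ca_default(pods[comp_ids], m,
                                  n_draws = config$ca_n_draws,
                                  p = config$percentile,
                                  seed = config$seed + 7L, inactive = inact))
        preds[[paste(mid, meth, sep = ".")]] <- pred
      }
      ## point-mode per-individual prediction for the individual-level LAI
      preds[[paste(mid, "indiv_point", sep = ".")]] <-
        ca_indiv(posteriors[comp_ids], m, censor_limit = censor,
                 mode = "point", p = config$percentile, inactive = inact)
    }
    write.csv(ca_prediction_table(preds),
              file.path(out, "ca_predictions.csv"),
              row.names = FALSE, quote = FALSE)
    preds
  })

  ## ---- lai --------------------------------------------------------------
  lai_res <- run_stage("lai", {
    rows <- list(); indiv_rows <- list(); draws_store <- list()
    for (m in sim$mixtures) {
      mid <- m$mixture_id
      measured <- pods[[mid]]
      for (meth in config$ca_methods) {
        pred <- ca[[paste(mid, meth, sep = ".")]]
        lv <- lai_levels(measured, pred)
        for (lr in lv) {
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(mixture_id = mid, method = meth,
                             level = lr$level), lr$summary)
          draws_store[[paste(mid, meth, lr$level, sep = ".")]] <- lr$lai
        }
      }
      pt <- ca[[paste(mid, "indiv_point", sep = ".")]]
      measured_indiv <- apply(posteriors[[mid]]$ec10, 2, median)
      indiv_rows[[mid]] <- lai_indiv(measured_indiv, pt$indiv,
                                     mixture_id = mid)
    }
    summary_tab <- do.call(rbind, rows)
    indiv_tab <- do.call(rbind, indiv_rows)
    write.csv(summary_tab, file.path(out, "lai_summary.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(indiv_tab, file.path(out, "lai_individual.csv"),
              row.names = FALSE, quote = FALSE)
    list(summary = summary_tab, individual = indiv_tab,
         draws = draws_store)
  })

  ## ---- report -----------------------------------------------------------
  report <- run_stage("report", {
    rep <- list()
    it <- lai_res$individual
    rep$within_fold <- within_fold_fraction(it$measured, it$predicted,
                                            fold = config$report_fold)
    if (length(sim$mixtures) >= 2L) {
      rep$variance <- anova_eta2(it)
      mat <- tapply(it$log10_lai, list(it$mixture_id, it$individual_id),
                    mean)
      rep$clustering <- cluster_lai(mat, impute = anyNA(mat))
    }
    tab_rows <- list()
    for (meth in config$ca_methods) {
      for (lev in c("median", "p01", "tdvf")) {
        keys <- paste(mixture_ids, meth, lev, sep = ".")
        keys <- keys[keys %in% names(lai_res$draws)]
        if (length(keys))
          tab_rows[[paste(meth, lev)]] <-
            summarize_lai(lai_res$draws[keys], method = meth, level = lev)
      }
    }
    rep$lai_table <- do.call(rbind, tab_rows)
    write.csv(rep$lai_table, file.path(out, "lai_table.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(within_fold_fraction = rep$within_fold,
           fold = config$report_fold,
           variance = if (!is.null(rep$variance))
             rep$variance[c("r_squared", "eta2_mixture", "eta2_individual",
                            "residual_se_fold", "n_cells")]),
      file.path(out, "variance_report.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
    if (config$figures) {
      plot_lai_scatter(it, fold = config$report_fold,
                       file = file.path(out, "fig_scatter_individual.pdf"))
      if (!is.null(rep$clustering))
        plot_lai_heatmap(rep$clustering,
                         file = file.path(out, "fig_lai_heatmap.pdf"))
    }
    rep
  })

  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_all,
                                                      units = "secs")), 2)
  manifest$files <- sort(list.files(out, recursive = TRUE))
  write_manifest(manifest, out)
  invisible(list(dataset = sim$dataset, truth = sim$truth,
                 posteriors = posteriors, pods = pods, ca = ca,
                 lai = lai_res, report = report, manifest = manifest))
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

ca_prediction_table <- function(preds) {
  do.call(rbind, lapply(preds[!grepl("indiv_point$", names(preds))],
                        function(p) {
    s <- p$summary
    data.frame(mixture_id = p$mixture_id, method = p$method,
               level = c("median", "p01", "tdvf"),
               median = s$median, lo95 = s$lo95, hi95 = s$hi95,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
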