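#' Validate a measurement CSV
#'
#' Schema check for user-supplied measurement tables: required columns,
#' compound vocabulary, dose/time domains, value ranges. All violations are
#' collected into one itemized error; nothing is partially loaded.
#'
#' @param path CSV path. Expected columns: `dose_uM`, `time_h`, `compound`,
#'   and either `concentration_uM` or `value` + `value_kind`
#'   (`"percent"`/`"concentration"`). Extra columns (e.g.
#'   `hepatocyte_sample`) pass through.
#' @return The validated measurement tibble.
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot read CSV: ", conditionMessage(e), call. = FALSE)
  )
  errs <- character()
  if (nrow(m) == 0) errs <- c(errs, "file contains no data rows")
  need <- c("dose_uM", "time_h", "compound")
  miss <- setdiff(need, names(m))
  if (length(miss)) errs <- c(errs, paste("missing column(s):", paste(miss, collapse = ", ")))
  has_conc <- "concentration_uM" %in% names(m)
  has_vk <- all(c("value", "value_kind") %in% names(m))
  if (!has_conc && !has_vk) {
    errs <- c(errs, "need either `concentration_uM` or `value` + `value_kind` columns")
  }
  if (length(errs) == 0) {
    bad_comp <- which(!m$compound %in% compound_vocabulary())
    if (length(bad_comp)) {
      errs <- c(errs, paste0(
        "unknown compound in row(s) ", paste(head(bad_comp, 10), collapse = ", "),
        ": allowed names are ", paste(compound_vocabulary(), collapse = ", ")
      ))
    }
    if (any(m$dose_uM <= 0 | !is.finite(m$dose_uM))) {
      errs <- c(errs, "dose_uM must be positive and finite")
    }
    if (any(m$time_h < 0 | !is.finite(m$time_h))) {
      errs <- c(errs, "time_h must be non-negative and finite")
    }
    if (has_conc && any(m$concentration_uM < 0, na.rm = TRUE)) {
      errs <- c(errs, "concentration_uM must be non-negative")
    }
    if (!has_conc && has_vk) {
      bad_kind <- which(!m$value_kind %in% c("percent", "concentration"))
      if (length(bad_kind)) {
        errs <- c(errs, paste("invalid value_kind in row(s):",
                              paste(head(bad_kind, 10), collapse = ", ")))
      }
      pct <- m$value_kind == "percent"
      if (any(m$value[pct] < 0 | m$value[pct] > 100, na.rm = TRUE)) {
        errs <- c(errs, "percent values must lie in [0, 100]")
      }
    }
  }
  if (length(errs)) {
    stop("invalid measurement table:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  m
}

#' Pipeline run configuration
#'
#' @param data `"hl1"` for the packaged hepatocyte dataset, or a CSV path in
#'   the [validate_input()] schema.
#' @param hypotheses Hypotheses to fit.
#' @param n_starts Multistart budget per hypothesis.
#' @param seed Global seed (mandatory); per-stage seeds are derived as
#'   `seed`, `seed + 1`, ... in stage order so stages are individually
#'   reproducible.
#' @param doses Dose grid (µM) for the ensemble sweep.
#' @param t_end Sweep horizon (h).
#' @param perturbation_factors CYP1A2 factors to simulate.
#' @param out_dir Output directory (created if missing).
#' @param explore_iter Optimizer iteration cap per exploratory start.
#' @return A list of class `meiqx_run_config`.
#' @export
run_config <- function(data = "hl1",
                       hypotheses = c("saturation", "dose_dependent"),
                       n_starts = 200, seed = 1,
                       doses = DEFAULT_DOSE_GRID, t_end = 180,
                       perturbation_factors = c(0.1, 10),
                       out_dir = tempfile("meiqx_run_"), explore_iter = 70) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  hypotheses <- match.arg(hypotheses, several.ok = TRUE)
  if (!identical(data, "hl1") && !file.exists(data)) {
    stop("`data` must be 'hl1' or an existing CSV path (got: ", data, ")",
         call. = FALSE)
  }
  structure(
    list(data = data, hypotheses = hypotheses, n_starts = n_starts,
         seed = as.integer(seed), doses = doses, t_end = t_end,
         perturbation_factors = perturbation_factors, out_dir = out_dir,
         explore_iter = explore_iter),
    class = "meiqx_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return A `meiqx_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: prepare (load and validate the measurements, assemble the
#' calibration records), fit (multistart under each hypothesis), filter
#' (p-gate + a-posteriori filters), sweep (ensemble dose sweep of the
#' accepted hypothesis), perturb (CYP1A2 scaling). Writes the ensemble JSON,
#' balance and ratio CSVs, the model-selection summary, and a reproducibility
#' manifest; returns everything invisibly as a list.
#'
#' @param cfg A [run_config()].
#' @return (Invisibly) list with `comparison`, `sweep`, `perturbations`,
#'   `manifest`, and the output `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "meiqx_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  obs <- stage("prepare", {
    if (identical(cfg$data, "hl1")) {
      hl1_dataset()
    } else {
      m <- validate_input(cfg$data)
      if (!"concentration_uM" %in% names(m)) {
        names(m)[names(m) == "value"] <- "value"
        m <- aggregate_compounds(m)
      }
      build_observations(m)
    }
  })

  fit_both <- length(cfg$hypotheses) == 2
  comparison <- stage("fit", {
    if (fit_both) {
      compare_hypotheses(obs, n_starts = cfg$n_starts, seed = cfg$seed,
                         explore_iter = cfg$explore_iter)
    } else {
      f <- fit_multistart(obs, cfg$hypotheses, n_starts = cfg$n_starts,
                          seed = cfg$seed, explore_iter = cfg$explore_iter)
      e <- filter_fits(f, obs)
      structure(
        list(
          summary = tibble::tibble(
            hypothesis = cfg$hypotheses, n_starts = nrow(f),
            best_chi2 = f$chi2[1], best_p_value = f$p_value[1],
            n_pass_p_gate = sum(f$p_value >= e$p_gate),
            n_accepted = ensemble_size(e),
            verdict = ifelse(ensemble_size(e) > 0, "accepted", "rejected")
          ),
          local_chi2 = NULL,
          ensembles = setNames(list(e), cfg$hypotheses),
          fits = setNames(list(f), cfg$hypotheses), seed = cfg$seed
        ),
        class = "meiqx_comparison"
      )
    }
  })

  accepted_h <- comparison$summary$hypothesis[comparison$summary$verdict == "accepted"]
  working <- if (length(accepted_h)) {
    accepted_h[which.max(comparison$summary$n_accepted[
      comparison$summary$verdict == "accepted"])]
  } else {
    NULL
  }

  sweep <- NULL
  perturbations <- list()
  ratio <- NULL
  if (!is.null(working)) {
    ens <- comparison$ensembles[[working]]
    sweep <- stage("sweep", dose_sweep(ens, doses = cfg$doses, t_end = cfg$t_end))
    ratio <- stage("ratio", ratio_curve(ens, doses = cfg$doses))
    perturbations <- stage("perturb", {
      setNames(
        lapply(cfg$perturbation_factors, function(f) {
          perturb_cyp1a2(ens, f, t_end = cfg$t_end)
        }),
        paste0("factor_", cfg$perturbation_factors)
      )
    })
  }

  paths <- list(
    summary = file.path(cfg$out_dir, "model_selection.csv"),
    manifest = file.path(cfg$out_dir, "manifest.json")
  )
  readr::write_csv(comparison$summary, paths$summary)
  if (!is.null(comparison$local_chi2)) {
    paths$local_chi2 <- file.path(cfg$out_dir, "local_chi2.csv")
    readr::write_csv(comparison$local_chi2, paths$local_chi2)
  }
  if (!is.null(working)) {
    paths$ensemble <- file.path(cfg$out_dir, "ensemble.json")
    write_ensemble_json(comparison$ensembles[[working]], paths$ensemble)
    paths$balance <- file.path(cfg$out_dir, "balance.csv")
    readr::write_csv(sweep, paths$balance)
    paths$ratio <- file.path(cfg$out_dir, "ratio.csv")
    readr::write_csv(ratio, paths$ratio)
    for (nm in names(perturbations)) {
      paths[[nm]] <- file.path(cfg$out_dir, paste0("balance_", nm, ".csv"))
      readr::write_csv(perturbations[[nm]], paths[[nm]])
    }
  }

  cfg_for_hash <- cfg[setdiff(names(cfg), "out_dir")]
  manifest <- list(
    package = "meiqxkin",
    version = as.character(utils::packageVersion("meiqxkin")),
    config = cfg_for_hash,
    config_hash = rlang::hash(cfg_for_hash),
    seed = cfg$seed,
    n_input_records = nrow(obs),
    stage_counts = list(
      fits = lapply(comparison$fits, nrow),
      accepted = lapply(comparison$ensembles, ensemble_size),
      sweep_rows = if (is.null(sweep)) 0L else nrow(sweep)
    ),
    working_hypothesis = working
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    obs = obs, comparison = comparison, sweep = sweep, ratio = ratio,
    perturbations = perturbations, manifest = manifest, paths = paths
  ))
}
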