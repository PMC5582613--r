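# Default dose grid (µM) for ensemble sweeps.
DEFAULT_DOSE_GRID <- c(0.05, 0.1, 0.5, 1, 2, 5, 10, 15, 30, 50, 75, 100)

ensemble_param_list <- function(ensemble) {
  if (inherits(ensemble, "meiqx_ensemble")) {
    if (ensemble_size(ensemble) == 0) stop("ensemble is empty", call. = FALSE)
    ensemble$accepted$params
  } else if (inherits(ensemble, "meiqx_params")) {
    list(ensemble)
  } else if (is.list(ensemble) && all(vapply(ensemble, inherits, logical(1), "meiqx_params"))) {
    ensemble
  } else {
    stop("`ensemble` must be a meiqx_ensemble, a meiqx_params, or a list of them",
         call. = FALSE)
  }
}

#' Ensemble dose sweep of the bioactivation/detoxification balance
#'
#' Simulates every model of the ensemble at every dose out to `t_end`
#' (default 180 h, by which the accepted hepatocyte models have reached
#' steady state) and tabulates the endpoint balance: detoxification pool,
#' bioactivation pool, their ratio, and the percent of the dose bioactivated,
#' detoxified, or still unmetabolized (residual MeIQx + transient).
#'
#' @param ensemble A `meiqx_ensemble`, a single [meiqx_params()], or a list
#'   of parameter sets.
#' @param doses Dose grid (µM).
#' @param t_end Horizon (h).
#' @param grid_points Output grid resolution per trajectory.
#' @return A tibble of class `meiqx_balance_table`: one row per
#'   model x dose with columns `model_id`, `dose_uM`, `time_h`,
#'   `detoxification_uM`, `bioactivation_uM`, `residual_uM`, `ratio`,
#'   `percent_detoxified`, `percent_bioactivated`, `percent_residual`.
#'   Models whose simulation fails are excluded with a warning.
#' @export
dose_sweep <- function(ensemble, doses = DEFAULT_DOSE_GRID, t_end = 180,
                       grid_points = 721) {
  plist <- ensemble_param_list(ensemble)
  rows <- purrr::map_dfr(seq_along(plist), function(id) {
    purrr::map_dfr(doses, function(d) {
      traj <- tryCatch(
        simulate_model(plist[[id]], d * 1e-6, t_end = t_end,
                       times = seq(0, t_end, length.out = grid_points),
                       maxsteps = 50000, atol = 1e-12, rtol = 1e-8),
        error = function(e) {
          warning(sprintf("model %d excluded at dose %g uM: %s",
                          id, d, conditionMessage(e)), call. = FALSE)
          NULL
        }
      )
      if (is.null(traj)) return(NULL)
      endpoint <- unlist(as.data.frame(traj)[nrow(traj), MEIQX_SPECIES]) * 1e6
      detox <- sum(endpoint[DETOX_SPECIES])
      bio <- endpoint[["potential_genotoxic"]]
      resid <- endpoint[["meiqx"]] + endpoint[["honh_meiqx"]]
      tibble::tibble(
        model_id = id, dose_uM = d, time_h = t_end,
        detoxification_uM = detox, bioactivation_uM = bio, residual_uM = resid,
        ratio = ifelse(detox > 0, bio / detox, ifelse(bio == 0, 0, NA_real_)),
        percent_detoxified = 100 * detox / d,
        percent_bioactivated = 100 * bio / d,
        percent_residual = 100 * resid / d
      )
    })
  })
  class(rows) <- c("meiqx_balance_table", class(rows))
  rows
}

#' Per-dose ensemble summary of a balance table
#'
#' @param balance A `meiqx_balance_table` from [dose_sweep()].
#' @return Tibble with per-dose mean, sd and median of the balance columns.
#' @export
balance_stats <- function(balance) {
  balance |>
    dplyr::summarise(
      dplyr::across(
        c("detoxification_uM", "bioactivation_uM", "ratio",
          "percent_detoxified", "percent_bioactivated", "percent_residual"),
        list(mean = mean, sd = sd, median = median)
      ),
      n_models = dplyr::n(),
      .by = c("dose_uM", "time_h")
    )
}

#' Bioactivation/detoxification ratio across doses and times
#'
#' @param ensemble As in [dose_sweep()].
#' @param doses Dose grid (µM).
#' @param times Evaluation times (h).
#' @return Tibble `model_id`, `dose_uM`, `time_h`, `detoxification_uM`,
#'   `bioactivation_uM`, `ratio`, with attribute `argmax`: the dose
#'   maximizing the ratio per model and time (undefined ratios excluded).
#' @export
ratio_curve <- function(ensemble, doses = DEFAULT_DOSE_GRID,
                        times = c(6, 24, 72, 120)) {
  plist <- ensemble_param_list(ensemble)
  tt <- sort(unique(c(0, times)))
  rows <- purrr::map_dfr(seq_along(plist), function(id) {
    purrr::map_dfr(doses, function(d) {
      traj <- simulate_model(plist[[id]], d * 1e-6, t_end = max(tt), times = tt,
                             maxsteps = 50000, atol = 1e-12, rtol = 1e-8)
      df <- as.data.frame(traj)
      keep <- df$time_h %in% times
      detox <- rowSums(df[keep, DETOX_SPECIES, drop = FALSE]) * 1e6
      bio <- df$potential_genotoxic[keep] * 1e6
      tibble::tibble(
        model_id = id, dose_uM = d, time_h = df$time_h[keep],
        detoxification_uM = detox, bioactivation_uM = bio,
        ratio = ifelse(detox > 0, bio / detox,
                       ifelse(bio == 0, 0, NA_real_))
      )
    })
  })
  argmax <- rows |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::slice_max(.data$ratio, n = 1, with_ties = FALSE,
                     by = c("model_id", "time_h")) |>
    dplyr::select("model_id", "time_h", argmax_dose_uM = "dose_uM",
                  max_ratio = "ratio")
  attr(rows, "argmax") <- argmax
  rows
}

#' Metabolism times of a trajectory
#'
#' Times at which 50%, 90% and (by the completion threshold) effectively all
#' of the parent MeIQx has been metabolized, obtained by linear interpolation
#' between output grid points.
#'
#' @param traj A `meiqx_trajectory`.
#' @param completion_fraction Residual MeIQx fraction defining "complete"
#'   metabolism (default 0.005, i.e. 99.5% metabolized).
#' @return Tibble with `t50`, `t90`, `t_complete` (h; `NA` where the
#'   threshold is not crossed within the horizon) and a logical
#'   `all_crossed`.
#' @export
metabolism_times <- function(traj, completion_fraction = 0.005) {
  stopifnot(inherits(traj, "meiqx_trajectory"))
  dose <- attr(traj, "dose_M")
  if (dose <= 0) stop("metabolism times need a positive dose", call. = FALSE)
  df <- as.data.frame(traj)
  frac <- df$meiqx / dose
  cross <- function(level) {
    below <- which(frac <= level)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1) return(df$time_h[1])
    # linear interpolation on the segment straddling the threshold
    t0 <- df$time_h[i - 1]; t1 <- df$time_h[i]
    f0 <- frac[i - 1]; f1 <- frac[i]
    t0 + (f0 - level) / (f0 - f1) * (t1 - t0)
  }
  out <- tibble::tibble(
    t50 = cross(0.5), t90 = cross(0.1), t_complete = cross(completion_fraction)
  )
  out$all_crossed <- !anyNA(out[1, c("t50", "t90", "t_complete")])
  out
}

#' CYP1A2 perturbation experiment
#'
#' Rescales the total CYP1A2 pool of every ensemble member by `factor` and
#' re-runs the dose sweep, mimicking enzyme induction (factor > 1) or
#' inhibition/low-expressor phenotypes (factor < 1).
#'
#' @param ensemble As in [dose_sweep()].
#' @param factor Multiplicative factor on `e_cyp1a2_total`, > 0.
#' @param doses Dose grid (µM); default 1, 10 and 100 µM.
#' @param t_end Horizon (h).
#' @return A `meiqx_balance_table` with an extra `cyp1a2_factor` column.
#' @export
perturb_cyp1a2 <- function(ensemble, factor, doses = c(1, 10, 100),
                           t_end = 180) {
  stopifnot(is.numeric(factor), factor > 0)
  plist <- lapply(ensemble_param_list(ensemble), scale_cyp1a2, factor = factor)
  out <- dose_sweep(plist, doses = doses, t_end = t_end)
  out$cyp1a2_factor <- factor
  out
}

#' Local sensitivity scan of the genotoxic endpoint
#'
#' Each of the 16 kinetic parameters is multiplied and divided by `factor` in
#' turn; the relative change of the potential genotoxic pool at `t_end` is
#' reported, ranked by the larger absolute effect of the two directions.
#'
#' @param params A [meiqx_params()].
#' @param factor Perturbation factor, > 1.
#' @param dose Dose (µM).
#' @param t_end Horizon (h).
#' @return Tibble `param`, `pgc_rel_change_up`, `pgc_rel_change_down`,
#'   `max_abs_effect`, sorted by decreasing `max_abs_effect`.
#' @export
sensitivity_scan <- function(params, factor = 10, dose = 10, t_end = 180) {
  stopifnot(inherits(params, "meiqx_params"), factor > 1)
  pgc_at_end <- function(p) {
    traj <- simulate_model(p, dose * 1e-6, t_end = t_end, times = c(0, t_end),
                           maxsteps = 50000, atol = 1e-12, rtol = 1e-8)
    as.data.frame(traj)[2, "potential_genotoxic"]
  }
  base <- pgc_at_end(params)
  rows <- purrr::map_dfr(KINETIC_PARAMS, function(nm) {
    up <- params; up[[nm]] <- up[[nm]] * factor
    dn <- params; dn[[nm]] <- dn[[nm]] / factor
    rel <- function(p) {
      val <- tryCatch(pgc_at_end(p), error = function(e) NA_real_)
      if (base > 0) val / base - 1 else NA_real_
    }
    tibble::tibble(
      param = nm,
      pgc_rel_change_up = rel(up),
      pgc_rel_change_down = rel(dn)
    )
  })
  rows |>
    dplyr::mutate(max_abs_effect = pmax(abs(.data$pgc_rel_change_up),
                                        abs(.data$pgc_rel_change_down),
                                        na.rm = TRUE)) |>
    dplyr::arrange(dplyr::desc(.data$max_abs_effect))
}

#' Ensemble distribution-coefficient curves
#'
#' Evaluates each accepted model's partition fractions alpha(S) (CYP1A2
#' toward C8-hydroxylation) and beta(S) (UGT toward MeIQx glucuronidation)
#' over a substrate grid.
#'
#' @param ensemble As in [dose_sweep()].
#' @param s_uM Substrate grid (µM).
#' @return Tibble `model_id`, `meiqx_uM`, `alpha`, `beta`.
#' @export
coefficient_curves <- function(ensemble,
                               s_uM = 10^seq(-2, 2, length.out = 81)) {
  plist <- ensemble_param_list(ensemble)
  purrr::map_dfr(seq_along(plist), function(id) {
    co <- distribution_coefficients(plist[[id]]$dist, s_uM * 1e-6)
    tibble::tibble(model_id = id, meiqx_uM = s_uM,
                   alpha = co$alpha, beta = co$beta)
  })
}
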