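#' Tidy a multistart fit table
#'
#' One row per fitted start with its chi-square and p-value, or (with
#' `unnest_params = TRUE`) one row per start x parameter.
#'
#' @param x A `meiqx_fits` tibble.
#' @param unnest_params Expand the kinetic parameters into long form.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy meiqx_fits
#' @export
tidy.meiqx_fits <- function(x, unnest_params = FALSE, ...) {
  base <- tibble::as_tibble(x[, c("start_index", "chi2", "p_value", "converged")])
  if (!unnest_params) return(base)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    kin <- unlist(x$params[[i]][KINETIC_PARAMS])
    tibble::tibble(
      start_index = x$start_index[i],
      term = names(kin), estimate = unname(kin)
    )
  }) |>
    dplyr::left_join(base, by = "start_index")
}

#' @method glance meiqx_fits
#' @export
glance.meiqx_fits <- function(x, ...) {
  tibble::tibble(
    hypothesis = attr(x, "hypothesis"),
    n_starts = nrow(x),
    best_chi2 = x$chi2[1],
    best_p_value = x$p_value[1],
    n_data = attr(x, "n_data"),
    n_free = attr(x, "n_free"),
    seed = attr(x, "seed")
  )
}

#' Tidy an ensemble: accepted parameter sets in long form
#'
#' @param x A `meiqx_ensemble`.
#' @param ... Unused.
#' @return Tibble `model_id`, `term`, `estimate` covering the 16 kinetic
#'   parameters of every accepted model.
#' @method tidy meiqx_ensemble
#' @export
tidy.meiqx_ensemble <- function(x, ...) {
  if (ensemble_size(x) == 0) {
    return(tibble::tibble(model_id = integer(), term = character(),
                          estimate = numeric()))
  }
  purrr::map_dfr(seq_len(ensemble_size(x)), function(i) {
    kin <- unlist(x$accepted$params[[i]][KINETIC_PARAMS])
    tibble::tibble(model_id = i, term = names(kin), estimate = unname(kin))
  })
}

#' @method glance meiqx_ensemble
#' @export
glance.meiqx_ensemble <- function(x, ...) {
  tibble::tibble(
    hypothesis = x$hypothesis,
    n_fits = nrow(x$filter_log %||% x$accepted),
    n_accepted = ensemble_size(x),
    best_chi2 = if (ensemble_size(x)) min(x$accepted$chi2) else NA_real_,
    p_gate = x$p_gate
  )
}

#' @method glance meiqx_comparison
#' @export
glance.meiqx_comparison <- function(x, ...) x$summary

`%||%` <- function(a, b) if (is.null(a)) b else a
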