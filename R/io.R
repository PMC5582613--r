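#' Serialize a parameter set to a plain list
#'
#' Flat mapping of the 16 kinetic parameters plus a `distribution` block:
#' `{mode, alpha, beta}` in saturation mode or
#' `{mode, alpha_sigmoid: {a, b, theta, n}, beta_sigmoid: {...}}` in
#' dose-dependent mode. Suitable for YAML/JSON round-tripping.
#'
#' @param params A [meiqx_params()].
#' @return A named list.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "meiqx_params"))
  out <- lapply(params[KINETIC_PARAMS], unname)
  d <- params$dist
  out$distribution <- if (d$mode == "saturation") {
    list(mode = "saturation", alpha = d$alpha, beta = d$beta)
  } else {
    list(
      mode = "dose_dependent",
      alpha_sigmoid = unclass(d$alpha_sigmoid),
      beta_sigmoid = unclass(d$beta_sigmoid)
    )
  }
  out
}

#' Rebuild a parameter set from its serialized list form
#'
#' @param x A list as produced by [params_to_list()].
#' @return A [meiqx_params()].
#' @export
params_from_list <- function(x) {
  db <- x$distribution
  if (is.null(db)) stop("missing `distribution` block", call. = FALSE)
  dist <- if (db$mode == "saturation") {
    dist_spec("saturation", alpha = db$alpha, beta = db$beta)
  } else {
    dist_spec(
      "dose_dependent",
      alpha_sigmoid = do.call(sigmoid_spec, db$alpha_sigmoid),
      beta_sigmoid = do.call(sigmoid_spec, db$beta_sigmoid)
    )
  }
  args <- x[KINETIC_PARAMS]
  missing <- KINETIC_PARAMS[vapply(args, is.null, logical(1))]
  if (length(missing)) {
    stop("missing kinetic parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(meiqx_params, c(args, list(dist = dist)))
}

#' Write an ensemble to JSON
#'
#' Stores each accepted fit as its serialized parameter mapping plus its
#' chi-square, p-value and provenance.
#'
#' @param ensemble A `meiqx_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "meiqx_ensemble"))
  acc <- ensemble$accepted
  payload <- list(
    hypothesis = ensemble$hypothesis,
    p_gate = ensemble$p_gate,
    seed = ensemble$seed,
    n_data = ensemble$n_data,
    n_free = ensemble$n_free,
    models = purrr::map(seq_len(nrow(acc)), function(i) {
      list(
        start_index = acc$start_index[i],
        chi2 = acc$chi2[i],
        p_value = acc$p_value[i],
        params = params_to_list(acc$params[[i]])
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an ensemble written by [write_ensemble_json()]
#'
#' @param path JSON path.
#' @return A `meiqx_ensemble` (accepted fits only; the filter log is not
#'   persisted).
#' @export
read_ensemble_json <- function(path) {
  payload <- jsonlite::read_json(path)
  acc <- purrr::map_dfr(payload$models, function(m) {
    tibble::tibble(
      start_index = m$start_index, chi2 = m$chi2, p_value = m$p_value,
      converged = TRUE, params = list(params_from_list(m$params))
    )
  })
  structure(
    list(
      accepted = acc, filter_log = NULL,
      hypothesis = payload$hypothesis, n_data = payload$n_data,
      n_free = payload$n_free, seed = payload$seed,
      p_gate = payload$p_gate, chydroxy_tol = NA_real_,
      detox_bounds = c(NA_real_, NA_real_)
    ),
    class = "meiqx_ensemble"
  )
}
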