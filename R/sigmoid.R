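#' Sigmoid specification for a dose-dependent distribution coefficient
#'
#' The fraction of an enzyme pool allocated to one of its two competing
#' reactions is modeled as a decreasing Hill-type sigmoid of the instantaneous
#' MeIQx concentration:
#' \deqn{\varphi(S) = a\,\frac{\theta^n}{\theta^n + S^n} + b,}
#' so that \eqn{\varphi} falls from \eqn{a + b} at low substrate to the
#' baseline \eqn{b} at high substrate, with inflection at \eqn{\theta}.
#'
#' @param a Amplitude in \[0, 1\]: the drop between the low- and
#'   high-concentration plateaus.
#' @param b Baseline in \[0, 1\]: the high-concentration asymptote.
#' @param theta Inflection concentration (M), > 0.
#' @param n Slope exponent, > 0. Fixed at 5 throughout the fitting and never
#'   estimated.
#' @return An object of class `sigmoid_spec`.
#' @examples
#' sp <- sigmoid_spec(a = 0.045, b = 0.005, theta = 7.5e-7)
#' sigmoid_phi(sp, c(0, 7.5e-7, 1e-4))
#' @export
sigmoid_spec <- function(a, b, theta, n = 5) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(theta), is.numeric(n))
  if (a < 0 || a > 1) stop("sigmoid amplitude `a` must lie in [0, 1]", call. = FALSE)
  if (b < 0 || b > 1) stop("sigmoid baseline `b` must lie in [0, 1]", call. = FALSE)
  if (a + b > 1 + 1e-12) stop("sigmoid bounds must satisfy a + b <= 1", call. = FALSE)
  if (theta <= 0) stop("sigmoid inflection `theta` must be > 0", call. = FALSE)
  if (n <= 0) stop("sigmoid exponent `n` must be > 0", call. = FALSE)
  structure(list(a = a, b = b, theta = theta, n = n), class = "sigmoid_spec")
}

#' @export
print.sigmoid_spec <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_spec> a = %g, b = %g, theta = %g M, n = %g  (range [%g, %g])\n",
    x$a, x$b, x$theta, x$n, x$b, x$a + x$b
  ))
  invisible(x)
}

#' Evaluate a distribution-coefficient sigmoid
#'
#' @param spec A [sigmoid_spec()].
#' @param s Substrate (MeIQx) concentration in M; vectorised, must be >= 0.
#' @return Coefficient values in `[spec$b, spec$a + spec$b]`, monotone
#'   non-increasing in `s`.
#' @export
sigmoid_phi <- function(spec, s) {
  stopifnot(inherits(spec, "sigmoid_spec"), is.numeric(s))
  if (any(s < 0)) stop("substrate concentration must be non-negative", call. = FALSE)
  tn <- spec$theta^spec$n
  spec$a * tn / (tn + s^spec$n) + spec$b
}

#' Distribution-coefficient specification for the two enzyme competitions
#'
#' CYP1A2 splits between C8-hydroxylation (detoxifying, fraction `alpha`) and
#' N-hydroxylation (bioactivating, fraction `1 - alpha`); UGT splits between
#' MeIQx glucuronidation (fraction `beta`) and HONH-MeIQx glucuronidation
#' (fraction `1 - beta`). Under the *saturation hypothesis* both fractions are
#' dose-independent constants; under the *dose-dependent hypothesis* each is a
#' sigmoid of the instantaneous MeIQx concentration.
#'
#' @param mode `"saturation"` or `"dose_dependent"`.
#' @param alpha,beta Fixed fractions in \[0, 1\] (saturation mode only).
#' @param alpha_sigmoid,beta_sigmoid [sigmoid_spec()] objects (dose-dependent
#'   mode only).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(mode = c("saturation", "dose_dependent"),
                      alpha = NULL, beta = NULL,
                      alpha_sigmoid = NULL, beta_sigmoid = NULL) {
  mode <- match.arg(mode)
  if (mode == "saturation") {
    if (is.null(alpha) || is.null(beta)) {
      stop("saturation mode requires fixed `alpha` and `beta`", call. = FALSE)
    }
    if (!is.null(alpha_sigmoid) || !is.null(beta_sigmoid)) {
      stop("saturation mode takes no sigmoid specs", call. = FALSE)
    }
    if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
      stop("fixed distribution coefficients must lie in [0, 1]", call. = FALSE)
    }
    structure(list(mode = mode, alpha = alpha, beta = beta), class = "dist_spec")
  } else {
    if (is.null(alpha_sigmoid) || is.null(beta_sigmoid)) {
      stop("dose_dependent mode requires `alpha_sigmoid` and `beta_sigmoid`", call. = FALSE)
    }
    if (!is.null(alpha) || !is.null(beta)) {
      stop("dose_dependent mode takes no fixed coefficients", call. = FALSE)
    }
    stopifnot(inherits(alpha_sigmoid, "sigmoid_spec"), inherits(beta_sigmoid, "sigmoid_spec"))
    structure(
      list(mode = mode, alpha_sigmoid = alpha_sigmoid, beta_sigmoid = beta_sigmoid),
      class = "dist_spec"
    )
  }
}

#' Distribution coefficients at a given MeIQx concentration
#'
#' @param dist A [dist_spec()].
#' @param meiqx_conc MeIQx concentration in M, >= 0 (vectorised).
#' @return A tibble with columns `meiqx_M`, `alpha`, `beta`.
#' @export
distribution_coefficients <- function(dist, meiqx_conc) {
  stopifnot(inherits(dist, "dist_spec"), is.numeric(meiqx_conc))
  if (any(meiqx_conc < 0)) stop("MeIQx concentration must be non-negative", call. = FALSE)
  if (dist$mode == "saturation") {
    tibble::tibble(
      meiqx_M = meiqx_conc,
      alpha = rep(dist$alpha, length(meiqx_conc)),
      beta = rep(dist$beta, length(meiqx_conc))
    )
  } else {
    tibble::tibble(
      meiqx_M = meiqx_conc,
      alpha = sigmoid_phi(dist$alpha_sigmoid, meiqx_conc),
      beta = sigmoid_phi(dist$beta_sigmoid, meiqx_conc)
    )
  }
}
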