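# Species order is load-bearing: it matches the compiled RHS and every state
# vector in the package.
MEIQX_SPECIES <- c(
  "meiqx", "c_hydroxy_meiqx", "meiqx_n2_gl", "meiqx_n2_so3h",
  "oxo_meiqx", "honh_meiqx", "hon_meiqx_n2_gl", "potential_genotoxic"
)

# Terminal products accumulate monotonically; MeIQx only decays; HONH-MeIQx is
# the single transient intermediate.
MEIQX_PRODUCTS <- setdiff(MEIQX_SPECIES, c("meiqx", "honh_meiqx"))

# Detoxification pool = everything excreted harmlessly; bioactivation pool =
# the potential genotoxic esters.
DETOX_SPECIES <- c(
  "meiqx_n2_gl", "meiqx_n2_so3h", "oxo_meiqx", "c_hydroxy_meiqx",
  "hon_meiqx_n2_gl"
)

KINETIC_PARAMS <- c(
  "k1", "k2", "k3", "k4", "km1", "km2", "km3", "km4",
  "vm_so3h", "km_so3h", "vm_oxo", "km_oxo", "vm_pgc", "km_pgc",
  "e_cyp1a2_total", "e_ugt_total"
)

#' Kinetic parameter set for the MeIQx metabolism model
#'
#' Bundles the 16 fixed kinetic parameters with a distribution-coefficient
#' specification ([dist_spec()]). Units are molar and hours throughout:
#' catalytic constants `k1..k4` in 1/h, Michaelis constants in M, lumped
#' maximal rates `vm_*` in M/h, enzyme totals in M.
#'
#' `k1, km1` govern CYP1A2 C8-hydroxylation (MeIQx to C-Hydroxy-MeIQx);
#' `k2, km2` CYP1A2 N-hydroxylation (MeIQx to HONH-MeIQx); `k3, km3` UGT
#' glucuronidation of MeIQx; `k4, km4` UGT glucuronidation of HONH-MeIQx.
#' The three single-enzyme reactions (sulfamation, oxidation to the oxo pool,
#' esterification of HONH-MeIQx into the potential genotoxic pool) carry their
#' enzyme inside a lumped `vm`.
#'
#' @param k1,k2,k3,k4 Catalytic constants (1/h), > 0.
#' @param km1,km2,km3,km4 Michaelis constants (M), > 0.
#' @param vm_so3h,vm_oxo,vm_pgc Lumped maximal rates (M/h), > 0.
#' @param km_so3h,km_oxo,km_pgc Michaelis constants (M), > 0.
#' @param e_cyp1a2_total,e_ugt_total Total enzyme pools (M), > 0.
#' @param dist A [dist_spec()].
#' @return An object of class `meiqx_params`.
#' @export
meiqx_params <- function(k1, k2, k3, k4, km1, km2, km3, km4,
                         vm_so3h, km_so3h, vm_oxo, km_oxo, vm_pgc, km_pgc,
                         e_cyp1a2_total, e_ugt_total, dist) {
  vals <- c(
    k1 = k1, k2 = k2, k3 = k3, k4 = k4,
    km1 = km1, km2 = km2, km3 = km3, km4 = km4,
    vm_so3h = vm_so3h, km_so3h = km_so3h, vm_oxo = vm_oxo, km_oxo = km_oxo,
    vm_pgc = vm_pgc, km_pgc = km_pgc,
    e_cyp1a2_total = e_cyp1a2_total, e_ugt_total = e_ugt_total
  )
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop("all kinetic parameters must be finite and >= 0", call. = FALSE)
  }
  stopifnot(inherits(dist, "dist_spec"))
  structure(c(as.list(vals), list(dist = dist)), class = "meiqx_params")
}

#' @export
print.meiqx_params <- function(x, ...) {
  cat("<meiqx_params> 16 kinetic parameters,", x$dist$mode, "partitioning\n")
  kin <- unlist(x[KINETIC_PARAMS])
  print(signif(kin, 4))
  invisible(x)
}

# Flatten to the 24-slot numeric vector the compiled RHS expects.  The
# saturation hypothesis is encoded as the a = 0 sub-model of the sigmoid law.
as_parm_vector <- function(params) {
  stopifnot(inherits(params, "meiqx_params"))
  d <- params$dist
  if (d$mode == "saturation") {
    sig <- c(0, d$alpha, 1, 5, 0, d$beta, 1, 5)
  } else {
    a <- d$alpha_sigmoid; b <- d$beta_sigmoid
    sig <- c(a$a, a$b, a$theta, a$n, b$a, b$b, b$theta, b$n)
  }
  out <- c(unlist(params[KINETIC_PARAMS], use.names = FALSE), sig)
  names(out) <- c(
    KINETIC_PARAMS,
    "a1", "b1", "theta1", "n1", "a2", "b2", "theta2", "n2"
  )
  out
}

#' Rescale the total CYP1A2 pool of a parameter set
#'
#' @param params A [meiqx_params()].
#' @param factor Multiplicative factor, > 0.
#' @return A new `meiqx_params` with `e_cyp1a2_total` scaled.
#' @export
scale_cyp1a2 <- function(params, factor) {
  stopifnot(inherits(params, "meiqx_params"), factor > 0)
  params$e_cyp1a2_total <- params$e_cyp1a2_total * factor
  params
}

#' Reference ground-truth parameter set for synthetic experiments
#'
#' A mid-range dose-dependent parameter set used as the generating truth in
#' parameter-recovery experiments. Michaelis constants sit in the low-µM
#' range typical of CYP1A2/UGT affinity for heterocyclic aromatic amines, the
#' enzyme pools at sub-µM hepatocyte levels, and the sigmoid partitioning of
#' CYP1A2 falls from 0.05 at low MeIQx to 0.005 at high MeIQx with inflection
#' at 0.75 µM (UGT: 0.9 down to 0.5, inflection 1.25 µM). With these values a
#' 1 µM dose is substantially metabolized within ~1-2 days and detoxification
#' dominates, mirroring the hepatocyte measurements.
#'
#' @return A [meiqx_params()] in dose-dependent mode.
#' @export
reference_params <- function() {
  meiqx_params(
    k1 = 20, k2 = 0.85, k3 = 0.28, k4 = 140,
    km1 = 3e-6, km2 = 3e-6, km3 = 8e-6, km4 = 3e-6,
    vm_so3h = 1.2e-7, km_so3h = 6e-6,
    vm_oxo = 5e-8, km_oxo = 6e-6,
    vm_pgc = 4.5e-6, km_pgc = 3e-6,
    e_cyp1a2_total = 2e-7, e_ugt_total = 1e-7,
    dist = dist_spec(
      "dose_dependent",
      alpha_sigmoid = sigmoid_spec(a = 0.045, b = 0.005, theta = 7.5e-7, n = 5),
      beta_sigmoid = sigmoid_spec(a = 0.4, b = 0.5, theta = 1.25e-6, n = 5)
    )
  )
}
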