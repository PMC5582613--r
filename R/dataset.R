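# Raw compound vocabulary (chromatographic peaks) and its reduction onto the
# 8 model species. IQx-8-COOH and its 8-CH2-OH intermediate are gathered as
# the C8-hydroxylated pool; the two 7-oxo derivatives as the oxo pool.
RAW_COMPOUNDS <- c(
  "meiqx" = "meiqx",
  "iqx_8_cooh" = "c_hydroxy_meiqx",
  "8_ch2_oh_iqx" = "c_hydroxy_meiqx",
  "meiqx_n2_gl" = "meiqx_n2_gl",
  "meiqx_n2_so3h" = "meiqx_n2_so3h",
  "7_oxo_meiqx" = "oxo_meiqx",
  "n_desmethyl_7_oxo_meiqx" = "oxo_meiqx",
  "honh_meiqx" = "honh_meiqx",
  "hon_meiqx_n2_gl" = "hon_meiqx_n2_gl",
  "potential_genotoxic" = "potential_genotoxic"
)

compound_vocabulary <- function() {
  unique(c(names(RAW_COMPOUNDS), unname(RAW_COMPOUNDS)))
}

# Constant log-scale measurement weight (~10% relative error) used in the
# chi-square objective; zero observations are floored before logging.
DEFAULT_SIGMA_LOG <- 0.1
DEFAULT_LOG_FLOOR_M <- 1e-10

#' Convert percent-of-dose to concentration
#'
#' Metabolite levels reported as a percentage of the initial MeIQx dose are
#' converted linearly: `c = dose * percent / 100`.
#'
#' @param percent Percent of the initial dose, in \[0, 100\].
#' @param dose Initial MeIQx dose (any concentration unit; output is in the
#'   same unit), >= 0.
#' @return Concentration in the unit of `dose`.
#' @export
percent_to_concentration <- function(percent, dose) {
  stopifnot(is.numeric(percent), is.numeric(dose))
  if (any(percent < 0 | percent > 100)) {
    stop("percent values must lie in [0, 100]", call. = FALSE)
  }
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  dose * percent / 100
}

#' Aggregate raw chromatographic compounds onto the 8 model species
#'
#' Sums the two C8-hydroxylated compounds (IQx-8-COOH, 8-CH2-OH-IQx) into
#' `c_hydroxy_meiqx` and the two oxo compounds (7-oxo, N-desmethyl-7-oxo) into
#' `oxo_meiqx`; all other compounds pass through. Measurements given in
#' percent of the dose are converted to concentration first.
#'
#' @param measurements Data frame with columns `dose_uM`, `time_h`,
#'   `compound`, `value` and optionally `value_kind` (`"percent"` or
#'   `"concentration"`, default concentration). Extra grouping columns (e.g.
#'   `hepatocyte_sample`) are preserved.
#' @return A tibble with columns of `measurements` (minus
#'   `value`/`value_kind`) plus `compound` (reduced name) and
#'   `concentration_uM`, one row per group x reduced compound.
#' @export
aggregate_compounds <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  req <- c("dose_uM", "time_h", "compound", "value")
  if (!all(req %in% names(m))) {
    stop("measurements need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(m) == 0) {
    return(tibble::tibble(dose_uM = numeric(), time_h = numeric(),
                          compound = character(), concentration_uM = numeric()))
  }
  unknown <- setdiff(unique(m$compound), compound_vocabulary())
  if (length(unknown)) {
    stop("unknown compound(s): ", paste(unknown, collapse = ", "),
         "\nallowed: ", paste(compound_vocabulary(), collapse = ", "),
         call. = FALSE)
  }
  if (!"value_kind" %in% names(m)) m$value_kind <- "concentration"
  bad_kind <- setdiff(unique(m$value_kind), c("percent", "concentration"))
  if (length(bad_kind)) {
    stop("value_kind must be 'percent' or 'concentration'", call. = FALSE)
  }
  m <- m |>
    dplyr::mutate(
      concentration_uM = ifelse(
        .data$value_kind == "percent",
        percent_to_concentration(.data$value, .data$dose_uM),
        .data$value
      ),
      compound = dplyr::coalesce(
        unname(RAW_COMPOUNDS[.data$compound]), .data$compound
      )
    )
  grp <- setdiff(names(m), c("value", "value_kind", "concentration_uM"))
  m |>
    dplyr::summarise(
      concentration_uM = sum(.data$concentration_uM),
      .by = dplyr::all_of(grp)
    )
}

#' Close the mass balance: infer the potential genotoxic pool
#'
#' The genotoxic esters are not chromatographically measured; assuming a
#' closed system, their pool is the initial dose minus everything recovered:
#' `PGC = dose - sum(measured)`.
#'
#' @param measured Numeric vector of measured species concentrations at 24 h
#'   (µM), including residual MeIQx.
#' @param dose Initial dose (µM).
#' @param tol Tolerance on `sum(measured) <= dose` (µM).
#' @return The closure concentration (µM), >= 0.
#' @export
close_mass_balance <- function(measured, dose, tol = 1e-9) {
  stopifnot(is.numeric(measured), is.numeric(dose), dose >= 0)
  s <- sum(measured)
  if (s > dose + tol) {
    stop(sprintf(
      "measured species sum to %.4g but the dose is only %.4g: data inconsistent with a closed system",
      s, dose
    ), call. = FALSE)
  }
  max(dose - s, 0)
}

#' Detoxification / bioactivation balance of one dose at one time
#'
#' Detoxification is the sum of the excretable pools (both glucuronides, the
#' sulfamate, the oxo pool and the C8-hydroxylated pool); bioactivation is the
#' potential genotoxic pool alone; the reported ratio is
#' bioactivation / detoxification.
#'
#' @param species Named numeric vector (or 1-row data frame) with the 8
#'   reduced species concentrations (µM).
#' @param dose Initial dose (µM).
#' @return A tibble (`dose_uM`, `detoxification_uM`, `bioactivation_uM`,
#'   `ratio`). The ratio is `NA` (with a warning) if detoxification is zero
#'   while bioactivation is positive.
#' @export
balance_summary <- function(species, dose) {
  if (is.data.frame(species)) species <- unlist(species[1, , drop = TRUE])
  if (!all(MEIQX_SPECIES %in% names(species))) {
    stop("all 8 reduced species are required: ",
         paste(setdiff(MEIQX_SPECIES, names(species)), collapse = ", "),
         call. = FALSE)
  }
  detox <- sum(species[DETOX_SPECIES])
  bio <- unname(species[["potential_genotoxic"]])
  ratio <- if (detox > 0) {
    bio / detox
  } else if (bio == 0) {
    0
  } else {
    warning("detoxification is zero with positive bioactivation: ratio undefined")
    NA_real_
  }
  tibble::tibble(
    dose_uM = dose, detoxification_uM = detox, bioactivation_uM = bio,
    ratio = ratio
  )
}

#' Assemble an observation set for fitting
#'
#' Expands per-compound 24 h measurements into the full calibration table the
#' chi-square objective consumes: for each dose, a t = 0 record per species
#' (all mass in MeIQx), a zero record for the undetected transient HONH-MeIQx
#' at 24 h, and the mass-balance closure record for the potential genotoxic
#' pool.
#'
#' @param measurements Tibble with columns `dose_uM`, `time_h` (= 24),
#'   `compound` (reduced names, 6 measured species per dose), and
#'   `concentration_uM`.
#' @param sigma_log Constant log-scale measurement weight.
#' @return A tibble of class `meiqx_observations` with columns `dose_uM`,
#'   `time_h`, `compound`, `y_obs_M`, `sigma_log`; 8 species x 2 times per
#'   dose.
#' @export
build_observations <- function(measurements, sigma_log = DEFAULT_SIGMA_LOG) {
  m <- tibble::as_tibble(measurements)
  measured <- setdiff(MEIQX_SPECIES, c("honh_meiqx", "potential_genotoxic"))
  obs <- purrr::map_dfr(sort(unique(m$dose_uM)), function(d) {
    md <- dplyr::filter(m, .data$dose_uM == d, .data$time_h == 24)
    if (!setequal(md$compound, measured)) {
      stop(sprintf(
        "dose %g needs exactly the 6 measured species at 24 h (got: %s)",
        d, paste(sort(md$compound), collapse = ", ")
      ), call. = FALSE)
    }
    conc <- setNames(md$concentration_uM, md$compound)[measured]
    pgc <- close_mass_balance(conc, d)
    y24 <- c(conc, honh_meiqx = 0, potential_genotoxic = pgc)[MEIQX_SPECIES]
    y0 <- setNames(c(d, rep(0, 7)), MEIQX_SPECIES)
    tibble::tibble(
      dose_uM = d,
      time_h = rep(c(0, 24), each = 8),
      compound = rep(MEIQX_SPECIES, 2),
      y_obs_M = unname(c(y0, y24)) * 1e-6,
      sigma_log = sigma_log
    )
  })
  class(obs) <- c("meiqx_observations", class(obs))
  obs
}

#' The packaged HL-1 hepatocyte calibration dataset
#'
#' Metabolite concentrations measured in HL-1 human hepatocytes 24 h after
#' MeIQx doses of 1, 10 and 50 µM, reduced to the 8 model species and expanded
#' into the 48-record calibration table (8 species x 2 time points x 3 doses).
#' The potential genotoxic pool is reconstructed by mass-balance closure.
#'
#' @param sigma_log Constant log-scale measurement weight.
#' @return A `meiqx_observations` tibble with 48 records.
#' @export
hl1_dataset <- function(sigma_log = DEFAULT_SIGMA_LOG) {
  path <- system.file("extdata", "hl1_metabolites.csv", package = "meiqxkin")
  raw <- readr::read_csv(path, show_col_types = FALSE)
  build_observations(raw, sigma_log = sigma_log)
}

#' Balance records of an observation set at 24 h
#'
#' @param obs A `meiqx_observations` tibble.
#' @return One [balance_summary()] row per dose.
#' @export
observed_balance <- function(obs) {
  obs |>
    dplyr::filter(.data$time_h == 24) |>
    dplyr::group_by(.data$dose_uM) |>
    dplyr::group_modify(function(df, key) {
      species <- setNames(df$y_obs_M * 1e6, df$compound)
      balance_summary(species, key$dose_uM)[-1]
    }) |>
    dplyr::ungroup()
}
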