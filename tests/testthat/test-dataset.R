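test_that("percent-of-dose conversion is linear and validated", {
  expect_equal(percent_to_concentration(100, 50), 50)
  expect_equal(percent_to_concentration(0, 10), 0)
  expect_equal(percent_to_concentration(41, 1), 0.41)
  # round trip to machine precision
  set.seed(303)
  pct <- runif(50, 0, 100); dose <- runif(50, 0.1, 100)
  expect_equal(percent_to_concentration(pct, dose) / dose * 100, pct)
  expect_error(percent_to_concentration(101, 1), "\\[0, 100\\]")
})

test_that("compound aggregation merges the hydroxylated and oxo pools", {
  m <- tibble::tibble(
    dose_uM = 1, time_h = 24,
    compound = c("iqx_8_cooh", "8_ch2_oh_iqx", "7_oxo_meiqx",
                 "n_desmethyl_7_oxo_meiqx", "meiqx"),
    value = c(0.41, 0, 0.03, 0.02, 0.05)
  )
  out <- aggregate_compounds(m)
  get <- function(cp) out$concentration_uM[out$compound == cp]
  expect_equal(get("c_hydroxy_meiqx"), 0.41)
  expect_equal(get("oxo_meiqx"), 0.05)
  expect_equal(get("meiqx"), 0.05)

  expect_equal(nrow(aggregate_compounds(m[0, ])), 0)
  m$compound[1] <- "mystery_peak"
  expect_error(aggregate_compounds(m), "mystery_peak.*allowed")
})

test_that("percent-kind measurements are converted before aggregation", {
  m <- tibble::tibble(
    dose_uM = 10, time_h = 24,
    compound = c("iqx_8_cooh", "8_ch2_oh_iqx"),
    value = c(5, 4), value_kind = "percent"
  )
  out <- aggregate_compounds(m)
  expect_equal(out$concentration_uM, 0.9)
})

test_that("mass-balance closure reproduces the printed genotoxic pool", {
  t1 <- table1_24h()
  expect_equal(close_mass_balance(t1$`1`, 1), 0.26)
  expect_equal(close_mass_balance(t1$`10`, 10), 2.5)
  expect_equal(close_mass_balance(t1$`50`, 50), 5)
  expect_equal(close_mass_balance(c(0.4, 0.6), 1), 0)
  expect_error(close_mass_balance(c(0.9, 0.2), 1), "closed system")
})

test_that("balance summaries reproduce the printed detoxification and ratio", {
  t1 <- table1_24h()
  rows <- lapply(names(t1), function(d) {
    dose <- as.numeric(d)
    sp <- c(t1[[d]], honh_meiqx = 0,
            potential_genotoxic = close_mass_balance(t1[[d]], dose))
    balance_summary(sp, dose)
  })
  b <- dplyr::bind_rows(rows)
  expect_equal(b$detoxification_uM, c(0.69, 6.1, 16))
  expect_equal(b$bioactivation_uM, c(0.26, 2.5, 5))
  expect_equal(b$ratio, c(0.26 / 0.69, 2.5 / 6.1, 5 / 16))
  expect_true(all(abs(b$ratio - c(0.377, 0.410, 0.313)) <= 0.0005 + 1e-12))

  # no bioactivation: ratio 0, never NA
  sp0 <- c(t1$`1`, honh_meiqx = 0, potential_genotoxic = 0)
  expect_equal(balance_summary(sp0, 1)$ratio, 0)
})

test_that("the packaged HL-1 dataset assembles the 48-record calibration table", {
  obs <- hl1_dataset()
  expect_s3_class(obs, "meiqx_observations")
  expect_equal(nrow(obs), 48)
  expect_setequal(unique(obs$dose_uM), c(1, 10, 50))

  # anchor record: residual MeIQx at 24 h under the 50 µM dose
  expect_equal(
    obs$y_obs_M[obs$dose_uM == 50 & obs$time_h == 24 & obs$compound == "meiqx"],
    29e-6
  )
  # pre-dose rows: everything in the parent compound
  for (d in c(1, 10, 50)) {
    y0 <- obs[obs$dose_uM == d & obs$time_h == 0, ]
    expect_equal(y0$y_obs_M[y0$compound == "meiqx"], d * 1e-6)
    expect_true(all(y0$y_obs_M[y0$compound != "meiqx"] == 0))
  }
  # the transient is absent at 24 h
  expect_true(all(
    obs$y_obs_M[obs$compound == "honh_meiqx" & obs$time_h == 24] == 0
  ))
  # closure restores conservation exactly
  sums <- obs |>
    dplyr::filter(time_h == 24) |>
    dplyr::summarise(total = sum(y_obs_M), .by = dose_uM)
  expect_equal(sums$total, c(1, 10, 50) * 1e-6)
})

test_that("observed balance matches the printed summary columns", {
  b <- observed_balance(hl1_dataset())
  expect_equal(b$detoxification_uM, c(0.69, 6.1, 16))
  expect_equal(b$bioactivation_uM, c(0.26, 2.5, 5))
  expect_true(all(abs(b$ratio - c(0.377, 0.410, 0.313)) <= 0.0005 + 1e-12))
})

test_that("observation assembly rejects incomplete species sets", {
  m <- tibble::tibble(
    dose_uM = 1, time_h = 24,
    compound = c("meiqx", "meiqx_n2_gl"), concentration_uM = c(0.05, 0.02)
  )
  expect_error(build_observations(m), "6 measured species")
})
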