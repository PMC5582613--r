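# Build a trajectory object by hand (exponential parent decay) so threshold
# crossings have closed forms.
fake_decay_trajectory <- function(dose = 1e-6, tau = 2.5, t_end = 24, n = 481) {
  t <- seq(0, t_end, length.out = n)
  df <- tibble::tibble(
    time_h = t, meiqx = dose * 2^(-t / tau),
    c_hydroxy_meiqx = dose * (1 - 2^(-t / tau)), meiqx_n2_gl = 0,
    meiqx_n2_so3h = 0, oxo_meiqx = 0, honh_meiqx = 0, hon_meiqx_n2_gl = 0,
    potential_genotoxic = 0
  )
  attr(df, "dose_M") <- dose
  class(df) <- c("meiqx_trajectory", class(df))
  df
}

test_that("metabolism times recover the closed-form half-life", {
  tr <- fake_decay_trajectory(tau = 2.5)
  mt <- metabolism_times(tr)
  expect_equal(mt$t50, 2.5, tolerance = 1e-3)
  expect_equal(mt$t90, 2.5 * log2(10), tolerance = 1e-3)
  expect_equal(mt$t_complete, 2.5 * log2(200), tolerance = 1e-3)
  expect_true(mt$all_crossed)
  expect_true(mt$t50 <= mt$t90 && mt$t90 <= mt$t_complete)

  # horizon too short: open-ended, never extrapolated
  short <- fake_decay_trajectory(tau = 2.5, t_end = 4)
  mt2 <- metabolism_times(short)
  expect_equal(mt2$t50, 2.5, tolerance = 1e-3)
  expect_true(is.na(mt2$t_complete))
  expect_false(mt2$all_crossed)
})

test_that("dose sweep tabulates the endpoint balance per model and dose", {
  p <- reference_params()
  sweep <- dose_sweep(list(p, p), doses = c(0, 1, 10), t_end = 180,
                      grid_points = 61)
  expect_s3_class(sweep, "meiqx_balance_table")
  expect_equal(nrow(sweep), 6)

  z <- dplyr::filter(sweep, dose_uM == 0)
  expect_true(all(z$detoxification_uM == 0 & z$bioactivation_uM == 0))

  nz <- dplyr::filter(sweep, dose_uM > 0)
  # steady state: everything metabolized, percentages close
  expect_true(all(nz$percent_residual < 0.5))
  expect_true(all(abs(nz$percent_detoxified + nz$percent_bioactivated +
                        nz$percent_residual - 100) < 0.01))

  # two identical models: zero ensemble spread
  st <- balance_stats(nz)
  expect_true(all(st$ratio_sd == 0))
  expect_equal(st$n_models, c(2L, 2L))
})

test_that("ratio curve endpoint agrees with the balance of its trajectory", {
  p <- reference_params()
  rc <- ratio_curve(p, doses = 5, times = c(6, 24))
  tr <- simulate_model(p, 5e-6, t_end = 24, times = c(0, 6, 24),
                       maxsteps = 50000, atol = 1e-12, rtol = 1e-8)
  df <- as.data.frame(tr)
  for (tt in c(6, 24)) {
    sp <- unlist(df[df$time_h == tt, meiqx_species()]) * 1e6
    expected <- balance_summary(sp, 5)
    got <- dplyr::filter(rc, time_h == tt)
    expect_lt(abs(got$ratio - expected$ratio), 1e-9)
  }
  expect_s3_class(attr(rc, "argmax"), "tbl_df")
})

test_that("a model without the genotoxic pathway never bioactivates", {
  p <- reference_params()
  p$vm_pgc <- 0
  rc <- ratio_curve(p, doses = c(0.5, 5, 50), times = 24)
  expect_true(all(rc$ratio == 0))
})

test_that("CYP1A2 perturbation shifts the balance in the expected direction", {
  p <- reference_params()
  base <- perturb_cyp1a2(p, 1, doses = c(1, 10), t_end = 180)
  same <- dose_sweep(p, doses = c(1, 10), t_end = 180)
  expect_equal(base$percent_bioactivated, same$percent_bioactivated)

  up <- perturb_cyp1a2(p, 10, doses = c(1, 10), t_end = 180)
  dn <- perturb_cyp1a2(p, 0.1, doses = c(1, 10), t_end = 180)
  expect_true(all(up$percent_bioactivated > base$percent_bioactivated))
  expect_true(all(dn$percent_bioactivated < base$percent_bioactivated))
})

test_that("sensitivity scan ranks decoupled parameters near zero", {
  p <- reference_params()
  p$vm_oxo <- 1e-12   # oxo pathway already negligible
  sens <- sensitivity_scan(p, factor = 10, dose = 10, t_end = 120)
  expect_equal(nrow(sens), 16)
  oxo_eff <- sens$max_abs_effect[sens$param == "vm_oxo"]
  expect_lt(oxo_eff, 1e-3)
  # once metabolism runs to completion the genotoxic endpoint is governed by
  # the fate of the hydroxylamine and the flux feeding it
  honh_branch <- c("k4", "km4", "e_ugt_total", "vm_pgc", "km_pgc",
                   "k2", "km2", "e_cyp1a2_total")
  expect_true(all(sens$param[1:3] %in% honh_branch))

  # continuity: a vanishing perturbation has a vanishing effect
  sens_small <- sensitivity_scan(p, factor = 1.001, dose = 10, t_end = 120)
  expect_true(all(sens_small$max_abs_effect < 0.05, na.rm = TRUE))
})

test_that("coefficient curves evaluate each model on the substrate grid", {
  cur <- coefficient_curves(list(reference_params()), s_uM = c(0.1, 1, 10))
  expect_equal(nrow(cur), 3)
  expect_true(all(diff(cur$alpha) < 0))
  expect_equal(cur$alpha[1], sigmoid_phi(sigmoid_spec(0.045, 0.005, 7.5e-7), 1e-7))
})
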