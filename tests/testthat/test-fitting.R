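test_that("chi-square is zero on self-generated data and 1 at a 1-sigma offset", {
  cfg <- generator_config(doses = c(1, 10), noise_sd_log = 0, seed = 5)
  obs <- generate_observations(cfg)
  expect_lt(chi_square(cfg$true_params, obs), 1e-10)

  # shift one positive observation by exactly one sigma on the log scale
  i <- which(obs$time_h == 24 & obs$compound == "c_hydroxy_meiqx")[1]
  obs$y_obs_M[i] <- obs$y_obs_M[i] * exp(-obs$sigma_log[i])
  expect_equal(chi_square(cfg$true_params, obs), 1, tolerance = 1e-6)
})

test_that("chi-square equals a hand-rolled loop over the 48 records", {
  obs <- hl1_dataset()
  p <- reference_params()
  # independent accumulation: per-dose simulation, explicit loop, no shared
  # assembly code
  acc <- 0
  for (d in unique(obs$dose_uM)) {
    traj <- as.data.frame(simulate_model(p, d * 1e-6, 24, times = c(0, 24)))
    od <- obs[obs$dose_uM == d, ]
    for (r in seq_len(nrow(od))) {
      ym <- traj[traj$time_h == od$time_h[r], od$compound[r]]
      acc <- acc + ((log(max(ym, 1e-10)) - log(max(od$y_obs_M[r], 1e-10))) /
                      od$sigma_log[r])^2
    }
  }
  expect_equal(chi_square(p, obs), acc, tolerance = 1e-12)
})

test_that("goodness-of-fit p-value behaves like an upper-tail probability", {
  expect_equal(goodness_pvalue(0, 48, 22), 1)
  expect_lt(goodness_pvalue(1e4, 48, 22), 1e-12)
  p_seq <- vapply(c(5, 15, 30, 60), goodness_pvalue, numeric(1),
                  n_data = 48, n_free = 22)
  expect_true(all(diff(p_seq) < 0))
  # chi2 = dof sits near the center of the distribution
  expect_gt(goodness_pvalue(26, 48, 22), 0.4)
  expect_lt(goodness_pvalue(26, 48, 22), 0.6)
  expect_error(goodness_pvalue(1, 10, 12), "degrees of freedom")
})

test_that("multistart fitting is reproducible given the seed", {
  cfg <- generator_config(doses = c(1, 10), noise_sd_log = 0.05, seed = 7)
  obs <- generate_observations(cfg)
  f1 <- fit_multistart(obs, "dose_dependent", n_starts = 2, seed = 99,
                       explore_iter = 15, polish_iter = 0)
  f2 <- fit_multistart(obs, "dose_dependent", n_starts = 2, seed = 99,
                       explore_iter = 15, polish_iter = 0)
  expect_identical(f1$chi2, f2$chi2)
  expect_identical(f1$params[[1]], f2$params[[1]])
  expect_true(all(diff(f1$chi2) >= 0))
  expect_equal(attr(f1, "n_free"), 22L)
})

test_that("search spaces carry the hypothesis-specific free parameters", {
  sat <- default_search_space("saturation")
  dd <- default_search_space("dose_dependent")
  expect_equal(nrow(sat), 18)
  expect_equal(nrow(dd), 22)
  expect_true(all(sat$lower < sat$upper))
  expect_setequal(setdiff(dd$param, sat$param),
                  c("a1", "u1", "theta1", "a2", "u2", "theta2"))
})

test_that("encode/decode round-trips parameter sets through the search space", {
  p <- reference_params()
  x <- meiqxkin:::encode_params(p, "dose_dependent")
  space <- default_search_space("dose_dependent")
  p2 <- meiqxkin:::decode_params(x[space$param], "dose_dependent")
  expect_equal(unlist(p2[meiqxkin:::KINETIC_PARAMS]),
               unlist(p[meiqxkin:::KINETIC_PARAMS]))
  expect_equal(p2$dist$alpha_sigmoid$b, p$dist$alpha_sigmoid$b, tolerance = 1e-12)

  # a saturation optimum embeds into the dose-dependent space as a = 0
  ps <- saturation_params(alpha = 0.3, beta = 0.6)
  xs <- meiqxkin:::encode_params(ps, "dose_dependent")
  pd <- meiqxkin:::decode_params(xs[space$param], "dose_dependent")
  co <- distribution_coefficients(pd$dist, c(0, 1e-6, 1e-4))
  expect_equal(co$alpha, rep(0.3, 3))
  expect_equal(co$beta, rep(0.6, 3))
})

test_that("the a-posteriori filters flag the documented violations", {
  obs <- hl1_dataset()
  # a fabricated fits table around the reference parameters
  p <- reference_params()
  fits <- tibble::tibble(
    start_index = 1L, chi2 = 5, p_value = 1, converged = TRUE,
    params = list(p)
  )
  attr(fits, "hypothesis") <- "dose_dependent"
  attr(fits, "n_data") <- 48L
  attr(fits, "n_free") <- 22L
  attr(fits, "seed") <- 1L
  class(fits) <- c("meiqx_fits", class(fits))

  ens <- filter_fits(fits, obs)
  lg <- ens$filter_log
  expect_equal(nrow(lg), 1)
  expect_true(lg$pass_p_gate)
  # reference params deviate from the HL-1 C-hydroxy point by more than 10%
  expect_equal(lg$first_failed, "chydroxy_deviation")
  expect_equal(ensemble_size(ens), 0)

  # a fit failing only the p-gate is rejected before any simulation
  fits2 <- fits; fits2$p_value <- 0.2
  class(fits2) <- class(fits)
  attributes(fits2)[c("hypothesis", "n_data", "n_free", "seed")] <-
    attributes(fits)[c("hypothesis", "n_data", "n_free", "seed")]
  lg2 <- filter_fits(fits2, obs)$filter_log
  expect_equal(lg2$first_failed, "p_gate")
  expect_true(is.na(lg2$products_monotone))
})

test_that("trajectory-shape checks detect non-monotone dynamics", {
  p <- reference_params()
  tr <- simulate_model(p, 1e-6, 24)
  tol <- 1e-15
  ok <- meiqxkin:::check_monotone(tr, tol)
  expect_true(all(ok))

  # corrupt a terminal product with a dip
  bad <- tr
  bad$meiqx_n2_gl[100] <- bad$meiqx_n2_gl[100] * 0.5
  expect_false(meiqxkin:::check_monotone(bad, tol)[["products_monotone"]])
})
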