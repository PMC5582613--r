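test_that("reaction fluxes obey Michaelis-Menten limits", {
  p <- saturation_params(alpha = 0.05, beta = 0.9)
  zero <- setNames(rep(0, 8), meiqx_species())
  expect_equal(reaction_rates(zero, p)$flux_M_per_h, rep(0, 7))

  # saturation limit of the C-hydroxylation branch
  s_big <- zero; s_big["meiqx"] <- 1e4 * p$km1
  v1 <- reaction_rates(s_big, p)$flux_M_per_h[1]
  expect_equal(v1, p$k1 * 0.05 * p$e_cyp1a2_total, tolerance = 1e-4)

  # half-maximal sulfamation at its Km
  s_km <- zero; s_km["meiqx"] <- p$km_so3h
  v5 <- reaction_rates(s_km, p)$flux_M_per_h[5]
  expect_equal(v5, p$vm_so3h / 2, tolerance = 1e-12)

  expect_error(reaction_rates(replace(zero, 1, -1e-9), p), "non-negative")
})

test_that("ode_rhs is a closed system and matches the independent oracle", {
  set.seed(202)
  for (i in 1:20) {
    p <- if (i %% 2) reference_params() else saturation_params(runif(1), runif(1))
    y <- setNames(10^runif(8, -9, -5), meiqx_species())
    d <- ode_rhs(0, y, p)
    o <- oracle_rhs(unname(y), p)
    expect_lt(abs(sum(d)), 1e-12 * max(abs(d)))
    expect_lt(max(abs(unname(d) - o)), 1e-12 * max(abs(o)))
  }
})

test_that("state with exhausted MeIQx only feeds the hydroxylamine branch", {
  p <- reference_params()
  y <- setNames(rep(0, 8), meiqx_species())
  y["honh_meiqx"] <- 1e-7
  d <- ode_rhs(0, y, p)
  expect_true(all(d[c("meiqx", "c_hydroxy_meiqx", "meiqx_n2_gl",
                      "meiqx_n2_so3h", "oxo_meiqx")] == 0))
  expect_lt(d[["honh_meiqx"]], 0)
  expect_gt(d[["hon_meiqx_n2_gl"]], 0)
  expect_gt(d[["potential_genotoxic"]], 0)
})

test_that("simulated trajectories satisfy the structural invariants", {
  p <- reference_params()
  for (dose in c(1e-6, 1e-5, 5e-5)) {
    tr <- simulate_model(p, dose, t_end = 24)
    df <- as.data.frame(tr)
    expect_equal(df$time_h[1], 0)
    expect_equal(unlist(df[1, meiqx_species()]),
                 setNames(c(dose, rep(0, 7)), meiqx_species()))
    # conservation and non-negativity up to solver tolerance
    expect_lt(conservation_error(tr), 1e-6)
    expect_true(all(as.matrix(df[, meiqx_species()]) >= -1e-12 * dose))
    # parent decays, terminal products accumulate
    expect_true(all(diff(df$meiqx) <= 1e-12 * dose))
    for (sp in setdiff(meiqx_species(), c("meiqx", "honh_meiqx"))) {
      expect_true(all(diff(df[[sp]]) >= -1e-12 * dose))
    }
  }
})

test_that("degenerate inputs give degenerate trajectories", {
  p <- reference_params()
  tr0 <- simulate_model(p, 0, t_end = 24)
  expect_true(all(as.matrix(as.data.frame(tr0)[, meiqx_species()]) == 0))

  # no enzymes, no lumped reactions: MeIQx stays at the dose
  inert <- meiqx_params(
    k1 = 1, k2 = 1, k3 = 1, k4 = 1, km1 = 1e-6, km2 = 1e-6, km3 = 1e-6,
    km4 = 1e-6, vm_so3h = 0, km_so3h = 1e-6, vm_oxo = 0, km_oxo = 1e-6,
    vm_pgc = 0, km_pgc = 1e-6, e_cyp1a2_total = 0, e_ugt_total = 0,
    dist = dist_spec("saturation", alpha = 0.5, beta = 0.5)
  )
  tri <- simulate_model(inert, 1e-6, t_end = 24)
  expect_equal(as.data.frame(tri)$meiqx, rep(1e-6, 241), tolerance = 1e-9)
})

test_that("stiff solution agrees with a fine-step explicit integrator", {
  p <- reference_params()
  dose <- 1e-6
  grid <- seq(0, 24, by = 3)
  tr <- simulate_model(p, dose, t_end = 24, times = grid)
  rk <- oracle_rk4(p, dose, t_end = 24, dt = 1e-3)
  idx <- match(grid, round(rk$times, 6))
  stiff <- as.matrix(as.data.frame(tr)[, meiqx_species()])
  for (j in 1:8) {
    ref <- rk$states[idx, j]
    denom <- pmax(abs(ref), 1e-9 * dose)
    expect_lt(max(abs(stiff[, j] - ref) / denom), 1e-4)
  }
})

test_that("all mass eventually reaches the terminal pools", {
  p <- reference_params()
  tr <- simulate_model(p, 1e-5, t_end = 600, times = c(0, 600))
  endpoint <- as.data.frame(tr)[2, ]
  expect_lt(endpoint$meiqx, 1e-4 * 1e-5)
  expect_lt(endpoint$honh_meiqx, 1e-4 * 1e-5)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  p <- reference_params()
  grid <- seq(0, 24, length.out = 9)
  a <- as.matrix(as.data.frame(
    simulate_model(p, 1e-6, 24, times = grid))[, meiqx_species()])
  b <- as.matrix(as.data.frame(
    simulate_model(p, 1e-6, 24, times = grid, compiled = FALSE))[, meiqx_species()])
  expect_equal(a, b, tolerance = 1e-6)
})
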