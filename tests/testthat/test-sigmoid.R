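test_that("sigmoid_phi matches closed-form anchor values", {
  # zero amplitude: constant at the baseline
  expect_equal(sigmoid_phi(sigmoid_spec(0, 0.3, 1e-6, 5), 1e-5), 0.3)
  # at the inflection point the sigmoid sits halfway up the amplitude
  expect_equal(sigmoid_phi(sigmoid_spec(0.4, 0.1, 2e-6, 5), 2e-6), 0.3)
  # direct evaluation: 1 / (1 + (0.5/1.25)^5) = 1 / 1.01024
  expect_equal(sigmoid_phi(sigmoid_spec(1, 0, 1.25e-6, 5), 0.5e-6),
               0.98986379474, tolerance = 1e-10)
})

test_that("sigmoid_phi is bounded and monotone non-increasing (random specs)", {
  set.seed(101)
  for (i in 1:1000) {
    a <- runif(1)
    b <- runif(1, 0, 1 - a)
    spec <- sigmoid_spec(a, b, 10^runif(1, -8, -4), runif(1, 0.5, 8))
    s <- sort(10^runif(7, -9, -3))
    phi <- sigmoid_phi(spec, s)
    expect_true(all(phi >= b - 1e-12 & phi <= a + b + 1e-12))
    expect_true(all(diff(phi) <= 1e-12))
  }
})

test_that("sigmoid inputs are validated", {
  expect_error(sigmoid_spec(1.2, 0, 1e-6, 5), "amplitude")
  expect_error(sigmoid_spec(0.7, 0.5, 1e-6, 5), "a \\+ b")
  expect_error(sigmoid_spec(0.5, 0.2, -1e-6, 5), "theta")
  expect_error(sigmoid_phi(sigmoid_spec(0.5, 0.2, 1e-6, 5), -1), "non-negative")
})

test_that("distribution coefficients follow the active mode", {
  sat <- dist_spec("saturation", alpha = 0.02, beta = 0.9)
  co <- distribution_coefficients(sat, c(0, 1e-7, 1e-4))
  expect_equal(co$alpha, rep(0.02, 3))
  expect_equal(co$beta, rep(0.9, 3))

  dd <- dist_spec(
    "dose_dependent",
    alpha_sigmoid = sigmoid_spec(0.045, 0.005, 7.5e-7, 5),
    beta_sigmoid = sigmoid_spec(0.4, 0.5, 1.25e-6, 5)
  )
  # phi(0) = a + b; the high-dose asymptote is the baseline b
  expect_equal(distribution_coefficients(dd, 0)$alpha, 0.05)
  expect_equal(distribution_coefficients(dd, 1)$alpha, 0.005, tolerance = 1e-6)
  expect_true(all(
    dplyr::between(distribution_coefficients(dd, 10^seq(-9, -3))$beta, 0, 1)
  ))
})

test_that("dist_spec rejects mixed or incomplete modes", {
  expect_error(dist_spec("saturation", alpha = 0.5), "beta")
  expect_error(dist_spec("dose_dependent", alpha = 0.5,
                         alpha_sigmoid = sigmoid_spec(0.1, 0.1, 1e-6),
                         beta_sigmoid = sigmoid_spec(0.1, 0.1, 1e-6)),
               "no fixed")
  expect_error(dist_spec("saturation", alpha = 1.4, beta = 0.2), "\\[0, 1\\]")
})
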