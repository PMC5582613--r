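# Shared fixtures built in code.

# A saturation-mode parameter set with the same kinetics as the reference
# truth; handy where dose-independent partition fractions make expectations
# easy to state.
saturation_params <- function(alpha = 0.05, beta = 0.9) {
  p <- reference_params()
  meiqx_params(
    k1 = p$k1, k2 = p$k2, k3 = p$k3, k4 = p$k4,
    km1 = p$km1, km2 = p$km2, km3 = p$km3, km4 = p$km4,
    vm_so3h = p$vm_so3h, km_so3h = p$km_so3h,
    vm_oxo = p$vm_oxo, km_oxo = p$km_oxo,
    vm_pgc = p$vm_pgc, km_pgc = p$km_pgc,
    e_cyp1a2_total = p$e_cyp1a2_total, e_ugt_total = p$e_ugt_total,
    dist = dist_spec("saturation", alpha = alpha, beta = beta)
  )
}

# Independent right-hand side used as an oracle: the eight balance equations
# written out directly, sharing no code with the package internals.
oracle_rhs <- function(y, p) {
  S <- max(y[1], 0)
  H <- max(y[6], 0)
  d <- p$dist
  if (d$mode == "saturation") {
    alpha <- d$alpha; beta <- d$beta
  } else {
    a <- d$alpha_sigmoid
    alpha <- a$a * a$theta^a$n / (a$theta^a$n + S^a$n) + a$b
    b <- d$beta_sigmoid
    beta <- b$a * b$theta^b$n / (b$theta^b$n + S^b$n) + b$b
  }
  v1 <- p$k1 * alpha * p$e_cyp1a2_total * S / (p$km1 + S)
  v2 <- p$k2 * (1 - alpha) * p$e_cyp1a2_total * S / (p$km2 + S)
  v3 <- p$k3 * beta * p$e_ugt_total * S / (p$km3 + S)
  v4 <- p$k4 * (1 - beta) * p$e_ugt_total * H / (p$km4 + H)
  v5 <- p$vm_so3h * S / (p$km_so3h + S)
  v6 <- p$vm_oxo * S / (p$km_oxo + S)
  v7 <- p$vm_pgc * H / (p$km_pgc + H)
  c(-(v1 + v2 + v3 + v5 + v6), v1, v3, v5, v6, v2 - v4 - v7, v4, v7)
}

# Classic fixed-step 4th-order Runge-Kutta on the oracle RHS.
oracle_rk4 <- function(p, dose, t_end, dt = 1e-3) {
  n <- round(t_end / dt)
  y <- c(dose, rep(0, 7))
  out <- matrix(NA_real_, nrow = n + 1, ncol = 8)
  out[1, ] <- y
  for (i in seq_len(n)) {
    k1 <- oracle_rhs(y, p)
    k2 <- oracle_rhs(y + dt / 2 * k1, p)
    k3 <- oracle_rhs(y + dt / 2 * k2, p)
    k4 <- oracle_rhs(y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  list(times = seq(0, by = dt, length.out = n + 1), states = out)
}

# Table 1 as printed (µM at 24 h), used by dataset expectations.
table1_24h <- function() {
  list(
    `1` = c(meiqx = 0.05, meiqx_n2_gl = 0.02, meiqx_n2_so3h = 0.13,
            oxo_meiqx = 0.05, c_hydroxy_meiqx = 0.41, hon_meiqx_n2_gl = 0.08),
    `10` = c(meiqx = 1.4, meiqx_n2_gl = 0.9, meiqx_n2_so3h = 2.3,
             oxo_meiqx = 1.2, c_hydroxy_meiqx = 0.9, hon_meiqx_n2_gl = 0.8),
    `50` = c(meiqx = 29, meiqx_n2_gl = 1, meiqx_n2_so3h = 6,
             oxo_meiqx = 6.5, c_hydroxy_meiqx = 1.5, hon_meiqx_n2_gl = 1)
  )
}

# Cache expensive shared fixtures (fitted ensembles) across test files.
fixture_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}
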