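test_that("nondimensionalization inverts the rate and concentration scalings", {
  rates <- rate_constants(k1 = 1, k2 = 1e-4, k3 = 7e-3, k4 = 6e-5)
  mix <- mixture_spec(c0 = 2.3e-3, p0 = 4.6e-3, n0 = 0.8 * 2.3e-3, phi = 0.2)
  par <- build_dimensionless(rates, mix)
  expect_equal(par$epsilon, 0.01)
  expect_equal(par$beta, 0.6)
  expect_equal(par$gamma, 0.7)
  expect_equal(par$sigma, 0.8)
  expect_equal(par$phi, 0.2)
  expect_equal(par$rho, 2)

  # bench fitting-series concentrations give sigma ~ 3.304
  mix2 <- mixture_spec(c0 = 2.3e-3, p0 = 6.7e-3, n0 = 7.6e-3, phi = 0.158)
  expect_equal(build_dimensionless(rates, mix2)$sigma, 7.6 / 2.3,
               tolerance = 1e-12)

  # round trip: dimensionalize(build_dimensionless(.)) is the identity
  back <- dimensionalize(par, k1 = rates$k1, c0 = mix$c0)
  for (k in c("k1", "k2", "k3", "k4"))
    expect_equal(back$rates[[k]], rates[[k]], tolerance = 1e-14)
  for (k in c("d0", "p0", "c0", "iota0"))
    expect_equal(back$mix[[k]], mix[[k]], tolerance = 1e-14)
})

test_that("inadmissible inputs are rejected", {
  expect_error(mixture_spec(c0 = 1e-3, p0 = 1e-3, n0 = 4e-3, phi = 0.3),
               "exceeds vitamin C")
  expect_error(rate_constants(1, -1, 1, 1), "positive")
  expect_error(nondim_params(1e-2, 0.6, 0.7, 6, 0.2, rho = 2), "exceeds vitamin C")
  expect_warning(mixture_spec(c0 = 1e-3, p0 = 1e-3, d0 = 1e-3, iota0 = 0,
                              q0 = 1e-5), "q0")
})

test_that("regime dispatch splits on p0/n0 with the boundary on the moderate side", {
  mk <- function(ratio) mixture_spec(c0 = 1e-3, p0 = ratio * 5e-3, n0 = 5e-3,
                                     phi = 0.1)
  expect_identical(classify_regime(mk(0.88)), "M-HP")
  expect_identical(classify_regime(mk(8.8)), "H-HP")
  expect_identical(classify_regime(mk(1.5)), "M-HP")
  expect_identical(classify_regime(mk(1.5 + 1e-9)), "H-HP")
})

test_that("mass-action RHS conserves atomic iodine and matches hand values", {
  rates <- rate_constants(1, 1e-4, 7e-3, 6e-5)
  set.seed(42)
  for (i in 1:50) {
    d <- rhs_full(rand_state(), rates)
    expect_equal(d[["D"]] + d[["Q"]] + 2 * d[["I"]], 0, tolerance = 1e-18)
  }
  # single-term evaluation of the peroxide equation
  st <- c(D = 1e-3, P = 1e-3, Q = 0, C = 0, I = 0)
  d <- rhs_full(st, rate_constants(1, 1, 1, 1))
  expect_equal(d[["P"]], -1e-6)
  expect_equal(d[["C"]], 0)
  # vitamin C factor: C = 0 anywhere kills dC/dt
  st2 <- c(D = 1e-3, P = 1e-3, Q = 1e-4, C = 0, I = 5e-4)
  expect_equal(rhs_full(st2, rates)[["C"]], 0)
})

test_that("vitamin C and peroxide derivatives are never positive", {
  rates <- rate_constants(1, 1e-4, 7e-3, 6e-5)
  set.seed(7)
  for (i in 1:50) {
    d <- rhs_full(rand_state(), rates)
    expect_lte(d[["C"]], 0)
    expect_lte(d[["P"]], 0)
  }
})

test_that("dimensionless RHS is the change of variables of the dimensional RHS", {
  set.seed(11)
  for (i in 1:20) {
    k1 <- stats::runif(1, 0.5, 2)
    eps <- stats::runif(1, 5e-3, 5e-2)
    beta <- stats::runif(1, 0.3, 1.5)
    gamma <- stats::runif(1, 0.3, 1.5)
    rates <- rate_constants(k1, eps^2 * k1, eps * gamma * k1, eps^2 * beta * k1)
    c0 <- stats::runif(1, 1e-3, 1e-2)
    mix <- mixture_spec(c0 = c0, p0 = stats::runif(1, 1e-3, 2e-2),
                        n0 = stats::runif(1, 0.2, 2) * c0,
                        phi = stats::runif(1, 0.05, 0.45))
    if (mix$iota0 >= c0) next
    par <- build_dimensionless(rates, mix)
    st_star <- c(Pstar = stats::runif(1, 0.1, 1), Qstar = stats::runif(1, 0, 0.3),
                 Cstar = stats::runif(1, 0.1, 1), Istar = stats::runif(1, 0, 0.3))
    st_dim <- dim_state(st_star, mix)
    d_dim <- rhs_full(st_dim, rates)
    d_star <- rhs_nondim(st_star, par)
    # transport the dimensional derivative through the scalings (dt* = k1 c0 dt)
    expect_equal(d_star[["Pstar"]], d_dim[["P"]] / (mix$p0 * k1 * c0),
                 tolerance = 1e-12)
    expect_equal(d_star[["Qstar"]], d_dim[["Q"]] / (mix$n0 * k1 * c0),
                 tolerance = 1e-12)
    expect_equal(d_star[["Cstar"]], d_dim[["C"]] / (c0 * k1 * c0),
                 tolerance = 1e-12)
    expect_equal(d_star[["Istar"]], d_dim[["I"]] / (mix$n0 * k1 * c0),
                 tolerance = 1e-12)
  }
})

test_that("degenerate iodide (Dstar = 0) shuts down the slow reaction", {
  par <- par_mhp()
  d <- rhs_nondim(c(Pstar = 1, Qstar = 0, Cstar = 1, Istar = 0.5), par)
  expect_equal(d[["Qstar"]], 0)
  expect_equal(d[["Istar"]], -0.5 * 1)
  # mixing initial condition reproduces (1, 0, 1, phi)
  expect_equal(unname(init_nondim(par)), c(1, 0, 1, 0.2))
})

test_that("analytic Jacobian of the dimensionless RHS matches finite differences", {
  par <- par_hhp()
  st <- c(Pstar = 0.7, Qstar = 0.2, Cstar = 0.5, Istar = 0.1)
  J <- clockkin:::jac_nondim(st, par)
  for (j in seq_along(st)) {
    fd <- num_deriv(function(x) {
      s2 <- st; s2[j] <- x; rhs_nondim(s2, par)
    }, st[j], h = 1e-4)
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-8)
  }
})

test_that("clock conversions are exact and invertible", {
  eps <- 1e-2
  expect_equal(clock_convert(1, "T", "tstar", eps), 1e4)
  expect_equal(clock_convert(1, "tau", "tstar", eps), 1e2)
  expect_equal(clock_convert(clock_convert(3.7, "T", "tau", eps), "tau", "T", eps), 3.7)
  expect_equal(clock_convert(1, "T", "seconds", eps, k1 = 663, c0 = 2.3e-3),
               1 / (eps^2 * 663 * 2.3e-3))
  est <- switchover_estimate(2, "T", "mhp_formula", "M-HP", epsilon = eps)
  expect_equal(switchover_in(est, "tau")$value, 2 / eps)
  expect_error(clock_convert(1, "T", "seconds", eps), "k1")
})
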