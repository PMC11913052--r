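test_that("induction constants match direct evaluation and stay real", {
  par <- par_hhp()
  cst <- hhp_constants(par)
  expect_equal(cst$a, 2.0, tolerance = 1e-12)
  expect_equal(cst$a^2 - 4 * par$gamma * par$sigma * par$rho_hat, 1.984,
               tolerance = 1e-12)
  expect_equal(cst$b, sqrt(1.984) / 2, tolerance = 1e-12)
  expect_equal(cst$b, 0.704275, tolerance = 1e-5)
  expect_equal(cst$Q0ss, (cst$a - 2 * cst$b) / (2 * par$gamma * par$sigma),
               tolerance = 1e-12)
  expect_equal(cst$Q0ss, 0.52808, tolerance = 1e-4)
  # discriminant positivity identity over random parameters
  set.seed(5)
  for (i in 1:30) {
    g <- stats::runif(1, 0.1, 3); s <- stats::runif(1, 0.1, 3)
    be <- stats::runif(1, 0.01, 3); rh <- stats::runif(1, 0.1, 3)
    a <- rh + g * s + be * rh
    expect_equal(a^2 - 4 * g * s * rh, (rh * (be - 1) + g * s)^2 + 4 * be * rh^2,
                 tolerance = 1e-12)
  }
})

test_that("induction profiles satisfy their governing equations pointwise", {
  par <- par_hhp()
  cst <- hhp_constants(par)
  g <- par$gamma; s <- par$sigma; be <- par$beta; rh <- par$rho_hat
  Q0 <- function(tau) clockkin:::hhp_Q0(tau, cst, par)
  C0 <- function(tau) clockkin:::hhp_C0(tau, cst, par)
  expect_equal(Q0(0), 0, tolerance = 1e-14)
  expect_equal(C0(0), 1 - s * par$phi, tolerance = 1e-12)
  expect_equal(Q0(50), cst$Q0ss, tolerance = 1e-12)
  for (tau in seq(0.2, 6, by = 0.9)) {
    # dQ0/dtau = rho_hat (1-Q0) - gamma sigma (1-Q0) Q0 - beta rho_hat Q0 (P0 = 1)
    resQ <- num_deriv(Q0, tau) -
      (rh * (1 - Q0(tau)) - g * s * (1 - Q0(tau)) * Q0(tau) - be * rh * Q0(tau))
    expect_lt(abs(resQ), 1e-9)
    # dC0/dtau = -sigma*Itilde0*C0 with Itilde0*C0 = gamma sigma (1-Q0) Q0
    resC <- num_deriv(C0, tau) + s * g * s * (1 - Q0(tau)) * Q0(tau)
    expect_lt(abs(resC), 1e-9)
  }
})

test_that("initial adjustment matches the moderate regime with linear Q growth", {
  par <- par_hhp()
  r0 <- eval_region_hhp("I", 0, par)
  expect_equal(unlist(r0[c("Pstar", "Qstar", "Cstar", "Istar")]),
               c(Pstar = 1, Qstar = 0, Cstar = 1, Istar = 0.2))
  # large t: Qtilde ~ rho_hat * t
  tl <- c(40, 80)
  tab <- eval_region_hhp("I", tl, par)
  slope <- diff(tab$Qstar / par$epsilon) / diff(tl)
  expect_equal(slope, par$rho_hat, tolerance = 1e-10)
  # region II at tau = 0 takes over region I's asymptote
  ii0 <- eval_region_hhp("II", 0, par)
  expect_equal(ii0$Qstar, 0, tolerance = 1e-14)
  expect_equal(ii0$Cstar, 0.84, tolerance = 1e-12)
})

test_that("three switchover approximations are ordered by their derivations", {
  par <- par_hhp()
  cst <- hhp_constants(par)
  full <- switchover_hhp(par, "full")$value
  # the full formula solves C0(tau) = 0 up to the tanh/cosh large-argument
  # approximation, accurate to ~exp(-2 b tau_sw)
  root <- stats::uniroot(function(tau) clockkin:::hhp_C0(tau, cst, par),
                         c(1, 30), tol = 1e-13)$root
  expect_equal(full, root, tolerance = 1e-5)
  # simplified agrees with full within the documented neglected terms
  # when sigma is small compared with 4*(1+beta)
  for (s in c(0.05, 0.1, 0.2, 0.4)) {
    p <- nondim_params(1e-2, 0.6, 0.7, s, 0.2, rho_hat = 0.9)
    f <- switchover_hhp(p, "full")$value
    si <- switchover_hhp(p, "simplified")$value
    bound <- (s / (4 * (1 + p$beta))) / (1 - s * p$phi)
    expect_lt(abs(f - si) / f, bound)
  }
  # dimensional heuristic at bench high-peroxide concentrations
  rates <- default_rates(k2 = 0.0663)
  mix <- mixture_spec(c0 = 6.3e-3, p0 = 0.12, n0 = 6.6e-3, phi = 0.158)
  tsw <- switchover_hhp(mix = mix, rates = rates, method = "heuristic")
  expect_equal(tsw$value, 100.1, tolerance = 1e-3)
  expect_gt(tsw$value, 23); expect_lt(tsw$value, 190)
  # boundary: no vitamin C surplus after the initial adjustment (only
  # reachable for raw concentration lists; the mixture invariant iota0 < c0
  # already excludes it upstream)
  mix0 <- list(c0 = 1.0e-3, p0 = 0.12, n0 = 6.6e-3, phi = 0.158)
  expect_error(switchover_hhp(mix = mix0, rates = rates, method = "heuristic"),
               "insufficient vitamin C")
})

test_that("terminal equilibrium eigenstructure matches a numerical Jacobian", {
  par <- par_hhp()
  eig <- equilibrium_eigenvalues_hhp(par)
  expect_equal(eig$values, c(0, -0.9 * 1.6))
  # finite-difference Jacobian of the (Q, I) terminal system at (0, 1/2)
  f <- function(y) clockkin:::terminal_rhs_hhp(c(Q = y[1], I = y[2]), par)
  J <- matrix(0, 2, 2)
  for (j in 1:2)
    J[, j] <- num_deriv(function(x) {
      y <- c(0, 0.5); y[j] <- x; f(y)
    }, c(0, 0.5)[j], h = 1e-5)
  ev <- sort(Re(eigen(J)$values))
  expect_equal(ev, c(-1.44, 0), tolerance = 1e-7)
  # beta = 0 specializes the nonzero eigenvalue to -rho_hat
  par0 <- nondim_params(1e-2, 1e-9, 0.7, 0.8, 0.2, rho_hat = 0.9)
  expect_equal(equilibrium_eigenvalues_hhp(par0)$values[2], -0.9,
               tolerance = 1e-6)
})

test_that("terminal dynamics approach (0, 1/2) along the slow manifold", {
  par <- par_hhp()
  cst <- hhp_constants(par)
  tt <- cst$tau_sw + seq(0, 400, by = 20)
  td <- integrate_terminal_hhp(par, tt)
  n <- nrow(td)
  # approach is algebraic, Q ~ (1+beta)/(2 beta gamma sigma taut)
  expect_equal(td$Q[n], 0, tolerance = 1e-2)
  expect_equal(td$I[n], 0.5, tolerance = 1e-2)
  # slow-manifold tangent: (I - 1/2)/Q -> -(1+beta)/2
  expect_equal((td$I[n] - 0.5) / td$Q[n], -(1 + par$beta) / 2, tolerance = 1e-2)
  # the approximate closed form tracks it with error shrinking in time
  approx <- eval_region_hhp("IV", tt, par)
  errs <- abs(approx$Istar - td$I)
  expect_lt(errs[n], errs[6])
  expect_lt(errs[n], 2e-3)
})

test_that("composite solution is near-continuous and its peroxide drift shrinks with epsilon", {
  par <- par_hhp()
  bnd <- clockkin:::hhp_boundaries(par)
  jumps <- vapply(bnd, function(b) {
    l <- composite_hhp(b * (1 - 1e-9), par)
    r <- composite_hhp(b * (1 + 1e-9), par)
    max(abs(unlist(l[c("Pstar", "Qstar", "Cstar", "Istar")]) -
              unlist(r[c("Pstar", "Qstar", "Cstar", "Istar")])))
  }, numeric(1))
  expect_lt(max(jumps), 2 * sqrt(par$epsilon))
  # late-time peroxide drift from the constant leading order decreases with eps
  drift <- vapply(c(1e-2, 1e-3), function(eps) {
    p <- par_hhp(eps)
    tl <- (hhp_constants(p)$tau_sw + 20) / eps
    tr <- integrate_nondim(p, times = c(0, tl),
                           settings = solver_settings(t_end = tl))
    abs(tr$Pstar[2] - 1)
  }, numeric(1))
  expect_lt(drift[2], drift[1])
})

test_that("regime guards reject moderate-peroxide inputs", {
  parm <- par_mhp()
  expect_error(hhp_constants(parm), "H-HP")
  expect_error(eval_region_hhp("II", 1, parm), "H-HP")
  expect_error(switchover_hhp(parm), "H-HP")
})
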