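test_that("region I starts at the mixing state and relaxes to the adjusted one", {
  par <- par_mhp()
  r0 <- eval_region_mhp("I", 0, par)
  expect_equal(unlist(r0[c("Pstar", "Qstar", "Cstar", "Istar")]),
               c(Pstar = 1, Qstar = 0, Cstar = 1, Istar = 0.2))
  # t -> infinity: a proportion sigma*phi of the vitamin C is consumed
  rinf <- eval_region_mhp("I", 60, par)
  expect_equal(rinf$Cstar, 1 - 0.8 * 0.2, tolerance = 1e-12)
  expect_equal(rinf$Istar, 0, tolerance = 1e-12)
})

test_that("region Ia limits agree with an independent integration of its ODEs", {
  par <- par_mhp()
  g <- par$gamma; s <- par$sigma; r <- par$rho
  ria <- eval_region_mhp("Ia", 60, par)
  expect_equal(ria$Qstar / par$epsilon, r / (g * s), tolerance = 1e-10)
  expect_equal(ria$Qstar / par$epsilon, 3.571428571, tolerance = 1e-6)
  expect_equal(ria$Istar / par$epsilon^2, r / (1 - s * par$phi), tolerance = 1e-10)
  expect_equal(ria$Istar / par$epsilon^2, 2.380952381, tolerance = 1e-6)
  # oracle: integrate dQt/dtau = rho - gamma*sigma*Qt from 0 and compare
  out <- deSolve::lsoda(c(Q = 0), seq(0, 3, by = 0.5),
                        function(t, y, p) list(r - g * s * y), NULL,
                        rtol = 1e-12, atol = 1e-14)
  tab <- eval_region_mhp("Ia", out[, "time"], par)
  expect_equal(tab$Qstar / par$epsilon, unname(out[, "Q"]), tolerance = 1e-8)
})

test_that("asymptotic matching chain holds across all five regions", {
  par <- par_mhp()
  e <- par$epsilon
  cst <- mhp_constants(par)
  # region I (t -> inf) equals region Ia (tau -> 0)
  i_end <- eval_region_mhp("I", 80, par)
  ia_0 <- eval_region_mhp("Ia", 0, par)
  expect_equal(i_end$Cstar, ia_0$Cstar, tolerance = 1e-8)
  expect_equal(i_end$Istar, ia_0$Istar, tolerance = 1e-8)
  expect_equal(i_end$Qstar, ia_0$Qstar, tolerance = 1e-8)
  # region Ia (tau -> inf) equals region II (T -> 0)
  ia_end <- eval_region_mhp("Ia", 80, par)
  ii_0 <- eval_region_mhp("II", 0, par)
  for (s in c("Pstar", "Qstar", "Cstar", "Istar"))
    expect_equal(ia_end[[s]], ii_0[[s]], tolerance = 1e-8)
  # region II at Tsw equals region III constants (P, Q) and C -> 0
  ii_sw <- eval_region_mhp("II", cst$Tsw, par)
  iii <- eval_region_mhp("III", 0, par)
  expect_equal(ii_sw$Pstar, iii$Pstar, tolerance = 1e-10)
  expect_equal(ii_sw$Qstar, iii$Qstar, tolerance = 1e-10)
  expect_equal(ii_sw$Cstar, 0, tolerance = 1e-12)
  # region III far field C -> -rho_bar*tbar (matches the region II slope)
  tb <- -30
  c_far <- eval_region_mhp("III", tb, par)$Cstar / e
  expect_equal(c_far / (-cst$rho_bar * tb), 1, tolerance = 1e-2)
  # region III (tbar -> +inf) meets region IV at Tsw: C -> 0, I -> 0, P -> b1
  iv_sw <- eval_region_mhp("IV", cst$Tsw, par)
  expect_equal(iv_sw$Pstar, cst$b1, tolerance = 1e-12)
  expect_equal(iv_sw$Istar, 0, tolerance = 1e-12)
})

test_that("corner closed form satisfies its Riccati equation pointwise", {
  par <- par_mhp()
  cst <- mhp_constants(par)
  f <- function(tb) clockkin:::riccati_corner(cst$rho_bar, tb)
  for (tb in seq(-3, 3, by = 0.75)) {
    lhs <- num_deriv(f, tb)
    rhs <- -(cst$rho_bar * tb + f(tb)) * f(tb)
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})

test_that("switchover formula matches arithmetic and responds monotonically", {
  par <- par_mhp()
  expect_equal(switchover_mhp(par)$value, 1.25 * log(2 / 1.16), tolerance = 1e-12)
  expect_equal(switchover_mhp(par)$value, 0.6809, tolerance = 1e-4)
  # abundant peroxide shortens the induction toward zero
  rhos <- c(2, 5, 20, 200)
  tsws <- vapply(rhos, function(r)
    switchover_mhp(nondim_params(1e-2, 0.6, 0.7, 0.8, 0.2, rho = r))$value,
    numeric(1))
  expect_true(all(diff(tsws) < 0))
  expect_lt(tsws[4], 0.01)
  expect_error(switchover_mhp(nondim_params(1e-2, 0.6, 0.7, 0.8, 0.2, rho = 0.5)),
               "insufficient oxidant")

  # dimensional form at bench moderate-regime concentrations
  rates <- default_rates(k2 = 0.0663)
  mix <- mixture_spec(c0 = 2.3e-3, p0 = 6.7e-3, n0 = 7.6e-3, phi = 0.158)
  tsw <- switchover_mhp(mix = mix, rates = rates)
  expect_equal(tsw$value, 355.6, tolerance = 1e-3)
  expect_gt(tsw$value, 60); expect_lt(tsw$value, 700)
  # monotone: more peroxide -> earlier, more vitamin C -> later
  mix_p <- mixture_spec(c0 = 2.3e-3, p0 = 8e-3, n0 = 7.6e-3, phi = 0.158)
  mix_c <- mixture_spec(c0 = 3e-3, p0 = 6.7e-3, n0 = 7.6e-3, phi = 0.158)
  expect_lt(switchover_mhp(mix = mix_p, rates = rates)$value, tsw$value)
  expect_gt(switchover_mhp(mix = mix_c, rates = rates)$value, tsw$value)
  expect_error(switchover_mhp(mix = mixture_spec(c0 = 8e-3, p0 = 1e-3,
                                                 n0 = 7.6e-3, phi = 0.158),
                              rates = rates), "insufficient oxidant")
})

test_that("terminal dichotomy is equivalent to the dimensional peroxide condition", {
  rates <- default_rates()
  set.seed(3)
  for (i in 1:20) {
    c0 <- stats::runif(1, 1e-3, 8e-3)
    n0 <- stats::runif(1, 2e-3, 1e-2)
    phi <- stats::runif(1, 0.05, 0.3)
    if (phi * n0 >= c0) next
    mix <- mixture_spec(c0 = c0, p0 = stats::runif(1, 1e-3, 1.2e-2),
                        n0 = n0, phi = phi)
    par <- build_dimensionless(rates, mix, threshold = Inf)
    if (par$rho + par$sigma * par$phi - 1 <= 0) next
    cst <- mhp_constants(par)
    lhs <- 2 * par$rho * cst$b1 - par$sigma > 0
    rhs <- mix$p0 > mix$n0 / 2 + mix$c0 - mix$iota0
    expect_identical(lhs, rhs)
  }
})

test_that("region II clamps vitamin C past the switchover with a flag", {
  par <- par_mhp()
  cst <- mhp_constants(par)
  tab <- eval_region_mhp("II", c(0.5, 1.5) * cst$Tsw, par)
  expect_true(attr(tab, "clamped"))
  expect_equal(tab$Cstar[2], 0)
  expect_true(is.na(tab$Istar[2]))
})

test_that("composite solution is near-continuous at handoffs and reaches its limits", {
  for (eps in c(1e-2, 1e-3)) {
    par <- par_mhp(eps)
    bnd <- clockkin:::mhp_boundaries(par)
    jumps <- vapply(bnd, function(b) {
      l <- composite_mhp(b * (1 - 1e-9), par)
      r <- composite_mhp(b * (1 + 1e-9), par)
      max(abs(unlist(l[c("Pstar", "Qstar", "Cstar", "Istar")]) -
                unlist(r[c("Pstar", "Qstar", "Cstar", "Istar")])))
    }, numeric(1))
    # handoffs sit at geometric timescale midpoints, where adjacent
    # expansions differ by O(sqrt(eps))
    expect_lt(max(jumps), 2 * sqrt(eps))
  }
  par <- par_mhp()
  cst <- mhp_constants(par)
  far <- composite_mhp((cst$Tsw + 40) / par$epsilon^2, par)
  expect_equal(far$Istar, 0.5, tolerance = 1e-6)   # 2*rho*b1 - sigma > 0 here
  expect_equal(far$Pstar, (2 * par$rho * cst$b1 - par$sigma) / (2 * par$rho),
               tolerance = 1e-6)
  expect_identical(far$region, "IV")
})
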