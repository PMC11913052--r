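# log(cosh(x) + c*sinh(x)) evaluated without overflow for x >= 0.
log_cosh_mix <- function(x, c) {
  x + log((1 + c) / 2 + (1 - c) / 2 * exp(-2 * x))
}

# arctanh for |x| > 1 via the principal log form 0.5*log((x+1)/(x-1));
# equals the usual arctanh continuation needed by the tanh-addition identity.
arctanh_recip <- function(x) 0.5 * log((x + 1) / (x - 1))

#' Matching constants of the high-peroxide asymptotic solution
#'
#' Constants of the high-peroxide (\code{rho = rho_hat/epsilon}) regions:
#' the induction-period Riccati coefficients \code{a = rho_hat + gamma*sigma
#' + beta*rho_hat} and \code{b = sqrt(a^2 - 4*gamma*sigma*rho_hat)/2}
#' (always real, since \code{a^2 - 4*gamma*sigma*rho_hat =
#' (rho_hat*(beta-1) + gamma*sigma)^2 + 4*beta*rho_hat^2}); the matching
#' constant \code{c5 = arctanh(a/2b)/b} (computed by the real log form,
#' as \code{a/2b > 1}); the vitamin C integration constants \code{w1, w2,
#' w3, c6}; the corner-region hypoiodous-acid steady state \code{Q0ss =
#' (a - 2b)/(2*gamma*sigma)}; the corner Riccati coefficient \code{mu2 =
#' gamma*sigma^2*(1 - Q0ss)*Q0ss} (the value for which the corner problem
#' reduces to the same Riccati template as the moderate-peroxide corner,
#' with far field matching the induction slope \code{w1*b + w3 =
#' -mu2}); \code{c7 = 0}; the full-formula switchover time \code{tau_sw};
#' and the terminal-dynamics matching constant \code{c8}.
#'
#' @param par a \code{\link{nondim_params}} object with regime
#'   \code{"H-HP"}.
#' @return A list of constants.
#' @export
hhp_constants <- function(par) {
  if (par$regime != "H-HP") stop("high-peroxide constants require regime H-HP")
  s <- par$sigma; g <- par$gamma; be <- par$beta; rh <- par$rho_hat
  phi <- par$phi
  a <- rh + g * s + be * rh
  disc <- a^2 - 4 * g * s * rh
  b <- sqrt(disc) / 2
  w1 <- -(1 + be) * rh / g
  w2 <- -2 * s * rh / a
  w3 <- rh * ((1 + be) * (g * s + rh * (1 + be)) - 2 * g * s) / (2 * g)
  Q0ss <- (a - 2 * b) / (2 * g * s)
  mu2 <- g * s^2 * (1 - Q0ss) * Q0ss
  denom <- w1 * b + w3
  numer <- -w1 * log(0.5 + a / (4 * b)) + w2 * a / (2 * b + a) - 1 + s * phi
  tau_sw <- if (denom < 0 && numer < 0) numer / denom else NA_real_
  list(a = a, b = b, c5 = arctanh_recip(a / (2 * b)) / b,
       w1 = w1, w2 = w2, w3 = w3, c6 = 1 - s * phi - w2,
       Q0ss = Q0ss, mu2 = mu2, c7 = 0,
       tau_sw = tau_sw,
       c8 = if (is.na(tau_sw)) NA_real_ else
         (1 + be)^2 - 2 * be * g * s * tau_sw)
}

# Induction-period hypoiodous acid profile Q0(tau) (order 1 in H-HP).
hhp_Q0 <- function(tau, cst, par) {
  g <- par$gamma; s <- par$sigma
  th <- tanh(cst$b * tau)
  -cst$b / (g * s) * (2 * cst$b * th + cst$a) / (2 * cst$b + cst$a * th) +
    cst$a / (2 * g * s)
}

# Induction-period vitamin C profile C0(tau).
hhp_C0 <- function(tau, cst, par) {
  s <- par$sigma; phi <- par$phi
  th <- tanh(cst$b * tau)
  cst$w1 * log_cosh_mix(cst$b * tau, cst$a / (2 * cst$b)) -
    cst$w2 * cst$a * th / (2 * cst$b + cst$a * th) +
    cst$w3 * tau + 1 - s * phi
}

#' Leading-order high-peroxide solution in one asymptotic region
#'
#' Evaluates the closed-form leading-order solution of the high-peroxide
#' model in one of its four matched regions, in starred variables. Clocks:
#' \describe{
#'   \item{I}{initial adjustment, \code{t = tstar}; hypoiodous acid grows
#'     linearly (\code{Qstar = epsilon*Qtilde})}
#'   \item{II}{induction period, \code{tau = epsilon*tstar}; \code{Qstar}
#'     order 1, iodine order \code{epsilon}}
#'   \item{III}{corner, \code{taubar = (epsilon*tstar - tau_sw)/sqrt(epsilon)};
#'     vitamin C and iodine order \code{sqrt(epsilon)}}
#'   \item{IV}{terminal equilibration, \code{tautilde = epsilon*tstar};
#'     approximate closed form, accurate near the equilibrium
#'     \code{(Q, I) = (0, 1/2)}}
#' }
#' In region II the vitamin C profile is clamped at zero beyond the
#' switchover and iodine is \code{NA} there (the order-\code{epsilon}
#' expression diverges).
#'
#' @param region one of \code{"I", "II", "III", "IV"}.
#' @param time numeric vector in the region's clock.
#' @param par a \code{\link{nondim_params}} with regime \code{"H-HP"}.
#' @return Data frame with columns \code{time, Pstar, Qstar, Cstar, Istar,
#'   region}; region clock in the \code{"clock"} attribute.
#' @export
eval_region_hhp <- function(region, time, par) {
  region <- match.arg(region, c("I", "II", "III", "IV"))
  if (par$regime != "H-HP") stop("eval_region_hhp requires regime H-HP")
  e <- par$epsilon; s <- par$sigma; g <- par$gamma
  be <- par$beta; rh <- par$rho_hat; phi <- par$phi
  cst <- hhp_constants(par)
  clamped <- FALSE
  out <- switch(region,
    I = {
      ci <- region1_CI(time, s, phi)
      k <- 1 - s * phi
      Qt <- rh * time - (2 * rh / s) * log(1 - s * phi * exp(-k * time)) +
        (2 * rh / s) * log(1 - s * phi)
      data.frame(time = time, Pstar = 1, Qstar = e * Qt,
                 Cstar = ci$C0, Istar = ci$I0)
    },
    II = {
      Q0 <- hhp_Q0(time, cst, par)
      C0 <- hhp_C0(time, cst, par)
      clamped <- any(C0 < 0)
      I1 <- ifelse(C0 > 0, g * s * (1 - Q0) * Q0 / C0, NA_real_)
      data.frame(time = time, Pstar = 1, Qstar = Q0,
                 Cstar = pmax(C0, 0), Istar = e * I1)
    },
    III = {
      Cb <- riccati_corner(cst$mu2, time)
      data.frame(time = time, Pstar = 1, Qstar = cst$Q0ss,
                 Cstar = sqrt(e) * Cb,
                 Istar = sqrt(e) * (Cb + cst$mu2 * time) / s)
    },
    IV = {
      if (is.na(cst$tau_sw)) stop("degenerate parameters: no H-HP switchover")
      den <- 2 * be * g * s * (time - cst$tau_sw) + (1 + be)^2
      data.frame(time = time, Pstar = 1,
                 Qstar = (1 + be) / den,
                 Cstar = 0,
                 Istar = 0.5 * (2 * be * g * s * (time - cst$tau_sw)) / den)
    })
  out$region <- region
  attr(out, "clock") <- switch(region, I = "tstar", II = "tau",
                               III = "taubar", IV = "tautilde")
  attr(out, "clamped") <- clamped
  out
}

#' High-peroxide switchover-time formulae
#'
#' Three nested approximations to the induction time in the high-peroxide
#' regime, in the \code{tau = epsilon*tstar} clock:
#' \describe{
#'   \item{full}{root of the induction-period vitamin C profile under the
#'     large-\code{b*tau} approximation:
#'     \code{tau_sw = (-w1*log(1/2 + a/4b) + w2*a/(2b+a) - 1 + sigma*phi) /
#'     (w1*b + w3)}.}
#'   \item{simplified}{drops numerator terms bounded by
#'     \code{sigma/(4*(1+beta))}: \code{tau_sw = 2*gamma*(1 - sigma*phi) /
#'     (rho_hat*((1+beta)*(2b - a) + 2*gamma*sigma))}.}
#'   \item{heuristic}{additionally keeps only the dominant denominator term:
#'     \code{tau_sw = (1 - sigma*phi)/(sigma*rho_hat)}; dimensionally
#'     \code{tsw = (c0 - phi*n0)/(k2*n0*p0)} seconds — the two-parameter
#'     form used for data fitting.}
#' }
#' Call with \code{par} for the dimensionless value, or with \code{mix} and
#' \code{rates} for the dimensional heuristic.
#'
#' @param par a \code{\link{nondim_params}} with regime \code{"H-HP"}.
#' @param method \code{"full"}, \code{"simplified"} or \code{"heuristic"}.
#' @param mix,rates dimensional inputs for the heuristic formula in seconds.
#' @return A \code{\link{switchover_estimate}} (clock \code{"tau"}, or
#'   \code{"seconds"} for dimensional input).
#' @export
switchover_hhp <- function(par = NULL,
                           method = c("full", "simplified", "heuristic"),
                           mix = NULL, rates = NULL) {
  method <- match.arg(method)
  if (is.null(par)) {
    if (is.null(mix) || is.null(rates))
      stop("supply either par, or both mix and rates")
    if (method != "heuristic")
      stop("dimensional evaluation is provided for the heuristic formula; ",
           "use a nondim_params input for full/simplified")
    surplus <- mix$c0 - mix$phi * mix$n0
    if (surplus <= 0)
      stop("insufficient vitamin C after initial adjustment (c0 <= phi*n0)")
    tsw <- surplus / (rates$k2 * mix$n0 * mix$p0)
    return(switchover_estimate(tsw, clock = "seconds",
                               method = "hhp_heuristic", regime = "H-HP",
                               epsilon = sqrt(rates$k2 / rates$k1)))
  }
  if (par$regime != "H-HP") stop("switchover_hhp requires regime H-HP")
  s <- par$sigma; phi <- par$phi
  if (1 - s * phi <= 0)
    stop("insufficient vitamin C after initial adjustment (sigma*phi >= 1)")
  cst <- hhp_constants(par)
  val <- switch(method,
    full = {
      if (is.na(cst$tau_sw))
        stop("degenerate parameters: w1*b + w3 must be negative with a ",
             "negative numerator")
      cst$tau_sw
    },
    simplified = 2 * par$gamma * (1 - s * phi) /
      (par$rho_hat * ((1 + par$beta) * (2 * cst$b - cst$a) + 2 * par$gamma * s)),
    heuristic = (1 - s * phi) / (s * par$rho_hat))
  switchover_estimate(val, clock = "tau",
                      method = paste0("hhp_", if (method == "full") "full" else method),
                      regime = "H-HP", epsilon = par$epsilon)
}

#' Eigenstructure of the high-peroxide terminal equilibrium
#'
#' The post-switchover \code{(Q0, I0)} dynamics have a single equilibrium at
#' \code{(0, 1/2)} (all iodide and hypoiodous acid converted to iodine) with
#' eigenvalues \code{0} and \code{-rho_hat*(1+beta)}. The zero eigenvalue
#' corresponds to the slow manifold tangent to \code{(2s, 1/2 - (1+beta)s)};
#' the stable manifold is tangent to \code{(1, 0)} (outside the physical
#' domain).
#'
#' @param par a \code{\link{nondim_params}} with regime \code{"H-HP"}.
#' @return List with \code{values} (eigenvalues, slow first),
#'   \code{slow_tangent} and \code{stable_tangent}.
#' @export
equilibrium_eigenvalues_hhp <- function(par) {
  if (par$regime != "H-HP") stop("requires regime H-HP")
  list(values = c(0, -par$rho_hat * (1 + par$beta)),
       slow_tangent = c(2, -(1 + par$beta)),
       stable_tangent = c(1, 0))
}

# RHS of the terminal (region IV) reduced system in the tautilde clock.
terminal_rhs_hhp <- function(y, par) {
  s <- par$sigma; g <- par$gamma; be <- par$beta; rh <- par$rho_hat
  Dst <- 1 - y[["Q"]] - 2 * y[["I"]]
  c(Q = rh * Dst - g * s * Dst * y[["Q"]] - be * rh * y[["Q"]],
    I = g * s * Dst * y[["Q"]])
}

#' Numerical terminal dynamics of the high-peroxide regime
#'
#' The post-switchover \code{(Q0, I0)} system has no closed-form solution;
#' this integrates it numerically from induction-matched initial data
#' (\code{Q = Q0ss}, \code{I = 0} at \code{tautilde = tau_sw} by default),
#' complementing the approximate closed form of region IV.
#'
#' @param par a \code{\link{nondim_params}} with regime \code{"H-HP"}.
#' @param times output times in the \code{tautilde = epsilon*tstar} clock.
#' @param init named vector \code{c(Q=, I=)}; default the induction match.
#' @return Data frame with columns \code{time, Q, I}.
#' @export
integrate_terminal_hhp <- function(par, times, init = NULL) {
  cst <- hhp_constants(par)
  if (is.null(init)) init <- c(Q = cst$Q0ss, I = 0)
  fn <- function(t, y, p) list(terminal_rhs_hhp(y, par))
  out <- deSolve::lsoda(y = init, times = times, func = fn, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  as.data.frame(unclass(out))
}

# Region handoff boundaries for the H-HP composite, in the tstar clock.
hhp_boundaries <- function(par) {
  e <- par$epsilon
  tau_sw <- hhp_constants(par)$tau_sw
  c(I_II = e^-0.5,
    II_III = (tau_sw - e^0.25) / e,
    III_IV = (tau_sw + e^0.25) / e)
}

#' Composite leading-order high-peroxide solution
#'
#' Piecewise leading-order solution across regions I--IV at times in the
#' fast clock \code{tstar}. Handoffs at \code{tstar = epsilon^-1/2} and at
#' \code{|tau - tau_sw| = epsilon^1/4} around the corner (geometric
#' midpoints of adjacent timescales). The leading-order peroxide profile is
#' constant at 1; numerically a drift of order \code{sqrt(epsilon)} develops
#' at late time, which this order cannot capture.
#'
#' @param tstar numeric vector of times (fast clock), nonnegative.
#' @param par a \code{\link{nondim_params}} with regime \code{"H-HP"}.
#' @return A \code{clock_trajectory} (tstar clock) with a \code{region}
#'   column.
#' @export
composite_hhp <- function(tstar, par) {
  bnd <- hhp_boundaries(par)
  e <- par$epsilon
  tau_sw <- hhp_constants(par)$tau_sw
  region <- cut(tstar, breaks = c(-Inf, bnd, Inf),
                labels = c("I", "II", "III", "IV"), right = TRUE)
  pieces <- lapply(levels(region), function(rg) {
    ts <- tstar[region == rg]
    if (length(ts) == 0) return(NULL)
    tt <- switch(rg, I = ts, II = e * ts,
                 III = (e * ts - tau_sw) / sqrt(e), IV = e * ts)
    df <- eval_region_hhp(rg, tt, par)
    df$time <- ts
    df
  })
  df <- do.call(rbind, pieces)
  df <- df[order(df$time), ]
  rownames(df) <- NULL
  make_trajectory(df, clock = "tstar", params = par,
                  extra = list(boundaries = bnd))
}
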