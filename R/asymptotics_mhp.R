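# Error function via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Corner-region Riccati profile: the solution of dC/dt = -(r*t + C)*C that
# approaches -r*t as t -> -inf, C = sqrt(2r/pi) exp(-r t^2/2)/(erf(sqrt(r/2) t)+1).
# Evaluated in logs for stability deep in the far field (the denominator is
# 2*pnorm(sqrt(r)*t)).
riccati_corner <- function(r, t) {
  exp(0.5 * log(2 * r / pi) - r * t^2 / 2 - log(2) -
        stats::pnorm(sqrt(r) * t, log.p = TRUE))
}

# Shared region-I (initial adjustment) leading-order profiles: the fast
# reaction converts the bulk of the iodine to iodide, consuming a fraction
# sigma*phi of the vitamin C. Identical in both peroxide regimes.
region1_CI <- function(t, sigma, phi) {
  k <- 1 - sigma * phi
  E <- exp(-k * t)
  I0 <- phi * k * E / (1 - sigma * phi * E)
  list(C0 = sigma * (I0 - phi) + 1, I0 = I0)
}

#' Matching constants of the moderate-peroxide asymptotic solution
#'
#' Derived constants used by the region III (corner) and region IV
#' (equilibration) closed forms: \code{rho_bar = sigma*(rho + sigma*phi - 1)}
#' (corner Riccati coefficient), \code{b1 = (rho + sigma*phi - 1)/rho} (the
#' peroxide fraction remaining after induction), the region IV matching
#' constant \code{b2}, the induction switchover time \code{Tsw}, and the
#' fixed matching constants \code{c1 = c2 = 0}, \code{c4 = 1}.
#'
#' @param par a \code{\link{nondim_params}} object (any regime tag; the
#'   constants only require \code{rho + sigma*phi - 1 > 0}).
#' @return A list of constants.
#' @export
mhp_constants <- function(par) {
  s <- par$sigma; r <- par$rho; phi <- par$phi
  excess <- r + s * phi - 1
  if (excess <= 0)
    stop("insufficient oxidant: requires rho + sigma*phi - 1 > 0 (p0 + phi*n0 > c0)")
  Tsw <- (1 / s) * log(r / excess)
  b1 <- excess / r
  k <- 2 * r * b1 - s
  b2 <- if (k != 0) -Tsw + log(b1 / s) / k else NA_real_
  list(rho_bar = s * excess, b1 = b1, b2 = b2, Tsw = Tsw,
       c1 = 0, c2 = 0, c4 = 1)
}

#' Leading-order moderate-peroxide solution in one asymptotic region
#'
#' Evaluates the closed-form leading-order solution of the moderate-peroxide
#' model in one of its five matched regions, returning starred
#' (dimensionless) variables. Each region has its own clock:
#' \describe{
#'   \item{I}{initial adjustment, \code{t = tstar}}
#'   \item{Ia}{hypoiodous-acid quasi-equilibrium, \code{tau = epsilon*tstar}}
#'   \item{II}{induction period, \code{T = epsilon^2*tstar}}
#'   \item{III}{corner, \code{tbar = (epsilon^2*tstar - Tsw)/epsilon}}
#'   \item{IV}{equilibration, \code{T = epsilon^2*tstar}}
#' }
#' Hypoiodous acid is order \code{epsilon} throughout this regime
#' (\code{Qstar = epsilon*Qtilde}); iodine is order \code{epsilon^2} in
#' regions Ia and II and order \code{epsilon} in region III. In region II the
#' vitamin C profile is clamped at zero beyond \code{Tsw} (flagged via the
#' \code{"clamped"} attribute) and iodine, which diverges at the switchover
#' at this order, is \code{NA} there.
#'
#' @param region one of \code{"I", "Ia", "II", "III", "IV"}.
#' @param time numeric vector in the region's clock.
#' @param par a \code{\link{nondim_params}} object.
#' @return Data frame with columns \code{time, Pstar, Qstar, Cstar, Istar,
#'   region}; the region clock is stored in the \code{"clock"} attribute.
#' @export
eval_region_mhp <- function(region, time, par) {
  region <- match.arg(region, c("I", "Ia", "II", "III", "IV"))
  e <- par$epsilon; s <- par$sigma; g <- par$gamma; r <- par$rho; phi <- par$phi
  if (s * phi >= 1) stop("requires sigma*phi < 1")
  clamped <- FALSE
  out <- switch(region,
    I = {
      ci <- region1_CI(time, s, phi)
      data.frame(time = time, Pstar = 1, Qstar = 0,
                 Cstar = ci$C0, Istar = ci$I0)
    },
    Ia = {
      grow <- 1 - exp(-g * s * time)
      data.frame(time = time, Pstar = 1,
                 Qstar = e * r / (g * s) * grow,
                 Cstar = 1 - s * phi,
                 Istar = e^2 * r / (1 - s * phi) * grow)
    },
    II = {
      cst <- mhp_constants(par)
      Ep <- exp(-s * time)
      C0 <- r * Ep + (1 - s * phi - r)
      clamped <- any(C0 < 0)
      I2 <- ifelse(C0 > 0, r * Ep / C0, NA_real_)
      data.frame(time = time, Pstar = Ep,
                 Qstar = e * r / (g * s) * Ep,
                 Cstar = pmax(C0, 0), Istar = e^2 * I2)
    },
    III = {
      cst <- mhp_constants(par)
      Cb <- riccati_corner(cst$rho_bar, time)
      data.frame(time = time, Pstar = cst$b1,
                 Qstar = e * (r + s * phi - 1) / (g * s),
                 Cstar = e * Cb,
                 Istar = e * (Cb + cst$rho_bar * time) / s)
    },
    IV = {
      cst <- mhp_constants(par)
      k <- 2 * r * cst$b1 - s
      Ex <- exp(-k * (time - cst$Tsw))
      P0 <- k / (2 * r - (s / cst$b1) * Ex)
      I0 <- r * cst$b1 * (1 - Ex) / (2 * r * cst$b1 - s * Ex)
      data.frame(time = time, Pstar = P0,
                 Qstar = e * r / (g * s) * P0,
                 Cstar = 0, Istar = I0)
    })
  out$region <- region
  attr(out, "clock") <- switch(region, I = "tstar", Ia = "tau",
                               II = "T", III = "tbar", IV = "T")
  attr(out, "clamped") <- clamped
  out
}

#' Moderate-peroxide switchover-time formula
#'
#' The induction-period solution predicts vitamin C exhaustion at
#' \code{Tsw = (1/sigma) * log(rho / (rho + sigma*phi - 1))} in the
#' \code{T = epsilon^2 tstar} clock, or dimensionally
#' \code{tsw = 1/(k2*n0) * log(p0 / (p0 + phi*n0 - c0))} seconds. The
#' formula requires sufficient combined oxidant, \code{p0 + phi*n0 > c0}.
#'
#' Call either with a dimensionless parameter set (\code{par}), or with a
#' \code{mix} and \code{rates} pair for the dimensional result.
#'
#' @param par a \code{\link{nondim_params}} object.
#' @param mix,rates dimensional inputs (\code{\link{mixture_spec}},
#'   \code{\link{rate_constants}}); used when \code{par} is NULL.
#' @return A \code{\link{switchover_estimate}} (clock \code{"T"}, or
#'   \code{"seconds"} for dimensional input; method \code{"mhp_formula"}).
#' @export
switchover_mhp <- function(par = NULL, mix = NULL, rates = NULL) {
  if (!is.null(par)) {
    cst <- mhp_constants(par)
    return(switchover_estimate(cst$Tsw, clock = "T", method = "mhp_formula",
                               regime = "M-HP", epsilon = par$epsilon))
  }
  if (is.null(mix) || is.null(rates))
    stop("supply either par, or both mix and rates")
  denom <- mix$p0 + mix$phi * mix$n0 - mix$c0
  if (denom <= 0)
    stop("insufficient oxidant: requires p0 + phi*n0 > c0")
  tsw <- log(mix$p0 / denom) / (rates$k2 * mix$n0)
  switchover_estimate(tsw, clock = "seconds", method = "mhp_formula",
                      regime = "M-HP", epsilon = sqrt(rates$k2 / rates$k1))
}

# Region handoff boundaries for the M-HP composite, in the tstar clock:
# geometric midpoints of adjacent timescales.
mhp_boundaries <- function(par) {
  e <- par$epsilon
  Tsw <- mhp_constants(par)$Tsw
  c(I_Ia = e^-0.5, Ia_II = e^-1.5,
    II_III = (Tsw - sqrt(e)) / e^2, III_IV = (Tsw + sqrt(e)) / e^2)
}

#' Composite leading-order moderate-peroxide solution
#'
#' Piecewise leading-order solution across regions I, Ia, II, III and IV,
#' evaluated at times given in the fast-reaction clock \code{tstar}. Region
#' handoffs are placed at geometric midpoints of adjacent timescales
#' (\code{tstar = epsilon^-1/2}, \code{epsilon^-3/2}, and
#' \code{|T - Tsw| = sqrt(epsilon)} around the corner).
#'
#' @param tstar numeric vector of times (fast clock), nonnegative.
#' @param par a \code{\link{nondim_params}} object with
#'   \code{rho + sigma*phi - 1 > 0}.
#' @return A \code{clock_trajectory} (tstar clock) with a \code{region}
#'   column.
#' @export
composite_mhp <- function(tstar, par) {
  bnd <- mhp_boundaries(par)
  e <- par$epsilon
  region <- cut(tstar, breaks = c(-Inf, bnd, Inf),
                labels = c("I", "Ia", "II", "III", "IV"), right = TRUE)
  pieces <- lapply(levels(region), function(rg) {
    ts <- tstar[region == rg]
    if (length(ts) == 0) return(NULL)
    tt <- switch(rg, I = ts, Ia = e * ts, II = e^2 * ts,
                 III = (e^2 * ts - mhp_constants(par)$Tsw) / e, IV = e^2 * ts)
    df <- eval_region_mhp(rg, tt, par)
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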