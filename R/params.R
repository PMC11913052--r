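#' Second-order rate constants of the clock-reaction network
#'
#' Bundles the four bimolecular rate constants of the iodine / vitamin C /
#' hydrogen peroxide network: the fast iodine--vitamin C reduction (\code{k1}),
#' the rate-limiting production of hypoiodous acid from iodide and peroxide
#' (\code{k2}), the conversion of iodide and hypoiodous acid to molecular
#' iodine (\code{k3}), and the slow reverse reduction of hypoiodous acid by
#' peroxide (\code{k4}). All constants are second order, in l mol^-1 s^-1.
#'
#' The asymptotic analysis assumes the ordering \code{k2, k4 << k3 << k1}.
#' The constructor does not enforce it; \code{\link{build_dimensionless}}
#' reports the implied disparity parameter instead.
#'
#' @param k1,k2,k3,k4 strictly positive rate constants (l mol^-1 s^-1).
#' @return An object of class \code{"rate_constants"}.
#' @seealso [default_rates()], [build_dimensionless()]
#' @export
rate_constants <- function(k1, k2, k3, k4) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all rate constants must be finite and strictly positive")
  structure(as.list(vals), class = "rate_constants")
}

#' Default rate constants consistent with a chosen rate disparity
#'
#' The switchover-time data determine only \code{k2}; the remaining constants
#' are conventions needed for full time-course simulation. They are derived
#' from \code{k2} and the dimensionless groups \code{epsilon^2 = k2/k1},
#' \code{beta = k4/k2} and \code{gamma = k3/(epsilon*k1)}. Defaults reproduce
#' a rate disparity of 1e-2 and order-one \code{beta}, \code{gamma}.
#'
#' @param k2 rate constant of the hypoiodous-acid producing step
#'   (l mol^-1 s^-1).
#' @param epsilon rate disparity parameter, \code{sqrt(k2/k1)}.
#' @param beta ratio \code{k4/k2}.
#' @param gamma scaled ratio \code{k3/(epsilon*k1)}.
#' @return A \code{"rate_constants"} object.
#' @export
default_rates <- function(k2 = 0.0663, epsilon = 1e-2, beta = 0.6, gamma = 0.7) {
  k1 <- k2 / epsilon^2
  rate_constants(k1 = k1, k2 = k2, k3 = epsilon * gamma * k1, k4 = beta * k2)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (l mol^-1 s^-1):\n")
  cat(sprintf("  k1 = %g  k2 = %g  k3 = %g  k4 = %g\n", x$k1, x$k2, x$k3, x$k4))
  cat(sprintf("  implied epsilon = sqrt(k2/k1) = %g\n", sqrt(x$k2 / x$k1)))
  invisible(x)
}

#' Initial reaction mixture
#'
#' Initial concentrations (mol l^-1) of iodide (\code{d0}), hydrogen peroxide
#' (\code{p0}), hypoiodous acid (\code{q0}, zero in all analysed settings),
#' vitamin C (\code{c0}) and molecular iodine (\code{iota0}). The total atomic
#' iodine \code{n0 = 2*iota0 + d0} and the iodine fraction
#' \code{phi = iota0/n0} are derived. Alternatively \code{n0} and \code{phi}
#' may be given in place of \code{d0} and \code{iota0}.
#'
#' The analysis requires \code{iota0 < c0} (the initial vitamin C survives the
#' initial adjustment; nondimensionally \code{sigma*phi < 1}).
#'
#' @param c0 initial vitamin C concentration (> 0).
#' @param p0 initial hydrogen peroxide concentration (>= 0).
#' @param d0 initial iodide concentration (>= 0).
#' @param iota0 initial molecular iodine concentration (>= 0).
#' @param n0,phi alternative parameterization: total atomic iodine and iodine
#'   fraction; used when \code{d0}/\code{iota0} are missing.
#' @param q0 initial hypoiodous acid concentration; nonzero values are
#'   accepted but flagged with a warning as outside the analysed regime.
#' @return An object of class \code{"mixture_spec"} with fields
#'   \code{d0, p0, q0, c0, iota0, n0, phi}.
#' @export
mixture_spec <- function(c0, p0, d0 = NULL, iota0 = NULL, n0 = NULL, phi = NULL,
                         q0 = 0) {
  if (is.null(d0) || is.null(iota0)) {
    if (is.null(n0) || is.null(phi))
      stop("supply either (d0, iota0) or (n0, phi)")
    iota0 <- phi * n0
    d0 <- n0 - 2 * iota0
    if (d0 < 0) stop("phi > 1/2 implies negative iodide concentration")
  }
  n0 <- 2 * iota0 + d0
  vals <- c(d0 = d0, p0 = p0, q0 = q0, c0 = c0, iota0 = iota0)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("all concentrations must be finite and nonnegative")
  if (c0 <= 0) stop("c0 must be strictly positive")
  if (n0 <= 0) stop("n0 = 2*iota0 + d0 must be strictly positive")
  if (iota0 >= c0)
    stop("initial iodine exceeds vitamin C (iota0 >= c0, i.e. sigma*phi >= 1)")
  if (q0 != 0)
    warning("nonzero q0 lies outside the analysed regime (q0 = 0 assumed there)")
  structure(list(d0 = d0, p0 = p0, q0 = q0, c0 = c0, iota0 = iota0,
                 n0 = n0, phi = iota0 / n0),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Mixture (mol l^-1):\n")
  cat(sprintf("  d0 = %g  p0 = %g  q0 = %g  c0 = %g  iota0 = %g\n",
              x$d0, x$p0, x$q0, x$c0, x$iota0))
  cat(sprintf("  n0 = %g  phi = %g  p0/n0 = %g\n", x$n0, x$phi, x$p0 / x$n0))
  invisible(x)
}

#' Classify the hydrogen-peroxide regime of a mixture
#'
#' A mixture is moderate-peroxide (\code{"M-HP"}) when \code{p0/n0 <= threshold}
#' and high-peroxide (\code{"H-HP"}) otherwise. The default threshold 1.5 is
#' the (arbitrary) dispatch value used when routing experiments to the two
#' switchover-time formulae.
#'
#' @param mix a \code{\link{mixture_spec}}, or a list with \code{p0},\code{n0}.
#' @param threshold dimensionless dispatch threshold on \code{p0/n0}.
#' @return \code{"M-HP"} or \code{"H-HP"}.
#' @export
classify_regime <- function(mix, threshold = 1.5) {
  if (mix$n0 <= 0) stop("n0 must be positive")
  if (mix$p0 / mix$n0 <= threshold) "M-HP" else "H-HP"
}

#' Dimensionless parameter group of the clock-reaction model
#'
#' Direct constructor for the dimensionless parameters
#' \code{epsilon} (rate disparity, \code{epsilon^2 = k2/k1}),
#' \code{beta = k4/k2}, \code{gamma = k3/(epsilon*k1)},
#' \code{sigma = n0/c0}, \code{rho = p0/c0} and the iodine fraction
#' \code{phi}. In the high-peroxide regime \code{rho} is order
#' \code{1/epsilon} and is carried as \code{rho_hat = epsilon*rho}.
#' Exactly one of \code{rho}, \code{rho_hat} must be given; the other is
#' derived. See \code{\link{build_dimensionless}} to obtain the group from
#' dimensional inputs.
#'
#' @param epsilon rate-disparity parameter in (0, 1).
#' @param beta,gamma,sigma,phi order-one dimensionless parameters.
#' @param rho peroxide-to-vitamin C ratio \code{p0/c0} (moderate regime).
#' @param rho_hat \code{epsilon*rho} (high regime).
#' @param regime \code{"M-HP"}, \code{"H-HP"} or \code{NULL} to infer from
#'   which of \code{rho}/\code{rho_hat} was supplied.
#' @return An object of class \code{"nondim_params"}.
#' @export
nondim_params <- function(epsilon, beta, gamma, sigma, phi,
                          rho = NULL, rho_hat = NULL, regime = NULL) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  if (any(c(beta, gamma, sigma) <= 0)) stop("beta, gamma, sigma must be positive")
  if (phi < 0 || phi > 0.5) stop("phi must lie in [0, 1/2]")
  if (is.null(rho) == is.null(rho_hat))
    stop("supply exactly one of rho, rho_hat")
  if (is.null(rho)) {
    rho <- rho_hat / epsilon
    if (is.null(regime)) regime <- "H-HP"
  } else {
    rho_hat <- epsilon * rho
    if (is.null(regime)) regime <- "M-HP"
  }
  if (rho < 0) stop("rho must be nonnegative")
  regime <- match.arg(regime, c("M-HP", "H-HP"))
  if (sigma * phi >= 1)
    stop("initial iodine exceeds vitamin C (sigma*phi >= 1)")
  structure(list(epsilon = epsilon, beta = beta, gamma = gamma, sigma = sigma,
                 phi = phi, rho = rho, rho_hat = rho_hat, regime = regime),
            class = "nondim_params")
}

#' @export
print.nondim_params <- function(x, ...) {
  cat(sprintf("Dimensionless parameters [%s]:\n", x$regime))
  cat(sprintf("  epsilon = %g  beta = %g  gamma = %g  sigma = %g  phi = %g\n",
              x$epsilon, x$beta, x$gamma, x$sigma, x$phi))
  cat(sprintf("  rho = %g  (rho_hat = %g)\n", x$rho, x$rho_hat))
  invisible(x)
}

#' Nondimensionalize rates and mixture
#'
#' Maps dimensional rate constants and initial concentrations to the
#' dimensionless group: \code{epsilon = sqrt(k2/k1)}, \code{beta = k4/k2},
#' \code{gamma = k3/(epsilon*k1)}, \code{sigma = n0/c0}, \code{rho = p0/c0},
#' \code{phi = iota0/n0}. The regime tag follows \code{\link{classify_regime}}
#' on \code{p0/n0}.
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @param mix a \code{\link{mixture_spec}} object.
#' @param threshold regime dispatch threshold on \code{p0/n0}.
#' @return A \code{\link{nondim_params}} object.
#' @export
build_dimensionless <- function(rates, mix, threshold = 1.5) {
  eps <- sqrt(rates$k2 / rates$k1)
  regime <- classify_regime(mix, threshold)
  if (regime == "M-HP")
    nondim_params(epsilon = eps, beta = rates$k4 / rates$k2,
                  gamma = rates$k3 / (eps * rates$k1),
                  sigma = mix$n0 / mix$c0, phi = mix$phi,
                  rho = mix$p0 / mix$c0, regime = regime)
  else
    nondim_params(epsilon = eps, beta = rates$k4 / rates$k2,
                  gamma = rates$k3 / (eps * rates$k1),
                  sigma = mix$n0 / mix$c0, phi = mix$phi,
                  rho_hat = eps * mix$p0 / mix$c0, regime = regime)
}

#' Re-dimensionalize a dimensionless parameter group
#'
#' Inverse of \code{\link{build_dimensionless}} given the two dimensional
#' anchors that the nondimensionalization removes: \code{k1} and \code{c0}.
#'
#' @param par a \code{\link{nondim_params}} object.
#' @param k1 fast-reaction rate constant (l mol^-1 s^-1).
#' @param c0 initial vitamin C concentration (mol l^-1).
#' @return A list with elements \code{rates} and \code{mix}.
#' @export
dimensionalize <- function(par, k1, c0) {
  eps <- par$epsilon
  rates <- rate_constants(k1 = k1, k2 = eps^2 * k1,
                          k3 = eps * par$gamma * k1,
                          k4 = eps^2 * par$beta * k1)
  n0 <- par$sigma * c0
  mix <- mixture_spec(c0 = c0, p0 = par$rho * c0, n0 = n0, phi = par$phi)
  list(rates = rates, mix = mix)
}
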