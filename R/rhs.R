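#' Mass-action right-hand side of the five-species dimensional model
#'
#' Time derivatives (mol l^-1 s^-1) of iodide \code{D}, hydrogen peroxide
#' \code{P}, hypoiodous acid \code{Q}, vitamin C \code{C} and molecular iodine
#' \code{I} under the law of mass action for the fast reaction
#' (I + C -> 2D, rate k1), the two slow-reaction steps
#' (D + P -> Q, rate k2; D + Q -> I, rate k3) and the reverse reduction
#' (Q + P -> D, rate k4). Atomic iodine is conserved:
#' \code{dD + dQ + 2*dI = 0} holds exactly for every input.
#'
#' @param state named numeric vector with components \code{D, P, Q, C, I}
#'   (mol l^-1), all nonnegative.
#' @param rates a \code{\link{rate_constants}} object.
#' @return Named numeric vector of derivatives \code{(D, P, Q, C, I)}.
#' @export
rhs_full <- function(state, rates) {
  D <- state[["D"]]; P <- state[["P"]]; Q <- state[["Q"]]
  C <- state[["C"]]; I <- state[["I"]]
  k1 <- rates$k1; k2 <- rates$k2; k3 <- rates$k3; k4 <- rates$k4
  c(D = -k2 * D * P - k3 * D * Q + k4 * Q * P + 2 * k1 * I * C,
    P = -k2 * D * P - k4 * Q * P,
    Q =  k2 * D * P - k3 * D * Q - k4 * Q * P,
    C = -k1 * I * C,
    I =  k3 * D * Q - k1 * I * C)
}

#' Right-hand side of the dimensionless reduced model
#'
#' Time derivatives of the dimensionless state \code{(Pstar, Qstar, Cstar,
#' Istar)} in the fast-reaction clock \code{t* = k1*c0*t}, with the iodide
#' fraction eliminated by conservation, \code{Dstar = 1 - Qstar - 2*Istar}.
#' Note the asymmetric prefactors: production terms in the \code{Pstar}
#' equation carry \code{epsilon^2*sigma} while those in the \code{Qstar}
#' equation carry \code{epsilon^2*rho}, because peroxide is scaled with
#' \code{p0} and hypoiodous acid with \code{n0}.
#'
#' @param state named numeric vector \code{(Pstar, Qstar, Cstar, Istar)}.
#' @param par a \code{\link{nondim_params}} object.
#' @return Named numeric vector of derivatives.
#' @export
rhs_nondim <- function(state, par) {
  P <- state[["Pstar"]]; Q <- state[["Qstar"]]
  C <- state[["Cstar"]]; I <- state[["Istar"]]
  e <- par$epsilon; s <- par$sigma; r <- par$rho; b <- par$beta; g <- par$gamma
  Dst <- 1 - Q - 2 * I
  c(Pstar = -e^2 * s * Dst * P - e^2 * b * s * Q * P,
    Qstar =  e^2 * r * Dst * P - e * g * s * Dst * Q - e^2 * b * r * Q * P,
    Cstar = -s * I * C,
    Istar =  e * g * s * Dst * Q - I * C)
}

# Analytic Jacobian of rhs_nondim; used by the stiff solver.
jac_nondim <- function(state, par) {
  P <- state[["Pstar"]]; Q <- state[["Qstar"]]
  C <- state[["Cstar"]]; I <- state[["Istar"]]
  e <- par$epsilon; s <- par$sigma; r <- par$rho; b <- par$beta; g <- par$gamma
  Dst <- 1 - Q - 2 * I
  matrix(c(
    # dP/d(P,Q,C,I)
    -e^2 * s * Dst - e^2 * b * s * Q,  e^2 * s * P - e^2 * b * s * P, 0, 2 * e^2 * s * P,
    # dQ/d(P,Q,C,I)
    e^2 * r * Dst - e^2 * b * r * Q,  -e^2 * r * P - e * g * s * (Dst - Q) - e^2 * b * r * P,
    0, -2 * e^2 * r * P + 2 * e * g * s * Q,
    # dC/d(P,Q,C,I)
    0, 0, -s * I, -s * C,
    # dI/d(P,Q,C,I)
    0, e * g * s * (Dst - Q), -I, -2 * e * g * s * Q - C),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("Pstar", "Qstar", "Cstar", "Istar"),
                    c("Pstar", "Qstar", "Cstar", "Istar")))
}

#' Convert a dimensional state to starred variables (and back)
#'
#' Applies the scalings \code{P = p0*Pstar}, \code{Q = n0*Qstar},
#' \code{C = c0*Cstar}, \code{I = n0*Istar}; iodide maps to the conserved
#' fraction \code{Dstar = D/n0}.
#'
#' @param state named numeric vector (\code{D,P,Q,C,I} for
#'   \code{nondim_state}; \code{Pstar,Qstar,Cstar,Istar} for
#'   \code{dim_state}).
#' @param mix a \code{\link{mixture_spec}} providing the scales.
#' @return Named numeric vector in the other variable set.
#' @export
nondim_state <- function(state, mix) {
  c(Pstar = state[["P"]] / mix$p0,
    Qstar = state[["Q"]] / mix$n0,
    Cstar = state[["C"]] / mix$c0,
    Istar = state[["I"]] / mix$n0)
}

#' @rdname nondim_state
#' @export
dim_state <- function(state, mix) {
  Q <- state[["Qstar"]] * mix$n0
  I <- state[["Istar"]] * mix$n0
  c(D = mix$n0 - Q - 2 * I,
    P = state[["Pstar"]] * mix$p0,
    Q = Q,
    C = state[["Cstar"]] * mix$c0,
    I = I)
}

#' Initial dimensionless state
#'
#' The mixing initial condition \code{(Pstar, Qstar, Cstar, Istar) =
#' (1, 0, 1, phi)}.
#'
#' @param par a \code{\link{nondim_params}} object.
#' @return Named numeric vector.
#' @export
init_nondim <- function(par) {
  c(Pstar = 1, Qstar = 0, Cstar = 1, Istar = par$phi)
}
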