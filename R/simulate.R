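#' Stiff-solver settings
#'
#' The reaction network spans rate ratios of \code{1/epsilon^2} (1e4 at
#' epsilon = 1e-2), so implicit adaptive stepping is required. Defaults use
#' tight tolerances because switchover-time convergence studies measure
#' relative errors down to about 1e-3.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (scalar or per-species).
#' @param t_end end time in the fast-reaction clock \code{tstar}; default
#'   \code{10/epsilon^2} covers the equilibration region, which lives on the
#'   \code{T = epsilon^2*tstar} scale.
#' @param max_steps maximum internal steps between output times.
#' @param n_out number of output times on a logarithmic grid.
#' @return Object of class \code{"solver_settings"}.
#' @export
solver_settings <- function(rtol = 1e-10, atol = 1e-12, t_end = NULL,
                            max_steps = 1e5, n_out = 400) {
  if (rtol <= 0 || any(atol <= 0)) stop("tolerances must be positive")
  if (!is.null(t_end) && t_end <= 0) stop("t_end must be positive")
  structure(list(rtol = rtol, atol = atol, t_end = t_end,
                 max_steps = max_steps, n_out = n_out),
            class = "solver_settings")
}

# Assemble a trajectory data.frame with metadata attributes.
make_trajectory <- function(df, clock, params = NULL, settings = NULL,
                            extra = list()) {
  stopifnot(!is.unsorted(df$time))
  attr(df, "clock") <- clock
  attr(df, "params") <- params
  attr(df, "settings") <- settings
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("clock_trajectory", class(df))
  df
}

# Clamp tiny solver undershoots below zero; warn if beyond tolerance.
clamp_nonneg <- function(m, atol) {
  neg <- m < 0
  if (any(neg)) {
    worst <- min(m[neg])
    if (worst < -10 * max(atol))
      warning(sprintf("solver undershoot clamped to zero (worst %.3e)", worst))
    m[neg] <- 0
  }
  m
}

#' Integrate the dimensionless clock-reaction model
#'
#' Solves the reduced dimensionless system with an adaptive implicit
#' (stiff) method (\code{deSolve::lsodar}) using the analytic Jacobian.
#' When \code{root_threshold} is supplied, integration stops at the first
#' time the vitamin C fraction \code{Cstar} falls below it, and the crossing
#' time found by the solver's root location is stored in the
#' \code{"root_time"} attribute.
#'
#' @param par a \code{\link{nondim_params}} object.
#' @param init initial state; default \code{\link{init_nondim}(par)}.
#' @param settings a \code{\link{solver_settings}} object.
#' @param times output times in the \code{tstar} clock; default a logarithmic
#'   grid on \code{[0, t_end]}.
#' @param root_threshold optional threshold on \code{Cstar} for root-stopping.
#' @return A \code{clock_trajectory}: data.frame with columns \code{time,
#'   Pstar, Qstar, Cstar, Istar, Dstar} (time in \code{tstar}), with solver
#'   metadata and any located root time as attributes.
#' @export
integrate_nondim <- function(par, init = NULL, settings = solver_settings(),
                             times = NULL, root_threshold = NULL) {
  if (is.null(init)) init <- init_nondim(par)
  t_end <- settings$t_end
  if (is.null(t_end)) t_end <- 10 / par$epsilon^2
  if (is.null(times)) {
    n <- if (is.null(root_threshold)) settings$n_out else 40L
    times <- c(0, 10^seq(-2, log10(t_end), length.out = n))
  }
  fn <- function(t, y, p) list(rhs_nondim(y, par))
  jac <- function(t, y, p) jac_nondim(y, par)
  if (is.null(root_threshold)) {
    out <- deSolve::lsoda(y = init, times = times, func = fn, parms = NULL,
                          jacfunc = jac, jactype = "fullusr",
                          rtol = settings$rtol, atol = settings$atol,
                          maxsteps = settings$max_steps)
    root_time <- NULL
  } else {
    if (init[["Cstar"]] <= root_threshold)
      stop("no switchover: Cstar(0) does not exceed the threshold")
    rootfn <- function(t, y, p) y[["Cstar"]] - root_threshold
    out <- deSolve::lsodar(y = init, times = times, func = fn, parms = NULL,
                           jacfunc = jac, jactype = "fullusr",
                           rootfunc = rootfn,
                           rtol = settings$rtol, atol = settings$atol,
                           maxsteps = settings$max_steps)
    root_time <- attr(out, "troot")
    if (length(root_time) == 0) root_time <- NULL
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("stiff solver failed with istate %d at t = %g",
                 istate[1], max(out[, "time"])))
  m <- as.data.frame(unclass(out))
  m[-1] <- clamp_nonneg(as.matrix(m[-1]), settings$atol)
  m$Dstar <- pmax(1 - m$Qstar - 2 * m$Istar, 0)
  make_trajectory(m, clock = "tstar", params = par, settings = settings,
                  extra = list(root_time = root_time,
                               root_threshold = root_threshold))
}

#' Integrate the five-species dimensional model
#'
#' Solves the full mass-action system (iodide, peroxide, hypoiodous acid,
#' vitamin C, iodine) in seconds. The conservation residual of atomic iodine
#' \code{D + Q + 2I} relative to \code{n0} is recorded.
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @param mix a \code{\link{mixture_spec}} object.
#' @param times output times in seconds; default logarithmic grid to
#'   \code{t_end}.
#' @param t_end end time in seconds (used when \code{times} is NULL);
#'   default covers the equilibration scale \code{10/(k2*c0)}.
#' @param settings a \code{\link{solver_settings}} object.
#' @return A \code{clock_trajectory} with columns \code{time, D, P, Q, C, I}.
#' @export
integrate_dim <- function(rates, mix, times = NULL, t_end = NULL,
                          settings = solver_settings(rtol = 1e-10, atol = 1e-16)) {
  init <- c(D = mix$d0, P = mix$p0, Q = mix$q0, C = mix$c0, I = mix$iota0)
  if (is.null(times)) {
    if (is.null(t_end)) t_end <- 10 / (rates$k2 * mix$c0)
    times <- c(0, 10^seq(log10(t_end) - 8, log10(t_end),
                         length.out = settings$n_out))
  }
  fn <- function(t, y, p) list(rhs_full(y, rates))
  out <- deSolve::lsoda(y = init, times = times, func = fn, parms = NULL,
                        rtol = settings$rtol, atol = settings$atol,
                        maxsteps = settings$max_steps)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("stiff solver failed with istate %d at t = %g",
                 istate[1], max(out[, "time"])))
  m <- as.data.frame(unclass(out))
  m[-1] <- clamp_nonneg(as.matrix(m[-1]), settings$atol)
  traj <- make_trajectory(m, clock = "seconds", params = NULL,
                          settings = settings,
                          extra = list(rates = rates, mix = mix, n0 = mix$n0))
  attr(traj, "conservation") <- conservation_residual(traj)
  traj
}

#' Conservation residual of atomic iodine along a trajectory
#'
#' Maximum relative deviation of \code{D + Q + 2I} from the total atomic
#' iodine \code{n0}. Zero for exact solutions; for stiff-solver output it
#' reflects the integration tolerances.
#'
#' @param traj a dimensional \code{clock_trajectory} (from
#'   \code{\link{integrate_dim}}).
#' @param n0 total atomic iodine (mol l^-1); defaults to the trajectory's
#'   recorded value.
#' @return Nonnegative scalar, \code{max |(D+Q+2I) - n0| / n0}.
#' @export
conservation_residual <- function(traj, n0 = NULL) {
  if (!all(c("D", "Q", "I") %in% names(traj)))
    stop("conservation residual requires a dimensional trajectory (D, Q, I)")
  if (is.null(n0)) n0 <- attr(traj, "n0")
  if (is.null(n0)) stop("n0 not supplied and not recorded on the trajectory")
  max(abs(traj$D + traj$Q + 2 * traj$I - n0)) / n0
}

# Cubic-Hermite refinement of the first down-crossing of Cstar through
# `threshold`, using the exact RHS for endpoint slopes.
hermite_crossing <- function(traj, threshold) {
  par <- attr(traj, "params")
  below <- which(traj$Cstar < threshold)
  if (length(below) == 0)
    stop("no switchover: Cstar never falls below the threshold")
  i1 <- below[1]
  if (i1 == 1) return(traj$time[1])
  i0 <- i1 - 1L
  t0 <- traj$time[i0]; t1 <- traj$time[i1]
  h <- t1 - t0
  y0 <- traj$Cstar[i0]; y1 <- traj$Cstar[i1]
  s0 <- rhs_nondim(unlist(traj[i0, c("Pstar", "Qstar", "Cstar", "Istar")]), par)[["Cstar"]]
  s1 <- rhs_nondim(unlist(traj[i1, c("Pstar", "Qstar", "Cstar", "Istar")]), par)[["Cstar"]]
  hermite <- function(u) { # u in [0,1]
    h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
    h00 * y0 + h10 * h * s0 + h01 * y1 + h11 * h * s1 - threshold
  }
  u <- stats::uniroot(hermite, c(0, 1), tol = 1e-14)$root
  t0 + u * h
}

#' Numerical switchover time from a trajectory
#'
#' First time at which the vitamin C fraction \code{Cstar} falls below a
#' threshold (default the trajectory's \code{epsilon}). If the trajectory was
#' integrated with root-stopping at the same threshold, the solver-located
#' root is used; otherwise the crossing is refined from the output grid by
#' cubic Hermite interpolation with exact endpoint slopes, not by
#' nearest-grid-point lookup.
#'
#' @param traj a dimensionless \code{clock_trajectory}.
#' @param threshold crossing threshold on \code{Cstar}; default
#'   \code{epsilon} of the trajectory parameters.
#' @return A \code{\link{switchover_estimate}} in the \code{tstar} clock
#'   (method \code{"numerical"}).
#' @export
numerical_switchover <- function(traj, threshold = NULL) {
  par <- attr(traj, "params")
  if (is.null(par)) stop("trajectory carries no dimensionless parameters")
  if (is.null(threshold)) threshold <- par$epsilon
  if (traj$Cstar[1] <= threshold)
    stop("no switchover: Cstar(0) does not exceed the threshold")
  rt <- attr(traj, "root_time")
  rthr <- attr(traj, "root_threshold")
  tsw <- if (!is.null(rt) && !is.null(rthr) && isTRUE(all.equal(rthr, threshold)))
    rt[1]
  else
    hermite_crossing(traj, threshold)
  switchover_estimate(tsw, clock = "tstar", method = "numerical",
                      regime = par$regime, epsilon = par$epsilon)
}

#' Convergence of the asymptotic switchover time as epsilon decreases
#'
#' For each value of the rate-disparity parameter on a decreasing grid,
#' integrates the dimensionless system, locates the first crossing of
#' \code{Cstar} below \code{epsilon}, evaluates the regime's asymptotic
#' switchover formula in the same clock, and regresses the logarithm of the
#' relative error \code{|t_num - t_asy|/t_num} on \code{log(epsilon)}.
#' The leading-order theory predicts slope about 1 in the moderate-peroxide
#' regime and a sublinear slope (about 0.4) in the high-peroxide regime.
#'
#' @param base list of order-one parameters: \code{beta, gamma, sigma, phi}
#'   and either \code{rho} (M-HP) or \code{rho_hat} (H-HP).
#' @param regime \code{"M-HP"} or \code{"H-HP"}.
#' @param epsilon_grid decreasing grid of epsilon values (>= 4 points).
#' @param formula asymptotic formula to compare against: \code{"auto"} picks
#'   the regime's induction-period formula (M-HP closed form, or the full
#'   H-HP expression); alternatively \code{"hhp_simplified"}.
#' @param settings solver settings.
#' @return List with \code{slope}, \code{intercept} and a data.frame
#'   \code{table} of \code{epsilon, t_num, t_asy, rel_err} (tstar clock).
#' @export
convergence_slope <- function(base, regime = c("M-HP", "H-HP"),
                              epsilon_grid = 10^seq(-1.5, -3, length.out = 6),
                              formula = c("auto", "hhp_simplified"),
                              settings = solver_settings()) {
  regime <- match.arg(regime)
  formula <- match.arg(formula)
  if (length(epsilon_grid) < 4 || is.unsorted(rev(epsilon_grid)))
    stop("epsilon_grid must be a decreasing grid with at least 4 points")
  rows <- lapply(epsilon_grid, function(eps) {
    par <- if (regime == "M-HP")
      nondim_params(eps, base$beta, base$gamma, base$sigma, base$phi,
                    rho = base$rho, regime = "M-HP")
    else
      nondim_params(eps, base$beta, base$gamma, base$sigma, base$phi,
                    rho_hat = base$rho_hat, regime = "H-HP")
    traj <- tryCatch(
      integrate_nondim(par, settings = settings, root_threshold = eps),
      error = function(e)
        stop(sprintf("no switchover found at epsilon = %g: %s",
                     eps, conditionMessage(e))))
    t_num <- numerical_switchover(traj, threshold = eps)$value
    est <- if (regime == "M-HP") switchover_mhp(par)
           else switchover_hhp(par, method = if (formula == "hhp_simplified")
             "simplified" else "full")
    t_asy <- switchover_in(est, "tstar")$value
    data.frame(epsilon = eps, t_num = t_num, t_asy = t_asy,
               rel_err = abs(t_num - t_asy) / t_num)
  })
  tab <- do.call(rbind, rows)
  if (any(tab$rel_err <= 0))
    stop("zero relative error: asymptotic formula coincides with the numerical crossing")
  fit <- stats::lm(log(rel_err) ~ log(epsilon), data = tab)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       table = tab)
}

#' Export a trajectory as CSV
#'
#' Writes the trajectory with a leading \code{clock} column (and a
#' \code{region} column when present, as produced by the composite
#' asymptotic solutions).
#'
#' @param traj a \code{clock_trajectory}.
#' @param file path to write.
#' @return Invisibly, the written data.frame.
#' @export
write_trajectory_csv <- function(traj, file) {
  df <- as.data.frame(traj)
  df <- cbind(clock = attr(traj, "clock"), df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
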