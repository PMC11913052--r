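# Run expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Design of a synthetic experiment series
#'
#' Describes one bench series: which initial concentration is varied
#' (\code{n0}, \code{c0} or \code{p0}) over a linear grid, the fixed
#' concentrations, the generating truth \code{(phi, k2)}, and a
#' multiplicative lognormal noise level on the observed switchover times.
#' Generation can use the closed-form two-branch model
#' (\code{mode = "formula"}) or a full stiff ODE solve with threshold
#' crossing (\code{mode = "ode"}).
#'
#' @param label series label.
#' @param vary which concentration varies: \code{"n0"}, \code{"c0"} or
#'   \code{"p0"}.
#' @param from,to positive grid bounds (mol l^-1).
#' @param n grid size (>= 3).
#' @param fixed named list of the other two concentrations (mol l^-1).
#' @param truth named vector \code{c(phi =, k2 =)}.
#' @param noise_sd standard deviation of the lognormal measurement noise
#'   (default 0.05, i.e. about 5\% relative scatter).
#' @param mode \code{"formula"} or \code{"ode"}.
#' @param threshold regime dispatch threshold on \code{p0/n0}.
#' @return Object of class \code{"series_design"}.
#' @export
series_design <- function(label, vary = c("n0", "c0", "p0"), from, to, n = 10,
                          fixed = list(), truth = c(phi = 0.158, k2 = 0.0663),
                          noise_sd = 0.05, mode = c("formula", "ode"),
                          threshold = 1.5) {
  vary <- match.arg(vary)
  mode <- match.arg(mode)
  if (from <= 0 || to <= 0) stop("grid bounds must be positive")
  if (n < 3) stop("grid must have at least 3 points")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  need <- setdiff(c("n0", "c0", "p0"), vary)
  if (!all(need %in% names(fixed)))
    stop(sprintf("fixed must supply %s", paste(need, collapse = ", ")))
  structure(list(label = label, vary = vary, from = from, to = to, n = n,
                 fixed = fixed, truth = truth, noise_sd = noise_sd,
                 mode = mode, threshold = threshold),
            class = "series_design")
}

#' Built-in series designs
#'
#' Presets reproducing the concentration ranges of the six bench series:
#' the moderate-peroxide fitting series NM (iodine varied) and CM (vitamin C
#' varied) at \code{p0 ~ 6.7e-3} mol/l; the high-peroxide fitting series NH
#' and CH at \code{p0 ~ 0.12} mol/l; and the peroxide-varied testing series
#' H1 and H2. H2 spans \code{p0/n0} from about 0.9 to 4.8, straddling the
#' regime dispatch threshold.
#'
#' @param label optional label(s) to select; default all six.
#' @param n records per series.
#' @param noise_sd lognormal noise level.
#' @param truth generating parameter truth \code{c(phi =, k2 =)}.
#' @return A named list of \code{\link{series_design}} objects.
#' @export
series_presets <- function(label = NULL, n = 10, noise_sd = 0.05,
                           truth = c(phi = 0.158, k2 = 0.0663)) {
  p <- list(
    NM = series_design("NM", "n0", 6.1e-3, 1.2e-2, n,
                       fixed = list(c0 = 2.3e-3, p0 = 6.7e-3),
                       truth = truth, noise_sd = noise_sd),
    CM = series_design("CM", "c0", 1.8e-3, 7.2e-3, n,
                       fixed = list(n0 = 7.6e-3, p0 = 6.7e-3),
                       truth = truth, noise_sd = noise_sd),
    NH = series_design("NH", "n0", 4.0e-3, 1.2e-2, n,
                       fixed = list(c0 = 6.3e-3, p0 = 0.12),
                       truth = truth, noise_sd = noise_sd),
    CH = series_design("CH", "c0", 2.1e-3, 6.3e-3, n,
                       fixed = list(n0 = 6.6e-3, p0 = 0.12),
                       truth = truth, noise_sd = noise_sd),
    H1 = series_design("H1", "p0", 3.3e-2, 0.17, n,
                       fixed = list(c0 = 6.0e-3, n0 = 7.0e-3),
                       truth = truth, noise_sd = noise_sd),
    H2 = series_design("H2", "p0", 6.7e-3, 3.6e-2, n,
                       fixed = list(c0 = 2.4e-3, n0 = 7.5e-3),
                       truth = truth, noise_sd = noise_sd))
  if (is.null(label)) p else p[label]
}

# Switchover time in seconds from a full dimensional ODE solve with
# threshold crossing at Cstar = epsilon (rates derived from k2 and the
# simulation conventions epsilon, gamma, beta).
tsw_from_ode <- function(c0, n0, p0, phi, k2,
                         epsilon = 1e-2, gamma = 0.7, beta = 0.6) {
  rates <- default_rates(k2 = k2, epsilon = epsilon, beta = beta, gamma = gamma)
  mix <- mixture_spec(c0 = c0, p0 = p0, n0 = n0, phi = phi)
  par <- build_dimensionless(rates, mix)
  traj <- integrate_nondim(par, root_threshold = epsilon)
  est <- numerical_switchover(traj, threshold = epsilon)
  switchover_in(est, "seconds", k1 = rates$k1, c0 = c0)$value
}

#' Generate a synthetic experiment series
#'
#' Builds the concentration grid of a \code{\link{series_design}}, computes
#' model switchover times at the design truth (closed-form two-branch model
#' or full ODE solve), and applies multiplicative lognormal noise:
#' \code{tsw_obs = tsw_model * exp(eta)}, \code{eta ~ N(0, noise_sd^2)}.
#' Grid points violating a formula precondition are dropped with a warning
#' (mirroring infeasible bench mixtures).
#'
#' @param design a \code{\link{series_design}}.
#' @param seed optional integer seed; the ambient RNG stream is used when
#'   NULL and restored otherwise.
#' @return An \code{\link{experiment_records}} data.frame with an extra
#'   column \code{tsw_model} (noise-free model time).
#' @export
generate_series <- function(design, seed = NULL) {
  grid <- seq(design$from, design$to, length.out = design$n)
  conc <- list(n0 = NULL, c0 = NULL, p0 = NULL)
  conc[[design$vary]] <- grid
  for (nm in names(design$fixed)) conc[[nm]] <- rep(design$fixed[[nm]], design$n)
  phi <- design$truth[["phi"]]; k2 <- design$truth[["k2"]]
  mhp <- conc$p0 / conc$n0 <= design$threshold
  tsw_model <- if (design$mode == "formula") {
    tsw_two_branch(conc$c0, conc$n0, conc$p0, phi, k2, mhp)
  } else {
    vapply(seq_len(design$n), function(i)
      tryCatch(tsw_from_ode(conc$c0[i], conc$n0[i], conc$p0[i], phi, k2),
               error = function(e) NA_real_), numeric(1))
  }
  keep <- is.finite(tsw_model) & tsw_model > 0
  if (!any(keep))
    stop(sprintf("series %s: every grid point is infeasible", design$label))
  if (!all(keep))
    warning(sprintf("series %s: dropped %d infeasible grid point(s)",
                    design$label, sum(!keep)))
  tsw_model <- tsw_model[keep]
  eta <- with_seed(seed,
                   stats::rnorm(sum(keep), mean = 0, sd = design$noise_sd))
  rec <- experiment_records(series = design$label,
                            c0 = conc$c0[keep], n0 = conc$n0[keep],
                            p0 = conc$p0[keep],
                            tsw = tsw_model * exp(eta))
  rec$tsw_model <- tsw_model
  rec
}

#' Generate records for several designs at once
#'
#' @param designs a list of \code{\link{series_design}} objects (see
#'   \code{\link{series_presets}}).
#' @param seed optional integer seed for the whole batch.
#' @return A pooled \code{\link{experiment_records}} data.frame.
#' @export
generate_records <- function(designs, seed = NULL) {
  with_seed(seed, {
    out <- do.call(rbind, lapply(designs, generate_series))
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic colour-change intensity trace
#'
#' Emulates the ROI-summed webcam signal around the switchover: a slow
#' linear drift before the colour change, a sharp sigmoidal intensity drop
#' of a few frames' width at \code{tsw}, a post-change plateau, and additive
#' Gaussian sensor noise.
#'
#' @param tsw switchover time (s), strictly inside the recording.
#' @param duration recording length (s).
#' @param fps frame rate (frames per second).
#' @param baseline pre-change intensity level (arbitrary units).
#' @param drift pre-change drift in intensity units per second.
#' @param step magnitude of the intensity drop at the colour change; zero
#'   produces a corner-free trace.
#' @param rise_frames width of the sigmoidal drop, in frames.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param window detector window used for the edge-margin check.
#' @param seed optional integer seed.
#' @return An \code{\link{intensity_trace}}.
#' @export
generate_trace <- function(tsw, duration, fps = 15, baseline = 5e4,
                           drift = -2, step = 2e4, rise_frames = 4,
                           noise_sd = 0, window = 10, seed = NULL) {
  if (tsw <= 0 || tsw >= duration) stop("need 0 < tsw < duration")
  margin <- 2 * window / fps
  if (tsw < margin || tsw > duration - margin)
    stop("tsw too close to the trace edges for corner detection")
  n <- floor(duration * fps) + 1L
  t <- (seq_len(n) - 1L) / fps
  k_sw <- round(tsw * fps)
  sig <- 1 / (1 + exp(-(seq_len(n) - 1L - k_sw) / (rise_frames / 4)))
  s <- baseline + drift * pmin(t, k_sw / fps) - step * sig
  s <- s + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  intensity_trace(s, fps = fps)
}

#' End-to-end parameter-recovery experiment
#'
#' Repeatedly generates synthetic series at a known truth, fits
#' \code{(phi, k2)} by relative least squares, optionally bootstraps BCa
#' intervals, and aggregates bias, RMSE and interval coverage. This is the
#' package's self-test that the whole pipeline (generator, two-branch
#' model, estimator, uncertainty quantification) recovers the parameters it
#' simulates.
#'
#' @param designs list of \code{\link{series_design}}s (default the four
#'   fitting presets NM, CM, NH, CH).
#' @param replicates number of independent synthetic datasets.
#' @param bootstrap_N bootstrap replicates per dataset; 0 skips bootstrap
#'   (no coverage reported).
#' @param level confidence level for coverage.
#' @param seed integer seed governing all randomness.
#' @return Object of class \code{"recovery_report"}: per-replicate
#'   estimates and a summary (relative bias, relative RMSE, median relative
#'   errors, coverage).
#' @export
recovery_experiment <- function(designs = series_presets(c("NM", "CM", "NH", "CH")),
                                replicates = 200, bootstrap_N = 0,
                                level = 0.95, seed = 1) {
  truth <- designs[[1]]$truth
  with_seed(seed, {
    rows <- lapply(seq_len(replicates), function(i) {
      rec <- generate_records(designs)
      fit <- fit_parameters(rec)
      row <- data.frame(replicate = i, phi_hat = fit$phi_hat,
                        k2_hat = fit$k2_hat, loss = fit$loss,
                        converged = fit$converged,
                        phi_cover = NA, k2_cover = NA)
      if (bootstrap_N > 0) {
        fit <- bootstrap_ci(rec, fit, N = bootstrap_N, level = level)
        row$phi_cover <- fit$ci["phi", 1] <= truth[["phi"]] &&
          truth[["phi"]] <= fit$ci["phi", 2]
        row$k2_cover <- fit$ci["k2", 1] <= truth[["k2"]] &&
          truth[["k2"]] <= fit$ci["k2", 2]
      }
      row
    })
    est <- do.call(rbind, rows)
    rel_phi <- est$phi_hat / truth[["phi"]] - 1
    rel_k2 <- est$k2_hat / truth[["k2"]] - 1
    summary <- list(
      truth = truth,
      replicates = replicates,
      bias_rel = c(phi = mean(rel_phi), k2 = mean(rel_k2)),
      rmse_rel = c(phi = sqrt(mean(rel_phi^2)), k2 = sqrt(mean(rel_k2^2))),
      median_abs_rel = c(phi = stats::median(abs(rel_phi)),
                         k2 = stats::median(abs(rel_k2))),
      coverage = c(phi = mean(est$phi_cover), k2 = mean(est$k2_cover)))
    structure(list(estimates = est, summary = summary),
              class = "recovery_report")
  })
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Parameter recovery over %d replicates (truth phi = %g, k2 = %g):\n",
              s$replicates, s$truth[["phi"]], s$truth[["k2"]]))
  cat(sprintf("  relative bias:        phi %+.3g  k2 %+.3g\n",
              s$bias_rel[["phi"]], s$bias_rel[["k2"]]))
  cat(sprintf("  relative RMSE:        phi %.3g  k2 %.3g\n",
              s$rmse_rel[["phi"]], s$rmse_rel[["k2"]]))
  cat(sprintf("  median |rel error|:   phi %.3g  k2 %.3g\n",
              s$median_abs_rel[["phi"]], s$median_abs_rel[["k2"]]))
  if (!all(is.na(s$coverage)))
    cat(sprintf("  CI coverage:          phi %.3g  k2 %.3g\n",
                s$coverage[["phi"]], s$coverage[["k2"]]))
  invisible(x)
}
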