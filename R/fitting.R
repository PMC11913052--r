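#' Clock-experiment records
#'
#' One row per experiment: series label, initial concentrations \code{c0}
#' (vitamin C), \code{n0} (total atomic iodine) and \code{p0} (hydrogen
#' peroxide), all mol l^-1, and the measured switchover time \code{tsw}
#' in seconds.
#'
#' @param series character vector of series labels (e.g. NM, CM, NH, CH,
#'   H1, H2).
#' @param c0,n0,p0 positive initial concentrations (mol l^-1).
#' @param tsw positive measured switchover times (s); may be NA for
#'   prediction-only records.
#' @return A data.frame of class \code{"experiment_records"}.
#' @export
experiment_records <- function(series, c0, n0, p0, tsw = NA_real_) {
  df <- data.frame(series = as.character(series), c0 = c0, n0 = n0, p0 = p0,
                   tsw = tsw)
  if (any(!is.finite(df$c0) | df$c0 <= 0) ||
      any(!is.finite(df$n0) | df$n0 <= 0) ||
      any(!is.finite(df$p0) | df$p0 <= 0))
    stop("concentrations must be finite and strictly positive")
  if (any(!is.na(df$tsw) & df$tsw <= 0))
    stop("measured switchover times must be positive")
  class(df) <- c("experiment_records", class(df))
  df
}

#' Read / write experiment-series CSV
#'
#' Series files use columns \code{series, c0_mol_per_l, n0_mol_per_l,
#' p0_mol_per_l, tsw_s}.
#'
#' @param file path to a CSV file.
#' @param records an \code{\link{experiment_records}} data.frame.
#' @return \code{read_series_csv} returns \code{experiment_records};
#'   \code{write_series_csv} invisibly returns the written data.frame.
#' @export
read_series_csv <- function(file) {
  df <- utils::read.csv(file)
  experiment_records(df$series, df$c0_mol_per_l, df$n0_mol_per_l,
                     df$p0_mol_per_l, df$tsw_s)
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(records, file) {
  df <- data.frame(series = records$series, c0_mol_per_l = records$c0,
                   n0_mol_per_l = records$n0, p0_mol_per_l = records$p0,
                   tsw_s = records$tsw)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

# Vectorized two-branch switchover model; returns NA where the branch
# precondition fails. `mhp` is the logical dispatch mask p0/n0 <= threshold.
tsw_two_branch <- function(c0, n0, p0, phi, k2, mhp) {
  out <- rep(NA_real_, length(c0))
  dd <- p0 + phi * n0 - c0
  i <- which(mhp & dd > 0)
  out[i] <- log(p0[i] / dd[i]) / (k2 * n0[i])
  su <- c0 - phi * n0
  j <- which(!mhp & su > 0)
  out[j] <- su[j] / (k2 * n0[j] * p0[j])
  out
}

#' Predict switchover times with regime dispatch
#'
#' For each record, applies the moderate-peroxide logarithmic formula
#' \code{tsw = log(p0/(p0 + phi*n0 - c0)) / (k2*n0)} when
#' \code{p0/n0 <= threshold}, and the high-peroxide heuristic
#' \code{tsw = (c0 - phi*n0)/(k2*n0*p0)} otherwise. These are the two
#' two-parameter formulae used for fitting and testing.
#'
#' @param records an \code{\link{experiment_records}} data.frame.
#' @param phi iodine fraction, in (0, 1).
#' @param k2 rate constant of the hypoiodous-acid producing step
#'   (l mol^-1 s^-1), positive.
#' @param threshold regime dispatch threshold on \code{p0/n0} (default 1.5).
#' @return Numeric vector of predicted switchover times (s).
#' @export
predict_tsw <- function(records, phi, k2, threshold = 1.5) {
  if (phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)")
  if (k2 <= 0) stop("k2 must be positive")
  mhp <- records$p0 / records$n0 <= threshold
  pred <- tsw_two_branch(records$c0, records$n0, records$p0, phi, k2, mhp)
  if (anyNA(pred)) {
    bad <- which(is.na(pred))
    stop(sprintf(
      "formula precondition failed for record(s) %s (series %s): %s",
      paste(bad, collapse = ", "),
      paste(unique(records$series[bad]), collapse = ", "),
      "M-HP needs p0 + phi*n0 > c0; H-HP needs c0 > phi*n0"))
  }
  pred
}

#' Relative sum-of-squares loss
#'
#' \code{sum(((pred - obs)/obs)^2)} over all records, the loss used to give
#' comparable weight to switchover times spanning more than an order of
#' magnitude.
#'
#' @inheritParams predict_tsw
#' @return Nonnegative scalar; zero iff the fit is perfect.
#' @export
relative_sse <- function(records, phi, k2, threshold = 1.5) {
  pred <- predict_tsw(records, phi, k2, threshold)
  sum(((pred - records$tsw) / records$tsw)^2)
}

# Loss in transformed coordinates (logit phi, log k2) with a finite penalty
# where a branch precondition fails, so the simplex can recover.
make_objective <- function(records, threshold) {
  mhp <- records$p0 / records$n0 <= threshold
  c0 <- records$c0; n0 <- records$n0; p0 <- records$p0; obs <- records$tsw
  function(theta) {
    phi <- stats::plogis(theta[1]); k2 <- exp(theta[2])
    pred <- tsw_two_branch(c0, n0, p0, phi, k2, mhp)
    if (anyNA(pred)) return(1e10)
    sum(((pred - obs) / obs)^2)
  }
}

#' Fit the iodine fraction and rate constant to switchover times
#'
#' Minimizes the relative sum-of-squares \code{\link{relative_sse}} over
#' \code{(phi, k2)} with the Nelder--Mead simplex method. The search runs in
#' transformed coordinates (logit \code{phi}, log \code{k2}) so that the
#' simplex cannot leave the admissible region; the reported estimates are
#' back-transformed. A warning is issued when all records fall on one
#' formula branch (the two parameters then trade off along a ridge).
#'
#' @param records an \code{\link{experiment_records}} data.frame with
#'   measured \code{tsw}.
#' @param init named starting values \code{c(phi =, k2 =)}.
#' @param threshold regime dispatch threshold on \code{p0/n0}.
#' @param control passed to \code{\link[stats]{optim}} (Nelder--Mead);
#'   sensible defaults are supplied.
#' @return Object of class \code{"clock_fit"}: estimates \code{phi_hat},
#'   \code{k2_hat}, the achieved \code{loss}, optimizer diagnostics and the
#'   data and threshold used.
#' @export
fit_parameters <- function(records, init = c(phi = 0.15, k2 = 0.05),
                           threshold = 1.5, control = list()) {
  if (sum(!is.na(records$tsw)) < 2) stop("need at least 2 measured records")
  mhp <- records$p0 / records$n0 <= threshold
  if (all(mhp) || all(!mhp))
    warning("all records fall on a single formula branch; phi and k2 may ",
            "not be jointly identifiable")
  obj <- make_objective(records, threshold)
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 1000), control)
  theta0 <- c(stats::qlogis(init[["phi"]]), log(init[["k2"]]))
  opt <- stats::optim(theta0, obj, method = "Nelder-Mead", control = ctrl)
  structure(list(phi_hat = stats::plogis(opt$par[1]),
                 k2_hat = exp(opt$par[2]),
                 loss = opt$value,
                 converged = opt$convergence == 0,
                 iterations = opt$counts[["function"]],
                 data = records, threshold = threshold, init = init),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("Relative least-squares fit over %d records:\n", nrow(x$data)))
  cat(sprintf("  phi_hat = %.5g  k2_hat = %.5g l mol^-1 s^-1\n",
              x$phi_hat, x$k2_hat))
  cat(sprintf("  loss = %.5g  (converged: %s, %d evaluations)\n",
              x$loss, x$converged, x$iterations))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% BCa CI phi: [%.5g, %.5g]\n", x$ci["phi", 1], x$ci["phi", 2]))
    cat(sprintf("  95%% BCa CI k2:  [%.5g, %.5g]\n", x$ci["k2", 1], x$ci["k2", 2]))
  }
  invisible(x)
}

#' Bias-corrected and accelerated bootstrap intervals for a fit
#'
#' Case-resamples the experiment records with replacement, refits per
#' replicate (warm-started at the point estimates), and forms BCa percentile
#' intervals for \code{phi} and \code{k2} via the \pkg{boot} package.
#' Resampling is pooled across series by default; \code{stratified = TRUE}
#' resamples within series. Replicates whose refit fails are dropped; more
#' than 10\% failures is an error.
#'
#' @param records measured \code{\link{experiment_records}}.
#' @param fit a \code{\link{fit_parameters}} result for those records.
#' @param N number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed optional integer seed (results are reproducible given the
#'   seed).
#' @param stratified resample within series rather than pooled.
#' @return A \code{clock_fit} with added components \code{ci} (2x2 matrix,
#'   rows phi and k2), \code{boot} (the \pkg{boot} object) and
#'   \code{n_failed}.
#' @export
bootstrap_ci <- function(records, fit, N = 1000, level = 0.95, seed = NULL,
                         stratified = FALSE) {
  if (!inherits(fit, "clock_fit")) stop("fit must be a clock_fit")
  if (!fit$converged) stop("fit did not converge; refit before bootstrapping")
  if (N < 100) stop("N must be at least 100")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  threshold <- fit$threshold
  warm <- c(stats::qlogis(fit$phi_hat), log(fit$k2_hat))
  stat <- function(data, idx) {
    d <- data[idx, , drop = FALSE]
    obj <- make_objective(d, threshold)
    res <- tryCatch(
      stats::optim(warm, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) return(c(NA_real_, NA_real_))
    c(stats::plogis(res$par[1]), exp(res$par[2]))
  }
  df <- as.data.frame(records)
  bo <- if (stratified)
    boot::boot(df, stat, R = N, strata = as.factor(df$series))
  else
    boot::boot(df, stat, R = N)
  ok <- stats::complete.cases(bo$t)
  n_failed <- sum(!ok)
  if (n_failed > 0.10 * N)
    stop(sprintf("%d of %d bootstrap refits failed", n_failed, N))
  if (n_failed > 0) {
    bo$t <- bo$t[ok, , drop = FALSE]
    bo$R <- sum(ok)
  }
  ci <- t(vapply(1:2, function(j) {
    L <- boot::empinf(data = df, statistic = stat, index = j,
                      stype = "i", type = "jack")
    boot::boot.ci(bo, conf = level, type = "bca", index = j, L = L)$bca[4:5]
  }, numeric(2)))
  dimnames(ci) <- list(c("phi", "k2"), c("lower", "upper"))
  fit$ci <- ci
  fit$boot <- bo
  fit$n_failed <- n_failed
  fit$level <- level
  fit
}
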