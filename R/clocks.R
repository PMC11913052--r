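#' Time clocks of the clock-reaction analysis
#'
#' The analysis uses several time variables: dimensional seconds \code{t};
#' the fast-reaction clock \code{tstar = k1*c0*t}; the slow-reaction clock
#' \code{tau = epsilon*tstar} (high-peroxide induction scale); and the
#' rate-limiting clock \code{T = epsilon^2*tstar} (moderate-peroxide
#' induction scale). \code{clock_convert} converts a value between them.
#' Conversion to or from \code{"seconds"} additionally requires the anchors
#' \code{k1} and \code{c0}.
#'
#' @param value numeric time value(s).
#' @param from,to one of \code{"tstar"}, \code{"tau"}, \code{"T"},
#'   \code{"seconds"}.
#' @param epsilon rate-disparity parameter.
#' @param k1,c0 dimensional anchors, needed only when converting to or from
#'   seconds.
#' @return Converted numeric value(s).
#' @export
clock_convert <- function(value, from, to, epsilon, k1 = NULL, c0 = NULL) {
  clocks <- c("tstar", "tau", "T", "seconds")
  from <- match.arg(from, clocks); to <- match.arg(to, clocks)
  if (from == to) return(value)
  to_tstar <- function(v, cl) {
    switch(cl,
           tstar = v,
           tau = v / epsilon,
           T = v / epsilon^2,
           seconds = {
             if (is.null(k1) || is.null(c0))
               stop("converting from seconds requires k1 and c0")
             v * k1 * c0
           })
  }
  from_tstar <- function(v, cl) {
    switch(cl,
           tstar = v,
           tau = v * epsilon,
           T = v * epsilon^2,
           seconds = {
             if (is.null(k1) || is.null(c0))
               stop("converting to seconds requires k1 and c0")
             v / (k1 * c0)
           })
  }
  from_tstar(to_tstar(value, from), to)
}

#' Switchover-time estimate
#'
#' Container for an induction-time estimate together with its clock, the
#' method that produced it (\code{"numerical"} threshold crossing,
#' \code{"mhp_formula"}, \code{"hhp_full"}, \code{"hhp_simplified"} or
#' \code{"hhp_heuristic"}) and the peroxide regime.
#'
#' @param value positive time value.
#' @param clock one of \code{"tstar"}, \code{"tau"}, \code{"T"},
#'   \code{"seconds"}.
#' @param method estimation method label.
#' @param regime \code{"M-HP"} or \code{"H-HP"}.
#' @param epsilon rate-disparity parameter, stored to allow clock conversion.
#' @return Object of class \code{"switchover_estimate"}.
#' @export
switchover_estimate <- function(value, clock, method, regime, epsilon = NA_real_) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value) || value <= 0) stop("switchover time must be positive")
  clock <- match.arg(clock, c("tstar", "tau", "T", "seconds"))
  method <- match.arg(method, c("numerical", "mhp_formula", "hhp_full",
                                "hhp_simplified", "hhp_heuristic"))
  regime <- match.arg(regime, c("M-HP", "H-HP"))
  structure(list(value = value, clock = clock, method = method,
                 regime = regime, epsilon = epsilon),
            class = "switchover_estimate")
}

#' Express a switchover estimate in another clock
#'
#' @param est a \code{\link{switchover_estimate}}.
#' @param clock target clock.
#' @param k1,c0 dimensional anchors for second conversions.
#' @return A new \code{switchover_estimate} in the target clock.
#' @export
switchover_in <- function(est, clock, k1 = NULL, c0 = NULL) {
  v <- clock_convert(est$value, est$clock, clock, est$epsilon, k1, c0)
  switchover_estimate(v, clock, est$method, est$regime, est$epsilon)
}

#' @export
print.switchover_estimate <- function(x, ...) {
  cat(sprintf("Switchover time: %g [%s clock] (method %s, regime %s)\n",
              x$value, x$clock, x$method, x$regime))
  invisible(x)
}
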