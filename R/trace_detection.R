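#' Colour-change intensity trace
#'
#' A per-frame region-of-interest summed intensity series, as produced by
#' imaging the reaction mixture from above: the starch--iodine colour change
#' at the switchover appears as a sharp darkening (drop) in summed intensity.
#'
#' @param intensity numeric vector of per-frame summed intensities
#'   (arbitrary units).
#' @param fps frame rate in frames per second (default 15).
#' @param frame optional frame indices; default 0-based
#'   \code{0:(length(intensity)-1)}, so frame \code{k} occurs at
#'   \code{k/fps} seconds.
#' @return Object of class \code{"intensity_trace"}.
#' @export
intensity_trace <- function(intensity, fps = 15, frame = NULL) {
  if (fps <= 0) stop("frame rate must be positive")
  if (is.null(frame)) frame <- seq_along(intensity) - 1L
  if (length(frame) != length(intensity) || is.unsorted(frame, strictly = TRUE))
    stop("frame must be strictly increasing and match intensity length")
  structure(list(frame = frame, intensity = as.numeric(intensity), fps = fps),
            class = "intensity_trace")
}

#' Read an intensity trace from CSV
#'
#' Expects columns \code{frame} and \code{intensity}.
#'
#' @param file path to a CSV file.
#' @param fps frame rate in frames per second.
#' @return An \code{\link{intensity_trace}}.
#' @export
read_trace_csv <- function(file, fps = 15) {
  df <- utils::read.csv(file)
  intensity_trace(df$intensity, fps = fps, frame = df$frame)
}

#' Detect the colour-change corner in an intensity trace
#'
#' Implements the switchover detector used on ROI-summed webcam traces:
#' (1) successive-frame differences \code{d_k = s_k - s_{k-1}};
#' (2) forward moving average \code{f_k = mean(d_k, ..., d_{k+window-1})}
#' and backward moving average \code{b_k = mean(d_{k-window+1}, ..., d_k)};
#' (3) the corner is the index minimizing \code{f_k - b_k} over indices with
#' both windows complete. This approximates the point of largest (negative)
#' second derivative of the signal, so the location is invariant to
#' intensity gain and offset. The minimum must be strictly negative; its
#' magnitude is reported as a quality score. Ties break to the earliest
#' frame; edge indices without complete windows are excluded (no padding).
#'
#' @param trace an \code{\link{intensity_trace}}.
#' @param window moving-average window in frames (default 10, >= 2).
#' @return Object of class \code{"detector_result"}: list with
#'   \code{corner_frame}, \code{corner_time} (seconds), \code{score}
#'   (the \code{f - b} series, NA at edges) and \code{quality}.
#' @export
detect_colour_change <- function(trace, window = 10) {
  if (!inherits(trace, "intensity_trace")) stop("trace must be an intensity_trace")
  if (window < 2) stop("window must be at least 2 frames")
  n <- length(trace$intensity)
  if (n < 2 * window + 2)
    stop(sprintf("trace too short: need at least %d frames", 2 * window + 2))
  d <- diff(trace$intensity)            # d[j] = s[j+1] - s[j], j = 1..n-1
  cs <- c(0, cumsum(d))
  m <- length(d)
  win_mean <- function(from, to) (cs[to + 1] - cs[from]) / window
  # score at difference index j: forward mean(d_j..d_{j+w-1}) minus
  # backward mean(d_{j-w+1}..d_j); complete for j in [window, m-window+1]
  score <- rep(NA_real_, m)
  idx <- seq.int(window, m - window + 1L)
  score[idx] <- win_mean(idx, idx + window - 1L) - win_mean(idx - window + 1L, idx)
  jmin <- idx[which.min(score[idx])]
  # strictly negative up to accumulated rounding in the window sums
  tol <- 1e-8 * max(abs(d), 1)
  if (!is.finite(score[jmin]) || score[jmin] >= -tol)
    stop("no corner detected: forward-backward difference has no strictly negative minimum")
  corner_frame <- trace$frame[jmin + 1L]  # d[j] sits between frames j and j+1
  structure(list(corner_frame = corner_frame,
                 corner_time = corner_frame / trace$fps,
                 score = score,
                 quality = -score[jmin],
                 window = window),
            class = "detector_result")
}

#' @export
print.detector_result <- function(x, ...) {
  cat(sprintf("Colour-change corner at frame %d (%.3f s), quality %.4g\n",
              x$corner_frame, x$corner_time, x$quality))
  invisible(x)
}
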