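# Logan graphical analysis with a reference-tissue input function.
# For a reversible tracer, plotting
#   y(T) = int_0^T C_target dt / C_target(T)
# against
#   x(T) = int_0^T C_ref dt / C_target(T)
# becomes linear at late times; the slope estimates the distribution volume
# ratio (DVR) of target vs reference tissue.

#' Time-activity curve
#'
#' @param time_min Frame mid-times in minutes, strictly increasing, positive.
#' @param activity Non-negative tracer concentrations, one per frame.
#' @param role `"target"` or `"reference"`.
#' @return Object of class `tac`: data.frame with `time_min`, `activity` and a
#'   `role` attribute.
#' @export
tac <- function(time_min, activity, role = c("target", "reference")) {
  role <- match.arg(role)
  if (length(time_min) != length(activity)) {
    stop("time and activity must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time_min)) || any(time_min <= 0) ||
      any(diff(time_min) <= 0)) {
    stop("frame mid-times must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(activity)) || any(activity < 0)) {
    stop("activity must be non-negative", call. = FALSE)
  }
  out <- data.frame(time_min = time_min, activity = activity)
  attr(out, "role") <- role
  class(out) <- c("tac", "data.frame")
  out
}

# cumulative trapezoidal integral from t = 0, with an implicit (0, 0) point
# before the first frame
cum_trapz0 <- function(time_min, activity) {
  t <- c(0, time_min)
  a <- c(0, activity)
  cumsum(c(0, diff(t) * (utils::head(a, -1) + utils::tail(a, -1)) / 2))[-1]
}

as_tac <- function(x, role) {
  if (inherits(x, "tac")) return(x)
  if (is.data.frame(x) && all(c("time_min", "activity") %in% names(x))) {
    return(tac(x$time_min, x$activity, role))
  }
  stop("expected a tac object or a data.frame with time_min and activity",
       call. = FALSE)
}

#' Logan graphical DVR estimate
#'
#' Ordinary least-squares fit of the Logan transform over frames with
#' mid-time at or after `t_star`. Integrals are cumulative trapezoids from
#' time zero (an implicit (0, 0) point precedes the first frame). The pure
#' reference-ratio form is used: no k2' correction term.
#'
#' @param target,reference [tac()] objects (or data.frames with `time_min`,
#'   `activity`) on the same frame grid.
#' @param t_star Start of the linear fit window, minutes; default 35.
#' @return Object of class `logan_fit`: list with `dvr` (slope), `intercept`
#'   (minutes), `t_star`, `n_fit_points`, `r_squared`.
#' @examples
#' tp <- generate_tac_pair(true_dvr = 1.5)
#' logan_dvr(tp$target, tp$reference)
#' @export
logan_dvr <- function(target, reference, t_star = 35) {
  target <- as_tac(target, "target")
  reference <- as_tac(reference, "reference")
  if (nrow(target) != nrow(reference) ||
      any(abs(target$time_min - reference$time_min) > 1e-9)) {
    stop("target and reference curves must share a frame grid", call. = FALSE)
  }
  fit_idx <- which(target$time_min >= t_star)
  if (length(fit_idx) < 3L) {
    stop("insufficient data: fewer than 3 frames at or after t_star",
         call. = FALSE)
  }
  if (any(target$activity[fit_idx] <= 0)) {
    stop("zero or negative target activity in the fit window", call. = FALSE)
  }
  int_t <- cum_trapz0(target$time_min, target$activity)
  int_r <- cum_trapz0(reference$time_min, reference$activity)
  y <- int_t[fit_idx] / target$activity[fit_idx]
  x <- int_r[fit_idx] / target$activity[fit_idx]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("Logan fit failed: non-positive slope", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  out <- list(dvr = slope,
              intercept = unname(stats::coef(fit)[1]),
              t_star = t_star,
              n_fit_points = length(fit_idx),
              r_squared = min(max(r2, 0), 1))
  class(out) <- "logan_fit"
  out
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "Logan fit: DVR = %.3f (intercept %.2f min, t* = %g min, %d points, R^2 = %.4f)\n",
    x$dvr, x$intercept, x$t_star, x$n_fit_points, x$r_squared))
  invisible(x)
}
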