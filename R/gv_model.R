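#' Gamma-variate contrast-transit parameters
#'
#' Container for the four parameters of a voxel's first-pass gamma-variate
#' time-intensity curve,
#' \deqn{v(t) = A (t - AT)^{\alpha} e^{-(t - AT)/\beta} \quad (t > AT),}
#' and zero at or before the contrast arrival time \eqn{AT}.  The curve is
#' unimodal with its maximum at \eqn{T_{max} = AT + \alpha\beta}.
#'
#' @param amplitude Intensity scale \eqn{A \ge 0} (arbitrary intensity units
#'   divided by \eqn{s^\alpha}).
#' @param alpha Dimensionless shape parameter, \eqn{\alpha > 0}.
#' @param beta Timescale in seconds, \eqn{\beta > 0}.
#' @param at Contrast arrival time in seconds, \eqn{AT \ge 0}.
#' @return An object of class \code{gv_params}.
#' @examples
#' p <- gv_params(amplitude = 1, alpha = 2, beta = 1, at = 0)
#' gv_value(p, 2)           # the peak, 4 * exp(-2)
#' gv_derived(p)$tmax       # 2
#' @export
gv_params <- function(amplitude, alpha, beta, at) {
  p <- list(amplitude = as.numeric(amplitude), alpha = as.numeric(alpha),
            beta = as.numeric(beta), at = as.numeric(at))
  class(p) <- "gv_params"
  validate_gv_params(p)
  p
}

validate_gv_params <- function(p) {
  for (f in c("amplitude", "alpha", "beta", "at")) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v))
      stop("gv_params: '", f, "' must be a single finite number", call. = FALSE)
  }
  if (p$alpha <= 0) stop("gv_params: alpha must be > 0", call. = FALSE)
  if (p$beta <= 0) stop("gv_params: beta must be > 0", call. = FALSE)
  if (p$amplitude < 0) stop("gv_params: amplitude must be >= 0", call. = FALSE)
  if (p$at < 0) stop("gv_params: arrival time must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.gv_params <- function(x, ...) {
  d <- gv_derived(x)
  cat(sprintf(
    "gv_params: amplitude=%.4g alpha=%.4g beta=%.4g s AT=%.4g s (Tmax=%.4g s, peak=%.4g)\n",
    x$amplitude, x$alpha, x$beta, x$at, d$tmax, d$peak))
  invisible(x)
}

#' Evaluate a gamma-variate curve
#'
#' @param params A \code{\link{gv_params}} object.
#' @param t Time(s) in seconds (vectorized).
#' @return Non-negative intensity; exactly 0 for \code{t <= at}.
#' @export
gv_value <- function(params, t) {
  validate_gv_params(params)
  if (any(!is.finite(t))) stop("gv_value: t must be finite", call. = FALSE)
  u <- t - params$at
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- params$amplitude * u[pos]^params$alpha * exp(-u[pos] / params$beta)
  out
}

# gv_value without per-call validation, for inner fitting loops
gv_eval_raw <- function(amplitude, alpha, beta, at, t) {
  u <- t - at
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- amplitude * u[pos]^alpha * exp(-u[pos] / beta)
  out
}

#' Derived quantities of a gamma-variate curve
#'
#' Computes the time of peak enhancement \code{tmax = at + alpha * beta}, the
#' peak intensity, and the leave time \code{leave_time}: the earliest
#' post-peak time at which the curve has decayed to \code{leave_fraction} of
#' its peak (contrast washout), found by a bracketed root search.
#'
#' @param params A \code{\link{gv_params}} object.
#' @param leave_fraction Washout threshold as a fraction of peak (default 0.05).
#' @return A list with \code{tmax}, \code{peak}, \code{leave_time} (seconds).
#'   For a zero-amplitude curve \code{leave_time} equals \code{tmax}.
#' @export
gv_derived <- function(params, leave_fraction = 0.05) {
  validate_gv_params(params)
  tmax <- params$at + params$alpha * params$beta
  peak <- params$amplitude * (params$alpha * params$beta)^params$alpha *
    exp(-params$alpha)
  if (peak <= 0) {
    return(list(tmax = tmax, peak = 0, leave_time = tmax))
  }
  target <- leave_fraction * peak
  f <- function(t) gv_eval_raw(params$amplitude, params$alpha, params$beta,
                               params$at, t) - target
  # bracket: expand past tmax until below target (monotone decay post-peak)
  hi <- tmax + params$beta
  while (f(hi) > 0) hi <- tmax + 2 * (hi - tmax)
  lt <- stats::uniroot(f, lower = tmax, upper = hi, tol = 1e-10)$root
  list(tmax = tmax, peak = peak, leave_time = lt)
}

#' Uniform acquisition time grid
#'
#' Frame \code{k} (0-based, as conventional for cine frame numbering) is
#' acquired at \code{origin + k / frame_rate} seconds.
#'
#' @param n_frames Number of frames, >= 1.
#' @param frame_rate Acquisition rate in frames per second, > 0.
#' @param origin Time of frame 0 in seconds (default 0).
#' @return An object of class \code{time_grid}.
#' @export
time_grid <- function(n_frames, frame_rate, origin = 0) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("time_grid: n_frames must be >= 1", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("time_grid: frame_rate must be > 0", call. = FALSE)
  g <- list(n_frames = n_frames, frame_rate = as.numeric(frame_rate),
            origin = as.numeric(origin))
  class(g) <- "time_grid"
  g
}

#' Frame acquisition times of a grid
#'
#' @param grid A \code{\link{time_grid}}.
#' @return Numeric vector of length \code{n_frames}; entry \code{k + 1} is the
#'   time of (0-based) frame \code{k}.
#' @export
frame_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$origin + (seq_len(grid$n_frames) - 1L) / grid$frame_rate
}

#' Sample a gamma-variate curve on a time grid
#'
#' @param params A \code{\link{gv_params}} object.
#' @param grid A \code{\link{time_grid}}.
#' @return Intensity series of length \code{grid$n_frames}.
#' @export
sample_curve <- function(params, grid) {
  gv_value(params, frame_times(grid))
}
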