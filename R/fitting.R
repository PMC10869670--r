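#' Configuration of the per-voxel gamma-variate fit
#'
#' @param noise_floor_k Background-classification multiplier: a voxel whose
#'   peak intensity is below \code{noise_floor_k * sigma} is classified as
#'   non-enhancing background and reconstructed as zero baseline (default 3).
#' @param min_fit_points Minimum number of retained samples required to
#'   attempt a fit; the model has four free parameters (default 4, floor 4).
#' @param max_iterations Levenberg-Marquardt iteration cap (default 200).
#' @param convergence_tol Relative tolerance on residual and parameter
#'   updates (default 1e-10; tight so that noise-free curves are recovered to
#'   numerical precision).
#' @param bounds Parameter box as a list with numeric vectors \code{lower}
#'   and \code{upper} over \code{(amplitude, alpha, beta, at)}.  An \code{NA}
#'   upper bound on \code{at} is resolved per voxel to the last sample time.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(noise_floor_k = 3, min_fit_points = 4,
                       max_iterations = 200, convergence_tol = 1e-10,
                       bounds = NULL) {
  if (min_fit_points < 4)
    stop("fit_config: min_fit_points must be >= 4 (four free parameters)",
         call. = FALSE)
  if (is.null(bounds))
    bounds <- list(lower = c(amplitude = 0, alpha = 0.1, beta = 0.01, at = 0),
                   upper = c(amplitude = Inf, alpha = 25, beta = 50, at = NA))
  stopifnot(is.list(bounds), all(c("lower", "upper") %in% names(bounds)))
  if (bounds$lower[["alpha"]] <= 0 || bounds$lower[["beta"]] <= 0 ||
      bounds$lower[["amplitude"]] < 0 || bounds$lower[["at"]] < 0)
    stop("fit_config: bounds must enforce alpha > 0, beta > 0, amplitude >= 0, at >= 0",
         call. = FALSE)
  cfg <- list(noise_floor_k = noise_floor_k,
              min_fit_points = as.integer(min_fit_points),
              max_iterations = as.integer(max_iterations),
              convergence_tol = convergence_tol, bounds = bounds)
  class(cfg) <- "fit_config"
  cfg
}

#' Read a fit configuration from a key=value text file
#'
#' Recognized keys: \code{noise_floor_k}, \code{min_fit_points},
#' \code{max_iterations}, \code{convergence_tol}, and bound entries
#' \code{lower.amplitude}, \code{upper.alpha}, etc.  Unknown keys are an
#' error; missing keys keep their defaults.
#'
#' @param path Text file of \code{key=value} lines (\code{#} comments allowed).
#' @return A \code{\link{fit_config}}.
#' @export
read_fit_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- as.numeric(vapply(kv, function(x) trimws(x[2]), character(1)))
  cfg <- fit_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% c("noise_floor_k", "min_fit_points", "max_iterations",
                 "convergence_tol")) {
      cfg[[k]] <- if (k %in% c("min_fit_points", "max_iterations"))
        as.integer(vals[i]) else vals[i]
    } else if (grepl("^(lower|upper)\\.", k)) {
      side <- sub("\\..*$", "", k)
      par <- sub("^[a-z]+\\.", "", k)
      if (!par %in% c("amplitude", "alpha", "beta", "at"))
        stop("read_fit_config: unknown bound '", k, "'", call. = FALSE)
      cfg$bounds[[side]][[par]] <- vals[i]
    } else stop("read_fit_config: unknown key '", k, "'", call. = FALSE)
  }
  fit_config(cfg$noise_floor_k, cfg$min_fit_points, cfg$max_iterations,
             cfg$convergence_tol, cfg$bounds)
}

#' Robust temporal noise estimate of a stack
#'
#' Estimates the standard deviation of temporal intensity fluctuation from
#' the median absolute deviation of the frame-to-frame first differences,
#' pooled over all voxels and scaled to a Gaussian sigma (the difference of
#' two independent samples has standard deviation \code{sigma * sqrt(2)}).
#' The median absolute deviation is insensitive to the minority of enhancing
#' voxels whose differences carry the contrast bolus.  On data whose
#' background noise was clipped at zero the estimate runs low (clipped
#' pairs contribute zero differences), so thresholds derived from it are
#' mildly permissive there.
#'
#' @param stack A \code{\link{frame_stack}} with at least 2 frames.
#' @return Non-negative noise sigma in intensity units.
#' @export
estimate_noise <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  f <- n_frames(stack)
  if (f < 2L)
    stop("estimate_noise: at least 2 frames are required", call. = FALSE)
  d <- stack$voxels[-1L, , , drop = FALSE] - stack$voxels[-f, , , drop = FALSE]
  stats::mad(as.vector(d)) / sqrt(2)
}

#' Heuristic starting parameters for a gamma-variate fit
#'
#' Standard bolus heuristics: the arrival time starts at the latest pre-peak
#' sample still at or below 10\% of the peak (or the first sample time); the
#' time to peak fixes the product \code{alpha * beta}; the shape \code{alpha}
#' comes from a log-domain two-point estimate using one off-peak sample,
#' clamped to the configured bounds; the amplitude is scaled so the curve
#' attains the observed peak.
#'
#' @param times Strictly increasing sample times (seconds).
#' @param values Intensities at \code{times}; \code{max(values)} must be > 0.
#' @param config A \code{\link{fit_config}} supplying the parameter box.
#' @return A \code{\link{gv_params}} starting point within bounds.
#' @export
initial_guess <- function(times, values, config = fit_config()) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  peak <- max(values)
  if (peak <= 0)
    stop("initial_guess: degenerate input (all values <= 0)", call. = FALSE)
  ipk <- which.max(values)
  tpk <- times[ipk]
  dt <- stats::median(diff(times))
  lo <- config$bounds$lower
  up <- config$bounds$upper
  pre <- which(seq_along(times) < ipk & values <= 0.1 * peak)
  at0 <- if (length(pre)) times[max(pre)] else times[1]
  at0 <- max(min(at0, tpk - dt), 0, lo[["at"]])
  m <- max(tpk - at0, dt)                       # alpha0 * beta0 = time to peak
  # log-domain two-point shape estimate: for tau = t - AT,
  #   log(v/peak) = alpha * (log(tau/m) + 1 - tau/m)
  cand <- which(values > 0 & values < peak & times > at0)
  alpha0 <- 2
  if (length(cand)) {
    # the sample nearest half-peak conditions the log-ratio estimate best
    # (near-peak samples give ratios ~ 1 and a vanishing denominator)
    i1 <- cand[which.min(abs(values[cand] - 0.5 * peak))]
    tau1 <- times[i1] - at0
    den <- log(tau1 / m) + 1 - tau1 / m
    if (is.finite(den) && den < 0) {
      a <- log(values[i1] / peak) / den
      if (is.finite(a) && a > 0) alpha0 <- a
    }
  }
  alpha0 <- min(max(alpha0, lo[["alpha"]]), up[["alpha"]])
  beta0 <- min(max(m / alpha0, lo[["beta"]]), up[["beta"]])
  amp0 <- peak / (m^alpha0 * exp(-alpha0))
  amp0 <- max(amp0, lo[["amplitude"]])
  if (is.finite(up[["amplitude"]])) amp0 <- min(amp0, up[["amplitude"]])
  gv_params(amp0, alpha0, beta0, at0)
}

# Log-linear start: for a fixed arrival time the gamma-variate is linear in
# (log amplitude, alpha, 1/beta) on the log scale,
#   log v = log A + alpha log(t - AT) - (t - AT)/beta,
# so candidate ATs between the last zero and first positive sample are
# scanned, each solved by ordinary least squares, and the candidate with the
# lowest original-scale residual wins.  Exact for noise-free data up to the
# AT grid resolution; the LM polish removes that.
loglinear_start <- function(times, values, lower, upper) {
  pos <- which(values > 0)
  if (length(pos) < 3L) return(NULL)
  t_first <- times[pos[1]]
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 1
  zeros <- times[times < t_first]
  at_lo <- max(if (length(zeros)) max(zeros) else t_first - dt, lower[4], 0)
  at_hi <- min(t_first - 1e-6 * dt, upper[4])
  if (at_hi <= at_lo) at_hi <- at_lo + 1e-6
  best <- NULL
  best_rss <- Inf
  for (at in seq(at_lo, at_hi, length.out = 9L)) {
    use <- pos[times[pos] > at]
    if (length(use) < 3L) next
    tau <- times[use] - at
    X <- cbind(1, log(tau), -tau)
    co <- tryCatch(stats::lm.fit(X, log(values[use]))$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || any(!is.finite(co))) next
    alpha <- co[2]
    beta <- 1 / co[3]
    amp <- exp(co[1])
    if (alpha <= 0 || beta <= 0 || !is.finite(amp)) next
    par <- pmin(pmax(c(amp, alpha, beta, at), lower), upper)
    rss <- sum((gv_eval_raw(par[1], par[2], par[3], par[4], times) -
                  values)^2)
    if (is.finite(rss) && rss < best_rss) {
      best_rss <- rss
      best <- par
    }
  }
  best
}

fit_result <- function(status, params = NULL, rmse = NA_real_,
                       n_points_used = NA_integer_) {
  r <- list(status = status, params = params, rmse = rmse,
            n_points_used = as.integer(n_points_used))
  class(r) <- "gv_fit"
  r
}

#' Fit a gamma-variate curve to one voxel's retained samples
#'
#' Classification cascade: a voxel whose peak is below
#' \code{noise_floor_k * sigma} (or is non-positive) is \code{background};
#' with fewer than \code{min_fit_points} samples the voxel is marked
#' \code{fallback_interp} (reconstructed later by piecewise-linear
#' interpolation); otherwise a bounded Levenberg-Marquardt least-squares fit
#' is started from \code{\link{initial_guess}}.  Convergence yields status
#' \code{fitted}; non-convergence yields \code{failed} (also reconstructed by
#' interpolation downstream).
#'
#' @param times Strictly increasing sample times (seconds).
#' @param values Intensities, same length as \code{times}.
#' @param config A \code{\link{fit_config}}.
#' @param sigma Noise sigma used by the background rule (default 0).
#' @return An object of class \code{gv_fit}: \code{status} (one of
#'   \code{"fitted"}, \code{"background"}, \code{"fallback_interp"},
#'   \code{"failed"}), \code{params} (a \code{\link{gv_params}} when fitted),
#'   \code{rmse}, and \code{n_points_used}.
#' @export
fit_voxel <- function(times, values, config = fit_config(), sigma = 0) {
  if (length(times) != length(values))
    stop("fit_voxel: times and values must have equal length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("fit_voxel: times must be strictly increasing", call. = FALSE)
  n <- length(times)
  peak <- max(values)
  if (peak <= config$noise_floor_k * sigma || peak <= 0)
    return(fit_result("background", n_points_used = n))
  if (n < config$min_fit_points)
    return(fit_result("fallback_interp", n_points_used = n))

  init <- tryCatch(initial_guess(times, values, config),
                   error = function(e) NULL)
  if (is.null(init)) return(fit_result("failed", n_points_used = n))

  lo <- config$bounds$lower
  up <- config$bounds$upper
  up_at <- up[["at"]]
  if (is.na(up_at)) up_at <- times[n]
  lower <- c(lo[["amplitude"]], lo[["alpha"]], lo[["beta"]], lo[["at"]])
  upper <- c(up[["amplitude"]], up[["alpha"]], up[["beta"]], up_at)

  dt <- stats::median(diff(times))
  tpk <- times[which.max(values)]
  make_start <- function(at0, alpha0) {
    at0 <- min(max(at0, lower[4]), upper[4])
    alpha0 <- min(max(alpha0, lower[2]), upper[2])
    m <- max(tpk - at0, dt / 2)
    beta0 <- min(max(m / alpha0, lower[3]), upper[3])
    amp0 <- min(max(peak / (m^alpha0 * exp(-alpha0)), lower[1]), upper[1])
    c(amp0, alpha0, beta0, at0)
  }
  # deterministic multi-start: the log-linear scan start, the heuristic
  # guess, and shape/arrival perturbations of it, to escape the occasional
  # wrong LM basin
  starts <- list(
    loglinear_start(times, values, lower, upper),
    pmin(pmax(c(init$amplitude, init$alpha, init$beta, init$at), lower),
         upper),
    make_start(init$at, 2 * init$alpha),
    make_start(init$at, init$alpha / 2),
    make_start(init$at - dt, init$alpha),
    make_start(min(init$at + dt / 2, tpk - dt / 2), init$alpha))
  starts <- Filter(Negate(is.null), starts)

  best <- NULL
  best_rmse <- Inf
  for (par0 in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = par0,
        lower = lower, upper = upper,
        fn = function(p) gv_eval_raw(p[1], p[2], p[3], p[4], times) - values,
        control = minpack.lm::nls.lm.control(
          maxiter = config$max_iterations,
          maxfev = 20L * (config$max_iterations + 1L),
          ftol = config$convergence_tol, ptol = config$convergence_tol))),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    rmse <- sqrt(mean(fit$fvec^2))
    if (!is.finite(rmse)) next
    # info 1-3: converged in residual/parameters.  An iteration-capped fit
    # whose residual is at numerical zero (flat valley of an exactly
    # interpolating family) is converged for every practical purpose.
    if (!(fit$info %in% 1:3 || rmse <= 1e-8 * peak)) next
    if (rmse < best_rmse) {
      best <- fit
      best_rmse <- rmse
    }
    if (best_rmse <= 1e-9 * peak) break      # exact fit found; stop early
  }
  if (is.null(best))
    return(fit_result("failed", n_points_used = n))
  p <- best$par
  rmse <- best_rmse
  params <- tryCatch(gv_params(p[1], p[2], p[3], p[4]),
                     error = function(e) NULL)
  if (is.null(params) || !is.finite(rmse))
    return(fit_result("failed", n_points_used = n))
  fit_result("fitted", params = params, rmse = rmse, n_points_used = n)
}

#' Fit every voxel of a (reduced) stack
#'
#' Applies \code{\link{fit_voxel}} independently to each voxel's
#' time-intensity curve.  Per-voxel failures never abort the stack; they
#' surface as \code{failed} rows.  The result is deterministic for identical
#' inputs and configuration, and voxel order is immaterial (fits are
#' independent).
#'
#' @param reduced A \code{\link{frame_stack}} (typically the output of
#'   \code{\link{reduce_stack}}).
#' @param config A \code{\link{fit_config}}.
#' @param sigma Noise sigma for the background rule; estimated with
#'   \code{\link{estimate_noise}} when \code{NULL} (0 for single-frame input).
#' @return A \code{gv_fit_map}: a data frame with one row per voxel
#'   (\code{row}, \code{col}, \code{status}, \code{amplitude}, \code{alpha},
#'   \code{beta}, \code{at}, \code{rmse}, \code{n_points}), with the image
#'   dimensions, sample times and sigma as attributes.
#' @export
fit_stack <- function(reduced, config = fit_config(), sigma = NULL) {
  stopifnot(inherits(reduced, "frame_stack"))
  if (is.null(sigma))
    sigma <- if (n_frames(reduced) >= 2L) estimate_noise(reduced) else 0
  d <- dim(reduced$voxels)
  times <- frame_times(reduced$grid)
  nv <- d[2] * d[3]
  status <- character(nv)
  pm <- matrix(NA_real_, nv, 5L,
               dimnames = list(NULL, c("amplitude", "alpha", "beta", "at",
                                       "rmse")))
  npts <- integer(nv)
  rows <- integer(nv)
  cols <- integer(nv)
  k <- 0L
  for (cc in seq_len(d[3])) {
    for (rr in seq_len(d[2])) {
      k <- k + 1L
      rows[k] <- rr; cols[k] <- cc
      fr <- fit_voxel(times, as.numeric(reduced$voxels[, rr, cc]),
                      config, sigma)
      status[k] <- fr$status
      npts[k] <- fr$n_points_used
      if (fr$status == "fitted") {
        pm[k, ] <- c(fr$params$amplitude, fr$params$alpha, fr$params$beta,
                     fr$params$at, fr$rmse)
      }
    }
  }
  fm <- data.frame(row = rows, col = cols, status = status,
                   amplitude = pm[, 1], alpha = pm[, 2], beta = pm[, 3],
                   at = pm[, 4], rmse = pm[, 5], n_points = npts)
  attr(fm, "dims") <- d[2:3]
  attr(fm, "sigma") <- sigma
  attr(fm, "times") <- times
  class(fm) <- c("gv_fit_map", "data.frame")
  fm
}

#' Census of fit statuses in a fit map
#'
#' @param fit_map A \code{gv_fit_map} from \code{\link{fit_stack}}.
#' @return Named integer vector over the four statuses.
#' @export
fit_census <- function(fit_map) {
  stopifnot(inherits(fit_map, "gv_fit_map"))
  lv <- c("fitted", "background", "fallback_interp", "failed")
  tab <- table(factor(fit_map$status, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
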