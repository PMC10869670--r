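#' Relative signal-intensity error at one voxel and time
#'
#' The fidelity metric is the absolute difference between original and
#' synthetic signal intensity, normalized by the original:
#' \deqn{R_{SI}(t) = |SI^o(t) - SI^s(t)| / SI^o(t).}
#' It is undefined (masked, returned as \code{NA}) where the original
#' intensity does not exceed \code{epsilon}, since the ratio is singular at
#' zero signal.
#'
#' @param si_original Original intensity (vectorized).
#' @param si_synthetic Synthetic intensity (vectorized).
#' @param epsilon Denominator guard; the metric is defined only where
#'   \code{si_original > epsilon}.
#' @return Non-negative error fraction, or \code{NA} where undefined.
#' @export
voxel_error <- function(si_original, si_synthetic, epsilon) {
  stopifnot(all(is.finite(si_original)), all(is.finite(si_synthetic)))
  out <- abs(si_original - si_synthetic) / si_original
  out[si_original <= epsilon] <- NA_real_
  out
}

#' Time-averaged relative-error map of a synthetic DSA
#'
#' For every voxel, averages the relative error over the frames where it is
#' defined (original intensity above \code{epsilon}).  A voxel is valid when
#' the metric is defined at one or more frames; mean and standard deviation
#' are computed over valid voxels only.
#'
#' @param original Ground-truth \code{\link{frame_stack}}.
#' @param sdsa Synthetic \code{\link{frame_stack}}, frame-aligned with
#'   \code{original}.
#' @param epsilon Denominator guard.  Defaults to the background threshold
#'   \code{noise_floor_k * estimate_noise(original)} (with
#'   \code{noise_floor_k = 3}), so that near-zero-signal voxels are masked
#'   rather than dominating the statistics.
#' @param noise_floor_k Multiplier for the default epsilon (default 3).
#' @return An object of class \code{error_map}: \code{per_voxel_error}
#'   (rows x cols matrix of fractions, \code{NA} where masked),
#'   \code{valid_mask} (logical matrix), and \code{summary} (list with
#'   \code{mean}, \code{sd}, \code{n_valid}, \code{epsilon}).
#' @export
error_map <- function(original, sdsa, epsilon = NULL, noise_floor_k = 3) {
  stopifnot(inherits(original, "frame_stack"), inherits(sdsa, "frame_stack"))
  if (!identical(dim(original$voxels), dim(sdsa$voxels)))
    stop("error_map: stacks must have identical dimensions", call. = FALSE)
  if (is.null(epsilon)) {
    sig <- if (n_frames(original) >= 2L) estimate_noise(original) else 0
    # floor at 1% of full scale: below that, "signal" in an 8-12 bit
    # angiogram is at quantization level and the ratio is meaningless
    epsilon <- max(noise_floor_k * sig, 0.01 * max(original$voxels))
  }
  o <- original$voxels
  s <- sdsa$voxels
  defined <- o > epsilon
  err <- abs(o - s) / o
  err[!defined] <- 0
  n_def <- apply(defined, c(2, 3), sum)
  tot <- apply(err, c(2, 3), sum)
  per_voxel <- tot / n_def            # NaN where n_def == 0
  per_voxel[n_def == 0] <- NA_real_
  valid <- n_def > 0
  vals <- per_voxel[valid]
  em <- list(per_voxel_error = per_voxel, valid_mask = valid,
             summary = list(mean = if (length(vals)) mean(vals) else NA_real_,
                            sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                            n_valid = sum(valid), epsilon = epsilon))
  class(em) <- "error_map"
  em
}

#' @export
print.error_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "error_map: %d valid voxels, mean error %.3f%% (sd %.3f%%), epsilon %.4g\n",
    s$n_valid, 100 * s$mean, 100 * s$sd, s$epsilon))
  invisible(x)
}

#' Render an error map as a green-to-red PNG heatmap
#'
#' Follows the reporting convention for DSA reconstruction error: green for
#' errors at or below \code{green_at} (default 3\%), red for errors at or
#' above \code{red_at} (default 15\%, values clipped), with a linear
#' green-yellow-red progression in between.  Masked voxels render neutral
#' gray.
#'
#' @param emap An \code{\link{error_map}}.
#' @param path Output PNG path.
#' @param green_at,red_at Error fractions anchoring the color scale.
#' @return \code{path}, invisibly.
#' @export
render_heatmap <- function(emap, path, green_at = 0.03, red_at = 0.15) {
  stopifnot(inherits(emap, "error_map"), red_at > green_at)
  e <- emap$per_voxel_error
  f <- pmin(pmax((e - green_at) / (red_at - green_at), 0), 1)
  rgb <- array(0.5, c(nrow(e), ncol(e), 3))       # neutral gray for masked
  ok <- emap$valid_mask & !is.na(f)
  # green (0,0.8,0) -> red (1,0,0) through yellow
  r <- ifelse(f[ok] < 0.5, 2 * f[ok], 1)
  g <- ifelse(f[ok] < 0.5, 0.8 + 0.4 * f[ok], 2 * (1 - f[ok]))
  ch <- rgb[, , 1]; ch[ok] <- r; rgb[, , 1] <- ch
  ch <- rgb[, , 2]; ch[ok] <- g; rgb[, , 2] <- ch
  ch <- rgb[, , 3]; ch[ok] <- 0; rgb[, , 3] <- ch
  png::writePNG(rgb, path)
  invisible(path)
}

#' Summary table of reconstruction fidelity per reduction scheme
#'
#' One row per scheme: mean and standard deviation of the per-voxel
#' time-averaged relative error (in percent, over valid voxels), the number
#' of valid voxels, and (when fit maps are supplied) the fit-status census.
#'
#' @param original Ground-truth \code{\link{frame_stack}}.
#' @param sdsas Named list of synthetic \code{\link{frame_stack}}s, one per
#'   scheme (names become the \code{scheme} column).
#' @param fit_maps Optional named list of \code{gv_fit_map}s aligned with
#'   \code{sdsas}.
#' @param epsilon Denominator guard passed to \code{\link{error_map}}.
#' @return A data frame with columns \code{scheme}, \code{mean_error_pct},
#'   \code{sd_error_pct}, \code{n_valid_voxels} and, if available,
#'   \code{n_fitted}, \code{n_background}, \code{n_fallback_interp},
#'   \code{n_failed}.
#' @export
study_report <- function(original, sdsas, fit_maps = NULL, epsilon = NULL) {
  stopifnot(is.list(sdsas), length(sdsas) >= 1L)
  if (is.null(names(sdsas)) || any(!nzchar(names(sdsas))))
    stop("study_report: sdsas must be a named list", call. = FALSE)
  rows <- lapply(names(sdsas), function(nm) {
    em <- error_map(original, sdsas[[nm]], epsilon = epsilon)
    out <- data.frame(scheme = nm,
                      mean_error_pct = 100 * em$summary$mean,
                      sd_error_pct = 100 * em$summary$sd,
                      n_valid_voxels = em$summary$n_valid)
    if (!is.null(fit_maps) && !is.null(fit_maps[[nm]])) {
      cen <- fit_census(fit_maps[[nm]])
      out$n_fitted <- cen[["fitted"]]
      out$n_background <- cen[["background"]]
      out$n_fallback_interp <- cen[["fallback_interp"]]
      out$n_failed <- cen[["failed"]]
    }
    out
  })
  do.call(rbind, rows)
}

#' Write a study report as CSV
#'
#' @param report Data frame from \code{\link{study_report}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_study_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
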