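#' Assemble a synthetic DSA from per-voxel fits
#'
#' Samples each voxel's reconstruction on the original acquisition grid:
#' fitted voxels are sampled from their gamma-variate curve, background
#' voxels are constant zero baseline, and fallback/failed voxels are
#' piecewise-linear interpolations of the retained samples (constant
#' extrapolation beyond the endpoints).  By default the retained
#' (acquired) frames are \emph{also} replaced by model values, so the whole
#' synthetic series is temporally consistent; \code{keep_acquired = TRUE}
#' passes the acquired frames through verbatim instead.
#'
#' @param fit_map A \code{gv_fit_map} from \code{\link{fit_stack}} covering
#'   every voxel.
#' @param original_grid The full-rate \code{\link{time_grid}} to sample on.
#' @param reduced The reduced \code{\link{frame_stack}} (source of the
#'   retained samples for interpolation fallbacks).
#' @param retained_indices 0-based indices of the retained frames in the
#'   original series.
#' @param keep_acquired Pass acquired frames through verbatim (default FALSE).
#' @return A \code{\link{frame_stack}} on \code{original_grid}.
#' @export
synthesize <- function(fit_map, original_grid, reduced, retained_indices,
                       keep_acquired = FALSE) {
  stopifnot(inherits(fit_map, "gv_fit_map"), inherits(original_grid, "time_grid"),
            inherits(reduced, "frame_stack"))
  d <- dim(reduced$voxels)
  if (original_grid$n_frames < d[1])
    stop("synthesize: original grid has fewer frames than the reduced stack",
         call. = FALSE)
  dims <- attr(fit_map, "dims")
  if (!identical(as.integer(dims), as.integer(d[2:3])) ||
      nrow(fit_map) != d[2] * d[3])
    stop("synthesize: fit_map does not cover every voxel of the stack",
         call. = FALSE)
  tt <- frame_times(original_grid)
  rt <- frame_times(reduced$grid)
  out <- array(0, c(original_grid$n_frames, d[2], d[3]))
  for (k in seq_len(nrow(fit_map))) {
    st <- fit_map$status[k]
    rr <- fit_map$row[k]; cc <- fit_map$col[k]
    if (st == "fitted") {
      v <- gv_eval_raw(fit_map$amplitude[k], fit_map$alpha[k],
                       fit_map$beta[k], fit_map$at[k], tt)
      out[, rr, cc] <- pmax(v, 0)
    } else if (st != "background") {
      ys <- as.numeric(reduced$voxels[, rr, cc])
      out[, rr, cc] <- if (d[1] == 1L) rep(ys, length(tt)) else
        stats::approx(rt, ys, xout = tt, rule = 2)$y
    }
  }
  if (keep_acquired)
    out[retained_indices + 1L, , ] <- reduced$voxels
  frame_stack(out, grid = original_grid, polarity = "contrast_bright",
              source_id = paste0(reduced$source_id, "/sdsa"))
}

#' End-to-end synthetic-DSA study: reduce, fit, resample
#'
#' Composition of \code{\link{reduce_stack}}, \code{\link{fit_stack}} and
#' \code{\link{synthesize}}: drops frames at the scheme's stride, fits the
#' gamma-variate model to every voxel of the reduced series, and samples the
#' fits back on the original frame grid.  A warning is emitted when the
#' input is shorter than \code{min_fit_points * stride} frames (the shortest
#' run that leaves enough retained samples per voxel; clinical series of at
#' least 16 frames clear it for all three schemes).
#'
#' @param stack The ground-truth \code{\link{frame_stack}}.
#' @param scheme A \code{\link{frr_scheme}} or level (50, 66, 75).
#' @param config A \code{\link{fit_config}}.
#' @param keep_acquired Pass retained frames through verbatim (default FALSE).
#' @param sigma Noise sigma for the background rule; estimated from the
#'   reduced stack when \code{NULL}.  Supply 0 (or a calibrated value) for
#'   data without non-enhancing background, where the median-based estimate
#'   is not meaningful.
#' @return A list with \code{sdsa} (the synthetic \code{\link{frame_stack}},
#'   frame-aligned with the input), \code{fit_map}, \code{retained_indices}
#'   (0-based) and \code{reduced}.
#' @export
synthesize_study <- function(stack, scheme, config = fit_config(),
                             keep_acquired = FALSE, sigma = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!inherits(scheme, "frr_scheme")) scheme <- frr_scheme(scheme)
  floor_frames <- config$min_fit_points * scheme$keep_stride
  if (n_frames(stack) < floor_frames)
    warning("synthesize_study: ", n_frames(stack), " frames is below the ",
            floor_frames, "-frame floor for ", scheme$level,
            "; fits may be infeasible", call. = FALSE)
  red <- reduce_stack(stack, scheme)
  fm <- fit_stack(red$reduced, config, sigma = sigma)
  sdsa <- synthesize(fm, stack$grid, red$reduced, red$retained_indices,
                     keep_acquired = keep_acquired)
  list(sdsa = sdsa, fit_map = fm, retained_indices = red$retained_indices,
       reduced = red$reduced)
}
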