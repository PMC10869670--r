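#' Multi-frame angiographic image stack
#'
#' The in-memory container for a DSA or synthetic DSA run: a 3-D intensity
#' array indexed \code{[frame, row, col]} plus its acquisition
#' \code{\link{time_grid}}.  The canonical polarity is
#' \code{"contrast_bright"}: contrast arrival raises stored intensity, so a
#' voxel's time-intensity curve is a non-negative bolus-shaped series.
#' Subtracted clinical images usually render contrast dark; such data is
#' inverted on read (see \code{\link{read_stack}}).
#'
#' @param voxels 3-D numeric array \code{[frame, row, col]}, all finite.
#' @param grid A \code{\link{time_grid}} with \code{n_frames} equal to
#'   \code{dim(voxels)[1]}, or \code{NULL} to build one from
#'   \code{frame_rate}.
#' @param frame_rate Frames per second; used only when \code{grid} is NULL.
#' @param polarity \code{"contrast_bright"} (canonical) or
#'   \code{"contrast_dark"}.
#' @param source_id Free-text provenance tag.
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(voxels, grid = NULL, frame_rate = NULL,
                        polarity = c("contrast_bright", "contrast_dark"),
                        source_id = "") {
  polarity <- match.arg(polarity)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("frame_stack: voxels must be a 3-D array [frame, row, col]",
         call. = FALSE)
  if (dim(voxels)[1] < 1L)
    stop("frame_stack: at least one frame is required", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("frame_stack: voxel intensities must be finite", call. = FALSE)
  if (is.null(grid)) {
    if (is.null(frame_rate))
      stop("frame_stack: supply either grid or frame_rate", call. = FALSE)
    grid <- time_grid(dim(voxels)[1], frame_rate)
  }
  stopifnot(inherits(grid, "time_grid"))
  if (grid$n_frames != dim(voxels)[1])
    stop("frame_stack: grid$n_frames (", grid$n_frames,
         ") != number of frames (", dim(voxels)[1], ")", call. = FALSE)
  s <- list(voxels = voxels, grid = grid, polarity = polarity,
            source_id = as.character(source_id))
  class(s) <- "frame_stack"
  s
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "frame_stack: %d frames of %dx%d voxels @ %.3g fps (%s)%s\n",
    d[1], d[2], d[3], x$grid$frame_rate, x$polarity,
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$voxels)

#' Number of frames in a stack
#' @param stack A \code{\link{frame_stack}}.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  stack$grid$n_frames
}

#' Time-intensity curve of one voxel
#'
#' @param stack A \code{\link{frame_stack}}.
#' @param row,col 1-based voxel coordinates.
#' @return Numeric intensity series of length \code{n_frames(stack)}.
#' @export
voxel_series <- function(stack, row, col) {
  stopifnot(inherits(stack, "frame_stack"))
  as.numeric(stack$voxels[, row, col])
}

# Normalize a stack to the canonical contrast_bright polarity.
# Inversion maps v -> max(v) - v so that the (bright) background of a
# subtracted dark-contrast image lands near zero.
normalize_polarity <- function(stack) {
  if (stack$polarity == "contrast_bright") return(stack)
  m <- max(stack$voxels)
  stack$voxels <- m - stack$voxels
  stack$polarity <- "contrast_bright"
  stack
}
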