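#' Frame-rate reduction scheme
#'
#' The three nominal reduction levels: 50\% keeps every 2nd frame, 66\% every
#' 3rd, 75\% every 4th, always starting at frame 0 (so the pre-arrival
#' baseline is always sampled).  "66\%" is an exact stride of 3 (one third of
#' frames retained); the nominal label is rounded.
#'
#' @param level One of 50, 66, 75 (or \code{"FRR50"} etc.).
#' @return An object of class \code{frr_scheme} with fields \code{level} and
#'   \code{keep_stride} (2, 3 or 4).
#' @export
frr_scheme <- function(level) {
  lvl <- sub("^FRR", "", toupper(as.character(level)))
  stride <- switch(lvl, "50" = 2L, "66" = 3L, "75" = 4L,
                   stop("frr_scheme: unsupported level '", level,
                        "' (supported: 50, 66, 75)", call. = FALSE))
  s <- list(level = paste0("FRR", lvl), keep_stride = stride)
  class(s) <- "frr_scheme"
  s
}

#' @export
print.frr_scheme <- function(x, ...) {
  cat(sprintf("frr_scheme %s: keep every %d%s frame\n", x$level,
              x$keep_stride, switch(as.character(x$keep_stride),
                                    "2" = "nd", "3" = "rd", "th")))
  invisible(x)
}

#' Drop frames from a stack at a fixed stride
#'
#' Simulates a reduced-dose acquisition by retaining frames
#' \code{0, s, 2s, ...} of the original series (0-based), where \code{s} is
#' the scheme's stride.  The reduced grid's frame rate is the original rate
#' divided by the stride; the original stack is not modified.
#'
#' @param stack A \code{\link{frame_stack}}.
#' @param scheme A \code{\link{frr_scheme}} (or a level accepted by it).
#' @return A list with \code{reduced} (the down-sampled
#'   \code{\link{frame_stack}}) and \code{retained_indices} (0-based indices
#'   into the original series).
#' @export
reduce_stack <- function(stack, scheme) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!inherits(scheme, "frr_scheme")) scheme <- frr_scheme(scheme)
  s <- scheme$keep_stride
  keep0 <- seq.int(0L, n_frames(stack) - 1L, by = s)   # 0-based
  reduced <- frame_stack(
    stack$voxels[keep0 + 1L, , , drop = FALSE],
    grid = time_grid(length(keep0), stack$grid$frame_rate / s,
                     stack$grid$origin),
    polarity = stack$polarity,
    source_id = paste0(stack$source_id,
                       if (nzchar(stack$source_id)) "/" else "",
                       scheme$level))
  list(reduced = reduced, retained_indices = keep0)
}

#' Fraction of frames retained by a scheme
#'
#' @param scheme A \code{\link{frr_scheme}} (or level).
#' @param n_frames Original frame count, >= 1.
#' @return \code{|retained| / n_frames}; tends to \code{1/stride} for long runs.
#' @export
retained_fraction <- function(scheme, n_frames) {
  if (!inherits(scheme, "frr_scheme")) scheme <- frr_scheme(scheme)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("retained_fraction: n_frames must be >= 1", call. = FALSE)
  length(seq.int(0L, n_frames - 1L, by = scheme$keep_stride)) / n_frames
}
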