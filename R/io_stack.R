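#' Read a multi-frame angiographic stack
#'
#' Supported formats:
#' \describe{
#'   \item{\code{raw_array}}{Lossless float64 container: a flat binary file of
#'     little-endian doubles (column-major \code{[frame, row, col]} order) plus
#'     a plain-text \code{<path>.meta} sidecar carrying \code{rows}, \code{cols},
#'     \code{n_frames}, \code{frame_rate}, \code{polarity}.  The package's
#'     native interchange/fixture format.}
#'   \item{\code{tiff_stack}}{Multi-page TIFF with 32-bit samples.  Intensities
#'     are stored divided by a power-of-two \code{scale} recorded in the same
#'     \code{<path>.meta} sidecar (TIFF samples are normalized to [0, 1] at
#'     32-bit depth), so round-trips are exact to one part in 2^32 of full
#'     scale -- far below the quantization of any clinical detector, but not
#'     bit-exact; use raw_array where bit-exactness matters.}
#'   \item{\code{dicom_multiframe}}{Multi-frame X-ray angiography DICOM, read
#'     through the host Python's \code{pydicom}.  Frame rate is taken from the
#'     cine-rate tag (0018,0040), the recommended display frame rate, or the
#'     frame-time tag (0018,1063), in that order; an explicit \code{frame_rate}
#'     argument overrides all of them.  Subtracted DICOM renders contrast dark,
#'     so polarity defaults to \code{contrast_dark} (and is inverted).}
#' }
#' The returned stack is always normalized to \code{contrast_bright} polarity:
#' contrast arrival raises intensity.
#'
#' @param path File to read.
#' @param format One of \code{"raw_array"}, \code{"tiff_stack"},
#'   \code{"dicom_multiframe"}.
#' @param frame_rate Optional frames-per-second override; takes precedence
#'   over any metadata (clinical frame-rate tags are unreliable).
#' @param polarity Optional polarity override (\code{"contrast_bright"} or
#'   \code{"contrast_dark"}) describing the data \emph{on file}.
#' @return A \code{\link{frame_stack}} in canonical bright-contrast polarity.
#' @seealso \code{\link{write_stack}}
#' @export
read_stack <- function(path,
                       format = c("raw_array", "tiff_stack", "dicom_multiframe"),
                       frame_rate = NULL, polarity = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("read_stack: file not found: ", path, call. = FALSE)
  s <- switch(format,
              raw_array = read_raw_array(path),
              tiff_stack = read_tiff_stack(path),
              dicom_multiframe = read_dicom_multiframe(path))
  if (!is.null(frame_rate)) {
    s$grid <- time_grid(s$grid$n_frames, frame_rate, s$grid$origin)
  } else if (is.na(s$grid$frame_rate)) {
    stop("read_stack: no frame-rate metadata in ", path,
         " and no frame_rate override supplied", call. = FALSE)
  }
  if (!is.null(polarity)) {
    s$polarity <- match.arg(polarity, c("contrast_bright", "contrast_dark"))
  }
  normalize_polarity(s)
}

#' Write a multi-frame angiographic stack
#'
#' @param stack A \code{\link{frame_stack}}.
#' @param path Output file.
#' @param format \code{"raw_array"} or \code{"tiff_stack"} (DICOM writing is
#'   out of scope).  Both formats write a plain-text \code{<path>.meta}
#'   sidecar with the acquisition metadata.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, format = c("raw_array", "tiff_stack")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "frame_stack"))
  switch(format,
         raw_array = write_raw_array(stack, path),
         tiff_stack = write_tiff_stack(stack, path))
  invisible(path)
}

meta_path <- function(path) paste0(path, ".meta")

write_meta <- function(path, fields) {
  lines <- sprintf("%s=%s", names(fields),
                   vapply(fields, function(v) format(v, digits = 17),
                          character(1)))
  writeLines(lines, meta_path(path))
}

read_meta <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp))
    stop("read_stack: missing metadata sidecar ", mp, call. = FALSE)
  lines <- readLines(mp, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1L))
}

write_raw_array <- function(stack, path) {
  d <- dim(stack$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(stack$voxels), con, size = 8L, endian = "little")
  write_meta(path, list(format = "raw_array", n_frames = d[1], rows = d[2],
                        cols = d[3], frame_rate = stack$grid$frame_rate,
                        origin = stack$grid$origin, polarity = stack$polarity))
}

read_raw_array <- function(path) {
  m <- read_meta(path)
  d <- as.integer(c(m$n_frames, m$rows, m$cols))
  if (any(is.na(d)) || d[1] < 1L)
    stop("read_stack: corrupt raw_array metadata for ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
  if (length(v) != prod(d))
    stop("read_stack: raw_array payload truncated: ", path, call. = FALSE)
  frame_stack(array(v, d),
              grid = time_grid(d[1], as.numeric(m$frame_rate),
                               as.numeric(m$origin %||% 0)),
              polarity = m$polarity %||% "contrast_bright")
}

write_tiff_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  vmax <- max(stack$voxels, 0)
  # power-of-two scale keeps the divide/multiply exact in floating point
  scale <- if (vmax <= 1) 1 else 2^ceiling(log2(vmax))
  pages <- lapply(seq_len(d[1]), function(k) stack$voxels[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  write_meta(path, list(format = "tiff_stack", n_frames = d[1], rows = d[2],
                        cols = d[3], frame_rate = stack$grid$frame_rate,
                        origin = stack$grid$origin, polarity = stack$polarity,
                        scale = scale))
}

read_tiff_stack <- function(path) {
  m <- read_meta(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L)
    stop("read_stack: empty TIFF stack: ", path, call. = FALSE)
  scale <- as.numeric(m$scale %||% 1)
  v <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (k in seq_along(pages)) v[k, , ] <- pages[[k]][, , drop = TRUE] * scale
  frame_stack(v,
              grid = time_grid(length(pages), as.numeric(m$frame_rate),
                               as.numeric(m$origin %||% 0)),
              polarity = m$polarity %||% "contrast_bright")
}

# pydicom bridge: dump pixel data and frame-rate tags of a multi-frame DICOM
# to a temporary raw_array that the native reader then loads.
dicom_dump_script <- '
import sys, json
import numpy as np
import pydicom

src, raw_out, meta_out = sys.argv[1:4]
ds = pydicom.dcmread(src)
arr = ds.pixel_array.astype(np.float64)
if arr.ndim == 2:
    arr = arr[None, :, :]
fps = ""
if getattr(ds, "CineRate", None):
    fps = float(ds.CineRate)
elif getattr(ds, "RecommendedDisplayFrameRate", None):
    fps = float(ds.RecommendedDisplayFrameRate)
elif getattr(ds, "FrameTime", None):
    fps = 1000.0 / float(ds.FrameTime)
# column-major [frame, row, col] doubles, matching the raw_array layout
arr.transpose(2, 1, 0).ravel(order="C").tofile(raw_out)
with open(meta_out, "w") as fh:
    fh.write("format=raw_array\\n")
    fh.write("n_frames=%d\\nrows=%d\\ncols=%d\\n" % arr.shape)
    fh.write("frame_rate=%s\\norigin=0\\npolarity=contrast_dark\\n" % (fps or "NA"))
'

read_dicom_multiframe <- function(path) {
  tmp <- tempfile(fileext = ".raw")
  on.exit(unlink(c(tmp, meta_path(tmp))), add = TRUE)
  status <- suppressWarnings(
    system2("python", c("-", shQuote(path), shQuote(tmp),
                        shQuote(meta_path(tmp))),
            input = dicom_dump_script, stdout = FALSE, stderr = TRUE))
  if (!is.null(attr(status, "status")) || !file.exists(tmp))
    stop("read_stack: pydicom could not parse ", path,
         if (length(status)) paste0(": ", paste(status, collapse = " ")),
         call. = FALSE)
  m <- read_meta(tmp)
  d <- as.integer(c(m$n_frames, m$rows, m$cols))
  con <- file(tmp, "rb")
  v <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
  close(con)
  fr <- suppressWarnings(as.numeric(m$frame_rate))
  g <- time_grid(d[1], if (is.na(fr)) 1 else fr)
  # NA frame rate is re-flagged by read_stack unless an override was given
  if (is.na(fr)) g$frame_rate <- NA_real_
  frame_stack(array(v, d), grid = g,
              polarity = "contrast_dark", source_id = basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
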