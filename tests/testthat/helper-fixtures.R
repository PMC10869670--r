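# Shared fixtures and independent oracles, built in code at test time.

gv_series <- function(amplitude, alpha, beta, at, times) {
  u <- times - at
  out <- numeric(length(times))
  pos <- u > 0
  out[pos] <- amplitude * u[pos]^alpha * exp(-u[pos] / beta)
  out
}

# a small stack where every voxel follows a known gamma-variate curve
make_gv_stack <- function(rows = 4, cols = 4, n_frames = 16, frame_rate = 2,
                          params = NULL, seed = 1) {
  grid <- time_grid(n_frames, frame_rate)
  tt <- frame_times(grid)
  if (is.null(params)) {
    set.seed(seed)
    params <- lapply(seq_len(rows * cols), function(i) {
      a <- runif(1, 1.5, 3.5); b <- runif(1, 0.4, 1.0)
      at <- runif(1, 0.5, 2.0); pk <- runif(1, 30, 100)
      m <- a * b
      list(amplitude = pk / (m^a * exp(-a)), alpha = a, beta = b, at = at)
    })
  }
  vox <- array(0, c(n_frames, rows, cols))
  k <- 0L
  for (cc in seq_len(cols)) for (rr in seq_len(rows)) {
    k <- k + 1L
    p <- params[[k]]
    vox[, rr, cc] <- gv_series(p$amplitude, p$alpha, p$beta, p$at, tt)
  }
  list(stack = frame_stack(vox, grid = grid), params = params)
}

# Eq.-1 error map computed by an exhaustive triple loop (independent oracle)
error_map_bruteforce <- function(original, sdsa, epsilon) {
  d <- dim(original$voxels)
  per <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    errs <- c()
    for (t in seq_len(d[1])) {
      o <- original$voxels[t, i, j]
      if (o > epsilon)
        errs <- c(errs, abs(o - sdsa$voxels[t, i, j]) / o)
    }
    if (length(errs)) {
      per[i, j] <- mean(errs)
      valid[i, j] <- TRUE
    }
  }
  list(per_voxel_error = per, valid_mask = valid)
}

# Kendall's W straight from the rank-sum-variance definition, with mid-ranks
# and the textbook tie correction (independent of the package implementation)
kendalls_w_bruteforce <- function(ratings) {
  m <- nrow(ratings); n <- ncol(ratings)
  rk <- t(apply(ratings, 1, rank))
  Rj <- colSums(rk)
  S <- sum((Rj - m * (n + 1) / 2)^2)
  Tcorr <- 0
  for (i in seq_len(m)) {
    for (tsize in table(rk[i, ])) Tcorr <- Tcorr + (tsize^3 - tsize)
  }
  12 * S / (m^2 * (n^3 - n) - m * Tcorr)
}

# write a tiny multi-frame XA DICOM with pydicom; returns path or NULL
make_dicom_fixture <- function(path, arr, cine_rate = NULL) {
  np_vals <- paste(as.integer(arr), collapse = ",")
  d <- dim(arr)  # [frame, row, col]
  script <- sprintf('
import sys
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
fm = FileMetaDataset()
fm.MediaStorageSOPClassUID = pydicom.uid.XRayAngiographicImageStorage
fm.MediaStorageSOPInstanceUID = generate_uid()
fm.TransferSyntaxUID = ExplicitVRLittleEndian
ds = Dataset(); ds.file_meta = fm
ds.SOPClassUID = fm.MediaStorageSOPClassUID
ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID
ds.NumberOfFrames, ds.Rows, ds.Columns = %d, %d, %d
ds.SamplesPerPixel = 1; ds.PhotometricInterpretation = "MONOCHROME2"
ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
ds.PixelRepresentation = 0
%s
vals = np.array([%s], dtype=np.uint16)
arr = vals.reshape((%d, %d, %d), order="F")  # match R column-major layout
ds.PixelData = np.ascontiguousarray(arr).tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', d[1], d[2], d[3],
    if (is.null(cine_rate)) "" else sprintf("ds.CineRate = %d", cine_rate),
    np_vals, d[1], d[2], d[3], path)
  status <- suppressWarnings(
    system2("python", "-", input = script, stdout = FALSE, stderr = TRUE))
  if (!is.null(attr(status, "status")) || !file.exists(path)) NULL else path
}
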