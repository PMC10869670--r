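#' Specification of a synthetic vascular phantom
#'
#' Describes a desk-scale stand-in for a cerebral DSA run: a procedural
#' vessel tree rasterized onto an image, where every vessel voxel's
#' time-intensity curve follows gamma-variate kinetics drawn from one of
#' three compartments whose arrival times reproduce the physiological
#' ordering arterial < capillary < venous, with optional additive Gaussian
#' noise.  The defaults emulate a short cerebral run that samples all three
#' phases: 16 frames at 2 frames/s.
#'
#' @param rows,cols Image dimensions (default 64 x 64).
#' @param n_frames Frame count (default 16, the clinical inclusion floor).
#' @param frame_rate Frames per second (default 2).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @param vessel_segments Number of random-walk vessel segments (default 9,
#'   three per compartment).
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   \code{max_intensity} (default 0.02); 0 for a noise-free phantom.
#' @param max_intensity Full-scale intensity (default 100, arbitrary units).
#' @param compartments Per-class kinetic ranges, a named list of lists with
#'   uniform-draw ranges \code{at}, \code{alpha}, \code{beta} (seconds) and
#'   \code{peak} (fraction of \code{max_intensity}).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(rows = 64, cols = 64, n_frames = 16, frame_rate = 2,
                         seed = 1, vessel_segments = 9, noise_sigma = 0.02,
                         max_intensity = 100,
                         compartments = default_compartments()) {
  if (rows < 8 || cols < 8)
    stop("phantom_spec: image must be at least 8x8", call. = FALSE)
  if (n_frames < 1)
    stop("phantom_spec: n_frames must be >= 1", call. = FALSE)
  stopifnot(all(c("arterial", "capillary", "venous") %in% names(compartments)))
  sp <- list(rows = as.integer(rows), cols = as.integer(cols),
             n_frames = as.integer(n_frames), frame_rate = frame_rate,
             seed = as.integer(seed),
             vessel_segments = as.integer(vessel_segments),
             noise_sigma = noise_sigma, max_intensity = max_intensity,
             compartments = compartments)
  class(sp) <- "phantom_spec"
  sp
}

#' Default compartment kinetics of the phantom
#'
#' Arrival-time windows stagger the three phases (arterial 0.5-1.5 s,
#' capillary 1.5-3 s, venous 3-5 s); shape and timescale ranges
#' (alpha 1.5-4, beta 0.3-1.2 s) give first-pass transit curves of 1-5 s
#' width; peak enhancement spans 30-100\% of full scale.
#'
#' @return Named list of per-class uniform ranges.
#' @export
default_compartments <- function() {
  base <- list(alpha = c(1.5, 4), beta = c(0.3, 1.2), peak = c(0.3, 1))
  list(arterial = c(list(at = c(0.5, 1.5)), base),
       capillary = c(list(at = c(1.5, 3)), base),
       venous = c(list(at = c(3, 5)), base))
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# anti-aliased stamping of a disc of diameter `width` centred at (r, c)
# onto a coverage matrix: coverage = clamp(width/2 + 0.5 - distance, 0, 1)
stamp_disc <- function(cov, r, c, width) {
  rad <- ceiling(width / 2 + 1)
  ri <- max(1, floor(r - rad)):min(nrow(cov), ceiling(r + rad))
  ci <- max(1, floor(c - rad)):min(ncol(cov), ceiling(c + rad))
  dist <- sqrt(outer((ri - r)^2, (ci - c)^2, `+`))
  patch <- pmin(pmax(width / 2 + 0.5 - dist, 0), 1)
  cov[ri, ci] <- pmax(cov[ri, ci], patch)
  cov
}

#' Generate a synthetic angiographic phantom with known ground truth
#'
#' Draws \code{vessel_segments} random-walk polylines (class assigned
#' round-robin over arterial, capillary, venous; width tapering along each
#' walk, arterial widest) and rasterizes them with anti-aliased thick
#' strokes.  Each vessel voxel receives gamma-variate parameters drawn
#' i.i.d. from its compartment's ranges, with the peak scaled by the
#' voxel's edge coverage (partial-volume effect); its time course is the
#' exact model curve plus optional Gaussian noise (clipped at 0).
#' Background voxels are pure noise.  All randomness flows from
#' \code{spec$seed}, so identical specs yield bit-identical phantoms.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list with \code{stack} (\code{\link{frame_stack}}),
#'   \code{truth} (data frame: \code{row}, \code{col}, \code{class},
#'   \code{amplitude}, \code{alpha}, \code{beta}, \code{at}, \code{tmax},
#'   \code{peak}) and \code{class_mask} (character matrix over
#'   \code{"background"}, \code{"arterial"}, \code{"capillary"},
#'   \code{"venous"}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    classes <- c("arterial", "capillary", "venous")
    seg_class <- rep(classes, length.out = spec$vessel_segments)
    start_width <- c(arterial = 6, capillary = 2, venous = 4)
    cov <- lapply(classes, function(cl) matrix(0, spec$rows, spec$cols))
    names(cov) <- classes
    n_steps <- max(spec$rows, spec$cols)
    for (s in seq_len(spec$vessel_segments)) {
      cl <- seg_class[s]
      r <- stats::runif(1, 0.15, 0.85) * spec$rows
      c <- stats::runif(1, 0.15, 0.85) * spec$cols
      ang <- stats::runif(1, 0, 2 * pi)
      w0 <- start_width[[cl]]
      for (k in seq_len(n_steps)) {
        w <- max(1, w0 * (1 - 0.8 * (k - 1) / n_steps))   # tapering caliber
        cov[[cl]] <- stamp_disc(cov[[cl]], r, c, w)
        ang <- ang + stats::rnorm(1, 0, 0.25)
        r <- r + sin(ang); c <- c + cos(ang)
        if (r < 2 || r > spec$rows - 1 || c < 2 || c > spec$cols - 1) break
      }
    }
    cov3 <- simplify2array(cov)                       # rows x cols x class
    best <- apply(cov3, c(1, 2), which.max)
    best_cov <- apply(cov3, c(1, 2), max)
    class_mask <- matrix("background", spec$rows, spec$cols)
    enh <- best_cov >= 0.5
    class_mask[enh] <- classes[best[enh]]

    idx <- which(enh, arr.ind = TRUE)
    n_enh <- nrow(idx)
    grid <- time_grid(spec$n_frames, spec$frame_rate)
    tt <- frame_times(grid)
    vox <- array(0, c(spec$n_frames, spec$rows, spec$cols))
    truth <- data.frame(row = integer(n_enh), col = integer(n_enh),
                        class = character(n_enh), amplitude = numeric(n_enh),
                        alpha = numeric(n_enh), beta = numeric(n_enh),
                        at = numeric(n_enh), tmax = numeric(n_enh),
                        peak = numeric(n_enh))
    for (i in seq_len(n_enh)) {
      rr <- idx[i, 1]; cc <- idx[i, 2]
      cl <- class_mask[rr, cc]
      rg <- spec$compartments[[cl]]
      at <- stats::runif(1, rg$at[1], rg$at[2])
      alpha <- stats::runif(1, rg$alpha[1], rg$alpha[2])
      beta <- stats::runif(1, rg$beta[1], rg$beta[2])
      pk <- stats::runif(1, rg$peak[1], rg$peak[2]) * spec$max_intensity *
        best_cov[rr, cc]
      m <- alpha * beta
      amp <- pk / (m^alpha * exp(-alpha))
      vox[, rr, cc] <- gv_eval_raw(amp, alpha, beta, at, tt)
      truth[i, ] <- list(rr, cc, cl, amp, alpha, beta, at, at + m, pk)
    }
    if (spec$noise_sigma > 0) {
      vox <- vox + stats::rnorm(length(vox),
                                sd = spec$noise_sigma * spec$max_intensity)
      vox <- pmax(vox, 0)
      vox <- array(vox, c(spec$n_frames, spec$rows, spec$cols))
    }
    stack <- frame_stack(vox, grid = grid, polarity = "contrast_bright",
                         source_id = sprintf("phantom(seed=%d)", spec$seed))
    list(stack = stack, truth = truth, class_mask = class_mask)
  })
}

#' Parameter-recovery table against phantom ground truth
#'
#' Joins a fit map with the phantom's true parameters and reports, per
#' compartment class, the median relative error of amplitude, alpha, beta,
#' arrival time and Tmax over voxels that were fitted.
#'
#' @param fit_map A \code{gv_fit_map} from \code{\link{fit_stack}}.
#' @param truth Truth data frame from \code{\link{generate_phantom}}.
#' @param class_mask Class matrix from \code{\link{generate_phantom}}
#'   (currently informational; classes come from \code{truth}).
#' @return Data frame with one row per class (plus \code{"all"}): \code{n}
#'   fitted voxels and median relative errors \code{amplitude},
#'   \code{alpha}, \code{beta}, \code{at}, \code{tmax}.
#' @export
truth_error <- function(fit_map, truth, class_mask = NULL) {
  stopifnot(inherits(fit_map, "gv_fit_map"), is.data.frame(truth))
  fitted <- fit_map[fit_map$status == "fitted", ]
  j <- merge(truth, fitted, by = c("row", "col"),
             suffixes = c("_true", "_fit"))
  rel <- function(a, b) abs(a - b) / abs(b)
  j$e_amplitude <- rel(j$amplitude_fit, j$amplitude_true)
  j$e_alpha <- rel(j$alpha_fit, j$alpha_true)
  j$e_beta <- rel(j$beta_fit, j$beta_true)
  j$e_at <- rel(j$at_fit, j$at_true)
  j$e_tmax <- rel(j$at_fit + j$alpha_fit * j$beta_fit, j$tmax)
  one <- function(d, label) {
    data.frame(class = label, n = nrow(d),
               amplitude = stats::median(d$e_amplitude),
               alpha = stats::median(d$e_alpha),
               beta = stats::median(d$e_beta),
               at = stats::median(d$e_at),
               tmax = stats::median(d$e_tmax))
  }
  cls <- c("arterial", "capillary", "venous")
  out <- do.call(rbind, lapply(cls, function(cl) one(j[j$class == cl, ], cl)))
  rbind(out, one(j, "all"))
}

#' Write phantom ground truth as CSV
#'
#' @param truth Truth data frame from \code{\link{generate_phantom}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
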