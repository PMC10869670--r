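test_that("noise estimate recovers the Gaussian sigma of a pure-noise stack", {
  set.seed(21)
  sigma <- 10
  vox <- array(rnorm(32 * 64 * 64, sd = sigma), c(32, 64, 64))
  st <- frame_stack(vox - min(vox), frame_rate = 2)   # keep finite/positive
  est <- estimate_noise(st)
  expect_lt(abs(est - sigma) / sigma, 0.15)
  # all-zero stack has zero temporal noise
  z <- frame_stack(array(0, c(4, 3, 3)), frame_rate = 2)
  expect_equal(estimate_noise(z), 0)
  # noise-free phantom (mostly background): estimate far below the peak
  ph <- generate_phantom(phantom_spec(rows = 32, cols = 32, seed = 2,
                                      noise_sigma = 0))
  expect_lt(estimate_noise(ph$stack), 0.05 * max(ph$stack$voxels))
  expect_error(estimate_noise(frame_stack(array(1, c(1, 2, 2)),
                                          frame_rate = 1)), "2 frames")
})

test_that("initial guess lands near the generating parameters", {
  tt <- seq(0, 15) / 1                     # 16 frames at 1 fps
  v <- gv_series(30, 2, 1, at = 1, times = tt)
  g <- initial_guess(tt, v)
  expect_lt(abs(g$at - 1), 1)              # within one frame of the true AT
  expect_gt(g$alpha, 0)
  expect_gt(g$beta, 0)
  # single nonzero sample: AT guess precedes it, peak time is at it
  v2 <- numeric(16); v2[6] <- 5
  g2 <- initial_guess(tt, v2)
  expect_lt(g2$at, tt[6])
  # monotone ramp: peak guess at the last frame still yields valid params
  g3 <- initial_guess(tt, seq_along(tt))
  expect_s3_class(g3, "gv_params")
  expect_error(initial_guess(tt, numeric(16)), "degenerate")
})

test_that("noise-free curves are recovered essentially exactly", {
  tt <- seq(2, 5.5, by = 0.5)              # 8 samples spanning AT and Tmax
  true <- list(amplitude = 50, alpha = 2, beta = 1.5, at = 2)
  v <- gv_series(true$amplitude, true$alpha, true$beta, true$at, tt)
  fr <- fit_voxel(tt, v, fit_config(), sigma = 0)
  expect_identical(fr$status, "fitted")
  for (nm in c("amplitude", "alpha", "beta", "at"))
    expect_lt(abs(fr$params[[nm]] - true[[nm]]) / true[[nm]], 1e-3)
  expect_lt(fr$rmse, 1e-6 * max(v))
})

test_that("exact recovery holds across random identifiable curves", {
  set.seed(11)
  tt <- seq(0, 7.5, 0.5)[seq(1, 16, 2)]    # the 50% reduced grid
  n_checked <- 0
  for (i in 1:60) {
    a <- runif(1, 1.5, 4); b <- runif(1, 0.3, 1.2); at <- runif(1, 0.5, 4)
    pk <- runif(1, 30, 100); m <- a * b
    amp <- pk / (m^a * exp(-a))
    v <- gv_series(amp, a, b, at, tt)
    # identifiable: >= 4 post-arrival samples and the window spans Tmax
    if (sum(v > 0) < 4 || at + m > max(tt[v > 0])) next
    n_checked <- n_checked + 1
    fr <- fit_voxel(tt, v)
    expect_identical(fr$status, "fitted")
    rel <- max(abs(fr$params$amplitude - amp) / amp,
               abs(fr$params$alpha - a) / a,
               abs(fr$params$beta - b) / b,
               abs(fr$params$at - at) / at)
    expect_lt(rel, 1e-3)
    expect_lt(fr$rmse, 1e-6 * pk)
  }
  expect_gt(n_checked, 20)
})

test_that("classification cascade: background, fallback, argument errors", {
  expect_identical(fit_voxel(0:7, numeric(8), sigma = 1)$status, "background")
  # peak below 3*sigma is background even if nonzero
  v <- c(0, 1, 2, 1, 0, 0, 0, 0)
  expect_identical(fit_voxel(0:7, v, sigma = 1)$status, "background")
  # too few samples for four free parameters
  expect_identical(fit_voxel(0:2, c(0, 5, 2), sigma = 0)$status,
                   "fallback_interp")
  expect_error(fit_voxel(0:3, 1:3), "equal length")
  expect_error(fit_voxel(c(0, 2, 1, 3), c(1, 2, 3, 4)), "increasing")
  expect_error(fit_config(min_fit_points = 3), "min_fit_points")
})

test_that("stack fitting covers every voxel and is deterministic", {
  fx <- make_gv_stack(rows = 6, cols = 5, n_frames = 16, frame_rate = 2,
                      seed = 3)
  red <- reduce_stack(fx$stack, 50)$reduced
  fm1 <- fit_stack(red)
  fm2 <- fit_stack(red)
  expect_identical(fm1, fm2)
  expect_equal(nrow(fm1), 30)
  expect_setequal(paste(fm1$row, fm1$col),
                  paste(rep(1:6, 5), rep(1:5, each = 6)))
  # all-background stack: every voxel classified background
  z <- frame_stack(array(0, c(8, 4, 4)), frame_rate = 2)
  fmz <- fit_stack(z, sigma = 1)
  expect_true(all(fmz$status == "background"))
  expect_equal(fit_census(fmz)[["background"]], 16L)
})

test_that("fit configuration round-trips through a key=value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("noise_floor_k=2.5", "min_fit_points=5",
               "max_iterations=77  # cap", "upper.alpha=12"), path)
  cfg <- read_fit_config(path)
  expect_equal(cfg$noise_floor_k, 2.5)
  expect_equal(cfg$min_fit_points, 5L)
  expect_equal(cfg$max_iterations, 77L)
  expect_equal(cfg$bounds$upper[["alpha"]], 12)
  writeLines("nonsense=1", path)
  expect_error(read_fit_config(path), "unknown key")
})
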