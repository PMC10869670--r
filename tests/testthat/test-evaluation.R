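test_that("voxelwise relative error follows the ratio definition", {
  expect_equal(voxel_error(100, 90, epsilon = 1), 0.10)
  expect_equal(voxel_error(50, 50, epsilon = 1), 0)
  expect_true(is.na(voxel_error(0, 5, epsilon = 1)))   # masked denominator
  expect_equal(voxel_error(c(100, 0, 10), c(90, 1, 11), epsilon = 0.5),
               c(0.10, NA, 0.10))
})

test_that("error map matches hand arithmetic on uniform scaling", {
  fx <- make_gv_stack(rows = 4, cols = 4, n_frames = 12, frame_rate = 2)
  same <- error_map(fx$stack, fx$stack, epsilon = 1)
  expect_true(all(same$per_voxel_error[same$valid_mask] == 0))
  expect_equal(same$summary$mean, 0)
  shrunk <- frame_stack(0.9 * fx$stack$voxels, grid = fx$stack$grid)
  em <- error_map(fx$stack, shrunk, epsilon = 1)
  expect_equal(em$per_voxel_error[em$valid_mask],
               rep(0.10, em$summary$n_valid))
  expect_equal(em$summary$sd, 0)
  expect_error(error_map(fx$stack,
                         frame_stack(array(1, c(12, 3, 3)), frame_rate = 2)),
               "dimensions")
})

test_that("vectorized error map equals the brute-force triple loop", {
  set.seed(31)
  for (rep in 1:5) {
    o <- frame_stack(array(runif(8 * 8 * 6, 0, 50), c(6, 8, 8)),
                     frame_rate = 2)
    s <- frame_stack(array(runif(8 * 8 * 6, 0, 50), c(6, 8, 8)),
                     frame_rate = 2)
    eps <- runif(1, 0, 10)
    em <- error_map(o, s, epsilon = eps)
    bf <- error_map_bruteforce(o, s, epsilon = eps)
    expect_equal(em$per_voxel_error, bf$per_voxel_error)
    expect_identical(em$valid_mask, bf$valid_mask)
    # masking conservation
    expect_equal(em$summary$n_valid + sum(!em$valid_mask), 64)
  }
})

test_that("the error metric is invariant under joint intensity scaling", {
  fx <- make_gv_stack(rows = 3, cols = 3, n_frames = 10, frame_rate = 2,
                      seed = 17)
  syn <- frame_stack(fx$stack$voxels * 0.95 +
                       0.5 * sin(seq_along(fx$stack$voxels)),
                     grid = fx$stack$grid)
  syn$voxels <- pmax(syn$voxels, 0)
  syn$voxels <- array(syn$voxels, dim(fx$stack$voxels))
  e1 <- error_map(fx$stack, syn, epsilon = 2)
  c_ <- 3.7
  o2 <- frame_stack(c_ * fx$stack$voxels, grid = fx$stack$grid)
  s2 <- frame_stack(c_ * syn$voxels, grid = fx$stack$grid)
  e2 <- error_map(o2, s2, epsilon = c_ * 2)
  expect_equal(e1$per_voxel_error, e2$per_voxel_error)
})

test_that("heatmaps render green at low and red at high error", {
  fx <- make_gv_stack(rows = 6, cols = 6, n_frames = 8, frame_rate = 2)
  zero <- error_map(fx$stack, fx$stack, epsilon = 1)
  p1 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(zero, p1)
  img <- png::readPNG(p1)
  valid <- zero$valid_mask
  expect_true(all(img[, , 2][valid] > 0.5))      # green channel dominant
  expect_true(all(img[, , 1][valid] < 0.1))
  # constant 15% error: uniformly red
  red15 <- zero
  red15$per_voxel_error[red15$valid_mask] <- 0.15
  render_heatmap(red15, p1)
  img <- png::readPNG(p1)
  expect_true(all(img[, , 1][valid] > 0.9))
  expect_true(all(img[, , 2][valid] < 0.1))
  # masked voxels are neutral gray
  expect_true(all(abs(img[, , 2][!valid] - 0.5) < 0.01))
})

test_that("a 0-20% ramp renders a monotone green-to-red progression, clipped", {
  em <- structure(list(
    per_voxel_error = matrix(seq(0, 0.20, length.out = 24), 4, 6),
    valid_mask = matrix(TRUE, 4, 6),
    summary = list(mean = 0.1, sd = 0.05, n_valid = 24, epsilon = 0)),
    class = "error_map")
  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(em, path)
  img <- png::readPNG(path)
  redness <- (img[, , 1] - img[, , 2])[order(em$per_voxel_error)]
  expect_true(all(diff(redness) >= -1e-9))       # monotone hue progression
  # clipped above 15%: top of the ramp is fully saturated red
  expect_equal(img[, , 1][em$per_voxel_error >= 0.15],
               rep(1, sum(em$per_voxel_error >= 0.15)))
})

test_that("study reports aggregate per scheme and are reproducible", {
  fx <- make_gv_stack(rows = 5, cols = 5, n_frames = 16, frame_rate = 2,
                      seed = 23)
  sdsas <- list()
  fms <- list()
  for (lvl in c(50, 75)) {
    res <- synthesize_study(fx$stack, lvl, sigma = 0)   # all-vessel fixture
    sdsas[[paste0("FRR", lvl)]] <- res$sdsa
    fms[[paste0("FRR", lvl)]] <- res$fit_map
  }
  rep1 <- study_report(fx$stack, sdsas, fms)
  expect_equal(nrow(rep1), 2)
  expect_true(all(c("mean_error_pct", "n_fitted") %in% names(rep1)))
  # more retained frames cannot hurt the noise-free reconstruction
  expect_lte(rep1$mean_error_pct[rep1$scheme == "FRR50"],
             rep1$mean_error_pct[rep1$scheme == "FRR75"])
  # identical stacks give a zero-error row
  rep0 <- study_report(fx$stack, list(self = fx$stack))
  expect_equal(rep0$mean_error_pct, 0)
  # byte-identical CSV on re-run
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_study_report(rep1, f1)
  write_study_report(study_report(fx$stack, sdsas, fms), f2)
  expect_identical(readLines(f1), readLines(f2))
})
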