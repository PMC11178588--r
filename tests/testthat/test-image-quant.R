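make_uniform_image <- function(value, n = 24, voxel = 4.7952, units = "cps/voxel",
                               window = 440) {
  quant_image(array(value, rep(n, 3)), rep(voxel, 3), units = units,
              window_kev = window)
}

test_that("calibration factor is the cps-to-concentration ratio", {
  voi <- voi_mask(array(TRUE, rep(24, 3)), "phantom")
  for (c_fac in c(0.5, 1, 2.7e-4)) {
    img <- make_uniform_image(524 * c_fac)
    f <- compute_calibration_factor(img, 524, voi)
    expect_equal(f$value, c_fac, tolerance = 1e-12)
  }
  expect_error(compute_calibration_factor(make_uniform_image(1), 0, voi),
               class = "acdosim_invalid_input")
  expect_error(voi_mask(array(FALSE, rep(24, 3))),
               class = "acdosim_segmentation_error")
  # calibrated units guard
  img_bq <- make_uniform_image(1, units = "Bq/ml")
  expect_error(compute_calibration_factor(img_bq, 524, voi),
               class = "acdosim_configuration_error")
})

test_that("Poisson-noised phantom recovers the factor within 3 standard errors", {
  sc <- test_scenario(seed = 5)
  ph <- make_calibration_phantom(sc, "bi440", matrix_size = 80)
  f <- compute_calibration_factor(ph$image, ph$truth_concentration_bqml,
                                  ph$central_voi)
  n_vox <- sum(ph$central_voi$mask)
  counts_per_vox <- ph$truth_concentration_bqml * ph$truth_factor * sc$count_time_s
  se <- ph$truth_factor / sqrt(n_vox * counts_per_vox)
  expect_lt(abs(f$value - ph$truth_factor), 3 * se)
})

test_that("calibration application is exact, invertible and window-checked", {
  img <- make_uniform_image(524 * 2e-4)
  f1 <- structure(list(value = 1, window_kev = 440), class = "calibration_factor")
  expect_equal(apply_calibration(img, f1)$voxels, img$voxels)
  f <- structure(list(value = 2e-4, window_kev = 440), class = "calibration_factor")
  cal <- apply_calibration(img, f)
  expect_true(all(abs(cal$voxels - 524) < 1e-9))
  expect_identical(cal$units, "Bq/ml")
  # round trip to 1e-12
  back <- cal; back$voxels <- cal$voxels * f$value; back$units <- "cps/voxel"
  expect_equal(back$voxels, img$voxels, tolerance = 1e-12)
  f_wrong <- structure(list(value = 1, window_kev = 218), class = "calibration_factor")
  expect_error(apply_calibration(img, f_wrong), class = "acdosim_configuration_error")
})

test_that("Gaussian post-filter: identity at 0, mass conservation, impulse response", {
  n <- 32; voxel <- 4.7952
  img <- quant_image(array(stats::runif(n^3), rep(n, 3)), rep(voxel, 3))
  expect_identical(gaussian_postfilter(img, 0), img)

  # interior-supported image: total counts conserved to 1e-6
  arr <- array(0, rep(n, 3)); arr[12:20, 12:20, 12:20] <- 5
  img2 <- quant_image(arr, rep(voxel, 3))
  sm <- gaussian_postfilter(img2, 30)
  expect_equal(sum(sm$voxels), sum(arr), tolerance = 1e-6)

  # delta impulse reproduces the grid-sampled Gaussian, sigma ~2.657 voxels
  arr3 <- array(0, rep(n, 3)); arr3[17, 17, 17] <- 1
  out <- gaussian_postfilter(quant_image(arr3, rep(voxel, 3)), 30)$voxels
  sigma_vox <- 30 / (2 * sqrt(2 * log(2))) / voxel
  expect_equal(sigma_vox, 2.657, tolerance = 1e-3)
  g1 <- exp(-((1:n - 17))^2 / (2 * sigma_vox^2)); g1 <- g1 / sum(g1)
  expected <- outer(outer(g1, g1), g1)
  expect_equal(out, expected, tolerance = 1e-8)

  # uniform image is a fixed point (periodic boundary)
  u <- make_uniform_image(3.2, n = 24)
  expect_equal(gaussian_postfilter(u, 30)$voxels, u$voxels, tolerance = 1e-9)

  expect_error(gaussian_postfilter(img, -1), class = "acdosim_invalid_input")
})

test_that("isocontour keeps the >=80% core of a blurred sphere", {
  n <- 48; voxel <- 4
  ctr <- (n + 1) / 2
  coords <- (1:n - ctr) * voxel
  r2 <- outer(outer(coords^2, coords^2, `+`), coords^2, `+`)
  arr <- array(0, rep(n, 3)); arr[r2 <= 30^2] <- 100
  img <- gaussian_postfilter(quant_image(arr, rep(voxel, 3), units = "Bq/ml"), 20)
  region <- voi_mask(array(r2 <= 60^2, rep(n, 3)), "search")
  mask <- isocontour_mask(img, region, 0.8)
  # oracle: threshold the analytic blurred profile (radially symmetric,
  # evaluated on the same grid) at 80% of its max inside the region
  vox <- img$voxels
  mx <- max(vox[region$mask])
  oracle <- region$mask & vox >= 0.8 * mx
  expect_identical(mask$mask, oracle)  # single connected blob: identical sets
  # monotone shrinking in the threshold fraction
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
    sum(isocontour_mask(img, region, f)$mask)
  }, 0)
  expect_true(all(diff(sizes) < 0))
})

test_that("isocontour tie-breaking and near-1 fraction behave as specified", {
  n <- 24
  arr <- array(0, rep(n, 3)); arr[8, 8, 8] <- 10; arr[8, 9, 8] <- 9
  img <- quant_image(arr, rep(1, 3), units = "Bq/ml")
  region <- voi_mask(array(TRUE, rep(n, 3)), "all")
  m <- isocontour_mask(img, region, 0.999)
  expect_equal(sum(m$mask), 1L)
  expect_true(m$mask[8, 8, 8])
  # two equal maxima in disconnected blobs: first in scan order wins, warning
  arr[8, 8, 8] <- 10; arr[20, 20, 20] <- 10
  img2 <- quant_image(arr, rep(1, 3), units = "Bq/ml")
  expect_warning(m2 <- isocontour_mask(img2, region, 0.95), "maxima")
  expect_true(m2$mask[8, 8, 8])
  expect_false(m2$mask[20, 20, 20])
})

test_that("voi_quant computes SUV, volume and total activity per definition", {
  n <- 20; voxel <- 4.7952
  injected <- 7.9; weight <- 85
  conc <- injected * 1e6 / (weight * 1000)   # Bq/ml equal to Bq/g dose per g
  img <- quant_image(array(conc, rep(n, 3)), rep(voxel, 3), units = "Bq/ml")
  mask <- voi_mask(array(c(TRUE, FALSE), rep(n, 3)), "half")
  q <- voi_quant(img, mask, injected, weight)
  expect_equal(q$suv_mean, 1.0, tolerance = 1e-12)
  n_vox <- sum(mask$mask)
  expect_equal(q$volume_ml, n_vox * voxel^3 / 1000)
  expect_equal(q$total_activity_bq, n_vox * voxel^3 / 1000 * conc)
  expect_equal(q$total_activity_bq, q$mean_concentration_bqml * q$volume_ml,
               tolerance = 1e-9)
  expect_error(voi_quant(quant_image(img$voxels, rep(voxel, 3)), mask, 7.9, 85),
               class = "acdosim_configuration_error")
})

test_that("images and masks round-trip through NIfTI", {
  sc <- noisefree_scenario()
  sim <- make_phantom_image(sc, 1, 24, "fr218")
  tmp <- tempfile(fileext = ".nii.gz")
  write_quant_image(sim$image, tmp)
  back <- read_quant_image(tmp, units = "cps/voxel")
  expect_equal(back$voxels, sim$image$voxels, tolerance = 1e-6)
  expect_equal(back$voxel_size_mm, sim$image$voxel_size_mm, tolerance = 1e-5)
  tmp2 <- tempfile(fileext = ".nii.gz")
  write_voi_mask(sim$truth_masks[[1]], tmp2, sim$image$voxel_size_mm)
  back2 <- read_voi_mask(tmp2, label = sim$truth_masks[[1]]$label)
  expect_identical(back2$mask, sim$truth_masks[[1]]$mask)
  unlink(c(tmp, tmp2))
})

test_that("mask shifting translates by whole voxels and drops out-of-grid voxels", {
  arr <- array(FALSE, rep(10, 3)); arr[5, 5, 5] <- TRUE
  m <- voi_mask(arr, "pt")
  s <- shift_mask(m, c(2, -1, 0))
  expect_true(s$mask[7, 4, 5]); expect_equal(sum(s$mask), 1L)
  # everything off the grid leaves an empty (hence invalid) mask
  expect_error(shift_mask(m, c(20, 0, 0)), class = "acdosim_segmentation_error")
})
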