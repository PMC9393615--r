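make_cube <- function(values, wl = c(500, 600, 700, 792, 900),
                      kind = "reflectance") {
  spectral_cube(values, wl, kind)
}

test_that("calibration is the exact two-point affine inverse", {
  wl <- c(500, 600, 700)
  dims <- c(4, 5, 3)
  dark <- make_cube(array(100, dims), wl, "raw")
  white <- make_cube(array(4000, dims), wl, "raw")
  expect_equal(calibrate(white, dark, white)$values, array(1, dims))
  expect_equal(calibrate(dark, dark, white)$values, array(0, dims))
  mid <- make_cube(array(2050, dims), wl, "raw")
  expect_equal(calibrate(mid, dark, white)$values, array(0.5, dims))
  expect_equal(calibrate(mid, dark, white)$kind, "reflectance")
  bad_white <- make_cube(array(100, dims), wl, "raw")
  expect_error(calibrate(mid, dark, bad_white), "positive")
  small <- make_cube(array(1, c(2, 2, 3)), wl, "raw")
  expect_error(calibrate(small, dark, white), "share shape")
})

test_that("plant segmentation thresholds the 792 nm band", {
  dims <- c(6, 6, 5)
  vals <- array(0.05, dims)
  vals[2:4, 2:4, ] <- 0.4
  cube <- make_cube(vals)
  mask <- segment_plant(cube)
  expect_equal(sum(mask), 9)
  expect_true(all(mask[2:4, 2:4]))
  # monotone non-increasing in threshold; 0.5 loses the leaf entirely
  expect_true(all(segment_plant(cube, threshold = 0.3) >=
                    segment_plant(cube, threshold = 0.5)))
  expect_equal(sum(segment_plant(cube, threshold = 0.5)), 0)
  expect_error(segment_plant(make_cube(vals, kind = "raw")), "reflectance")
  expect_error(segment_plant(cube, wavelength = 1500), "no band within")
})

test_that("stem rectangles are half-open, bounds-checked removals", {
  mask <- matrix(TRUE, 10, 12)
  expect_identical(remove_stems(mask, NULL), mask)
  expect_identical(remove_stems(mask, tibble::tibble(x = numeric(),
                                                     y = numeric(),
                                                     width = numeric(),
                                                     height = numeric())),
                   mask)
  whole <- tibble::tibble(x = 0, y = 0, width = 12, height = 10)
  expect_false(any(remove_stems(mask, whole)))
  two <- tibble::tibble(x = c(0, 6), y = c(0, 4),
                        width = c(2, 3), height = c(3, 2))
  out <- remove_stems(mask, two)
  expect_equal(sum(!out), 2 * 3 + 3 * 2)  # disjoint, direct enumeration
  expect_false(out[1, 1])   # (x=0, y=0)
  expect_true(out[4, 1])    # y=3 is outside [0, 3)
  oob <- tibble::tibble(x = 11, y = 0, width = 2, height = 2)
  expect_error(remove_stems(mask, oob), "outside the image")
})

test_that("leaf extraction uses 8-connectivity, raster order and min_area", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE       # diagonal pair: one component
  comp <- extract_leaves(m, min_area = 1)
  expect_equal(max(comp), 1)
  expect_equal(comp[2, 2], comp[3, 3])

  m2 <- matrix(FALSE, 10, 10)
  m2[2:3, 2:4] <- TRUE                   # area 6, first in raster order
  m2[6:8, 6:8] <- TRUE                   # area 9
  comp2 <- extract_leaves(m2, min_area = 1)
  expect_equal(max(comp2), 2)
  expect_equal(comp2[2, 2], 1L)
  expect_equal(comp2[7, 7], 2L)
  expect_equal(sum(comp2 == 1), 6)
  expect_equal(sum(comp2 == 2), 9)
  # filter boundary: min_area = 7 drops the 6-pixel component
  comp3 <- extract_leaves(m2, min_area = 7)
  expect_equal(max(comp3), 1)
  expect_equal(sum(comp3 == 1), 9)
  expect_equal(max(extract_leaves(matrix(FALSE, 4, 4))), 0)
})

test_that("mean_spectrum averages the component's pixels per band", {
  dims <- c(3, 3, 2)
  vals <- array(0.7, dims)
  vals[1, 1, ] <- c(0.2, 0.2)
  vals[1, 2, ] <- c(0.4, 0.4)
  cube <- make_cube(vals, wl = c(500, 600))
  sel <- matrix(FALSE, 3, 3); sel[1, 1:2] <- TRUE
  ms <- mean_spectrum(cube, sel)
  expect_equal(ms$wl_500, 0.3)
  expect_equal(ms$n_pixels, 2)
  const <- mean_spectrum(cube, matrix(c(FALSE, TRUE, rep(TRUE, 7)), 3, 3))
  expect_error(mean_spectrum(cube, matrix(FALSE, 3, 3)), "empty")
})

test_that("band trimming keeps 450-902 inclusively and is idempotent", {
  full <- spectrum_row(function(w) 0.5, wl = seq(380, 1030, by = 2))
  trimmed <- trim_bands(full)
  expect_equal(length(wl_cols(trimmed)), 227)
  expect_equal(range(wl_grid(trimmed)), c(450, 902))
  expect_identical(trim_bands(trimmed), trimmed)
  single <- trim_bands(full, low = 500, high = 500)
  expect_equal(wl_grid(single), 500)
  expect_error(trim_bands(full, low = 2000, high = 2100))
})

test_that("outlier screening fires the documented rules and is stable", {
  # a clean batch: measurement noise only, no biological random effects.
  # The distance rule is calibrated against noise (ratios of chi-like
  # distances concentrate far below the 4x median multiplier); biological
  # plant-to-plant spread is screened much more loosely.
  cfg <- small_config(seed = 11, plant_effect_sd = 0, leaf_effect_sd = 0)
  clean <- simulate_experiment(cfg, "Exp1")
  ann <- reject_outliers(clean)
  expect_equal(sum(ann$.outlier), 0)

  negated <- clean
  m <- spectra_matrix(clean)
  negated[1, wl_cols(clean)] <- as.list(-m[1, ])
  ann2 <- reject_outliers(negated)
  expect_true(ann2$.outlier[1])
  expect_match(ann2$.reason[1], "physical range")

  background <- clean
  background[2, wl_cols(clean)] <- as.list(rep(0.05, ncol(m)))
  ann3 <- reject_outliers(background)
  expect_true(ann3$.outlier[2])
  expect_match(ann3$.reason[2], "NIR")
  # 0.05 mean NIR is indeed below the 0.15 floor
  expect_lt(mean(rep(0.05, sum(wl_grid(clean) >= 780 &
                                 wl_grid(clean) <= 900))), 0.15)

  # distance rule: re-screening the retained set rejects nothing
  kept <- dplyr::select(dplyr::filter(ann3, !.outlier), -.outlier, -.reason)
  expect_equal(sum(reject_outliers(kept)$.outlier), 0)
})

test_that("render -> calibrate -> segment -> mean recovers input spectra", {
  cfg <- small_config(seed = 3)
  spectra <- simulate_experiment(cfg, "Exp1")[c(1, 30, 70), ]
  noise_sd <- 0.004
  scene <- withr::with_seed(99, {
    render_cube(spectra, pixel_noise_sd = noise_sd)
  })
  got <- extract_leaf_spectra(scene$raw, scene$dark, scene$white,
                              stems = scene$stems, min_area = 20)
  expect_equal(nrow(got), 3)
  truth <- spectra_matrix(spectra)
  rec <- spectra_matrix(got)
  # raster order of placement matches input order (left-to-right rows)
  err <- abs(rec - truth)
  expect_lt(max(err), 3 * noise_sd)
  # stem pixels are gone: no recovered component overlaps a stem rectangle
  refl <- calibrate(scene$raw, scene$dark, scene$white)
  mask <- remove_stems(segment_plant(refl), scene$stems)
  comp <- extract_leaves(mask, 20)
  for (i in seq_len(nrow(scene$stems))) {
    r <- scene$stems[i, ]
    expect_true(all(comp[(r$y + 1):(r$y + r$height),
                         (r$x + 1):(r$x + r$width)] == 0))
  }
})

test_that("ENVI BIL write/read round-trips a cube", {
  vals <- array(runif(4 * 5 * 3), c(4, 5, 3))
  cube <- spectral_cube(vals, c(500, 600, 700), "reflectance")
  path <- file.path(withr::local_tempdir(), "cube")
  write_envi(cube, path)
  back <- read_envi(path)
  expect_equal(back$wavelengths, cube$wavelengths)
  expect_equal(back$kind, "reflectance")
  expect_equal(back$values, cube$values, tolerance = 1e-6)  # float32
})
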