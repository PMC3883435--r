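test_that("rendered plates are reproducible and faithful to the scenario", {
  lay <- quad_layout(roi = roi_spec("disk", 5))
  null_sc <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 0),
    pixel_noise_sd = 2)

  a <- render_plate(null_sc, lay, 50, seed = 7)
  b <- render_plate(null_sc, lay, 50, seed = 7)
  expect_identical(a$pixels, b$pixels)  # bit-identical under one seed
  c <- render_plate(null_sc, lay, 50, seed = 8)
  expect_false(identical(a$pixels, c$pixels))

  # zero slope, zero noise: all wells identical, all deltas zero
  quiet <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 0))
  img <- render_plate(quiet, lay, 100, seed = 1)
  d <- compute_differences(extract_well_totals(img, lay), lay)
  expect_true(all(d$delta == 0))
})

test_that("the rendered delta equals the forward model up to per-pixel rounding", {
  lay <- tiny_layout(roi = roi_spec("disk", 10), pitch = c(40, 40),
                     origin = c(20, 20))
  # m * c = 3170 over the 317-pixel disk: per-pixel shift exactly 10
  sc <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 31.7))
  img <- render_plate(sc, lay, 100, seed = 1)
  d <- compute_differences(extract_well_totals(img, lay), lay)
  expect_equal(d$delta[d$channel == "G"], 3170)
  expect_equal(d$delta[d$channel == "R"], 0)

  # non-integral per-pixel shift stays within the rounding bound
  sc2 <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 31.75))
  d2 <- compute_differences(
    extract_well_totals(render_plate(sc2, lay, 100, seed = 1), lay), lay)
  expect_lte(abs(d2$delta[d2$channel == "G"] - 3175), 317 / 2)

  # a shift that would leave the channel range is a scenario error
  big <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 1e4),
    baseline = c(180, 20, 140))
  expect_error(render_plate(big, lay, 100, seed = 1), "scenario error")
})

test_that("difference tables follow the replication scheme and the noise model", {
  sc <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 50))
  tbl <- generate_difference_table(sc, n_plates = 3, n_assays = 3, seed = 42,
                                   concentrations = c(10, 25), sigma_delta = 0)
  expect_equal(nrow(tbl), 2 * 9)
  expect_equal(as.vector(table(tbl$concentration_mM)), c(9L, 9L))
  expect_equal(tbl$delta, 50 * tbl$concentration_mM)  # sigma 0: exact line

  noisy1 <- generate_difference_table(sc, seed = 42, sigma_delta = 100)
  noisy2 <- generate_difference_table(sc, seed = 42, sigma_delta = 100)
  expect_identical(noisy1, noisy2)

  # default sigma_delta derives from the per-pixel noise over the ROI pair
  sc_n <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "G", slope = 0),
    pixel_noise_sd = 2)
  tbl_n <- generate_difference_table(sc_n, n_plates = 40, n_assays = 10,
                                     seed = 3, concentrations = 10)
  expect_equal(stats::sd(tbl_n$delta), 2 * sqrt(2 * 317), tolerance = 0.1)
  expect_error(generate_difference_table(sc, n_plates = 0, seed = 1), ">= 1")
})

test_that("synthetic spectra hit the anchored endpoints and reproduce under seed", {
  sc <- ketamine_spectrum_scenario()
  ctl <- generate_spectrum(sc, "ketamine", 0, seed = 1)
  pk0 <- find_lambda_max(ctl)
  expect_equal(pk0$lambda_max, 516)
  expect_equal(pk0$a_max, 1.05)

  hi <- generate_spectrum(sc, "ketamine", 90, seed = 1)
  pk90 <- find_lambda_max(hi)
  expect_equal(pk90$lambda_max, 520)
  expect_equal(pk90$a_max, 0.66)
  # fractional peak drop: (1.05 - 0.66) / 1.05, ~37%
  expect_equal((pk0$a_max - pk90$a_max) / pk0$a_max, 0.39 / 1.05)

  noisy <- ketamine_spectrum_scenario(noise_sd = 0.01)
  s1 <- generate_spectrum(noisy, "ketamine", 45, replicate = 2, seed = 7)
  s2 <- generate_spectrum(noisy, "ketamine", 45, replicate = 2, seed = 7)
  expect_identical(s1$absorbances, s2$absorbances)
  s3 <- generate_spectrum(noisy, "ketamine", 45, replicate = 3, seed = 7)
  expect_false(identical(s1$absorbances, s3$absorbances))
})

test_that("color-change counts rise monotonically with concentration at zero noise", {
  lay <- default_layout()
  sc <- ketamine_plate_scenario()  # noiseless
  counts <- vapply(sc$concentrations, function(conc) {
    tot <- extract_well_totals(render_plate(sc, lay, conc, seed = 1), lay)
    count_color_changes(plate_code(tot, lay))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])

  # same monotonicity straight from the expected-code shortcut
  exp_counts <- vapply(sc$concentrations, function(conc) {
    count_color_changes(scenario_expected_code(sc, lay, conc))
  }, integer(1))
  expect_equal(counts, exp_counts)
})

test_that("plate images survive PNG and 16-bit TIFF round-trips", {
  lay <- tiny_layout()
  sc <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "B", slope = 20),
    pixel_noise_sd = 1)
  img <- render_plate(sc, lay, 50, seed = 4)
  png_path <- withr::local_tempfile(fileext = ".png")
  write_plate_image(img, png_path)
  expect_identical(read_plate_image(png_path)$pixels, img$pixels)

  sc16 <- plate_scenario(
    data.frame(sensor = "DC1", condition = 1L, channel = "B", slope = 20),
    baseline = c(30000, 20000, 10000), bit_depth = 16L)
  img16 <- render_plate(sc16, lay, 50, seed = 4)
  tif_path <- withr::local_tempfile(fileext = ".tif")
  write_plate_image(img16, tif_path)
  back <- read_plate_image(tif_path)
  expect_equal(back$bit_depth, 16L)
  expect_identical(back$pixels, img16$pixels)
  expect_error(write_plate_image(img16, png_path), "TIFF")
})
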