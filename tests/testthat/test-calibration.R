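test_that("replicate averaging collapses to per-concentration points", {
  raw <- expand.grid(plate = 1:3, assay = 1:3,
                     concentration_mM = c(10, 25))
  raw$delta <- 50 * raw$concentration_mM
  pts <- average_replicates(raw)
  expect_equal(pts$n, c(9L, 9L))  # 3 plates x 3 assays per point
  expect_equal(pts$concentration, c(10, 25))
  expect_equal(pts$mean_delta, c(500, 1250))
  expect_equal(pts$sd_delta, c(0, 0))

  one <- average_replicates(data.frame(concentration_mM = 5, delta = 123))
  expect_equal(one$mean_delta, 123)
  expect_equal(one$sd_delta, 0)
  expect_equal(one$n, 1L)

  trio <- average_replicates(
    data.frame(concentration_mM = 5, delta = c(10, 20, 30)))
  expect_equal(trio$mean_delta, 20)
  expect_equal(trio$sd_delta, 10)  # sample sd, n - 1 denominator

  expect_error(average_replicates(data.frame()), "empty")
  expect_error(average_replicates(data.frame(concentration_mM = -1,
                                             delta = 0)),
               "non-negative")
})

test_that("noiseless lines are fitted exactly with the right r sign", {
  pts_up <- tibble::tibble(concentration = c(10, 25, 50, 100),
                           mean_delta = 50 * c(10, 25, 50, 100))
  up <- fit_standard_curve(pts_up)
  expect_equal(up$slope, 50)
  expect_equal(up$intercept, 0)
  expect_equal(up$r, 1)

  pts_down <- tibble::tibble(concentration = c(10, 25, 50),
                             mean_delta = 100 - 2 * c(10, 25, 50))
  expect_equal(fit_standard_curve(pts_down)$r, -1)

  expect_error(fit_standard_curve(
    tibble::tibble(concentration = c(5, 5), mean_delta = c(1, 2))),
    "degenerate")
})

test_that("OLS matches the closed-form normal equations to 1e-9 relative", {
  for (seed in c(21, 22, 23)) {
    pts <- withr::with_seed(seed, tibble::tibble(
      concentration = sort(stats::runif(6, 0, 100)),
      mean_delta = stats::rnorm(6, 0, 500)
    ))
    fit <- fit_standard_curve(pts)
    oracle <- ols_closed_form(pts$concentration, pts$mean_delta)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
    # r is invariant under affine rescaling of delta
    rescaled <- pts
    rescaled$mean_delta <- 3.7 * pts$mean_delta - 250
    expect_equal(fit_standard_curve(rescaled)$r, fit$r, tolerance = 1e-12)
  }
})

test_that("inverse prediction inverts the line and flags flat curves", {
  pts <- tibble::tibble(concentration = c(10, 25, 50, 100),
                        mean_delta = 50 * c(10, 25, 50, 100))
  curve <- fit_standard_curve(pts)
  est <- estimate_concentration(curve, 2500)
  expect_equal(est$c_hat, 50)
  expect_equal(unname(est$interval), c(50, 50))  # perfect fit, zero width
  expect_equal(estimate_concentration(curve, curve$intercept)$c_hat, 0)

  flat <- fit_standard_curve(tibble::tibble(concentration = c(10, 50, 90),
                                            mean_delta = c(5, 5, 5)))
  expect_error(estimate_concentration(flat, 5), "flat")

  # round-trip recovery across random non-degenerate curves
  for (seed in c(31, 32)) {
    pts <- withr::with_seed(seed, tibble::tibble(
      concentration = c(10, 25, 50, 62.5, 80, 100),
      mean_delta = 40 * c(10, 25, 50, 62.5, 80, 100) + stats::rnorm(6, 0, 30)
    ))
    curve <- fit_standard_curve(pts)
    for (c_true in c(15, 47.3, 88)) {
      delta <- curve$slope * c_true + curve$intercept
      expect_equal(estimate_concentration(curve, delta)$c_hat, c_true,
                   tolerance = 1e-9)
    }
  }
})

test_that("the slope estimate converges to truth as replicate noise vanishes", {
  conc <- c(10, 25, 50, 62.5, 80, 100)
  err <- vapply(c(100, 10, 0.1), function(sigma) {
    tbl <- generate_difference_table(
      plate_scenario(data.frame(sensor = "DC1", condition = 1L,
                                channel = "G", slope = 50)),
      seed = 5, concentrations = conc, sigma_delta = sigma)
    abs(fit_standard_curve(average_replicates(tbl))$slope - 50)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-2)
})

test_that("the inverse-prediction interval covers truth near the stated rate", {
  conc <- c(10, 25, 50, 62.5, 80, 100)
  c_true <- 40
  hits <- vapply(1:300, function(i) {
    tbl <- generate_difference_table(
      plate_scenario(data.frame(sensor = "DC1", condition = 1L,
                                channel = "G", slope = 50)),
      seed = 1000 + i, concentrations = conc, sigma_delta = 150)
    curve <- fit_standard_curve(average_replicates(tbl))
    obs <- 50 * c_true + withr::with_seed(5000 + i,
                                          stats::rnorm(1, 0, 150 / 3))
    est <- estimate_concentration(curve, obs, confidence = 0.95)
    est$interval["low"] <= c_true && c_true <= est$interval["high"]
  }, logical(1))
  expect_gt(mean(hits), 0.85)
  expect_lte(mean(hits), 1)
})

test_that("curves and replicate tables round-trip through their file formats", {
  tbl <- generate_difference_table(ketamine_plate_scenario(), seed = 9,
                                   sigma_delta = 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tbl), csv, row.names = FALSE)
  back <- read_replicates(csv)
  expect_equal(back$delta, tbl$delta)

  curve <- fit_standard_curve(
    average_replicates(tbl[tbl$sensor == "DC1", ]),
    slot = list("DC1", 1L, "G"))
  path <- withr::local_tempfile(fileext = ".json")
  write_curve(curve, path)
  got <- read_curve(path)
  expect_equal(got$slope, curve$slope)
  expect_equal(got$intercept, curve$intercept)
  expect_equal(got$r, curve$r)
  expect_equal(estimate_concentration(got, 2500)$c_hat,
               estimate_concentration(curve, 2500)$c_hat)
})
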