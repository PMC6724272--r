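test_that("noiseless model data are recovered to four significant digits", {
  prof <- make_sigmoid_profile(L_noise = 10, L_max = 600, d50 = 2500,
                               delta = 500, n = 100)
  fit <- fit_sigmoid(prof)
  expect_equal(fit$L_noise, 10, tolerance = 1e-4)
  expect_equal(fit$L_max, 600, tolerance = 1e-4)
  expect_equal(fit$d50, 2500, tolerance = 1e-4)
  expect_equal(fit$delta, 500, tolerance = 1e-4)
  expect_gte(fit$r2, 0.9999)
  # the fitted curve at d50 is exactly the asymptote midpoint
  expect_equal(rh_sigmoid(fit$d50, fit$L_noise, fit$L_max, fit$d50, fit$delta),
               (fit$L_noise + fit$L_max) / 2)
})

test_that("degenerate data and too few points are rejected", {
  pts <- data.frame(distance_um = seq(0, 900, by = 100),
                    length_um = 5, side = "left", stringsAsFactors = FALSE)
  prof <- rh_profile(pts, w_um = 8)
  expect_error(fit_sigmoid(prof), "degenerate")
  small <- rh_profile(pts[1:5, ], w_um = 8)
  expect_error(fit_sigmoid(small), ">= 8")
})

test_that("fit drops points flagged with excluded labels", {
  prof <- make_sigmoid_profile(L_noise = 0, L_max = 400, d50 = 1500,
                               delta = 300, n = 60, d_max = 4000)
  # corrupt a flagged stretch; excluding the flag must restore the fit
  bad <- prof$points$distance_um > 1800 & prof$points$distance_um < 2400
  prof$points$length_um[bad] <- 1000
  prof$points$flag_artefact <- as.integer(bad)
  with_bad <- fit_sigmoid(prof)
  without <- fit_sigmoid(prof, exclude_flags = "artefact")
  expect_gt(abs(with_bad$L_max - 400), abs(without$L_max - 400))
  expect_equal(without$L_max, 400, tolerance = 1e-3)
})

test_that("two-step fit reproduces itself on exact data and reports its range", {
  prof <- make_sigmoid_profile(L_noise = 5, L_max = 550, d50 = 2200,
                               delta = 450, n = 150)
  tsf <- two_step_fit(prof, first_range_um = c(0, 6000))
  expect_equal(tsf$second_range_requested_um,
               c(tsf$fit1$d50 - 5 * tsf$fit1$delta,
                 tsf$fit1$d50 + 5 * tsf$fit1$delta))
  expect_equal(mean(tsf$second_range_requested_um), tsf$fit1$d50)
  expect_equal(tsf$fit2$L_max, tsf$fit1$L_max, tolerance = 1e-4)
  expect_equal(tsf$fit2$d50, tsf$fit1$d50, tolerance = 1e-4)
  expect_equal(tsf$fit2$delta, tsf$fit1$delta, tolerance = 1e-4)
})

test_that("the second-fit range is d50 +/- 5 delta for arbitrary first fits", {
  set.seed(61)
  for (i in 1:10) {
    L_max <- runif(1, 100, 900); d50 <- runif(1, 500, 4000)
    delta <- runif(1, 80, 800)
    prof <- make_sigmoid_profile(0, L_max, d50, delta, n = 120,
                                 d_max = d50 + 6 * delta, noise_sd = 0.03 * L_max)
    tsf <- two_step_fit(prof, first_range_um = c(0, d50 + 6 * delta))
    expect_identical(tsf$second_range_requested_um,
                     c(tsf$fit1$d50 - 5 * tsf$fit1$delta,
                       tsf$fit1$d50 + 5 * tsf$fit1$delta))
    expect_gte(tsf$second_range_um[1], tsf$second_range_requested_um[1])
    expect_lte(tsf$second_range_um[2], tsf$second_range_requested_um[2])
  }
})

test_that("a second-fit window with too few points errors from step two", {
  # widely spaced points: 5*delta window holds fewer than 8 of them
  d <- seq(0, 4000, by = 400)
  L <- rh_sigmoid(d, 0, 500, 2000, 60)
  pts <- data.frame(distance_um = d, length_um = L, side = "left",
                    stringsAsFactors = FALSE)
  prof <- rh_profile(pts, w_um = 8)
  expect_error(two_step_fit(prof, c(0, 4000)), "second fit")
})

test_that("translating distances shifts d50 exactly and nothing else", {
  prof <- make_sigmoid_profile(L_noise = 20, L_max = 480, d50 = 1800,
                               delta = 350, n = 90, d_max = 4500)
  shifted <- prof
  shifted$points$distance_um <- shifted$points$distance_um + 700
  f0 <- fit_sigmoid(prof)
  f1 <- fit_sigmoid(shifted)
  expect_equal(f1$d50 - f0$d50, 700, tolerance = 1e-6)
  expect_equal(f1$L_max, f0$L_max, tolerance = 1e-6)
  expect_equal(f1$L_noise, f0$L_noise, tolerance = 1e-6)
  expect_equal(f1$delta, f0$delta, tolerance = 1e-6)
})

test_that("the inflection tangent meets the asymptotes 2 delta from d50", {
  set.seed(62)
  for (i in 1:100) {
    L_noise <- runif(1, 0, 50); L_max <- L_noise + runif(1, 50, 900)
    d50 <- runif(1, 200, 5000); delta <- runif(1, 30, 900)
    # analytic slope at the inflection vs the tangent construction
    slope <- (L_max - L_noise) / (4 * delta)
    f_d50 <- rh_sigmoid(d50, L_noise, L_max, d50, delta)
    lower_x <- d50 + (L_noise - f_d50) / slope
    upper_x <- d50 + (L_max - f_d50) / slope
    expect_lt(abs((d50 - lower_x) - 2 * delta) / (2 * delta), 1e-10)
    expect_lt(abs((upper_x - d50) - 2 * delta) / (2 * delta), 1e-10)
    expect_lt(abs((upper_x - lower_x) - 4 * delta) / (4 * delta), 1e-10)
    # numeric derivative confirms the slope used for the tangent
    h <- delta * 1e-5
    num <- (rh_sigmoid(d50 + h, L_noise, L_max, d50, delta) -
              rh_sigmoid(d50 - h, L_noise, L_max, d50, delta)) / (2 * h)
    expect_equal(num, slope, tolerance = 1e-8)
  }
})

test_that("derived parameters follow the growth-rate and zone arithmetic", {
  p <- sigmoid_params(L_noise = 0, L_max = 600, d50 = 2500, delta = 500,
                      r2 = 0.99, fit_range_um = c(0, 6000), n_points = 100)
  d <- derive_parameters(p, root_growth_rate_um_h = 300)
  expect_equal(d$rh_growth_rate_um_h, 600 / 2000 * 300)  # 90 um/h
  expect_equal(d$initiation_um, 1500)
  expect_equal(d$arrest_um, 3500)
  expect_equal(d$growth_region_um, 2000)
  expect_equal(d$div_elong_zone_um, d$initiation_um)
  expect_equal(d$arrest_um - d$initiation_um, d$growth_region_um)

  no_rate <- derive_parameters(p)
  expect_null(no_rate$rh_growth_rate_um_h)
  expect_false(is.null(no_rate$growth_region_um))

  set.seed(63)
  for (i in 1:20) {
    L_noise <- runif(1, 0, 40); L_max <- L_noise + runif(1, 100, 800)
    delta <- runif(1, 50, 900); rate <- runif(1, 30, 400)
    pp <- sigmoid_params(L_noise, L_max, runif(1, 500, 4000), delta, 0.95,
                         c(0, 6000), 50)
    dd <- derive_parameters(pp, rate)
    want <- (L_max - L_noise) / (4 * delta) * rate
    expect_lt(abs(dd$rh_growth_rate_um_h - want) / want, 1e-12)
  }
})

test_that("two-step fit recovers parameters from noisy profiles", {
  set.seed(64)
  errs <- replicate(20, {
    prof <- make_sigmoid_profile(L_noise = 5, L_max = 600, d50 = 2500,
                                 delta = 500, n = 100, d_max = 6000,
                                 noise_sd = 60)   # sigma = 10% of L_max
    tsf <- two_step_fit(prof, c(0, 6000))
    c(abs(tsf$fit2$L_max - 600) / 600, abs(tsf$fit2$d50 - 2500) / 2500,
      abs(tsf$fit2$delta - 500) / 500, tsf$fit2$r2)
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
  expect_lt(median(errs[3, ]), 0.20)
  expect_true(all(errs[4, ] >= 0.9))
})
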