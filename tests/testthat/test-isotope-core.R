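test_that("ratio_to_delta implements standard delta notation", {
  expect_equal(ratio_to_delta(2.005e-3, 2.005e-3), 0)
  expect_equal(ratio_to_delta(1.001, 1), 1.0)
  expect_equal(ratio_to_delta(0.999, 1), -1.0)
  expect_error(ratio_to_delta(-1, 1), "positive")
  expect_error(ratio_to_delta(1, 0), "positive")
})

test_that("salinity -> water d18O is the North Sea mixing line", {
  d <- salinity_to_water_d18O(35)
  expect_s3_class(d, "delta_value")
  expect_identical(d$scale, "VSMOW")
  # frozen regression fixture: direct substitution into the mixing line
  expect_equal(d$value, 0.30, tolerance = 1e-12)
  # linearity: unit salinity step adds exactly the slope
  rel <- get_mixing_relation("northsea-mixing")
  for (S in c(5, 20, 33.7)) {
    expect_equal(salinity_to_water_d18O(S + 1)$value -
                 salinity_to_water_d18O(S)$value, rel$slope)
  }
  expect_error(salinity_to_water_d18O(-0.1), "\\[0, 40\\]")
  expect_error(salinity_to_water_d18O(41), "\\[0, 40\\]")
})

test_that("convert_scale is the printed affine map and inverts exactly", {
  z <- delta_value(0, "VSMOW", "water")
  # frozen fixture: 0 permil VSMOW maps to the conversion intercept
  expect_equal(convert_scale(z, "VPDB")$value, -29.98)
  # round trip and affinity over a grid of values
  for (x in seq(-40, 40, by = 7.3)) {
    d <- delta_value(x, "VPDB", "otolith")
    back <- convert_scale(convert_scale(d, "VSMOW"), "VPDB")
    expect_lt(abs(back$value - x), 1e-9)
  }
  gap <- function(x) convert_scale(delta_value(x, "VSMOW", "water"), "VPDB")$value
  expect_equal(gap(13) - gap(12), gap(1) - gap(0))
  expect_warning(convert_scale(z, "VSMOW"), "already")
})

test_that("predict_otolith_d18O matches direct substitution and is monotone", {
  # frozen fixture: direct evaluation at T = 283.15 K, dw = 0 (VPDB)
  expect_equal(predict_otolith_d18O(283.15, 0)$value, 32.5244665715,
               tolerance = 1e-9)
  expect_lt(predict_otolith_d18O(284.15, 0)$value,
            predict_otolith_d18O(283.15, 0)$value)
  # strict monotone decrease on a 0.1 K grid across the validity range
  Tg <- seq(273.15, 313.15, by = 0.1)
  v <- predict_otolith_d18O(Tg, -29.7)$value
  expect_true(all(diff(v) < 0))
  expect_error(predict_otolith_d18O(-3, 0), "positive")
  expect_warning(predict_otolith_d18O(350, 0, "kim-aragonite"), "validity")
})

test_that("finite difference of the prediction matches a*1000/T^2", {
  dw <- -29.7
  for (T in seq(276, 292, by = 2)) {
    fd <- predict_otolith_d18O(T, dw)$value -
      predict_otolith_d18O(T + 1, dw)$value
    expect_equal(fd, 17.88 * 1000 / T^2, tolerance = 0.01)
  }
})

test_that("invert_temperature is the exact inverse", {
  dw_grid <- c(-30, -29.7, 0, 0.5)
  for (T in c(278.15, 283.15, 288.15)) for (dw in dw_grid) {
    do_ <- predict_otolith_d18O(T, dw)
    expect_equal(invert_temperature(do_, dw), T, tolerance = 1e-6)
  }
  # fixture consistency
  expect_equal(invert_temperature(32.5244665715, 0), 283.15, tolerance = 1e-6)
  # strictly decreasing in the otolith delta at fixed water delta
  ts <- vapply(seq(30, 34, by = 0.5), invert_temperature, numeric(1),
               d18Ow = 0)
  expect_true(all(diff(ts) < 0))
  expect_error(invert_temperature(-1001, 0), "not positive")
})

test_that("plaice-type model behaves like the inorganic model structurally", {
  m <- get_fractionation_model("geffen-plaice")
  expect_gt(m$a, 0)
  Tg <- seq(m$valid_T_range[1], m$valid_T_range[2], by = 0.1)
  v <- predict_otolith_d18O(Tg, -29.7, m)$value
  expect_true(all(diff(v) < 0))
  for (T in c(285.15, 288.15)) {
    do_ <- predict_otolith_d18O(T, -29.7, m)
    expect_equal(invert_temperature(do_, -29.7, m), T, tolerance = 1e-6)
  }
  # fixed-T difference between the two models equals the coefficient gap
  k <- get_fractionation_model("kim-aragonite")
  T <- 287.15
  gap_lnalpha <- (m$a - k$a) * 1000 / T + (m$b - k$b)
  dk <- suppressWarnings(predict_otolith_d18O(T, -29.7, k)$value)
  dm <- suppressWarnings(predict_otolith_d18O(T, -29.7, m)$value)
  expect_equal(1000 * log((1000 + dm) / (1000 + dk)), gap_lnalpha,
               tolerance = 1e-9)
})

test_that("salinity-unit temperature bias matches reported sensitivities", {
  expect_equal(temperature_bias_per_salinity(), 1.3, tolerance = 0.05)
  expect_equal(temperature_bias_per_salinity("natl-mixing"), 2.5,
               tolerance = 0.05)
  expect_equal(temperature_bias_per_salinity(dS = 0), 0)
  # first-order linearity in dS
  b1 <- temperature_bias_per_salinity(dS = 0.5)
  b2 <- temperature_bias_per_salinity(dS = 1.0)
  expect_equal(b2 / b1, 2, tolerance = 0.05)
})

test_that("registry lookup and user-supplied models work", {
  expect_error(get_fractionation_model("nope"), "registered")
  expect_error(get_mixing_relation("nope"), "registered")
  custom <- fractionation_model("custom", a = 18, b = -31)
  expect_s3_class(predict_otolith_d18O(283.15, 0, custom), "delta_value")
  expect_error(fractionation_model("bad", a = -1, b = 0), "positive")
  expect_error(water_mixing_relation("bad", slope = -0.2, intercept = 0),
               "positive")
})
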