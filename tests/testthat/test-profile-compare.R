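test_that("predict_daily_series composes the chain day by day", {
  days <- seq(as.Date("1998-03-01"), as.Date("1998-04-30"), by = "day")
  tag <- data.frame(date = days, temperature_c = 9)
  sal <- data.frame(date = days, salinity = 34.5)
  ps <- predict_daily_series(tag, sal, fish_id = "F1")
  expect_equal(nrow(ps$daily), length(days))
  expect_true(all(abs(ps$daily$d18O - oracle_chain(9, 34.5)) < 1e-9))
  expect_equal(nrow(ps$monthly), 2)
  # seasonal temperature cycle: delta extrema anti-aligned with temperature
  year <- seq(as.Date("1998-01-01"), as.Date("1998-12-31"), by = "day")
  doy <- as.numeric(year - year[1])
  tmp <- 11.5 + 5 * cos(2 * pi * (doy - 227) / 365)  # warmest mid-August
  ps2 <- predict_daily_series(data.frame(date = year, temperature_c = tmp),
                              data.frame(date = year, salinity = 35))
  expect_equal(ps2$monthly$month[which.min(ps2$monthly$d18O)],
               unname(which.max(tapply(tmp, format(year, "%m"), mean))))
  # gaps are rejected with the offending date
  expect_error(predict_daily_series(tag[-10, ], sal), "gaps > 1 day")
  expect_error(predict_daily_series(tag, sal[-10, ]), "gaps > 1 day")
  expect_error(predict_daily_series(tag, sal[1:30, ]), "salinity missing")
})

test_that("monthly_means averages per calendar month and flags partials", {
  days <- seq(as.Date("1998-01-01"), as.Date("1998-01-30"), by = "day")
  mm <- monthly_means(data.frame(date = days, d18O = 2.2))
  expect_equal(mm$d18O, 2.2); expect_false(mm$partial)
  # linear ramp over full January: mean is (a+b)/2
  ramp <- seq(1, 3, length.out = 31)
  mm2 <- monthly_means(data.frame(
    date = seq(as.Date("1998-01-01"), as.Date("1998-01-31"), by = "day"),
    d18O = ramp))
  expect_equal(mm2$d18O, 2)
  # 10-day month flagged partial but still reported
  mm3 <- monthly_means(data.frame(
    date = seq(as.Date("1998-02-01"), as.Date("1998-02-10"), by = "day"),
    d18O = 1:10))
  expect_true(mm3$partial); expect_equal(mm3$d18O, 5.5)
})

test_that("self-alignment recovers spot dates", {
  pred <- make_sine_predicted(1998)
  mm <- pred$monthly
  prof <- data.frame(
    distance_um = as.numeric(mm$mid_date - min(pred$daily$date)),
    d18O = mm$d18O)
  al <- align_profile(prof, pred)
  expect_identical(al$method, "paired")
  # interior extremum anchors land exactly on the predicted extremum dates
  expect_true(all(al$anchors$date %in% mm$mid_date))
  # all spot dates recovered within one sampling interval (one month)
  expect_true(all(abs(as.numeric(al$aligned$date - mm$mid_date)) <= 31))
  # warp strictly increasing; spot order preserved
  expect_true(all(diff(as.numeric(al$warp$date)) > 0))
  expect_true(all(diff(as.numeric(al$aligned$date)) >= 0))
})

test_that("a uniformly stretched distance axis yields a half-slope warp", {
  pred <- make_sine_predicted(1998)
  mm <- pred$monthly
  prof <- data.frame(
    distance_um = 2 * as.numeric(mm$mid_date - min(pred$daily$date)),
    d18O = mm$d18O)
  al <- align_profile(prof, pred)
  w <- al$warp
  slope <- diff(as.numeric(w$date)) / diff(w$distance_um)
  # interior segments carry the true time-per-distance rate; the endpoint
  # segments absorb the half-sample offset of the window anchors
  expect_true(all(abs(slope[2:(length(slope) - 1)] - 0.5) < 0.05))
  expect_true(all(slope > 0))
  expect_true(all(abs(as.numeric(al$aligned$date - mm$mid_date)) <= 31))
})

test_that("alignment fails cleanly without extrema, falls back to DP", {
  ramp_days <- seq(as.Date("1998-01-01"), as.Date("1998-06-30"), by = "day")
  ramp_pred <- structure(list(
    fish_id = "F", model = "kim-aragonite",
    daily = data.frame(date = ramp_days,
                       d18O = seq(0, 2, length.out = length(ramp_days))),
    monthly = monthly_means(data.frame(
      date = ramp_days, d18O = seq(0, 2, length.out = length(ramp_days))))),
    class = "predicted_series")
  prof <- data.frame(distance_um = seq(10, 100, by = 10),
                     d18O = seq(0.1, 1.9, length.out = 10))
  expect_error(align_profile(prof, ramp_pred), "no interior extrema")
  # unequal extremum counts: measured spans only half the seasonal cycle
  pred <- make_sine_predicted(1998)
  mm <- pred$monthly
  half <- mm[1:8, ]  # one interior extremum (max Feb) + min edge
  prof2 <- data.frame(
    distance_um = as.numeric(half$mid_date - min(pred$daily$date)) + 10,
    d18O = half$d18O + c(0, 0, 0, 0, 0.02, 0, 0, 0.04))
  expect_message(al2 <- align_profile(prof2, pred), "DP")
  expect_true(all(diff(as.numeric(al2$warp$date)) > 0))
  expect_error(align_profile(prof2[1:3, ], pred), ">= 4 spots")
})

# build n_fish measured profiles from a shared predicted series
make_profiles <- function(pred, n_fish, offset = 0, noise_sd = 0,
                          n_spots = 12) {
  mm <- pred$monthly
  idx <- round(seq(1, nrow(mm), length.out = n_spots))
  lapply(seq_len(n_fish), function(i) {
    data.frame(distance_um = seq(30, 1000, length.out = n_spots),
               d18O = mm$d18O[idx] + offset + rnorm(n_spots, 0, noise_sd))
  })
}

test_that("offset_summary: exact null and constant shift", {
  pred <- make_sine_predicted(1998)
  profs <- make_profiles(pred, 4)
  names(profs) <- paste0("F", 1:4)
  preds <- setNames(rep(list(pred), 4), names(profs))
  grouping <- setNames(rep("A", 4), names(profs))
  null_sum <- offset_summary(profs, preds, grouping)
  expect_equal(null_sum$mean, c(0, 0))
  expect_equal(null_sum$se, c(0, 0))
  expect_true(all(null_sum$stars == "ns"))
  shifted <- lapply(profs, function(p) transform(p, d18O = d18O + 0.30))
  shift_sum <- offset_summary(shifted, preds, grouping)
  expect_equal(shift_sum$mean, c(0.30, 0.30), tolerance = 1e-9)
  expect_true(all(shift_sum$direction == "greater"))
})

test_that("an injected +0.25 offset is recovered within 0.10 over 10 seeds", {
  pred <- make_sine_predicted(1998)
  rec <- vapply(1:10, function(seed) {
    set.seed(seed)
    profs <- make_profiles(pred, 4, offset = 0.25, noise_sd = 0.20)
    names(profs) <- paste0("F", 1:4)
    preds <- setNames(rep(list(pred), 4), names(profs))
    grouping <- setNames(rep("A", 4), names(profs))
    s <- suppressWarnings(offset_summary(profs, preds, grouping))
    mean(s$mean)  # combined over annual minimum and maximum offsets
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.25), 0.10)
})

test_that("offset estimates are unbiased under the null", {
  pred <- make_sine_predicted(1998)
  n_fish <- 8
  passes <- vapply(1:100, function(seed) {
    set.seed(1000 + seed)
    profs <- make_profiles(pred, n_fish, offset = 0, noise_sd = 0.20)
    names(profs) <- paste0("F", seq_len(n_fish))
    preds <- setNames(rep(list(pred), n_fish), names(profs))
    grouping <- setNames(rep("A", n_fish), names(profs))
    s <- suppressWarnings(offset_summary(profs, preds, grouping))
    # z-check against the known generator noise (2 extremes x n_fish values)
    abs(mean(s$mean)) < 2 * 0.20 / sqrt(2 * n_fish)
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("test direction follows the offset sign for strong offsets", {
  pred <- make_sine_predicted(1998)
  for (off in c(0.5, -0.5)) {   # >= 2x the 0.20 spot noise
    set.seed(99)
    profs <- make_profiles(pred, 6, offset = off, noise_sd = 0.20)
    names(profs) <- paste0("F", 1:6)
    preds <- setNames(rep(list(pred), 6), names(profs))
    grouping <- setNames(rep("A", 6), names(profs))
    s <- suppressWarnings(offset_summary(profs, preds, grouping))
    expect_true(all(s$direction == if (off > 0) "greater" else "less"))
    expect_true(all(sign(s$mean) == sign(off)))
  }
})

test_that("small groups warn but still report", {
  pred <- make_sine_predicted(1998)
  profs <- make_profiles(pred, 2)
  names(profs) <- c("F1", "F2")
  preds <- setNames(rep(list(pred), 2), names(profs))
  grouping <- setNames(rep("A", 2), names(profs))
  expect_warning(s <- offset_summary(profs, preds, grouping), "low power")
  expect_equal(nrow(s), 2)
})
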