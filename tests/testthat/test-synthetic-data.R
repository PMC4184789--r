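test_that("environmental fields honour the stated climate structure", {
  cfg <- test_synth_config(seed = 11)
  f <- generate_env_fields(cfg)
  df <- f$data
  ctr <- cell_center(cfg$grid, df$cell)
  # northern sector (lat >= 55.5) monthly sector means never reach 12 degC
  north <- ctr$lat >= 55.5
  for (m in 1:12) {
    expect_lt(mean(df$temperature_c[north & df$month == m]), 12)
  }
  # southern warm sector cycles between about 6.5 and 16.5 degC
  south <- ctr$lat < 54.5
  s_mean <- tapply(df$temperature_c[south], df$month[south], mean)
  expect_equal(min(s_mean), 6.5, tolerance = 1)
  expect_equal(max(s_mean), 16.5, tolerance = 1)
  # eastern sector is fresher and more variable than the west
  east <- ctr$lon > 6; west <- ctr$lon < 3
  expect_lt(mean(df$salinity[east]), 34.5)
  expect_gt(mean(df$salinity[west]), 34.8)
  expect_gt(sd(df$salinity[east]), sd(df$salinity[west]))
  # determinism: same seed bit-identical, new seed same structure, new noise
  f2 <- generate_env_fields(cfg)
  expect_identical(f$data, f2$data)
  f3 <- generate_env_fields(test_synth_config(seed = 12))
  expect_false(identical(f$data$temperature_c, f3$data$temperature_c))
  expect_lt(abs(mean(f$data$temperature_c) - mean(f3$data$temperature_c)),
            0.1)
})

test_that("stocks separate in summer and mix on winter grounds", {
  cfg <- test_synth_config(seed = 21)
  st <- generate_stocks_and_tracks(cfg)
  occ <- build_occupancy_map(st$geolocations, cfg$grid)
  aug <- lapply(c("A", "B", "C"), function(s) occ$cells[[s]][[8]])
  jan <- lapply(c("A", "B", "C"), function(s) occ$cells[[s]][[1]])
  for (i in 1:2) for (j in (i + 1):3) {
    expect_length(intersect(aug[[i]], aug[[j]]), 0)
    expect_gt(length(intersect(jan[[i]], jan[[j]])), 0)
  }
  # daily interpolated positions stay inside the study grid
  for (fid in unique(st$tracks$fish_id)[1:3]) {
    tr <- st$tracks[st$tracks$fish_id == fid, ]
    dp <- daily_positions(tr[, c("date", "lat", "lon")])
    expect_true(all(dp$lat >= cfg$grid$lat_min & dp$lat <= cfg$grid$lat_max))
    expect_true(all(dp$lon >= cfg$grid$lon_min & dp$lon <= cfg$grid$lon_max))
  }
  # record lengths drawn from the configured range
  expect_true(all(st$fish$record_days >= 200 & st$fish$record_days <= 300))
})

test_that("tag records are the field plus sensor noise", {
  cfg0 <- test_synth_config(seed = 31, tag_noise_sd = 0, t_noise = 0)
  f <- generate_env_fields(cfg0)
  st <- generate_stocks_and_tracks(cfg0)
  tg <- generate_tag_records(cfg0, st$tracks, f)
  fid <- st$fish$fish_id[1]
  tag <- tg$tags[tg$tags$fish_id == fid, ]
  dm <- daily_mean_temperature(tag)
  # noise-free limit: within-day readings are constant (pure field value)
  ctrs <- daily_positions(st$tracks[st$tracks$fish_id == fid,
                                    c("date", "lat", "lon")])
  spread <- tapply(tag$temperature_c, as.Date(tag$timestamp, tz = "UTC"),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  expect_equal(nrow(dm), nrow(ctrs))
  # with noise: daily means concentrate around the noise-free values
  cfg1 <- test_synth_config(seed = 31, t_noise = 0)  # same world, tag noise on
  tg1 <- generate_tag_records(cfg1, st$tracks, f)
  tag1 <- tg1$tags[tg1$tags$fish_id == fid, ]
  dm1 <- daily_mean_temperature(tag1)
  per_day <- 24 * 60 / cfg1$tag_cadence_min
  se <- cfg1$tag_noise_sd / sqrt(per_day)
  frac_in <- mean(abs(dm1$temperature_c - dm$temperature_c) <= 3 * se)
  expect_gte(frac_in, 0.98)
  # pressures consistent with seabed residence (20-50 m nominal depth)
  depth <- pressure_to_depth(tag$pressure_psi)
  expect_true(all(depth > 15 & depth < 55))
})

test_that("otolith generator closes on the prediction chain", {
  cfg <- test_synth_config(
    seed = 41, t_noise = 0, tag_noise_sd = 0, annual_noise_sd = 0,
    spot_noise_sd = 0,
    vital_offsets = list(A = 0, B = 0, C = 0))
  f <- generate_env_fields(cfg)
  st <- generate_stocks_and_tracks(cfg)
  tg <- generate_tag_records(cfg, st$tracks, f)
  oto <- generate_otolith_measurements(cfg, st$tracks, f)
  for (fid in st$fish$fish_id[c(1, 4)]) {
    tag <- tg$tags[tg$tags$fish_id == fid, ]
    sal <- tg$salinity[tg$salinity$fish_id == fid, ]
    pred <- suppressWarnings(predict_daily_series(tag, sal, fish_id = fid))
    mm <- pred$monthly
    w <- scenario_weights(cfg$truth_scenario)$weights[mm$month] * mm$n_days
    expected <- sum(w * mm$d18O) / sum(w)
    got <- oto$annual$d18O[oto$annual$fish_id == fid]
    expect_equal(got, expected, tolerance = 1e-9)
    # spot values fall inside the predicted daily range (pure averages)
    prof <- oto$profiles[[fid]]
    expect_true(all(prof$d18O >= min(pred$daily$d18O) - 1e-9 &
                    prof$d18O <= max(pred$daily$d18O) + 1e-9))
    expect_true(all(diff(prof$distance_um) > 0))
  }
  # with offsets 0, measured annual values lie inside the field envelope
  dmap <- compute_d18O_field(f)
  expect_true(all(oto$annual$d18O >= min(dmap, na.rm = TRUE) &
                  oto$annual$d18O <= max(dmap, na.rm = TRUE)))
})

test_that("a configured stock offset propagates into offset_summary", {
  cfg <- test_synth_config(
    seed = 51, n_fish_per_stock = 4, record_days_range = c(330, 360),
    spot_span_days = 30,
    vital_offsets = list(A = 0.25, B = 0.25, C = 0.25))
  f <- generate_env_fields(cfg)
  st <- generate_stocks_and_tracks(cfg)
  tg <- generate_tag_records(cfg, st$tracks, f)
  oto <- generate_otolith_measurements(cfg, st$tracks, f)
  fishA <- st$fish$fish_id[st$fish$stock == "A"]
  aligned <- list(); preds <- list()
  for (fid in fishA) {
    tag <- tg$tags[tg$tags$fish_id == fid, ]
    sal <- tg$salinity[tg$salinity$fish_id == fid, ]
    preds[[fid]] <- suppressWarnings(predict_daily_series(tag, sal,
                                                          fish_id = fid))
    aligned[[fid]] <- oto$profiles[[fid]]
  }
  grouping <- setNames(rep("A", length(fishA)), fishA)
  s <- suppressWarnings(offset_summary(aligned, preds, grouping))
  expect_lt(abs(mean(s$mean) - 0.25), 0.10)
})

test_that("ensemble means order north > intermediate > fresher stock", {
  cfg <- test_synth_config(seed = 61)
  f <- generate_env_fields(cfg)
  st <- generate_stocks_and_tracks(cfg)
  occ <- build_occupancy_map(st$geolocations, cfg$grid)
  dmap <- compute_d18O_field(f)
  means <- vapply(c("A", "B", "C"), function(s) {
    p <- simulate_paths(occ, s, sim_config(n_paths = 400, seed = 5))
    mean(simulate_annual_ensemble(p, dmap, "OG1")$annual_d18O)
  }, numeric(1))
  expect_gt(means["A"], means["C"])
  expect_gt(means["C"], means["B"])
})

test_that("generate_dataset writes a complete, reloadable bundle", {
  dir <- tempfile("synthdata")
  cfg <- test_synth_config(seed = 71, n_fish_per_stock = 1,
                           tag_cadence_min = 720)
  man <- generate_dataset(cfg, dir)
  expect_true(all(file.exists(file.path(dir, man$files))))
  expect_equal(man$seed, 71)
  f <- suppressMessages(read_env_field(file.path(dir, "env_fields.csv"),
                                       cfg$grid))
  expect_equal(nrow(f$data), nrow(generate_env_fields(cfg)$data))
  geo <- suppressMessages(read_geolocations(file.path(dir,
                                                      "geolocations.csv"),
                                            cfg$grid))
  occ <- build_occupancy_map(geo, cfg$grid)
  expect_setequal(names(occ$cells), c("A", "B", "C"))
})
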