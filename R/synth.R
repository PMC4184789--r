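#' Synthetic-data configuration
#'
#' Describes the emulated study system in one place: a North Sea-like
#' gridded domain, three plaice-like sub-stocks with distinct summer
#' feeding areas converging on southern winter spawning grounds, a seasonal
#' bottom-temperature field with a stratification front (the northern
#' sector stays below 12 degrees C year-round while southern waters cycle
#' between about 6.5 and 16.5 degrees C), stable high salinity in the west
#' against a fresher, more variable eastern sector, and measurement noise
#' at the instrument precisions (tag 0.2 degrees C; milled annual d18O
#' 0.07 per mil; ion-probe spot d18O 0.20 per mil). The master seed fully
#' determines every generated output.
#'
#' @param seed master seed (integer).
#' @param grid a [grid_spec()].
#' @param years calendar years generated (default 1997:1999; the three
#'   years share one climatology plus seed-driven noise).
#' @param stocks stock labels, north to south-east to west.
#' @param summer_centroids,winter_centroids named lists of `c(lat, lon)`
#'   monthly aggregation centres (summer = Jul-Sep, winter = Jan-Mar,
#'   linear transit between).
#' @param geo_sd geolocation scatter around the monthly centroid, degrees.
#' @param geolocations_per_month geolocations per stock, month and year.
#' @param n_fish_per_stock tagged fish per stock.
#' @param t_winter_min,t_summer_max_south,t_summer_max_north,front_lat
#'   temperature climatology: winter minimum everywhere; summer maximum
#'   south of `front_lat`, ramping down to the northern maximum over 1.5
#'   degrees of latitude.
#' @param sal_west,sal_east_gradient,sal_noise_west,sal_noise_east,t_noise
#'   salinity level/gradient and field noise SDs.
#' @param tag_noise_sd,annual_noise_sd,spot_noise_sd measurement noise SDs.
#' @param tag_cadence_min tag sampling cadence, minutes (default 10).
#' @param record_days_range archival record lengths drawn uniformly from
#'   this range, days (default 97-512).
#' @param vital_offsets named list per stock: either a constant per-mil
#'   offset or `list(cold=, mid=, warm=)` applied below/between/above the
#'   `offset_thresholds` temperatures.
#' @param offset_thresholds cold/warm thresholds, degrees C (default 9, 14).
#' @param truth_scenario,truth_model growth scenario and fractionation
#'   model used to manufacture "measured" otolith values.
#' @param spot_span_days ion-probe spot integration span, days (default 60,
#'   i.e. about two months of growth).
#' @param annual_growth_um nominal otolith growth per year, micrometres.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1,
    grid = grid_spec(),
    years = 1997:1999,
    stocks = c("A", "B", "C"),
    summer_centroids = list(A = c(56.75, 2.75), B = c(54.25, 6.75),
                            C = c(53.75, 0.75)),
    winter_centroids = list(A = c(52.25, 2.75), B = c(52.25, 3.25),
                            C = c(51.75, 2.25)),
    geo_sd = 0.8,
    geolocations_per_month = 60,
    n_fish_per_stock = 4,
    t_winter_min = 6.5,
    t_summer_max_south = 16.5,
    t_summer_max_north = 9.5,
    front_lat = 54.5,
    sal_west = 35.0,
    sal_east_gradient = 0.45,
    sal_noise_west = 0.05,
    sal_noise_east = 0.25,
    t_noise = 0.15,
    tag_noise_sd = 0.2,
    annual_noise_sd = 0.07,
    spot_noise_sd = 0.20,
    tag_cadence_min = 10,
    record_days_range = c(97, 512),
    vital_offsets = list(A = 0.25,
                         B = list(cold = -0.35, mid = 0, warm = -0.35),
                         C = list(cold = -0.38, mid = 0, warm = -0.38)),
    offset_thresholds = c(9, 14),
    truth_scenario = "OG1",
    truth_model = "kim-aragonite",
    spot_span_days = 60,
    annual_growth_um = 1000) {
  stopifnot(inherits(grid, "grid_spec"),
            tag_noise_sd >= 0, annual_noise_sd >= 0, spot_noise_sd >= 0,
            t_noise >= 0, geo_sd >= 0,
            all(stocks %in% names(summer_centroids)),
            all(stocks %in% names(winter_centroids)),
            all(stocks %in% names(vital_offsets)))
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# climatological monthly mean bottom temperature at a latitude
synth_temperature <- function(cfg, lat, month) {
  t_max <- cfg$t_summer_max_south -
    (cfg$t_summer_max_south - cfg$t_summer_max_north) *
    clamp((lat - cfg$front_lat) / 1.5, 0, 1)
  t_mid <- (cfg$t_winter_min + t_max) / 2
  amp <- (t_max - cfg$t_winter_min) / 2
  t_mid + amp * cos(2 * pi * (month - 8.5) / 12)
}

synth_salinity <- function(cfg, lon) {
  cfg$sal_west - cfg$sal_east_gradient * pmax(0, lon - 4)
}

# monthly aggregation centroid for a stock (piecewise linear seasonal loop)
stock_centroid <- function(cfg, stock, month) {
  s <- cfg$summer_centroids[[stock]]
  w <- cfg$winter_centroids[[stock]]
  f <- if (month <= 3) 0
       else if (month <= 6) (month - 3) / 4
       else if (month <= 9) 1
       else 1 - (month - 9) / 4
  w + (s - w) * f
}

#' Generate monthly gridded environmental fields
#'
#' Builds the synthetic bottom temperature and salinity climatology on the
#' full grid for every month and year in the configuration: a seasonal
#' sinusoid (peaking mid-August/September, coldest February/March) whose
#' summer amplitude collapses north of the stratification front, plus an
#' eastward freshening, with small seed-driven noise and no systematic
#' year effect.
#'
#' @param cfg a [synth_config()].
#' @return an [env_field()] covering all cells, months and years.
#' @export
generate_env_fields <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_stock_seed(cfg$seed, "env-fields"))
  grid <- cfg$grid
  ids <- seq_len(n_cells(grid))
  ctr <- cell_center(grid, ids)
  df <- expand.grid(cell = ids, month = 1:12, year = cfg$years,
                    KEEP.OUT.ATTRS = FALSE)
  lat <- ctr$lat[df$cell]; lon <- ctr$lon[df$cell]
  t_clim <- synth_temperature(cfg, lat, df$month)
  s_clim <- synth_salinity(cfg, lon)
  s_sd <- ifelse(lon < 4, cfg$sal_noise_west, cfg$sal_noise_east)
  df$temperature_c <- t_clim + stats::rnorm(nrow(df), 0, cfg$t_noise)
  df$salinity <- clamp(s_clim + stats::rnorm(nrow(df), 0, s_sd), 30, 36)
  env_field(df, grid)
}

#' Generate stock geolocations, fish tracks and metadata
#'
#' Geolocations are scattered around each stock's monthly centroid; fish
#' tracks are anchor sequences (release, roughly fortnightly geolocations,
#' recapture) following the same seasonal loop, with record lengths drawn
#' from the configured range.
#'
#' @param cfg a [synth_config()].
#' @return list with `geolocations` (stock, fish_id, date, lat, lon, cell),
#'   `tracks` (fish_id, stock, anchor_type, date, lat, lon) and `fish`
#'   (fish_id, stock, release/recapture dates).
#' @export
generate_stocks_and_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_stock_seed(cfg$seed, "stocks-tracks"))
  grid <- cfg$grid
  pad <- grid$cell_size / 2
  geo <- list()
  for (s in cfg$stocks) for (y in cfg$years) for (m in 1:12) {
    ctr <- stock_centroid(cfg, s, m)
    n <- cfg$geolocations_per_month
    lat <- clamp(stats::rnorm(n, ctr[1], cfg$geo_sd),
                 grid$lat_min + pad, grid$lat_max - pad)
    lon <- clamp(stats::rnorm(n, ctr[2], cfg$geo_sd),
                 grid$lon_min + pad, grid$lon_max - pad)
    day <- sample.int(28, n, replace = TRUE)
    geo[[length(geo) + 1]] <- data.frame(
      stock = s, fish_id = NA_character_,
      date = as.Date(sprintf("%d-%02d-%02d", y, m, day)),
      lat = lat, lon = lon)
  }
  geo <- do.call(rbind, geo)
  geo$cell <- cell_of(grid, geo$lat, geo$lon)

  tracks <- list(); fish <- list()
  for (s in cfg$stocks) for (i in seq_len(cfg$n_fish_per_stock)) {
    fid <- sprintf("%s-%d", s, i)
    len <- round(stats::runif(1, cfg$record_days_range[1],
                              cfg$record_days_range[2]))
    start <- as.Date(sprintf("%d-01-01", cfg$years[1])) +
      sample.int(300, 1)
    dates <- seq(start, start + len, by = "14 days")
    if (dates[length(dates)] < start + len) dates <- c(dates, start + len)
    mo <- as.integer(format(dates, "%m"))
    pos <- t(vapply(mo, function(m) stock_centroid(cfg, s, m), numeric(2)))
    lat <- clamp(pos[, 1] + stats::rnorm(length(dates), 0, 0.3),
                 grid$lat_min + pad, grid$lat_max - pad)
    lon <- clamp(pos[, 2] + stats::rnorm(length(dates), 0, 0.3),
                 grid$lon_min + pad, grid$lon_max - pad)
    type <- c("release", rep("geolocation", length(dates) - 2), "recapture")
    tracks[[length(tracks) + 1]] <- data.frame(
      fish_id = fid, stock = s, anchor_type = type, date = dates,
      lat = lat, lon = lon)
    fish[[length(fish) + 1]] <- data.frame(
      fish_id = fid, stock = s, release = start, recapture = start + len,
      record_days = len)
  }
  list(geolocations = geo, tracks = do.call(rbind, tracks),
       fish = do.call(rbind, fish))
}

# noise-free daily environmental exposure of one fish along its track
fish_daily_environment <- function(cfg, track, field) {
  pos <- daily_positions(track[, c("date", "lat", "lon")])
  grid <- field$grid
  pad <- grid$cell_size / 2
  pos$lat <- clamp(pos$lat, grid$lat_min + pad, grid$lat_max - pad)
  pos$lon <- clamp(pos$lon, grid$lon_min + pad, grid$lon_max - pad)
  pos$cell <- cell_of(grid, pos$lat, pos$lon)
  pos$year <- as.integer(format(pos$date, "%Y"))
  pos$month <- as.integer(format(pos$date, "%m"))
  fd <- field$data
  key_f <- paste(fd$cell, fd$year, fd$month)
  j <- match(paste(pos$cell, pos$year, pos$month), key_f)
  if (anyNA(j)) {
    # years outside the generated span fall back to climatology (first year)
    j2 <- match(paste(pos$cell, min(fd$year), pos$month), key_f)
    j[is.na(j)] <- j2[is.na(j)]
  }
  pos$temperature_c <- fd$temperature_c[j]
  pos$salinity <- fd$salinity[j]
  pos
}

#' Generate archival-tag records and daily salinity tables
#'
#' Tag temperature series are the fish's noise-free daily environmental
#' exposure plus white sensor noise (SD 0.2 degrees C by default) at the
#' configured cadence; pressures are consistent with seabed residence
#' (20-50 m, small tidal oscillation). The paired daily salinity table is
#' what the prediction stage consumes.
#'
#' @param cfg a [synth_config()].
#' @param tracks track table from [generate_stocks_and_tracks()].
#' @param field an [env_field()] from [generate_env_fields()].
#' @return list with `tags` (fish_id, timestamp, temperature_c,
#'   pressure_psi) and `salinity` (fish_id, date, salinity).
#' @export
generate_tag_records <- function(cfg, tracks, field) {
  stopifnot(inherits(cfg, "synth_config"), inherits(field, "env_field"))
  set.seed(derive_stock_seed(cfg$seed, "tag-records"))
  per_day <- max(1L, as.integer(round(24 * 60 / cfg$tag_cadence_min)))
  tags <- list(); sal <- list()
  for (fid in unique(tracks$fish_id)) {
    tr <- tracks[tracks$fish_id == fid, ]
    env <- fish_daily_environment(cfg, tr, field)
    nd <- nrow(env)
    depth <- stats::runif(1, 20, 50)
    tod <- rep(seq(0, 86400 - 1, length.out = per_day), nd)
    ts <- rep(as.POSIXct(paste(env$date, "00:00:00"), tz = "UTC"),
              each = per_day) + tod
    temp <- rep(env$temperature_c, each = per_day) +
      stats::rnorm(nd * per_day, 0, cfg$tag_noise_sd)
    press <- (depth + 0.8 * sin(2 * pi * as.numeric(ts) / (12.42 * 3600)) +
                stats::rnorm(nd * per_day, 0, 0.1)) * 1.46
    tags[[length(tags) + 1]] <- data.frame(
      fish_id = fid, timestamp = ts, temperature_c = temp,
      pressure_psi = pmax(press, 0))
    sal[[length(sal) + 1]] <- data.frame(
      fish_id = fid, date = env$date, salinity = env$salinity)
  }
  list(tags = do.call(rbind, tags), salinity = do.call(rbind, sal))
}

# per-stock vital-effect offset at given temperatures
vital_offset_at <- function(cfg, stock, temperature_c) {
  off <- cfg$vital_offsets[[stock]]
  if (is.numeric(off) && length(off) == 1L) {
    return(rep(off, length(temperature_c)))
  }
  th <- cfg$offset_thresholds
  ifelse(temperature_c < th[1], off$cold,
         ifelse(temperature_c > th[2], off$warm, off$mid))
}

#' Generate "measured" otolith values from the prediction chain
#'
#' Manufactures measured annual values and distance-indexed intra-annual
#' spot profiles by running the package's own prediction chain on each
#' fish's noise-free environmental exposure under the designated truth
#' scenario and model, then adding the configured stock-specific
#' vital-effect offsets and analytical noise. With offsets and noise set
#' to zero, measured values equal predictions exactly (pipeline closure).
#' Spot values integrate the predicted daily series over the configured
#' span (emulating 1-3 months of growth per ablation) and sit at distances
#' that accumulate with the truth scenario's monthly growth weights, so
#' the distance axis is non-linear in time.
#'
#' @param cfg a [synth_config()].
#' @param tracks track table from [generate_stocks_and_tracks()].
#' @param field an [env_field()].
#' @return list with `annual` (fish_id, stock, d18O) and `profiles` (named
#'   list per fish of data.frames fish_id, distance_um, d18O).
#' @export
generate_otolith_measurements <- function(cfg, tracks, field) {
  stopifnot(inherits(cfg, "synth_config"), inherits(field, "env_field"))
  set.seed(derive_stock_seed(cfg$seed, "otoliths"))
  scen <- as_scenario(cfg$truth_scenario)
  annual <- list(); profiles <- list()
  for (fid in unique(tracks$fish_id)) {
    tr <- tracks[tracks$fish_id == fid, ]
    stock <- tr$stock[1]
    env <- fish_daily_environment(cfg, tr, field)
    pred <- suppressWarnings(predict_daily_series(
      data.frame(date = env$date, temperature_c = env$temperature_c),
      data.frame(date = env$date, salinity = env$salinity),
      model = cfg$truth_model, fish_id = fid))
    month_t <- tapply(env$temperature_c,
                      format(env$date, "%Y-%m"), mean)
    mm <- pred$monthly
    m_off <- vital_offset_at(cfg, stock, as.numeric(month_t))
    w <- scen$weights[mm$month] * mm$n_days
    ann_true <- sum(w * (mm$d18O + m_off)) / sum(w)
    annual[[length(annual) + 1]] <- data.frame(
      fish_id = fid, stock = stock,
      d18O = ann_true + stats::rnorm(1, 0, cfg$annual_noise_sd))
    # spot profile: distances from cumulative scenario-weighted growth
    daily_w <- scen$weights[as.integer(format(env$date, "%m"))]
    dist <- cumsum(daily_w) / 365 * cfg$annual_growth_um
    span <- cfg$spot_span_days
    n_spots <- max(4L, floor(nrow(env) / span))
    centre_i <- round(seq(span / 2, nrow(env) - span / 2,
                          length.out = n_spots))
    spot_val <- vapply(centre_i, function(i) {
      win <- max(1, i - span %/% 2):min(nrow(env), i + span %/% 2)
      mean(pred$daily$d18O[win] + vital_offset_at(cfg, stock,
                                                  env$temperature_c[win]))
    }, numeric(1))
    profiles[[fid]] <- data.frame(
      fish_id = fid, distance_um = dist[centre_i],
      d18O = spot_val + stats::rnorm(n_spots, 0, cfg$spot_noise_sd))
  }
  list(annual = do.call(rbind, annual), profiles = profiles)
}

#' Emit a complete synthetic dataset directory
#'
#' Runs all four generators under the configuration's master seed and
#' writes the delimited-text tables the pipeline consumes (environmental
#' fields, geolocations, tracks, tag records, daily salinity, otolith
#' measurements) plus a manifest JSON recording the seed and key
#' parameters.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
generate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  field <- generate_env_fields(cfg)
  st <- generate_stocks_and_tracks(cfg)
  tg <- generate_tag_records(cfg, st$tracks, field)
  oto <- generate_otolith_measurements(cfg, st$tracks, field)
  ctr <- cell_center(field$grid, field$data$cell)
  utils::write.csv(
    data.frame(year = field$data$year, month = field$data$month,
               lat_cell = ctr$lat, lon_cell = ctr$lon,
               temperature_c = field$data$temperature_c,
               salinity = field$data$salinity),
    file.path(dir, "env_fields.csv"), row.names = FALSE)
  utils::write.csv(st$geolocations[, c("stock", "fish_id", "date", "lat", "lon")],
                   file.path(dir, "geolocations.csv"), row.names = FALSE)
  utils::write.csv(st$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(tg$tags, file.path(dir, "tag_records.csv"), row.names = FALSE)
  utils::write.csv(tg$salinity, file.path(dir, "daily_salinity.csv"),
                   row.names = FALSE)
  utils::write.csv(oto$annual, file.path(dir, "otolith_annual.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, oto$profiles),
                   file.path(dir, "otolith_profiles.csv"), row.names = FALSE)
  manifest <- list(seed = cfg$seed, years = cfg$years, stocks = cfg$stocks,
                   truth_scenario = cfg$truth_scenario,
                   truth_model = cfg$truth_model,
                   n_fish_per_stock = cfg$n_fish_per_stock,
                   tag_cadence_min = cfg$tag_cadence_min,
                   files = c("env_fields.csv", "geolocations.csv",
                             "tracks.csv", "tag_records.csv",
                             "daily_salinity.csv", "otolith_annual.csv",
                             "otolith_profiles.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
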