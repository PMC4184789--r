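#' Predict a daily and monthly otolith d18O series from a tag record
#'
#' Composes the full prediction chain at daily resolution over a tag's
#' recording window: daily mean tag temperature and the salinity at the
#' fish's daily position are pushed through mixing relation -> scale
#' conversion -> fractionation model. Calendar-month means are derived for
#' comparison with measured intra-annual otolith values (whose spots
#' integrate one to a few months of growth).
#'
#' @param tag either a raw tag data.frame (`timestamp`, `temperature_c`; it
#'   is collapsed with [daily_mean_temperature()]) or an already-daily
#'   data.frame (`date`, `temperature_c`).
#' @param daily_salinity data.frame with `date`, `salinity`, covering every
#'   day of the tag window; gaps longer than one day in either input are an
#'   error listing the dates.
#' @param relation mixing relation or registry name.
#' @param model fractionation model or registry name.
#' @param fish_id carried into provenance.
#' @return a `predicted_series`: list with `fish_id`, `model`, `daily`
#'   (date, d18O) and `monthly` (year, month, d18O, n_days, partial,
#'   mid_date).
#' @export
predict_daily_series <- function(tag, daily_salinity,
                                 relation = "northsea-mixing",
                                 model = "kim-aragonite",
                                 fish_id = NA_character_) {
  model <- as_fractionation_model(model)
  daily <- if ("timestamp" %in% names(tag)) daily_mean_temperature(tag) else {
    stopifnot(all(c("date", "temperature_c") %in% names(tag)))
    data.frame(date = as.Date(tag$date), temperature_c = tag$temperature_c)
  }
  check_gaps <- function(dates, what) {
    dd <- diff(sort(unique(as.Date(dates))))
    if (any(dd > 1)) {
      i <- which(dd > 1)[1]
      stop_input("%s has gaps > 1 day (e.g. after %s)", what,
                 sort(unique(as.Date(dates)))[i])
    }
  }
  check_gaps(daily$date, "tag record")
  sal <- data.frame(date = as.Date(daily_salinity$date),
                    salinity = daily_salinity$salinity)
  check_gaps(sal$date, "salinity series")
  j <- match(daily$date, sal$date)
  if (anyNA(j)) {
    stop_input("salinity missing for days: %s",
               paste(daily$date[is.na(j)][1:min(5, sum(is.na(j)))],
                     collapse = ", "))
  }
  dw <- convert_scale(salinity_to_water_d18O(sal$salinity[j], relation), "VPDB")
  do_ <- predict_otolith_d18O(celsius_to_kelvin(daily$temperature_c), dw, model)
  daily_out <- data.frame(date = daily$date, d18O = do_$value)
  structure(list(fish_id = fish_id, model = model$name, daily = daily_out,
                 monthly = monthly_means(daily_out)),
            class = "predicted_series")
}

#' @export
print.predicted_series <- function(x, ...) {
  cat(sprintf("<predicted_series> fish %s, model %s: %d days (%s to %s)\n",
              x$fish_id, x$model, nrow(x$daily), min(x$daily$date),
              max(x$daily$date)))
  invisible(x)
}

#' Calendar-month means of a dated daily series
#'
#' @param series data.frame with `date` and a value column (`d18O` or the
#'   second column).
#' @return data.frame with `year`, `month`, `d18O` (monthly mean),
#'   `n_days`, `partial` (TRUE when fewer than 15 days contribute) and
#'   `mid_date` (mean contributing date, used as the month's time stamp).
#' @export
monthly_means <- function(series) {
  stopifnot("date" %in% names(series))
  val <- if ("d18O" %in% names(series)) series$d18O else series[[2]]
  date <- as.Date(series$date)
  keep <- !is.na(val)
  val <- val[keep]; date <- date[keep]
  if (!length(val)) stop_input("no values to average")
  ym <- format(date, "%Y-%m")
  agg_v <- tapply(val, ym, mean)
  agg_n <- tapply(val, ym, length)
  agg_d <- tapply(as.numeric(date), ym, mean)
  out <- data.frame(
    year = as.integer(substr(names(agg_v), 1, 4)),
    month = as.integer(substr(names(agg_v), 6, 7)),
    d18O = as.numeric(agg_v),
    n_days = as.integer(agg_n),
    partial = as.integer(agg_n) < 15,
    mid_date = as.Date(round(as.numeric(agg_d)), origin = "1970-01-01"),
    row.names = NULL)
  out[order(out$year, out$month), ]
}

# interior local extrema of a numeric series; returns indices and type.
# Flat runs are collapsed to their midpoint.
local_extrema <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(0), type = character(0)))
  d <- diff(y)
  s <- sign(d)
  # carry last non-zero slope through flats
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- integer(0); typ <- character(0)
  for (i in seq_len(n - 2)) {
    if (s[i] > 0 && s[i + 1] < 0) { idx <- c(idx, i + 1); typ <- c(typ, "max") }
    if (s[i] < 0 && s[i + 1] > 0) { idx <- c(idx, i + 1); typ <- c(typ, "min") }
  }
  data.frame(index = idx, type = typ)
}

# order-preserving one-to-one matching of measured extrema values to
# predicted extrema values minimising total squared mismatch (skips allowed
# on either side); returns matched index pairs.
dp_match_extrema <- function(em, ep) {
  n1 <- length(em); n2 <- length(ep)
  big <- 1e18
  # D[i+1, j+1] = best cost using first i measured, first j predicted
  D <- matrix(0, n1 + 1, n2 + 1)
  take <- matrix(FALSE, n1 + 1, n2 + 1)
  skip_pen <- stats::var(c(em, ep)) %||% 1  # discourage gratuitous skips
  if (!is.finite(skip_pen) || skip_pen <= 0) skip_pen <- 1
  for (i in 0:n1) for (j in 0:n2) {
    if (i == 0 && j == 0) next
    best <- big
    if (i > 0 && j > 0) best <- D[i, j] + (em[i] - ep[j])^2
    tk <- best < big
    if (i > 0 && D[i, j + 1] + skip_pen < best) { best <- D[i, j + 1] + skip_pen; tk <- FALSE }
    if (j > 0 && D[i + 1, j] + skip_pen < best) { best <- D[i + 1, j] + skip_pen; tk <- FALSE }
    D[i + 1, j + 1] <- best
    take[i + 1, j + 1] <- tk
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- n1; j <- n2
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && take[i + 1, j + 1]) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + skip_pen) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs
}

#' Align a measured otolith profile to a predicted series
#'
#' Calibrates the distance axis of a distance-indexed measured d18O profile
#' to calendar time by matching the turning points (interior local extrema)
#' of the measured profile, in order, with those of the predicted monthly
#' series - the seasonal cycle's winter maxima and summer minima act as
#' tie points. A piecewise-linear strictly monotone warp is interpolated
#' between anchor pairs, with the first and last spots anchored to the
#' predicted window's endpoints. When the two series show different numbers
#' of extrema, an order-preserving dynamic-programming match (minimising
#' squared extremum-value mismatch, skips permitted) selects the anchors
#' and a message notes the fallback. Profiles with no interior extrema in
#' either series cannot be aligned and raise an error.
#'
#' @param profile data.frame with `distance_um` (strictly increasing) and
#'   `d18O`; at least 4 spots.
#' @param predicted a `predicted_series` from [predict_daily_series()].
#' @return a `profile_alignment`: list with `warp` (data.frame
#'   `distance_um`, `date`: the anchor map), `aligned` (data.frame
#'   `distance_um`, `date`, `d18O`: every spot dated), `method`
#'   (`"paired"` or `"dp"`), and `anchors`.
#' @export
align_profile <- function(profile, predicted) {
  stopifnot(inherits(predicted, "predicted_series"))
  need <- c("distance_um", "d18O")
  if (!all(need %in% names(profile))) {
    stop_input("profile needs columns distance_um, d18O")
  }
  if (nrow(profile) < 4) stop_input("need >= 4 spots for alignment")
  if (any(diff(profile$distance_um) <= 0)) {
    stop_input("spot distances must be strictly increasing")
  }
  mm <- predicted$monthly
  ex_m <- local_extrema(profile$d18O)
  ex_p <- local_extrema(mm$d18O)
  if (!nrow(ex_m) || !nrow(ex_p)) {
    stop_input("alignment failed: no interior extrema in %s series",
               if (!nrow(ex_m)) "the measured" else "the predicted")
  }
  if (nrow(ex_m) == nrow(ex_p) && all(ex_m$type == ex_p$type)) {
    pairs <- cbind(seq_len(nrow(ex_m)), seq_len(nrow(ex_p)))
    method <- "paired"
  } else {
    pairs <- dp_match_extrema(profile$d18O[ex_m$index], mm$d18O[ex_p$index])
    method <- "dp"
    message("align_profile: unequal extremum counts, using monotone DP match")
  }
  anchor_d <- profile$distance_um[ex_m$index[pairs[, 1]]]
  anchor_t <- as.numeric(mm$mid_date[ex_p$index[pairs[, 2]]])
  # endpoint anchors: first/last spot onto the predicted window endpoints
  d0 <- profile$distance_um[1]; d1 <- profile$distance_um[nrow(profile)]
  t0 <- as.numeric(min(predicted$daily$date))
  t1 <- as.numeric(max(predicted$daily$date))
  ad <- c(d0, anchor_d, d1)
  at <- c(t0, anchor_t, t1)
  keep <- !duplicated(ad)
  ad <- ad[keep]; at <- at[keep]
  # enforce strict monotonicity by dropping violating interior anchors
  repeat {
    bad <- which(diff(at) <= 0 | diff(ad) <= 0)
    if (!length(bad)) break
    drop_i <- pmin(bad[1] + 1, length(at) - 1)
    if (drop_i <= 1 || drop_i >= length(at)) break
    ad <- ad[-drop_i]; at <- at[-drop_i]
  }
  if (length(ad) < 2 || any(diff(at) <= 0)) {
    stop_input("alignment failed: could not build a monotone warp")
  }
  dates <- stats::approx(ad, at, xout = profile$distance_um, rule = 2)$y
  aligned <- data.frame(distance_um = profile$distance_um,
                        date = as.Date(round(dates), origin = "1970-01-01"),
                        d18O = profile$d18O)
  structure(list(
    warp = data.frame(distance_um = ad,
                      date = as.Date(round(at), origin = "1970-01-01")),
    aligned = aligned, method = method,
    anchors = data.frame(distance_um = anchor_d,
                         date = as.Date(round(anchor_t), origin = "1970-01-01"))),
    class = "profile_alignment")
}

#' Measured-vs-predicted extreme-value offset summary
#'
#' For each fish, the measured profile's annual extreme values (minimum and
#' maximum d18O, optionally the mean of the `k_extreme` most extreme spots)
#' are compared with the predicted monthly series' extremes over the same
#' window: offset = observed - predicted. Offsets are then summarised per
#' stock as mean +/- SE, with a one-sided paired Wilcoxon signed-rank test
#' whose direction is fixed by the sign of the group mean (exact
#' distribution for <= 25 pairs). Groups with fewer than 4 fish are
#' computed with a small-sample warning. Significance stars: `*` p<0.05,
#' `**` p<0.01, `***` p<0.001.
#'
#' @param aligned_profiles named list (by fish id) of aligned measured
#'   series (data.frames with `d18O`; output `$aligned` of
#'   [align_profile()] or any dated spot table).
#' @param predicted_list named list (by fish id) of `predicted_series`.
#' @param grouping named character vector mapping fish id -> stock.
#' @param k_extreme number of extreme spots averaged per extreme (default 1,
#'   the single aligned extremum).
#' @return data.frame with one row per (stock, extreme): `stock`, `model`,
#'   `extreme`, `n`, `mean`, `se`, `p`, `stars`, `direction`.
#' @export
offset_summary <- function(aligned_profiles, predicted_list, grouping,
                           k_extreme = 1) {
  fish <- names(aligned_profiles)
  stopifnot(length(fish) > 0, all(fish %in% names(predicted_list)),
            all(fish %in% names(grouping)))
  ext_mean <- function(v, k, which_) {
    v <- sort(v, decreasing = (which_ == "max"))
    mean(v[seq_len(min(k, length(v)))])
  }
  per_fish <- do.call(rbind, lapply(fish, function(f) {
    obs <- aligned_profiles[[f]]$d18O
    pred <- predicted_list[[f]]$monthly$d18O
    data.frame(
      fish_id = f, stock = unname(grouping[f]),
      model = predicted_list[[f]]$model,
      obs_min = ext_mean(obs, k_extreme, "min"),
      obs_max = ext_mean(obs, k_extreme, "max"),
      pred_min = min(pred), pred_max = max(pred))
  }))
  rows <- list()
  for (s in sort(unique(per_fish$stock))) {
    sub <- per_fish[per_fish$stock == s, ]
    if (nrow(sub) < 4) {
      warning(sprintf("stock %s has only %d fish (< 4): offsets reported with low power",
                      s, nrow(sub)), call. = FALSE)
    }
    for (ext in c("min", "max")) {
      obs <- sub[[paste0("obs_", ext)]]
      pred <- sub[[paste0("pred_", ext)]]
      diffs <- obs - pred
      mu <- mean(diffs)
      se <- stats::sd(diffs) / sqrt(length(diffs))
      direction <- if (mu >= 0) "greater" else "less"
      p <- if (all(diffs == 0)) 1 else {
        suppressWarnings(stats::wilcox.test(
          obs, pred, paired = TRUE, alternative = direction,
          exact = length(diffs) <= 25)$p.value)
      }
      stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
               else if (p < 0.05) "*" else "ns"
      rows[[length(rows) + 1]] <- data.frame(
        stock = s, model = sub$model[1], extreme = ext, n = nrow(sub),
        mean = mu, se = se, p = p, stars = stars, direction = direction)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
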