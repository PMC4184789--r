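#' Monthly environmental field container
#'
#' Holds gridded monthly mean bottom temperature (degrees C) and salinity
#' (PSU) for one or more years, keyed by grid cell id. Constructed from a
#' long-format data frame (one row per cell/month/year) or read from
#' delimited text with [read_env_field()].
#'
#' @param data data.frame with columns `cell` (integer id), `year`,
#'   `month` (1-12), `temperature_c`, `salinity`.
#' @param grid the [grid_spec()] the cell ids refer to.
#' @return an object of class `env_field`.
#' @export
env_field <- function(data, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  need <- c("cell", "year", "month", "temperature_c", "salinity")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_input("env_field missing columns: %s",
                               paste(miss, collapse = ", "))
  if (any(data$month < 1 | data$month > 12)) stop_input("month must be 1-12")
  if (any(data$cell < 1 | data$cell > n_cells(grid))) {
    stop_input("cell id outside grid")
  }
  if (any(data$temperature_c < -2 | data$temperature_c > 30)) {
    stop_input("temperature outside plausible range [-2, 30] degC")
  }
  if (any(data$salinity < 0 | data$salinity > 40)) {
    stop_input("salinity outside [0, 40]")
  }
  structure(list(data = data[need], grid = grid), class = "env_field")
}

#' @export
print.env_field <- function(x, ...) {
  cat(sprintf("<env_field> %d rows, %d cells, years %s\n",
              nrow(x$data), length(unique(x$data$cell)),
              paste(sort(unique(x$data$year)), collapse = "/")))
  invisible(x)
}

#' Read environmental fields / geolocations from delimited text
#'
#' `read_env_field()` expects columns `year, month, lat_cell, lon_cell,
#' temperature_c, salinity` (cell-centre coordinates); `read_geolocations()`
#' expects `stock, fish_id, date, lat, lon` with ISO-8601 dates. Both
#' validate schema and value ranges and report the row count.
#'
#' @param path delimited text file (comma-separated, header row).
#' @param grid a [grid_spec()].
#' @return an `env_field`, or a data.frame of geolocations with a `Date`
#'   column and cell ids attached.
#' @export
read_env_field <- function(path, grid = grid_spec()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "lat_cell", "lon_cell", "temperature_c", "salinity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("%s: missing columns %s", path,
                               paste(miss, collapse = ", "))
  df$cell <- cell_of(grid, df$lat_cell, df$lon_cell)
  message(sprintf("read_env_field: %d rows from %s", nrow(df), path))
  env_field(df, grid)
}

#' @rdname read_env_field
#' @export
read_geolocations <- function(path, grid = grid_spec()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stock", "fish_id", "date", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("%s: missing columns %s", path,
                               paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop_input("%s: unparseable dates", path)
  df$cell <- cell_of(grid, df$lat, df$lon)
  message(sprintf("read_geolocations: %d rows from %s", nrow(df), path))
  df
}

#' Build per-stock monthly occupancy maps from geolocations
#'
#' For each stock and calendar month, cells are ranked by geolocation count
#' (ties broken by ascending cell id) and the smallest prefix whose
#' cumulative count reaches `fraction` of the month's total is retained:
#' the "cells containing 80 percent of geolocations". Years are pooled by
#' default (monthly climatological occupancy); `by_year = TRUE` builds one
#' map per year.
#'
#' @param geolocations data.frame with `stock`, `date` (Date or ISO-8601
#'   character), and either `cell` or `lat`/`lon` columns.
#' @param grid a [grid_spec()].
#' @param fraction target cumulative share of geolocations, in (0, 1]
#'   (default 0.8).
#' @param by_year build separate maps per year instead of pooling.
#' @return an `occupancy_map`: list with `grid`, `fraction` and `cells`, a
#'   named list `stock -> list of 12 integer cell-id vectors` (or
#'   `stock -> year -> ...` when `by_year`).
#' @export
build_occupancy_map <- function(geolocations, grid = grid_spec(),
                                fraction = 0.8, by_year = FALSE) {
  stopifnot(fraction > 0, fraction <= 1)
  geo <- geolocations
  if (!"cell" %in% names(geo)) geo$cell <- cell_of(grid, geo$lat, geo$lon)
  geo$date <- as.Date(geo$date)
  geo$month <- as.integer(format(geo$date, "%m"))
  one_map <- function(sub, stock_label) {
    lapply(1:12, function(m) {
      cells <- sub$cell[sub$month == m]
      if (!length(cells)) {
        stop_input("stock '%s' has no geolocations in month %d", stock_label, m)
      }
      tab <- sort(table(cells), decreasing = TRUE)
      ids <- as.integer(names(tab))
      ord <- order(-as.integer(tab), ids)
      counts <- as.integer(tab)[ord]
      ids <- ids[ord]
      k <- which(cumsum(counts) >= fraction * sum(counts))[1]
      sort(ids[seq_len(k)])
    })
  }
  stocks <- sort(unique(geo$stock))
  cells <- if (by_year) {
    lapply(stats::setNames(stocks, stocks), function(s) {
      sub <- geo[geo$stock == s, ]
      yrs <- sort(unique(as.integer(format(sub$date, "%Y"))))
      lapply(stats::setNames(yrs, yrs), function(y) {
        one_map(sub[format(sub$date, "%Y") == y, ], paste0(s, "/", y))
      })
    })
  } else {
    lapply(stats::setNames(stocks, stocks),
           function(s) one_map(geo[geo$stock == s, ], s))
  }
  structure(list(grid = grid, fraction = fraction, by_year = by_year,
                 cells = cells),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> stocks: %s; fraction %.2f%s\n",
              paste(names(x$cells), collapse = ", "), x$fraction,
              if (x$by_year) " (per year)" else " (years pooled)"))
  invisible(x)
}

occ_cells <- function(occ, stock, month) {
  if (!stock %in% names(occ$cells)) {
    stop_input("unknown stock '%s' in occupancy map", stock)
  }
  occ$cells[[stock]][[month]]
}

#' Predict a monthly otolith d18O field (isoscape) from an environmental field
#'
#' Element-wise composition of the prediction chain over every (cell,
#' month): salinity -> water d18O (VSMOW) via the mixing relation -> VPDB
#' via [convert_scale()] -> otolith d18O via the fractionation model at the
#' cell's monthly temperature. Years are pooled by averaging the per-year
#' predicted deltas (the delta differences involved make averaging in
#' delta space and in ratio space indistinguishable at the per-mil level).
#'
#' @param field an [env_field()].
#' @param relation mixing relation or registry name.
#' @param model fractionation model or registry name.
#' @param cells optional integer cell ids that must be covered; missing
#'   (cell, month) combinations among them raise an error naming the cells.
#' @return a `d18o_field`: numeric matrix `[n_cells x 12]` of otolith d18O
#'   (VPDB, per mil), NA where the field has no data, with the model and
#'   relation names attached as attributes.
#' @export
compute_d18O_field <- function(field, relation = "northsea-mixing",
                               model = "kim-aragonite", cells = NULL) {
  stopifnot(inherits(field, "env_field"))
  relation <- as_mixing_relation(relation)
  model <- as_fractionation_model(model)
  df <- field$data
  dw <- convert_scale(salinity_to_water_d18O(df$salinity, relation), "VPDB")
  do_ <- predict_otolith_d18O(celsius_to_kelvin(df$temperature_c), dw, model)
  # pool years: mean predicted delta per (cell, month)
  key <- interaction(df$cell, df$month, drop = TRUE)
  agg <- tapply(do_$value, key, mean)
  parts <- strsplit(names(agg), ".", fixed = TRUE)
  cell_i <- as.integer(vapply(parts, `[[`, "", 1L))
  month_i <- as.integer(vapply(parts, `[[`, "", 2L))
  dmap <- matrix(NA_real_, nrow = n_cells(field$grid), ncol = 12)
  dmap[cbind(cell_i, month_i)] <- as.numeric(agg)
  if (!is.null(cells)) {
    bad <- which(is.na(dmap[cells, , drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_input("d18O field missing for cell/month: %s",
                 paste(sprintf("%d/%d", cells[bad[, 1]], bad[, 2]),
                       collapse = ", "))
    }
  }
  structure(dmap, class = "d18o_field", grid = field$grid,
            model = model$name, relation = relation$name)
}
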