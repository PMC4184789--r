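#' Regular lat/lon grid specification
#'
#' Defines the gridded study area: half-open cells
#' `[south, north) x [west, east)` of `cell_size` degrees, identified by
#' `(row, col)` counted from the south-west origin (row 1 is the
#' southernmost band). The default covers the study area 49.5-58 N,
#' 0-8 E at 0.5 degree resolution (the 51-58 N core plus the English
#' Channel strip south of 51 N used by the named regions).
#'
#' @param lat_min,lat_max,lon_min,lon_max extent in decimal degrees; must be
#'   integer multiples of `cell_size` apart.
#' @param cell_size cell edge, degrees (default 0.5).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(lat_min = 49.5, lat_max = 58, lon_min = 0, lon_max = 8,
                      cell_size = 0.5) {
  stopifnot(lat_max > lat_min, lon_max > lon_min, cell_size > 0)
  nr <- (lat_max - lat_min) / cell_size
  nc <- (lon_max - lon_min) / cell_size
  if (abs(nr - round(nr)) > 1e-8 || abs(nc - round(nc)) > 1e-8) {
    stop_input("grid extent must be an integer multiple of cell_size")
  }
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 cell_size = cell_size,
                 nrow = as.integer(round(nr)), ncol = as.integer(round(nc))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g-%g N x %g-%g E, %g deg cells (%d x %d = %d cells)\n",
              x$lat_min, x$lat_max, x$lon_min, x$lon_max, x$cell_size,
              x$nrow, x$ncol, x$nrow * x$ncol))
  invisible(x)
}

n_cells <- function(grid) grid$nrow * grid$ncol

cell_id <- function(grid, row, col) (row - 1L) * grid$ncol + col

cell_rowcol <- function(grid, id) {
  id <- as.integer(id)
  list(row = (id - 1L) %/% grid$ncol + 1L, col = (id - 1L) %% grid$ncol + 1L)
}

#' Locate points on a grid
#'
#' Maps positions to cell ids under the half-open cell convention; points on
#' the northern/eastern outer boundary are assigned to the outermost cell so
#' that the closed study rectangle is fully covered.
#'
#' @param grid a [grid_spec()].
#' @param lat,lon positions, decimal degrees.
#' @return integer cell ids.
#' @export
cell_of <- function(grid, lat, lon) {
  if (any(lat < grid$lat_min | lat > grid$lat_max |
          lon < grid$lon_min | lon > grid$lon_max)) {
    stop_input("position outside grid extent")
  }
  row <- pmin(floor((lat - grid$lat_min) / grid$cell_size) + 1, grid$nrow)
  col <- pmin(floor((lon - grid$lon_min) / grid$cell_size) + 1, grid$ncol)
  as.integer(cell_id(grid, row, col))
}

#' @rdname cell_of
#' @param id integer cell ids.
#' @return `cell_center()`: data.frame with `lat`, `lon` of cell centres.
#' @export
cell_center <- function(grid, id) {
  rc <- cell_rowcol(grid, id)
  data.frame(
    lat = grid$lat_min + (rc$row - 0.5) * grid$cell_size,
    lon = grid$lon_min + (rc$col - 0.5) * grid$cell_size)
}

# Named regions partitioning the study area (printed bounds, half-open at
# the 0.01 degree precision of the captions: "52.49" upper limits become
# "< 52.50").
REGION_TABLE <- data.frame(
  name    = c("EC",  "SNS",  "WNS",  "CNS",  "ENS",  "NNS"),
  lat_lo  = c(-Inf,  51.00,  52.50,  52.50,  52.50,  55.50),
  lat_hi  = c(51.00, 52.50,  55.50,  55.50,  55.50,  Inf),
  lon_lo  = c(-Inf,  -Inf,   -Inf,   2.50,   5.00,   -Inf),
  lon_hi  = c(Inf,   Inf,    2.50,   5.00,   Inf,    Inf),
  stringsAsFactors = FALSE)

#' Assign a position to a named region of the study area
#'
#' Six regions partition the study area: English Channel (EC, lat < 51 N),
#' Southern North Sea (SNS, 51-52.49 N), and, within 52.50-55.49 N, the
#' Western (WNS, lon < 2.50 E), Central (CNS, 2.50-4.99 E) and Eastern
#' (ENS, lon >= 5.00 E) North Sea, with the Northern North Sea (NNS) at
#' lat >= 55.50 N. Boundaries are half-open, consistent with the grid.
#'
#' @param lat,lon position(s), decimal degrees; must lie inside `grid`.
#' @param grid study-area extent used for the domain check.
#' @return character vector of region names.
#' @examples
#' assign_region(53, 2)  # "WNS"
#' @export
assign_region <- function(lat, lon, grid = grid_spec()) {
  if (any(lat < grid$lat_min | lat > grid$lat_max |
          lon < grid$lon_min | lon > grid$lon_max)) {
    stop_input("position outside the study area")
  }
  out <- character(length(lat))
  lon <- rep_len(lon, length(lat))
  for (i in seq_along(lat)) {
    hit <- which(lat[i] >= REGION_TABLE$lat_lo & lat[i] < REGION_TABLE$lat_hi &
                 lon[i] >= REGION_TABLE$lon_lo & lon[i] < REGION_TABLE$lon_hi)
    if (length(hit) != 1L) stop_input("position matches %d regions", length(hit))
    out[i] <- REGION_TABLE$name[hit]
  }
  out
}
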