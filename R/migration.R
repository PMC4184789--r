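#' Random-walk simulation configuration
#'
#' @param n_paths number of annual paths per stock (default 10000, the
#'   ensemble size used for stock signature simulation).
#' @param seed master seed; a per-stock stream is derived from it so each
#'   stock's ensemble can be regenerated independently.
#' @param adjacency `"8-neighbour"` (default; queen moves) or
#'   `"4-neighbour"` (rook moves).
#' @param allow_stay may a walker remain in its current cell (default TRUE;
#'   "moving to any adjacent cell" is read as including no net movement at
#'   monthly resolution).
#' @param stranded_policy what to do when no adjacent cell is inside next
#'   month's occupancy: `"nearest-cell"` (default) relocates to the nearest
#'   allowed cell by Chebyshev grid distance (ties by cell id) and logs the
#'   relocation; `"resample"` redraws the whole path (with a retry cap).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_paths = 10000, seed = 1,
                       adjacency = c("8-neighbour", "4-neighbour"),
                       allow_stay = TRUE,
                       stranded_policy = c("nearest-cell", "resample")) {
  adjacency <- match.arg(adjacency)
  stranded_policy <- match.arg(stranded_policy)
  stopifnot(n_paths >= 1, is.numeric(seed), length(seed) == 1L)
  structure(list(n_paths = as.integer(n_paths), seed = as.integer(seed),
                 adjacency = adjacency, allow_stay = allow_stay,
                 stranded_policy = stranded_policy),
            class = "sim_config")
}

# stable per-stock seed derivation, kept within 32-bit integer range
derive_stock_seed <- function(seed, stock) {
  h <- sum(utf8ToInt(as.character(stock)) * seq_along(utf8ToInt(as.character(stock))))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483629)
}

neighbour_ids <- function(grid, id, adjacency, allow_stay) {
  rc <- cell_rowcol(grid, id)
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  if (adjacency == "4-neighbour") { dr <- c(-1, 0, 0, 1); dc <- c(0, -1, 1, 0) }
  r <- rc$row + dr; c_ <- rc$col + dc
  ok <- r >= 1 & r <= grid$nrow & c_ >= 1 & c_ <= grid$ncol
  ids <- cell_id(grid, r[ok], c_[ok])
  if (allow_stay) ids <- c(id, ids)
  as.integer(ids)
}

chebyshev_dist <- function(grid, id_from, ids_to) {
  a <- cell_rowcol(grid, id_from); b <- cell_rowcol(grid, ids_to)
  pmax(abs(a$row - b$row), abs(a$col - b$col))
}

#' Simulate stock-constrained random-walk migration paths
#'
#' Generates `n_paths` annual (12-month, January-December) cell sequences
#' for one stock. The January cell is drawn uniformly from the stock's
#' January occupancy set; each subsequent month's cell is drawn uniformly
#' from the intersection of the current cell's adjacency neighbourhood with
#' the next month's occupancy set, so every path respects the stock's
#' observed monthly range. Walkers with an empty intersection are handled
#' by the configured stranding policy; under the default nearest-cell
#' relocation the move is deterministic and counted per path.
#'
#' @param occ an `occupancy_map` (see [build_occupancy_map()]).
#' @param stock stock id present in `occ`.
#' @param config a [sim_config()].
#' @return `migration_paths` object: list with `stock`, `cells` (integer
#'   matrix `n_paths x 12`), `relocations` (per-path count of stranding
#'   relocations), `config` and `seed_used`.
#' @export
simulate_paths <- function(occ, stock, config = sim_config()) {
  stopifnot(inherits(occ, "occupancy_map"), inherits(config, "sim_config"))
  grid <- occ$grid
  monthly <- lapply(1:12, function(m) occ_cells(occ, stock, m))
  if (any(vapply(monthly, length, 0L) == 0L)) {
    stop_input("stock '%s' has an empty monthly occupancy set", stock)
  }
  seed_used <- derive_stock_seed(config$seed, stock)
  # transition table: for every cell in month m's set, the allowed cells in
  # month m+1 (possibly a deterministic relocation target when stranded)
  trans <- vector("list", 11L)
  reloc_flag <- vector("list", 11L)
  for (m in 1:11) {
    nxt <- monthly[[m + 1]]
    trans[[m]] <- lapply(monthly[[m]], function(cl) {
      allowed <- intersect(neighbour_ids(grid, cl, config$adjacency,
                                         config$allow_stay), nxt)
      if (length(allowed)) return(allowed)
      if (config$stranded_policy == "resample") return(integer(0))
      d <- chebyshev_dist(grid, cl, nxt)
      nxt[order(d, nxt)][1]  # nearest allowed cell, ties by cell id
    })
    reloc_flag[[m]] <- vapply(seq_along(monthly[[m]]), function(i) {
      length(trans[[m]][[i]]) == 1L &&
        !trans[[m]][[i]] %in% intersect(
          neighbour_ids(grid, monthly[[m]][i], config$adjacency,
                        config$allow_stay), nxt)
    }, logical(1))
    names(trans[[m]]) <- monthly[[m]]
    names(reloc_flag[[m]]) <- monthly[[m]]
  }
  run_walk <- function(n) {
    cells <- matrix(0L, nrow = n, ncol = 12)
    reloc <- integer(n)
    cells[, 1] <- monthly[[1]][sample.int(length(monthly[[1]]), n, replace = TRUE)]
    for (m in 1:11) {
      cur <- cells[, m]
      for (cl in unique(cur)) {
        idx <- which(cur == cl)
        allowed <- trans[[m]][[as.character(cl)]]
        if (!length(allowed)) {            # resample policy: mark invalid
          cells[idx, m + 1] <- NA_integer_
        } else if (length(allowed) == 1L) {
          cells[idx, m + 1] <- allowed
          if (reloc_flag[[m]][[as.character(cl)]]) {
            reloc[idx] <- reloc[idx] + 1L
          }
        } else {
          cells[idx, m + 1] <- allowed[sample.int(length(allowed),
                                                  length(idx), replace = TRUE)]
        }
      }
    }
    list(cells = cells, reloc = reloc)
  }
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed_used)
    expr
  }
  res <- withr_seed({
    out <- run_walk(config$n_paths)
    tries <- 0L
    while (anyNA(out$cells) && tries < 100L) {
      bad <- which(apply(is.na(out$cells), 1, any))
      repl <- run_walk(length(bad))
      out$cells[bad, ] <- repl$cells
      out$reloc[bad] <- repl$reloc
      tries <- tries + 1L
    }
    if (anyNA(out$cells)) {
      stop_input("resampling failed to produce %d valid paths", config$n_paths)
    }
    out
  })
  structure(list(stock = stock, cells = res$cells, relocations = res$reloc,
                 config = config, seed_used = seed_used, grid = grid),
            class = "migration_paths")
}

#' @export
print.migration_paths <- function(x, ...) {
  cat(sprintf("<migration_paths> stock %s: %d paths, %d relocation events (seed %d)\n",
              x$stock, nrow(x$cells), sum(x$relocations), x$seed_used))
  invisible(x)
}

#' Sample monthly d18O values along migration paths
#'
#' Joins paths with a monthly otolith d18O field: value(m) = field value of
#' the cell occupied in month m.
#'
#' @param paths a `migration_paths` object, or an integer vector of 12 cell
#'   ids, or an integer matrix with 12 columns.
#' @param dmap a `d18o_field` from [compute_d18O_field()].
#' @return numeric matrix `n_paths x 12` of per-mil values.
#' @export
sample_monthly_values <- function(paths, dmap) {
  cells <- if (inherits(paths, "migration_paths")) paths$cells
           else if (is.matrix(paths)) paths
           else matrix(as.integer(paths), nrow = 1)
  if (ncol(cells) != 12) stop_input("paths must have 12 monthly cells")
  vals <- matrix(NA_real_, nrow = nrow(cells), ncol = 12)
  for (m in 1:12) vals[, m] <- dmap[cells[, m], m]
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop_input("d18O field missing for path cell/month: %s",
               paste(sprintf("%d/%d", cells[bad], bad[, 2])[seq_len(min(5, nrow(bad)))],
                     collapse = ", "))
  }
  vals
}

#' Export migration paths as a long-format data.frame
#'
#' @param paths a `migration_paths` object.
#' @return data.frame with `stock`, `path_id`, `month`, `lat_cell`,
#'   `lon_cell` (cell-centre coordinates).
#' @export
paths_to_table <- function(paths) {
  stopifnot(inherits(paths, "migration_paths"))
  n <- nrow(paths$cells)
  ctr <- cell_center(paths$grid, as.integer(paths$cells))
  data.frame(stock = paths$stock,
             path_id = rep(seq_len(n), times = 12),
             month = rep(1:12, each = n),
             lat_cell = ctr$lat, lon_cell = ctr$lon)
}
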