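# Shared fixture builders and independent oracles. Everything here is
# deliberately plain arithmetic, independent of the package's own
# implementation paths.

# uniform environmental field: one temperature and salinity everywhere
make_uniform_field <- function(grid, t_c, sal, years = 1997) {
  df <- expand.grid(cell = seq_len(grid$nrow * grid$ncol), month = 1:12,
                    year = years, KEEP.OUT.ATTRS = FALSE)
  df$temperature_c <- t_c
  df$salinity <- sal
  env_field(df, grid)
}

# direct evaluation of the prediction chain, written out long-hand
oracle_chain <- function(t_c, sal, slope = 0.29, intercept = -9.85,
                         a = 17.88, b = -31.14) {
  dw_vsmow <- slope * sal + intercept
  dw_vpdb <- 0.97002 * dw_vsmow - 29.98
  alpha <- exp((a * 1000 / (t_c + 273.15) + b) / 1000)
  alpha * (1000 + dw_vpdb) - 1000
}

# numeric-integration Bayes accuracy for Gaussian classes, equal priors
oracle_bayes_accuracy <- function(mu, sd, dx = 1e-4, pad = 6) {
  x <- seq(min(mu) - pad * max(sd), max(mu) + pad * max(sd), by = dx)
  dens <- vapply(seq_along(mu), function(k) dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  win <- max.col(dens)
  100 * mean(vapply(seq_along(mu),
                    function(k) sum(dens[win == k, k]) * dx, numeric(1)))
}

# small synthetic config used across tests: few fish, coarse tag cadence
test_synth_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_fish_per_stock = 2, tag_cadence_min = 360,
         record_days_range = c(200, 300)),
    list(...))
  do.call(synth_config, args)
}

# a 12-month predicted series with a clean seasonal cycle over one year
make_sine_predicted <- function(year = 1998, amplitude = 1.2, level = 1.5,
                                fish_id = "F1") {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- as.numeric(days - days[1])
  vals <- level + amplitude * cos(2 * pi * (doy - 45) / 365)  # max mid-Feb
  daily <- data.frame(date = days, d18O = vals)
  structure(list(fish_id = fish_id, model = "kim-aragonite", daily = daily,
                 monthly = monthly_means(daily)),
            class = "predicted_series")
}
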