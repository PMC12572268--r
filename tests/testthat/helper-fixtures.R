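# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

small_sim_config <- function(seed = 42, n_facilities = 80, ...) {
  sim_config(
    n_facilities = n_facilities,
    grid_extent = list(lat = c(-14, -12), lon = c(33, 35), resolution = 0.5),
    period = c("2011-01", "2014-12"),
    seed = seed,
    ...
  )
}

# One simulated world (grid, facilities, indices, panel) reused across tests.
simulate_world <- function(cfg = small_sim_config()) {
  grid <- generate_precip_grid(cfg)
  facilities <- assign_grid_cells(generate_facilities(cfg), grid)
  indices <- build_index_table(grid, lags = cfg$lags)
  panel <- generate_anc_counts(facilities, indices, cfg)
  list(cfg = cfg, grid = grid, facilities = facilities, indices = indices, panel = panel)
}

# Deterministic daily series for one synthetic month (28 days by default).
random_month_series <- function(n_days = 28, max_mm = 40) {
  stats::runif(n_days, 0, max_mm)
}

# Independent oracle: exhaustive 5-day window scan.
rx5day_oracle <- function(values) {
  n <- length(values)
  max(vapply(1:(n - 4L), function(i) sum(values[i:(i + 4L)]), numeric(1L)))
}

# Independent oracle: brute-force nearest cell centre (lowest id on ties).
nearest_cell_oracle <- function(lon, lat, cells) {
  d2 <- (cells$lon - lon)^2 + (cells$lat - lat)^2
  cells$cell_id[which(d2 == min(d2))][1L]
}

# Minimal hand-built fitted_model for arithmetic-only tests.
stub_model <- function(terms, coefficients, loglik = 0, n_obs = 100L) {
  structure(
    list(
      terms = terms,
      coefficients = coefficients,
      se = coefficients * 0,
      p_values = coefficients * 0,
      loglik = loglik,
      aic = 2 * (length(coefficients) + 1L) - 2 * loglik,
      n_obs = n_obs,
      adj_r2 = NA_real_,
      sigma = NA_real_
    ),
    class = "fitted_model"
  )
}

# Small uniform grid as a cells data.frame.
toy_cells <- function(n_lat = 4, n_lon = 5) {
  g <- precip_grid(
    lat = seq(0, by = 1, length.out = n_lat),
    lon = seq(0, by = 1, length.out = n_lon),
    time = as.Date("2020-01-01"),
    precip = array(0, c(1, n_lat, n_lon))
  )
  grid_cells(g)
}
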