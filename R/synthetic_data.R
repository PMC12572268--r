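#' Simulation configuration
#'
#' Bundles every parameter of the synthetic facility/rainfall/service-count
#' generator, with defaults emulating the study system: ~200 reporting
#' facilities on a quarter-degree grid over a Malawi-sized extent, a
#' November-April wet season, occasional multi-day extreme rainfall bursts,
#' and service counts drawn from the log-linear model with known
#' coefficients.
#'
#' @param n_facilities Number of facilities (>= 2).
#' @param grid_extent List with `lat = c(min, max)`, `lon = c(min, max)`,
#'   `resolution` (degrees, > 0).
#' @param period Character `c(start, end)` as `"YYYY-MM"`.
#' @param wet_season_months Integer month numbers of the wet season.
#' @param mean_wet_daily_mm,mean_dry_daily_mm Expected (unconditional) daily
#'   rainfall in wet/dry-season months, mm/day.
#' @param wet_day_prob_wet,wet_day_prob_dry Probability a day is wet in
#'   wet/dry-season months (rainfall occurrence).
#' @param gamma_shape Shape of the gamma wet-day amount distribution.
#' @param extreme_event_prob Per cell-month probability of an added extreme
#'   burst.
#' @param extreme_event_mm Total mm added by a burst, spread over 1-5
#'   consecutive days.
#' @param true_coefficients Named numeric vector: the data-generating
#'   log-linear coefficients. Names must be `intercept` or terms constructible
#'   by the design assembler (covariate terms or precipitation index columns).
#' @param noise_sd SD of additive Gaussian noise on the log scale.
#' @param missing_rate Probability a facility-month report is absent.
#' @param lags Integer lags available to precipitation terms.
#' @param seed Integer master seed; per-component substreams are derived from
#'   it.
#'
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_facilities = 199,
                       grid_extent = list(
                         lat = c(-17.1, -9.3), lon = c(32.6, 35.95),
                         resolution = 0.25
                       ),
                       period = c("2011-01", "2024-10"),
                       wet_season_months = c(11L, 12L, 1L, 2L, 3L, 4L),
                       mean_wet_daily_mm = 6,
                       mean_dry_daily_mm = 0.3,
                       wet_day_prob_wet = 0.55,
                       wet_day_prob_dry = 0.08,
                       gamma_shape = 0.9,
                       extreme_event_prob = 0.03,
                       extreme_event_mm = 250,
                       true_coefficients = default_true_coefficients(),
                       noise_sd = 0.3,
                       missing_rate = 0.1,
                       lags = c(1L, 2L, 3L, 4L, 9L),
                       seed = 1L) {
  cfg <- list(
    n_facilities = as.integer(n_facilities),
    grid_extent = grid_extent,
    period = period,
    wet_season_months = as.integer(wet_season_months),
    mean_wet_daily_mm = mean_wet_daily_mm,
    mean_dry_daily_mm = mean_dry_daily_mm,
    wet_day_prob_wet = wet_day_prob_wet,
    wet_day_prob_dry = wet_day_prob_dry,
    gamma_shape = gamma_shape,
    extreme_event_prob = extreme_event_prob,
    extreme_event_mm = extreme_event_mm,
    true_coefficients = true_coefficients,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    lags = sort(unique(as.integer(lags))),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

# Data-generating coefficients with the observed signs and magnitudes of the
# historical fit: strong urban/ownership effects, small per-mm precipitation
# effects. Distance enters per metre at a plausible per-metre magnitude.
#' @rdname sim_config
#' @export
default_true_coefficients <- function() {
  c(
    intercept = 0.4,
    year = 0.0021,
    month = 0.0047,
    urban = 1.3042,
    zone_central_west = 0.1277,
    zone_northern = -0.5821,
    zone_south_east = 0.1089,
    zone_south_west = 0.0487,
    owner_government = 0.2592,
    owner_private = -1.8440,
    altitude = 0.00005,
    min_distance = 0.00003,
    cumulative = -0.0004,
    rx5day = 0.0005,
    cumulative_lag4 = -0.0002,
    cumulative_lag9 = -0.00006,
    rx5day_lag1 = 0.0006
  )
}

covariate_terms <- function() {
  c(
    "year", "month", "urban",
    "zone_central_west", "zone_northern", "zone_south_east", "zone_south_west",
    "owner_government", "owner_ngo", "owner_private",
    "altitude", "min_distance"
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_facilities >= 2L)
  ext <- cfg$grid_extent
  if (ext$resolution <= 0) stop("grid resolution must be > 0", call. = FALSE)
  if (diff(ext$lat) <= 0 || diff(ext$lon) <= 0) {
    stop("grid extent is degenerate (zero area)", call. = FALSE)
  }
  probs <- c(
    cfg$wet_day_prob_wet, cfg$wet_day_prob_dry,
    cfg$extreme_event_prob, cfg$missing_rate
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$mean_wet_daily_mm < 0 || cfg$mean_dry_daily_mm < 0 ||
      cfg$extreme_event_mm < 0 || cfg$noise_sd < 0) {
    stop("rainfall means, extreme mm and noise_sd must be nonnegative", call. = FALSE)
  }
  s <- parse_ym(cfg$period[1L]); e <- parse_ym(cfg$period[2L])
  if (ym_to_index(s[1L], s[2L]) > ym_to_index(e[1L], e[2L])) {
    stop("period start is after period end", call. = FALSE)
  }
  allowed <- c("intercept", covariate_terms(), index_columns(cfg$lags))
  bad <- setdiff(names(cfg$true_coefficients), allowed)
  if (length(bad) > 0L) {
    stop(
      "true_coefficients name terms the design assembler cannot construct: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(cfg)
}

zone_levels <- function() {
  c("Northern", "Central East", "Central West", "South East", "South West")
}
owner_levels <- function() c("Government", "CHAM", "NGO", "Private")
type_levels <- function() {
  c("Dispensary", "Health Centre", "Clinic", "Rural/Community Hospital", "District Hospital")
}

#' Generate a synthetic facility table
#'
#' Facilities are placed uniformly over the grid extent; zone, district,
#' setting, owner, type and altitude are drawn over the standard categorical
#' levels. District is nested within zone and type is drawn conditionally on
#' owner, so the collinearity screen has realistic structure to detect.
#'
#' @param config A [sim_config].
#' @return A data.frame with columns `facility_id`, `lon`, `lat`, `zone`,
#'   `district`, `setting`, `owner`, `type`, `altitude`, `min_distance`.
#' @export
generate_facilities <- function(config) {
  validate_sim_config(config)
  n <- config$n_facilities
  ext <- config$grid_extent
  set.seed(substream_seed(config$seed, "facilities"))

  zone <- sample(zone_levels(), n, replace = TRUE)
  district <- paste(zone, sample(1:3, n, replace = TRUE), sep = " D")
  owner <- sample(owner_levels(), n, replace = TRUE, prob = c(0.55, 0.3, 0.05, 0.10))
  # facility type tracks ownership closely (hospitals mostly Government etc.)
  type <- vapply(owner, function(o) {
    p <- switch(o,
      Government = c(0.05, 0.45, 0.10, 0.20, 0.20),
      CHAM = c(0.10, 0.60, 0.10, 0.20, 0.00),
      NGO = c(0.40, 0.30, 0.30, 0.00, 0.00),
      Private = c(0.30, 0.10, 0.60, 0.00, 0.00)
    )
    sample(type_levels(), 1L, prob = p)
  }, character(1L))

  fac <- data.frame(
    facility_id = sprintf("F%03d", seq_len(n)),
    lon = stats::runif(n, ext$lon[1L], ext$lon[2L]),
    lat = stats::runif(n, ext$lat[1L], ext$lat[2L]),
    zone = zone,
    district = district,
    setting = sample(c("urban", "rural"), n, replace = TRUE, prob = c(0.15, 0.85)),
    owner = owner,
    type = type,
    altitude = stats::runif(n, 474, 1600)
  )
  fac$min_distance <- min_distance_to_closest(fac)
  fac
}

#' Generate a synthetic daily precipitation grid
#'
#' Daily rainfall per cell is a Bernoulli wet-day occurrence times a
#' gamma-distributed wet-day amount (the standard stochastic weather-generator
#' form), with season-dependent occurrence probability and mean. With
#' probability `extreme_event_prob` a cell-month additionally receives an
#' extreme burst of `extreme_event_mm`, spread evenly over 1-5 consecutive
#' days starting at a uniformly drawn day.
#'
#' The grid starts `warm_up_months` before the configured period so that
#' lagged indices are defined from the first analysis month.
#'
#' @param config A [sim_config].
#' @param warm_up_months Months of spin-up prepended before `period` start;
#'   defaults to the maximum lag.
#' @return A [precip_grid].
#' @export
generate_precip_grid <- function(config, warm_up_months = max(config$lags)) {
  validate_sim_config(config)
  ext <- config$grid_extent
  lat <- seq(ext$lat[1L], ext$lat[2L], by = ext$resolution)
  lon <- seq(ext$lon[1L], ext$lon[2L], by = ext$resolution)

  s <- parse_ym(config$period[1L])
  start_idx <- ym_to_index(s[1L], s[2L]) - as.integer(warm_up_months)
  start_ym <- index_to_ym(start_idx)
  e <- parse_ym(config$period[2L])
  first_day <- as.Date(sprintf("%04d-%02d-01", start_ym$year, start_ym$month))
  last_day <- as.Date(sprintf("%04d-%02d-%02d", e[1L], e[2L], days_in_month(e[1L], e[2L])))
  time <- seq(first_day, last_day, by = "1 day")

  month_of <- as.integer(format(time, "%m"))
  is_wet_season <- month_of %in% config$wet_season_months
  p_wet <- ifelse(is_wet_season, config$wet_day_prob_wet, config$wet_day_prob_dry)
  mean_daily <- ifelse(is_wet_season, config$mean_wet_daily_mm, config$mean_dry_daily_mm)
  # conditional wet-day mean so the unconditional daily mean matches config
  cond_mean <- ifelse(p_wet > 0, mean_daily / p_wet, 0)

  n_t <- length(time)
  shape <- config$gamma_shape
  ym_keys <- format(time, "%Y-%m")
  month_starts <- which(!duplicated(ym_keys))
  month_lens <- as.vector(table(factor(ym_keys, levels = unique(ym_keys))))

  set.seed(substream_seed(config$seed, "grid"))
  precip <- array(0, dim = c(n_t, length(lat), length(lon)))
  for (i in seq_along(lat)) {
    for (j in seq_along(lon)) {
      wet <- stats::rbinom(n_t, 1L, p_wet)
      amt <- ifelse(
        cond_mean > 0,
        stats::rgamma(n_t, shape = shape, scale = cond_mean / shape),
        0
      )
      series <- wet * amt
      if (config$extreme_event_prob > 0 && config$extreme_event_mm > 0) {
        hit <- stats::rbinom(length(month_starts), 1L, config$extreme_event_prob)
        for (m in which(hit == 1L)) {
          len <- sample(1:5, 1L)
          start <- month_starts[m] + sample.int(month_lens[m] - len + 1L, 1L) - 1L
          idx <- start:(start + len - 1L)
          series[idx] <- series[idx] + config$extreme_event_mm / len
        }
      }
      precip[, i, j] <- series
    }
  }
  precip_grid(lat, lon, time, precip)
}

#' Generate service counts from the log-linear model
#'
#' For each facility-month of the configured period, builds the model design
#' row (covariates plus precipitation indices for the facility's grid cell)
#' and draws `count = max(0, round(exp(X beta + noise) - epsilon))` with
#' `epsilon = 1`. This is the ground-truth data-generating process the
#' regression module is expected to recover.
#'
#' @param facilities Facility table with a `cell_id` column (see
#'   [assign_grid_cells]).
#' @param indices A `precip_index_table` covering every facility-month of the
#'   period.
#' @param config A [sim_config].
#' @param epsilon Offset inside the log; must match the analysis epsilon.
#' @return An `anc_panel` data.frame: `facility_id`, `year`, `month`,
#'   `anc_count`, `missing_flag` (all `FALSE` here).
#' @export
generate_anc_counts <- function(facilities, indices, config, epsilon = 1) {
  validate_sim_config(config)
  if (is.null(facilities$cell_id)) {
    stop("facilities need a cell_id column; run assign_grid_cells() first", call. = FALSE)
  }
  months <- ym_seq(config$period[1L], config$period[2L])
  frame <- covariate_frame(facilities, indices, months)

  beta <- config$true_coefficients
  terms <- setdiff(names(beta), "intercept")
  missing_terms <- setdiff(terms, names(frame))
  if (length(missing_terms) > 0L) {
    stop(
      "true_coefficients name terms with no design column: ",
      paste(missing_terms, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(frame[terms])) {
    stop(
      "indices do not cover every facility-month of the period ",
      "(undefined lags or missing cell-months); extend the grid warm-up",
      call. = FALSE
    )
  }
  lp <- rep(unname(beta["intercept"] %||% 0), nrow(frame))
  if (!"intercept" %in% names(beta)) lp <- rep(0, nrow(frame))
  for (tm in terms) lp <- lp + beta[[tm]] * frame[[tm]]

  set.seed(substream_seed(config$seed, "counts"))
  noise <- if (config$noise_sd > 0) stats::rnorm(nrow(frame), 0, config$noise_sd) else 0
  counts <- pmax(0, round(exp(lp + noise) - epsilon))
  panel <- data.frame(
    facility_id = frame$facility_id,
    year = frame$year,
    month = frame$month,
    anc_count = as.integer(counts),
    missing_flag = FALSE
  )
  structure(panel, class = c("anc_panel", "data.frame"))
}

#' Blank out reports: random non-reporting and confirmed closures
#'
#' Random non-reporting removes each report independently with probability
#' `missing_rate`; months inside a closure range also become missing (the
#' panel builder later restores confirmed-closure months as zeros). Retained
#' entries are never altered; the pre-missingness panel is the only
#' ground-truth record.
#'
#' @param panel An `anc_panel`.
#' @param closures Optional closure registry (see [closure_registry]).
#' @param config A [sim_config] (uses `missing_rate` and the missingness seed
#'   substream).
#' @return The panel with `anc_count = NA` and `missing_flag = TRUE` on the
#'   affected rows.
#' @export
apply_missingness <- function(panel, closures = NULL, config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "missingness"))
  drop <- stats::runif(nrow(panel)) < config$missing_rate
  if (!is.null(closures) && nrow(closures) > 0L) {
    drop <- drop | closure_mask(panel, closures)
  }
  panel$anc_count[drop] <- NA_integer_
  panel$missing_flag <- drop | panel$missing_flag
  panel
}

#' Simulate a closure registry
#'
#' Draws `n_closures` facilities (without replacement) and gives each a
#' closure of 1-6 consecutive months inside the period, emulating
#' storm-damage closures confirmed by secondary sources.
#'
#' @param facilities Facility table.
#' @param config A [sim_config].
#' @param n_closures Number of closed facilities.
#' @return A closure registry data.frame (see [closure_registry]).
#' @export
generate_closures <- function(facilities, config, n_closures = 2L) {
  validate_sim_config(config)
  if (n_closures == 0L) return(closure_registry())
  set.seed(substream_seed(config$seed, "closures"))
  months <- ym_seq(config$period[1L], config$period[2L])
  idx <- sample.int(nrow(facilities), min(n_closures, nrow(facilities)))
  rows <- lapply(idx, function(i) {
    len <- sample(1:6, 1L)
    start <- sample.int(nrow(months) - len + 1L, 1L)
    data.frame(
      facility_id = facilities$facility_id[i],
      start = ym_label(months$year[start], months$month[start]),
      end = ym_label(months$year[start + len - 1L], months$month[start + len - 1L]),
      evidence = "synthetic closure report"
    )
  })
  closure_registry(do.call(rbind, rows))
}
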