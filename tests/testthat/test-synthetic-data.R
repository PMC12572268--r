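test_that("facility generation is deterministic with valid categories", {
  cfg <- small_sim_config(n_facilities = 199)
  fac <- generate_facilities(cfg)
  expect_equal(nrow(fac), 199)
  expect_true(all(fac$zone %in% c(
    "Northern", "Central East", "Central West", "South East", "South West"
  )))
  expect_true(all(fac$owner %in% c("Government", "CHAM", "NGO", "Private")))
  expect_true(all(fac$setting %in% c("urban", "rural")))
  expect_true(all(fac$altitude >= 0))
  expect_true(all(fac$min_distance > 0))
  ext <- cfg$grid_extent
  expect_true(all(fac$lon >= ext$lon[1] & fac$lon <= ext$lon[2]))
  expect_true(all(fac$lat >= ext$lat[1] & fac$lat <= ext$lat[2]))

  expect_identical(fac, generate_facilities(cfg))

  pair <- generate_facilities(small_sim_config(n_facilities = 2))
  expect_equal(pair$min_distance[1], pair$min_distance[2])

  bad <- small_sim_config()
  bad$grid_extent$lat <- c(-12, -12)
  expect_error(generate_facilities(bad), "degenerate")
})

test_that("precipitation generator honours seasonality, zeros and extremes", {
  # all-zero configuration
  cfg0 <- small_sim_config(
    mean_wet_daily_mm = 0, mean_dry_daily_mm = 0, extreme_event_prob = 0
  )
  g0 <- generate_precip_grid(cfg0)
  expect_true(all(g0$precip == 0))

  # wet-season months wetter than dry at every cell over 10 years
  cfg <- sim_config(
    n_facilities = 2,
    grid_extent = list(lat = c(-12, -11), lon = c(34, 35), resolution = 0.5),
    period = c("2011-01", "2020-12"),
    mean_wet_daily_mm = 10, mean_dry_daily_mm = 1,
    extreme_event_prob = 0, seed = 3
  )
  g <- generate_precip_grid(cfg, warm_up_months = 0)
  wet <- as.integer(format(g$time, "%m")) %in% cfg$wet_season_months
  for (cid in grid_cells(g)$cell_id) {
    s <- ancrain:::cell_series(g, cid)
    expect_gt(mean(s$values[wet]), mean(s$values[!wet]))
  }

  # certain extremes force Rx5day >= burst size in every month
  cfge <- sim_config(
    n_facilities = 2,
    grid_extent = list(lat = c(-12, -11.5), lon = c(34, 34.5), resolution = 0.5),
    period = c("2012-01", "2012-12"),
    extreme_event_prob = 1, extreme_event_mm = 300, seed = 9
  )
  ge <- generate_precip_grid(cfge, warm_up_months = 0)
  idx <- build_index_table(ge, lags = integer())
  expect_true(all(idx$rx5day >= 300))

  # determinism
  expect_identical(generate_precip_grid(cfg), generate_precip_grid(cfg))
})

test_that("count generation follows the log-linear form exactly when noiseless", {
  cfg <- small_sim_config(
    n_facilities = 5,
    noise_sd = 0,
    true_coefficients = c(intercept = log(101))
  )
  cfg$period <- c("2012-01", "2012-06")
  world <- list(
    grid = generate_precip_grid(cfg),
    facilities = NULL
  )
  fac <- assign_grid_cells(generate_facilities(cfg), world$grid)
  idx <- build_index_table(world$grid, lags = cfg$lags)
  panel <- generate_anc_counts(fac, idx, cfg)
  expect_true(all(panel$anc_count == 100L))

  # closed-form ratio on the (count + 1) scale for a cumulative-only model
  cfg2 <- cfg
  cfg2$true_coefficients <- c(intercept = log(1001), cumulative = -0.0004)
  panel2 <- generate_anc_counts(fac, idx, cfg2)
  frame_idx <- idx[match(
    paste(fac$cell_id[1], panel2$year, panel2$month)[panel2$facility_id == fac$facility_id[1]],
    paste(idx$cell_id, idx$year, idx$month)
  ), ]
  sub <- panel2[panel2$facility_id == fac$facility_id[1], ]
  expected <- 1001 * exp(-0.0004 * frame_idx$cumulative)
  expect_equal(sub$anc_count + 1, round(expected - 1) + 1, tolerance = 1e-9)

  # a +1000 mm difference scales (count + 1) by exp(-0.4)
  lp <- log(1001) - 0.0004 * c(500, 1500)
  counts <- round(exp(lp) - 1)
  expect_equal((counts[2] + 1) / (counts[1] + 1), exp(-0.4), tolerance = 2e-3)

  # unknown term is named in the error
  cfg3 <- cfg
  cfg3$true_coefficients <- c(intercept = 1, cumulative_lag7 = 0.1)
  expect_error(ancrain:::validate_sim_config(cfg3), "cumulative_lag7")
})

test_that("missingness blanks at the configured rate and conserves the rest", {
  world <- simulate_world()
  cfg <- world$cfg

  cfg0 <- cfg; cfg0$missing_rate <- 0
  expect_identical(apply_missingness(world$panel, NULL, cfg0), world$panel)

  cfg1 <- cfg; cfg1$missing_rate <- 1
  all_gone <- apply_missingness(world$panel, NULL, cfg1)
  expect_true(all(all_gone$missing_flag))
  expect_true(all(is.na(all_gone$anc_count)))

  out <- apply_missingness(world$panel, NULL, cfg) # rate 0.1
  n <- nrow(out)
  frac <- mean(out$missing_flag)
  bound <- 2.58 * sqrt(0.1 * 0.9 / n) # binomial 99% bounds
  expect_lt(abs(frac - 0.1), bound)

  # retained values unchanged
  kept <- !out$missing_flag
  expect_identical(out$anc_count[kept], world$panel$anc_count[kept])

  # closures force missingness in range
  cl <- closure_registry(data.frame(
    facility_id = world$facilities$facility_id[1],
    start = "2012-03", end = "2012-05", evidence = "test"
  ))
  cfgc <- cfg; cfgc$missing_rate <- 0
  closed <- apply_missingness(world$panel, cl, cfgc)
  in_range <- closed$facility_id == world$facilities$facility_id[1] &
    closed$year == 2012 & closed$month %in% 3:5
  expect_true(all(closed$missing_flag[in_range]))
  expect_true(all(!closed$missing_flag[!in_range]))
})
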