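make_panel <- function(missing_by_facility) {
  rows <- lapply(names(missing_by_facility), function(fid) {
    n_missing <- missing_by_facility[[fid]]
    data.frame(
      facility_id = fid,
      year = 2020,
      month = 1:10,
      anc_count = c(rep(NA_integer_, n_missing), seq_len(10 - n_missing) * 10L),
      missing_flag = c(rep(TRUE, n_missing), rep(FALSE, 10 - n_missing))
    )
  })
  structure(do.call(rbind, rows), class = c("anc_panel", "data.frame"))
}

test_that("sparse-facility exclusion uses a strict threshold and is idempotent", {
  panel <- make_panel(c(A = 10, B = 9, C = 2, D = 0))
  out <- exclude_sparse_facilities(panel, 0.9)
  # 100% missing dropped; exactly 90% retained (strict inequality)
  expect_setequal(unique(out$facility_id), c("B", "C", "D"))
  expect_identical(exclude_sparse_facilities(out, 0.9), out)

  # hand-counted survivor set on a panel with known missing fractions
  fractions <- c(F1 = 0, F2 = 1, F3 = 5, F4 = 10, F5 = 9, F6 = 10, F7 = 3, F8 = 8, F9 = 10, F10 = 1)
  panel10 <- make_panel(fractions)
  survivors <- exclude_sparse_facilities(panel10, 0.9)
  expect_setequal(unique(survivors$facility_id), names(fractions)[fractions <= 9])

  expect_error(exclude_sparse_facilities(panel, 0), "threshold")
})

test_that("closure zeros repair missing months only, inside ranges only", {
  panel <- make_panel(c(A = 4, B = 0))
  closures <- closure_registry(data.frame(
    facility_id = "A", start = "2020-02", end = "2020-06", evidence = "storm damage"
  ))
  out <- apply_closure_zeros(panel, closures)

  # missing months inside the closure become observed zeros
  fixed <- out[out$facility_id == "A" & out$month %in% 2:4, ]
  expect_true(all(fixed$anc_count == 0L))
  expect_true(all(!fixed$missing_flag))
  # missing month outside the closure stays missing
  expect_true(out$missing_flag[out$facility_id == "A" & out$month == 1])
  # observed months inside the closure keep their counts (observed data wins)
  expect_identical(
    out[out$facility_id == "B", c("anc_count", "missing_flag")],
    panel[panel$facility_id == "B", c("anc_count", "missing_flag")]
  )

  expect_warning(
    apply_closure_zeros(panel, closure_registry(data.frame(
      facility_id = "ZZZ", start = "2020-01", end = "2020-02", evidence = ""
    ))),
    "ZZZ"
  )
  expect_error(
    closure_registry(data.frame(facility_id = "A", start = "2020-05", end = "2020-02")),
    "inverted"
  )
})

test_that("altitude imputation fills with the observed mean", {
  fac <- data.frame(facility_id = c("a", "b", "c"), altitude = c(100, 300, NA))
  expect_equal(impute_altitude(fac)$altitude, c(100, 300, 200))

  none_missing <- data.frame(facility_id = "a", altitude = 500)
  expect_identical(impute_altitude(none_missing), none_missing)

  mostly <- data.frame(facility_id = letters[1:4], altitude = c(500, NA, NA, NA))
  expect_equal(impute_altitude(mostly)$altitude, rep(500, 4))

  expect_error(
    impute_altitude(data.frame(facility_id = "a", altitude = NA_real_)),
    "cannot impute"
  )
})

test_that("collinearity screen drops the second member of confounded pairs", {
  set.seed(55)
  n <- 200
  owner <- sample(c("Government", "CHAM", "Private"), n, replace = TRUE)
  fac <- data.frame(
    owner = owner,
    type = paste0("type-", owner), # perfectly confounded
    zone = sample(c("N", "S"), n, replace = TRUE),
    district = NA
  )
  fac$district <- paste0(fac$zone, sample(1:2, n, replace = TRUE)) # nested
  fac$independent <- sample(c("x", "y"), n, replace = TRUE)

  res <- collinearity_screen(
    fac,
    pairs = list(c("owner", "type"), c("zone", "district"), c("owner", "independent"))
  )
  expect_setequal(res$dropped, c("type", "district"))
  expect_true(all(c("owner", "zone", "independent") %in% res$kept))
  expect_equal(unname(res$associations[["owner~type"]]), 1, tolerance = 1e-9)
  expect_lt(res$associations[["owner~independent"]], 0.3)
})

test_that("design assembly encodes one-hots, epsilon and exclusions correctly", {
  world <- simulate_world()
  cfg <- world$cfg
  panel <- apply_missingness(world$panel, NULL, cfg)
  design <- assemble_design(
    panel, world$facilities, world$indices,
    precip_terms = c("cumulative", "rx5day")
  )

  # response back-transform recovers the integer count exactly
  expect_equal(exp(design$response) - 1, design$anc_count, tolerance = 1e-12)
  # zero counts map to response 0 under epsilon = 1
  if (any(design$anc_count == 0)) {
    expect_true(all(design$response[design$anc_count == 0] == 0))
  }

  # row count = non-missing rows with complete lag history (independent count)
  obs <- panel[!panel$missing_flag, ]
  key_obs <- paste(world$facilities$cell_id[
    match(obs$facility_id, world$facilities$facility_id)
  ], obs$year, obs$month)
  idx_ok <- !is.na(world$indices$cumulative)
  key_idx <- paste(world$indices$cell_id, world$indices$year, world$indices$month)
  expect_equal(nrow(design), sum(key_obs %in% key_idx[idx_ok]))

  # one-hot encoding against the reference levels
  urban_gov_north <- world$facilities[
    world$facilities$setting == "urban" &
      world$facilities$owner == "Government" &
      world$facilities$zone == "Northern",
  ]
  if (nrow(urban_gov_north) > 0) {
    row <- design[design$facility_id == urban_gov_north$facility_id[1], ][1, ]
    expect_equal(row$urban, 1L)
    expect_equal(row$owner_government, 1L)
    expect_equal(row$zone_northern, 1L)
    expect_equal(row$zone_central_west + row$zone_south_east + row$zone_south_west, 0L)
  }
  # reference facility: all one-hots zero
  ref <- world$facilities[
    world$facilities$setting == "rural" &
      world$facilities$owner == "CHAM" &
      world$facilities$zone == "Central East",
  ]
  if (nrow(ref) > 0) {
    row <- design[design$facility_id == ref$facility_id[1], ][1, ]
    onehots <- c(
      "urban", "zone_central_west", "zone_northern", "zone_south_east",
      "zone_south_west", "owner_government", "owner_private"
    )
    expect_true(all(row[onehots] == 0))
  }

  # undefined-lag months excluded when lag terms are requested
  design_lag <- assemble_design(
    panel, world$facilities, world$indices, precip_terms = c("cumulative_lag9")
  )
  expect_false(anyNA(design_lag$cumulative_lag9))

  # epsilon is honoured
  d2 <- assemble_design(
    panel, world$facilities, world$indices,
    precip_terms = "cumulative", epsilon = 0.5
  )
  expect_equal(exp(d2$response) - 0.5, d2$anc_count, tolerance = 1e-12)

  expect_error(
    assemble_design(panel, world$facilities, world$indices, precip_terms = "no_such"),
    "no_such"
  )
})
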