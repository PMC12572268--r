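#' Scenario ensemble of precipitation grids
#'
#' A named set of precipitation series (ensemble members) sharing grid
#' geometry and period, e.g. the downscaled projections of one emissions
#' pathway, or a single-member early-period counterfactual.
#'
#' @param name Scenario label (opaque string, e.g. `"ssp245"`).
#' @param members Named list of [precip_grid] objects.
#' @return A `scenario_ensemble` object.
#' @export
scenario_ensemble <- function(name, members) {
  if (length(members) == 0L) stop("ensemble has no members", call. = FALSE)
  if (is.null(names(members)) || any(names(members) == "")) {
    stop("ensemble members must be named", call. = FALSE)
  }
  ref <- members[[1L]]
  for (m in members) {
    stopifnot(inherits(m, "precip_grid"))
    if (!identical(m$lat, ref$lat) || !identical(m$lon, ref$lon) ||
        !identical(m$time, ref$time)) {
      stop("ensemble members must share grid geometry and period", call. = FALSE)
    }
  }
  structure(list(name = name, members = members), class = "scenario_ensemble")
}

#' Select the lowest / mean / highest ensemble members
#'
#' Computes each member's mean monthly precipitation over all grid cells and
#' months of its period, then selects the member with the lowest grand mean,
#' the member whose grand mean is closest to the median of the grand means
#' (the "mean" pathway), and the member with the highest. Ties are broken by
#' member name, so the selection is invariant to member ordering.
#'
#' @param ensemble A [scenario_ensemble].
#' @return List with `lowest`, `mean`, `highest` (member names) and `means`
#'   (named vector of member grand means, mm/month).
#' @export
select_ensemble_members <- function(ensemble) {
  stopifnot(inherits(ensemble, "scenario_ensemble"))
  means <- vapply(ensemble$members, function(g) {
    idx <- build_index_table(g, lags = integer())
    mean(idx$cumulative)
  }, numeric(1L))
  ord <- order(means, names(means))
  lowest <- names(means)[ord[1L]]
  highest <- names(means)[ord[length(ord)]]
  med <- stats::median(means)
  gap <- abs(means - med)
  mid_candidates <- names(means)[gap == min(gap)]
  middle <- sort(mid_candidates)[1L]
  list(lowest = lowest, mean = middle, highest = highest, means = means)
}

# Map analysis years onto alternative-series years: k-th analysis year ->
# k-th eligible alternative year, cycling when the alternative window is
# shorter. Months map within the year, preserving seasonality. Only fully
# covered alternative years (all 12 months with defined values) are eligible
# as remap targets; partial warm-up years supply lags, not substitutes.
remap_years <- function(analysis_years, alt_indices, idx_cols) {
  complete_rows <- stats::complete.cases(alt_indices[, idx_cols, drop = FALSE])
  month_count <- tapply(
    alt_indices$month[complete_rows],
    alt_indices$year[complete_rows],
    function(m) length(unique(m))
  )
  cy <- sort(as.integer(names(month_count)[month_count == 12L]))
  if (length(cy) == 0L) {
    stop("alternative series has no fully covered year to map onto", call. = FALSE)
  }
  ay <- sort(unique(analysis_years))
  cy[((match(analysis_years, ay) - 1L) %% length(cy)) + 1L]
}

#' Re-run the attribution under a substituted precipitation series
#'
#' Replaces every precipitation index column of the base design with the
#' values of an alternative index table (an early-period counterfactual or a
#' projection member), calendar-aligned month-for-month: month m of the k-th
#' analysis year takes the alternative's month m of its k-th year (cycling if
#' the alternative window is shorter). All non-climate covariates, and the
#' response, are untouched. The extreme-month flag is recomputed from the
#' substituted cumulative totals against the *historical* threshold.
#'
#' @param m0,m1 The fitted models (m0 without, m1 with precipitation terms).
#' @param alt_indices A `precip_index_table` from the alternative series,
#'   covering every (cell, mapped year, month) of the base design with
#'   defined lags.
#' @param base_design The factual `anc_design`.
#' @param threshold_mm Extreme threshold from the historical window (never
#'   recomputed per scenario).
#' @return A `disruption_series` under the substituted precipitation.
#' @export
counterfactual_run <- function(m0, m1, alt_indices, base_design, threshold_mm) {
  design <- base_design
  idx_cols <- intersect(
    setdiff(names(alt_indices), c("cell_id", "year", "month")),
    names(design)
  )
  if (length(idx_cols) == 0L) {
    stop("base design carries no precipitation index columns", call. = FALSE)
  }
  alt_key <- paste(alt_indices$cell_id, alt_indices$year, alt_indices$month)
  coverage <- function(mapped_year) {
    pos <- match(paste(design$cell_id, mapped_year, design$month), alt_key)
    gaps <- is.na(pos)
    for (cn in idx_cols) gaps <- gaps | is.na(alt_indices[[cn]][pos])
    list(pos = pos, gaps = gaps)
  }
  # identity alignment first (exact when the alternative IS the factual
  # series); calendar remapping only when identity leaves gaps
  mapped_year <- design$year
  hit <- coverage(mapped_year)
  if (any(hit$gaps)) {
    mapped_year <- remap_years(design$year, alt_indices, idx_cols)
    hit <- coverage(mapped_year)
  }
  pos <- hit$pos
  gaps <- hit$gaps
  if (any(gaps)) {
    bad <- unique(paste0(
      "cell ", design$cell_id[gaps], " @ ",
      ym_label(mapped_year[gaps], design$month[gaps])
    ))
    stop(
      "alternative series does not cover ", length(bad), " design cell-months: ",
      paste(utils::head(bad, 5L), collapse = "; "),
      if (length(bad) > 5L) " ..." else "",
      call. = FALSE
    )
  }
  for (cn in idx_cols) design[[cn]] <- alt_indices[[cn]][pos]
  disruption_series(m0, m1, design, threshold_mm)
}

#' Build a prediction-only design for a projection period
#'
#' Constructs the covariate frame for future facility-months (no observed
#' counts): the facility covariates are carried forward unchanged and the
#' precipitation indices come from the scenario member's grid. Rows with
#' undefined lags are dropped (scenario lag warm-up should come from the
#' member's own preceding months).
#'
#' @param facilities Facility table with `cell_id`.
#' @param indices `precip_index_table` of the scenario member.
#' @param period Character `c(start, end)` `"YYYY-MM"` of the projection.
#' @param precip_terms,base_terms,epsilon As in [assemble_design].
#' @return An `anc_design` without `anc_count`/`response` columns.
#' @export
project_design <- function(facilities, indices, period,
                           precip_terms,
                           base_terms = default_base_terms(),
                           epsilon = 1) {
  months <- ym_seq(period[1L], period[2L])
  frame <- covariate_frame(facilities, indices, months)
  terms <- c(base_terms, precip_terms)
  unknown <- setdiff(terms, names(frame))
  if (length(unknown) > 0L) {
    stop("requested terms have no design column: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  complete <- stats::complete.cases(frame[, terms, drop = FALSE])
  frame <- frame[complete, , drop = FALSE]
  rownames(frame) <- NULL
  keep_cols <- unique(c(
    "facility_id", "cell_id", "year", "month", "cumulative", terms
  ))
  structure(
    frame[, intersect(keep_cols, names(frame)), drop = FALSE],
    terms = terms, epsilon = epsilon,
    class = c("anc_design", "data.frame")
  )
}

#' Cumulative scenario summary table
#'
#' One row per run: cumulative deficit services, percent of total services,
#' extreme-attributed deficit and its share — the national summary layout for
#' comparing historical, counterfactual and projection runs.
#'
#' @param runs Named list of `disruption_series`; names label the rows
#'   (e.g. `"historical"`, `"ssp245:mean"`).
#' @param totals Named numeric vector (or single number recycled) of total
#'   services per run, the percentage denominator.
#' @return A `scenario_summary` data.frame with columns `scenario`,
#'   `member_selection`, `deficit_services`, `total_services`,
#'   `percent_disrupted`, `extreme_deficit_services`, `extreme_share_percent`.
#' @export
scenario_summary <- function(runs, totals) {
  stopifnot(length(runs) > 0L, !is.null(names(runs)))
  if (length(totals) == 1L && is.null(names(totals))) {
    totals <- stats::setNames(rep(totals, length(runs)), names(runs))
  }
  rows <- lapply(names(runs), function(nm) {
    agg <- aggregate_disruption(runs[[nm]], unname(totals[[nm]]))
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    data.frame(
      scenario = parts[1L],
      member_selection = if (length(parts) > 1L) parts[2L] else "n/a",
      agg[, c(
        "deficit_services", "total_services", "percent_disrupted",
        "extreme_deficit_services", "extreme_share_percent"
      )]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("scenario_summary", "data.frame"))
}

#' Percentage reduction between two disruption totals
#'
#' `100 * (1 - a / b)`: how much smaller run `a` is than reference `b`, e.g.
#' a counterfactual against the historical run.
#'
#' @param a Disruption total of the comparison run.
#' @param b Disruption total of the reference run (> 0).
#' @return Percent reduction (negative if `a > b`).
#' @export
percent_reduction <- function(a, b) {
  if (b <= 0) stop("reference total must be positive", call. = FALSE)
  100 * (1 - a / b)
}

#' Fold change between two disruption totals
#'
#' @param b Reference total.
#' @param a Comparison total (> 0).
#' @return `b / a`.
#' @export
fold_change <- function(b, a) {
  if (a <= 0) stop("comparison total must be positive", call. = FALSE)
  b / a
}
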