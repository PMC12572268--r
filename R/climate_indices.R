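#' Monthly cumulative precipitation
#'
#' Sums daily precipitation over one calendar month. The series must cover
#' every day of the month: partial months would silently understate the total,
#' so missing days are an error.
#'
#' @param dates `Date` vector, all within one calendar month.
#' @param values Daily precipitation (mm/day), same length as `dates`.
#' @return Monthly total in mm.
#' @export
monthly_cumulative <- function(dates, values) {
  dates <- as.Date(dates)
  if (length(dates) != length(values)) {
    stop("dates and values must have equal length", call. = FALSE)
  }
  ym <- unique(format(dates, "%Y-%m"))
  if (length(ym) != 1L) {
    stop("series spans multiple months: ", paste(ym, collapse = ", "), call. = FALSE)
  }
  year <- as.integer(substr(ym, 1, 4))
  month <- as.integer(substr(ym, 6, 7))
  expected <- seq(
    as.Date(sprintf("%04d-%02d-01", year, month)),
    by = "1 day",
    length.out = days_in_month(year, month)
  )
  missing_days <- setdiff(format(expected), format(dates))
  if (length(missing_days) > 0L) {
    stop(
      "month ", ym, " not fully covered; missing days: ",
      paste(missing_days, collapse = ", "),
      call. = FALSE
    )
  }
  sum(values)
}

#' Maximum 5-day consecutive precipitation (Rx5day)
#'
#' The ETCCDI Rx5day index: the maximum, over all windows of 5 consecutive
#' days fully inside the month, of the window's precipitation total. Windows
#' never cross month boundaries.
#'
#' @param values Daily precipitation (mm/day) for the days of one month, in
#'   calendar order.
#' @return Maximum 5-day total in mm.
#' @export
rx5day <- function(values) {
  n <- length(values)
  if (n < 5L) stop("Rx5day needs at least 5 days, got ", n, call. = FALSE)
  cs <- cumsum(c(0, values))
  max(cs[6:(n + 1L)] - cs[1:(n - 4L)])
}

# Internal: monthly cumulative + rx5day for one daily series covering whole months.
monthly_base_indices <- function(dates, values) {
  ym <- format(dates, "%Y-%m")
  split_idx <- split(seq_along(dates), ym)
  out <- lapply(names(split_idx), function(key) {
    i <- split_idx[[key]]
    data.frame(
      year = as.integer(substr(key, 1, 4)),
      month = as.integer(substr(key, 6, 7)),
      cumulative = monthly_cumulative(dates[i], values[i]),
      rx5day = rx5day(values[i])
    )
  })
  out <- do.call(rbind, out)
  out[order(out$year, out$month), , drop = FALSE]
}

#' Build the monthly precipitation index table
#'
#' For each requested grid cell, computes the monthly cumulative total and
#' Rx5day, their lagged copies at the requested lags, squares, cubes, and the
#' cumulative-by-Rx5day product. Months without sufficient lag history carry
#' `NA` in the lag columns (never silent zeros); downstream model assembly
#' drops such rows.
#'
#' Only whole calendar months of the grid are indexed; leading/trailing
#' partial months are discarded.
#'
#' @param grid A [precip_grid].
#' @param cells Integer cell ids (see [grid_cells]); default all cells.
#' @param lags Integer lags in months for the lagged copies.
#' @return A data.frame of class `precip_index_table`, keyed by
#'   (`cell_id`, `year`, `month`), with columns `cumulative`, `rx5day`,
#'   `cumulative_lag<k>`, `rx5day_lag<k>`, `cumulative_sq`, `cumulative_cub`,
#'   `rx5day_sq`, `rx5day_cub`, `cumulative_rx5day`.
#' @export
build_index_table <- function(grid, cells = NULL, lags = c(1L, 2L, 3L, 4L, 9L)) {
  stopifnot(inherits(grid, "precip_grid"))
  all_cells <- grid_cells(grid)
  if (is.null(cells)) cells <- all_cells$cell_id
  bad <- setdiff(cells, all_cells$cell_id)
  if (length(bad) > 0L) {
    stop("requested cells outside grid: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lags <- sort(unique(as.integer(lags)))

  # keep only fully covered months
  ym_all <- format(grid$time, "%Y-%m")
  counts <- table(ym_all)
  full <- vapply(names(counts), function(key) {
    counts[[key]] == days_in_month(
      as.integer(substr(key, 1, 4)), as.integer(substr(key, 6, 7))
    )
  }, logical(1L))
  keep_days <- ym_all %in% names(counts)[full]
  if (!any(keep_days)) stop("grid covers no complete calendar month", call. = FALSE)

  per_cell <- lapply(cells, function(cid) {
    s <- cell_series(grid, cid)
    base <- monthly_base_indices(s$dates[keep_days], s$values[keep_days])
    # lags on the cell's own calendar series, crossing year boundaries
    midx <- ym_to_index(base$year, base$month)
    for (k in lags) {
      pos <- match(midx - k, midx)
      base[[paste0("cumulative_lag", k)]] <- base$cumulative[pos]
      base[[paste0("rx5day_lag", k)]] <- base$rx5day[pos]
    }
    base$cumulative_sq <- base$cumulative^2
    base$cumulative_cub <- base$cumulative^3
    base$rx5day_sq <- base$rx5day^2
    base$rx5day_cub <- base$rx5day^3
    base$cumulative_rx5day <- base$cumulative * base$rx5day
    cbind(cell_id = cid, base)
  })
  out <- do.call(rbind, per_cell)
  rownames(out) <- NULL
  structure(out, lags = lags, class = c("precip_index_table", "data.frame"))
}

#' Names of the precipitation index columns
#'
#' @param lags Integer lags used when the table was built.
#' @return Character vector of index column names, in table order.
#' @export
index_columns <- function(lags = c(1L, 2L, 3L, 4L, 9L)) {
  lags <- sort(unique(as.integer(lags)))
  c(
    "cumulative", "rx5day",
    as.vector(rbind(paste0("cumulative_lag", lags), paste0("rx5day_lag", lags))),
    "cumulative_sq", "cumulative_cub", "rx5day_sq", "rx5day_cub",
    "cumulative_rx5day"
  )
}

#' Percentile threshold of monthly totals
#'
#' Linear-interpolation percentile (between order statistics) of a pooled
#' vector of monthly precipitation totals, used to label extreme months, e.g.
#' the 90th percentile of all historical cell-months.
#'
#' @param monthly_totals Numeric vector of monthly totals (mm), pooled over the
#'   cells and months of the reference window.
#' @param q Percentile in `[0, 100]`.
#' @return Threshold in mm.
#' @export
percentile_threshold <- function(monthly_totals, q = 90) {
  if (length(monthly_totals) == 0L) stop("empty vector of monthly totals", call. = FALSE)
  if (anyNA(monthly_totals)) stop("monthly totals contain NA", call. = FALSE)
  if (q < 0 || q > 100) stop("percentile q must be in [0, 100]", call. = FALSE)
  unname(stats::quantile(monthly_totals, probs = q / 100, type = 7))
}
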