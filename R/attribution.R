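#' Predict service counts from a fitted model
#'
#' Evaluates the linear predictor on the design rows and back-transforms to
#' the count scale as `exp(Xb) - epsilon`, floored at 0. The back-transform is
#' the naive inverse of the log link (no smearing correction); a Duan
#' smearing factor can be supplied to rescale `exp(Xb)` if desired.
#'
#' @param model A `fitted_model`.
#' @param design An `anc_design` (or any data.frame with the model's term
#'   columns).
#' @param epsilon Offset used in the response transform; defaults to the
#'   design's epsilon attribute (or 1).
#' @param smearing Multiplicative retransformation factor applied to
#'   `exp(Xb)` (default 1 = none).
#' @return Numeric vector of predicted counts.
#' @export
predict_counts <- function(model, design, epsilon = NULL, smearing = 1) {
  epsilon <- epsilon %||% (attr(design, "epsilon") %||% 1)
  missing_cols <- setdiff(model$terms, names(design))
  if (length(missing_cols) > 0L) {
    stop(
      "design lacks model term columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  beta <- model$coefficients
  lp <- rep(unname(beta[["(Intercept)"]]), nrow(design))
  for (tm in model$terms) lp <- lp + beta[[tm]] * design[[tm]]
  pmax(smearing * exp(lp) - epsilon, 0)
}

#' Counterfactual-difference disruption series
#'
#' The core attribution statistic: per facility-month, the difference between
#' the precipitation-free prediction and the precipitation-aware prediction,
#' `delta = y0_hat - y1_hat` on the count scale. Positive deltas are service
#' deficits attributed to precipitation. A month is flagged extreme when its
#' cumulative precipitation meets or exceeds `threshold_mm` (a percentile of
#' the historical monthly totals; see [percentile_threshold]).
#'
#' @param m0 `fitted_model` without precipitation terms.
#' @param m1 `fitted_model` with precipitation terms.
#' @param design An `anc_design` carrying the columns of both models and a
#'   `cumulative` column.
#' @param threshold_mm Extreme-month threshold in mm/month.
#' @return A `disruption_series` data.frame keyed by
#'   (`facility_id`, `year`, `month`) with `y0_hat`, `y1_hat`, `delta`,
#'   `is_deficit`, `is_extreme_month`.
#' @export
disruption_series <- function(m0, m1, design, threshold_mm) {
  if (is.null(design$cumulative)) {
    stop("design lacks the cumulative precipitation column", call. = FALSE)
  }
  y0 <- predict_counts(m0, design)
  y1 <- predict_counts(m1, design)
  out <- data.frame(
    facility_id = design$facility_id,
    year = design$year,
    month = design$month,
    y0_hat = y0,
    y1_hat = y1,
    delta = y0 - y1,
    is_deficit = (y0 - y1) > 0,
    is_extreme_month = design$cumulative >= threshold_mm
  )
  structure(out, threshold_mm = threshold_mm,
    class = c("disruption_series", "data.frame"))
}

#' Restrict a disruption series to deficit months
#'
#' Only months where the precipitation model predicts fewer services than the
#' precipitation-free model count as disruptions; surplus months are removed
#' (or their deltas zeroed, keeping the panel shape).
#'
#' @param series A `disruption_series`.
#' @param action `"drop"` removes non-deficit rows; `"zero"` keeps them with
#'   `delta = 0`.
#' @return The filtered `disruption_series`.
#' @export
deficit_filter <- function(series, action = c("drop", "zero")) {
  action <- match.arg(action)
  if (action == "drop") {
    out <- series[series$is_deficit, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- series
    out$delta[!out$is_deficit] <- 0
  }
  out
}

#' Aggregate attributed disruption
#'
#' Sums deficit services per group and expresses them as a percentage of the
#' group's total services, together with the extreme-month share of the
#' deficit. Non-deficit rows never contribute (the deficit filter is applied
#' internally).
#'
#' @param series A `disruption_series`.
#' @param total_services Either a single national total, or a data.frame with
#'   the grouping columns and a `total_services` column.
#' @param by Character vector of grouping columns present in `series`
#'   (`NULL` = one national row).
#' @return Data.frame with `deficit_services`, `total_services`,
#'   `percent_disrupted`, `extreme_deficit_services`, `extreme_share_percent`
#'   and `percent_defined` (FALSE where a group's total is 0).
#' @export
aggregate_disruption <- function(series, total_services, by = NULL) {
  pos <- deficit_filter(series, "zero")
  grp <- if (is.null(by)) {
    rep("all", nrow(pos))
  } else {
    do.call(paste, c(pos[by], sep = "\r"))
  }
  agg_delta <- tapply(pos$delta, grp, sum)
  agg_extreme <- tapply(pos$delta * pos$is_extreme_month, grp, sum)
  keys <- names(agg_delta)
  out <- if (is.null(by)) {
    data.frame(row.names = NULL, deficit_services = as.numeric(agg_delta))
  } else {
    key_df <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    key_df <- as.data.frame(key_df, stringsAsFactors = FALSE)
    names(key_df) <- by
    cbind(key_df, deficit_services = as.numeric(agg_delta))
  }
  out$extreme_deficit_services <- as.numeric(agg_extreme)

  if (is.data.frame(total_services)) {
    if (is.null(by)) stop("grouped totals supplied but no grouping columns", call. = FALSE)
    tot_key <- do.call(paste, c(total_services[by], sep = "\r"))
    out$total_services <- total_services$total_services[match(keys, tot_key)]
  } else {
    out$total_services <- total_services
  }
  if (anyNA(out$total_services)) {
    stop("total services missing for some groups", call. = FALSE)
  }
  out$percent_defined <- out$total_services > 0
  out$percent_disrupted <- ifelse(
    out$percent_defined, 100 * out$deficit_services / out$total_services, NA_real_
  )
  out$extreme_share_percent <- ifelse(
    out$deficit_services > 0,
    100 * out$extreme_deficit_services / out$deficit_services,
    0
  )
  cols <- c(
    by, "deficit_services", "total_services", "percent_disrupted",
    "extreme_deficit_services", "extreme_share_percent", "percent_defined"
  )
  out[, cols, drop = FALSE]
}

#' Convert disrupted services to affected pregnancies
#'
#' Two conversions are supported: `per_pregnancy` divides disrupted visits by
#' the visits-per-pregnancy ratio (default 4.4 delivered appointments per
#' live birth); `per_visit` counts each disrupted visit as one affected
#' pregnancy.
#'
#' @param deficit_services Nonnegative count of disrupted services.
#' @param visits_per_pregnancy Positive ratio of ANC visits per pregnancy.
#' @param mode `"per_pregnancy"` or `"per_visit"`.
#' @return Affected pregnancies (numeric).
#' @export
affected_pregnancies <- function(deficit_services,
                                 visits_per_pregnancy = 4.4,
                                 mode = c("per_pregnancy", "per_visit")) {
  mode <- match.arg(mode)
  if (any(deficit_services < 0)) stop("deficit services must be nonnegative", call. = FALSE)
  if (visits_per_pregnancy <= 0) stop("visits_per_pregnancy must be > 0", call. = FALSE)
  if (mode == "per_pregnancy") deficit_services / visits_per_pregnancy else deficit_services
}
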