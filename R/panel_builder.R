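#' Closure registry
#'
#' Records facility closures confirmed by secondary sources, as inclusive
#' year-month ranges. Missing reports inside a confirmed closure are taken to
#' mean "no services delivered" and are repaired to zero counts by
#' [apply_closure_zeros]; missing reports outside any closure are treated as
#' random non-reporting.
#'
#' @param x Optional data.frame with columns `facility_id`, `start`, `end`
#'   (`"YYYY-MM"`), `evidence`.
#' @return A validated `closure_registry` data.frame (possibly empty).
#' @export
closure_registry <- function(x = NULL) {
  if (is.null(x)) {
    x <- data.frame(
      facility_id = character(), start = character(),
      end = character(), evidence = character()
    )
  }
  needed <- c("facility_id", "start", "end")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("closure registry lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(x$evidence)) x$evidence <- NA_character_
  for (i in seq_len(nrow(x))) {
    s <- parse_ym(x$start[i]); e <- parse_ym(x$end[i])
    if (ym_to_index(s[1L], s[2L]) > ym_to_index(e[1L], e[2L])) {
      stop("closure range ", x$start[i], "..", x$end[i], " is inverted", call. = FALSE)
    }
  }
  structure(
    x[, c("facility_id", "start", "end", "evidence")],
    class = c("closure_registry", "data.frame")
  )
}

# Logical mask over panel rows: TRUE where the row falls inside a closure.
closure_mask <- function(panel, closures) {
  mask <- rep(FALSE, nrow(panel))
  if (is.null(closures) || nrow(closures) == 0L) return(mask)
  row_idx <- ym_to_index(panel$year, panel$month)
  for (i in seq_len(nrow(closures))) {
    s <- parse_ym(closures$start[i]); e <- parse_ym(closures$end[i])
    mask <- mask | (
      panel$facility_id == closures$facility_id[i] &
        row_idx >= ym_to_index(s[1L], s[2L]) &
        row_idx <= ym_to_index(e[1L], e[2L])
    )
  }
  mask
}

#' Drop facilities with mostly-missing reporting
#'
#' Removes entirely any facility whose fraction of missing facility-month
#' reports strictly exceeds `threshold` (default: more than 90% missing).
#'
#' @param panel An `anc_panel`.
#' @param threshold Missing fraction above which a facility is dropped;
#'   in (0, 1].
#' @return The panel restricted to surviving facilities.
#' @export
exclude_sparse_facilities <- function(panel, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  frac <- tapply(panel$missing_flag, panel$facility_id, mean)
  keep <- names(frac)[frac <= threshold]
  out <- panel[panel$facility_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repair confirmed-closure months to zero counts
#'
#' Missing entries that fall inside a confirmed closure range become observed
#' zero counts (no services were delivered). Observed entries are never
#' modified, and missing entries outside any closure remain missing.
#' Closures for facilities absent from the panel are skipped with a warning.
#'
#' @param panel An `anc_panel`.
#' @param closures A [closure_registry].
#' @return The repaired panel.
#' @export
apply_closure_zeros <- function(panel, closures) {
  closures <- closure_registry(closures)
  unknown <- setdiff(unique(closures$facility_id), unique(panel$facility_id))
  if (length(unknown) > 0L) {
    warning(
      "closures for facilities not in the panel skipped: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
    closures <- closures[!closures$facility_id %in% unknown, , drop = FALSE]
  }
  fix <- closure_mask(panel, closures) & panel$missing_flag
  panel$anc_count[fix] <- 0L
  panel$missing_flag[fix] <- FALSE
  panel
}

#' Mean-impute missing altitudes
#'
#' @param facilities Facility table with an `altitude` column.
#' @return The table with missing altitudes replaced by the mean of the
#'   observed ones.
#' @export
impute_altitude <- function(facilities) {
  alt <- facilities$altitude
  if (all(is.na(alt))) stop("all altitudes missing; cannot impute", call. = FALSE)
  facilities$altitude[is.na(alt)] <- mean(alt, na.rm = TRUE)
  facilities
}

# Cramér's V between two categorical vectors (bias-uncorrected).
cramers_v <- function(a, b) {
  tab <- table(a, b)
  if (min(dim(tab)) < 2L) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1L)))
}

#' Screen covariate pairs for collinearity
#'
#' For each listed pair, measures the association (Cramér's V for a pair of
#' categorical covariates, absolute Pearson correlation for numeric ones) and
#' drops the second member of any pair whose association exceeds the
#' threshold — e.g. facility type is dropped when it tracks ownership, and
#' district when it is nested in zone.
#'
#' @param facilities Facility table.
#' @param pairs List of `c(keep, candidate_drop)` column-name pairs.
#' @param threshold Association above which the second member is dropped.
#' @return List with `kept`, `dropped`, and `associations` (named per pair).
#' @export
collinearity_screen <- function(facilities,
                                pairs = list(c("owner", "type"), c("zone", "district")),
                                threshold = 0.7) {
  assoc <- vapply(pairs, function(p) {
    a <- facilities[[p[1L]]]; b <- facilities[[p[2L]]]
    if (is.numeric(a) && is.numeric(b)) {
      abs(stats::cor(a, b, use = "complete.obs"))
    } else {
      cramers_v(a, b)
    }
  }, numeric(1L))
  names(assoc) <- vapply(pairs, paste, character(1L), collapse = "~")
  candidates <- vapply(pairs, `[`, character(1L), 2L)
  dropped <- candidates[assoc > threshold]
  all_covs <- unique(unlist(pairs))
  list(
    kept = setdiff(all_covs, dropped),
    dropped = dropped,
    associations = assoc
  )
}

# Full covariate frame: one row per facility-month with one-hot covariate
# terms and the facility cell's precipitation index columns. Shared by the
# count generator and the design assembler so the two construct identical
# terms.
covariate_frame <- function(facilities, indices, months) {
  n_f <- nrow(facilities)
  n_m <- nrow(months)
  frame <- data.frame(
    facility_id = rep(facilities$facility_id, each = n_m),
    cell_id = rep(facilities$cell_id, each = n_m),
    year = rep(months$year, times = n_f),
    month = rep(months$month, times = n_f)
  )
  fac_cols <- facilities[match(frame$facility_id, facilities$facility_id), ]
  frame$urban <- as.integer(fac_cols$setting == "urban")
  frame$zone_central_west <- as.integer(fac_cols$zone == "Central West")
  frame$zone_northern <- as.integer(fac_cols$zone == "Northern")
  frame$zone_south_east <- as.integer(fac_cols$zone == "South East")
  frame$zone_south_west <- as.integer(fac_cols$zone == "South West")
  frame$owner_government <- as.integer(fac_cols$owner == "Government")
  frame$owner_ngo <- as.integer(fac_cols$owner == "NGO")
  frame$owner_private <- as.integer(fac_cols$owner == "Private")
  frame$altitude <- fac_cols$altitude
  frame$min_distance <- fac_cols$min_distance

  idx_cols <- setdiff(names(indices), c("cell_id", "year", "month"))
  pos <- match(
    paste(frame$cell_id, frame$year, frame$month),
    paste(indices$cell_id, indices$year, indices$month)
  )
  for (cn in idx_cols) frame[[cn]] <- indices[[cn]][pos]
  frame
}

#' Default non-climate model terms
#'
#' Year, month, the one-hot setting/zone/owner terms (references rural,
#' Central East, CHAM), altitude and minimum distance to the closest
#' facility — the fixed covariate set of the precipitation-free model.
#'
#' @return Character vector of term names.
#' @export
default_base_terms <- function() {
  c(
    "year", "month", "urban",
    "zone_central_west", "zone_northern", "zone_south_east", "zone_south_west",
    "owner_government", "owner_private",
    "altitude", "min_distance"
  )
}

#' Assemble the regression design matrix
#'
#' Joins the service-count panel, facility covariates and precipitation
#' indices into the modelling frame. The response is `log(count + epsilon)`.
#' Categorical covariates are one-hot encoded against the reference levels
#' rural / Central East / CHAM; by default NGO ownership is absorbed into the
#' reference with CHAM (set `ngo_separate = TRUE` for its own column). Rows
#' with a missing report, or with undefined lagged indices, are excluded
#' rather than imputed.
#'
#' @param panel An `anc_panel` (cleaned).
#' @param facilities Facility table with `cell_id` (and imputed altitude).
#' @param indices A `precip_index_table`.
#' @param precip_terms Character vector of precipitation index columns to
#'   carry as model terms (may be empty for the precipitation-free model).
#' @param base_terms Non-climate model terms; defaults to year, month, the
#'   one-hot setting/zone/owner terms, altitude and minimum distance.
#' @param epsilon Offset inside the log (default 1, so zero counts map to
#'   response 0).
#' @param ngo_separate Keep a separate NGO one-hot column.
#' @return An `anc_design` data.frame with key columns (`facility_id`,
#'   `cell_id`, `year`, `month`, `anc_count`, `response`, `cumulative`) and
#'   the term columns; attributes `terms` and `epsilon`.
#' @export
assemble_design <- function(panel, facilities, indices,
                            precip_terms = character(),
                            base_terms = default_base_terms(),
                            epsilon = 1,
                            ngo_separate = FALSE) {
  if (is.null(facilities$cell_id)) {
    stop("facilities need a cell_id column; run assign_grid_cells() first", call. = FALSE)
  }
  if (ngo_separate && !"owner_ngo" %in% base_terms) {
    base_terms <- c(base_terms, "owner_ngo")
  }
  terms <- c(base_terms, precip_terms)

  obs <- panel[!panel$missing_flag & !is.na(panel$anc_count), , drop = FALSE]
  months <- unique(obs[, c("year", "month")])
  months <- months[order(months$year, months$month), ]
  frame <- covariate_frame(facilities, indices, months)

  key_frame <- paste(frame$facility_id, frame$year, frame$month)
  key_obs <- paste(obs$facility_id, obs$year, obs$month)
  pos <- match(key_obs, key_frame)
  if (anyNA(pos)) {
    stop(
      "panel rows without covariate coverage (facility missing from table?): ",
      paste(utils::head(key_obs[is.na(pos)], 5L), collapse = "; "),
      call. = FALSE
    )
  }
  design <- frame[pos, , drop = FALSE]
  design$anc_count <- obs$anc_count

  unknown <- setdiff(terms, names(design))
  if (length(unknown) > 0L) {
    stop(
      "requested terms have no design column: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  design$response <- log(design$anc_count + epsilon)
  # drop undefined-lag (or otherwise incomplete) rows instead of imputing
  complete <- stats::complete.cases(design[, c("response", terms), drop = FALSE])
  design <- design[complete, , drop = FALSE]
  rownames(design) <- NULL

  keep_cols <- unique(c(
    "facility_id", "cell_id", "year", "month", "anc_count", "response",
    "cumulative", terms
  ))
  keep_cols <- intersect(keep_cols, names(design))
  design <- design[, keep_cols, drop = FALSE]
  structure(
    design,
    terms = terms,
    epsilon = epsilon,
    class = c("anc_design", "data.frame")
  )
}

#' @export
print.anc_design <- function(x, ...) {
  cat(
    "anc_design:", nrow(x), "facility-months,",
    length(attr(x, "terms")), "model terms, epsilon =", attr(x, "epsilon"), "\n"
  )
  cat("  terms:", paste(attr(x, "terms"), collapse = ", "), "\n")
  invisible(x)
}
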