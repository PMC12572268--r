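# Readers and writers for the pipeline's interchange formats. Grids travel as
# long-format CSV (date, lat, lon, precip_mm); tables as headered CSV; fitted
# models as JSON. Every writer's output is re-readable by its paired reader.

#' Write a precipitation grid to CSV
#'
#' Long format, one row per (date, lat, lon), columns
#' `date, lat, lon, precip_mm`, sorted by date then lat then lon.
#'
#' @param grid A [precip_grid].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_precip_grid <- function(grid, path) {
  stopifnot(inherits(grid, "precip_grid"))
  cells <- grid_cells(grid)
  n_t <- length(grid$time)
  df <- data.frame(
    date = rep(format(grid$time), times = nrow(cells)),
    lat = rep(cells$lat, each = n_t),
    lon = rep(cells$lon, each = n_t),
    precip_mm = as.vector(vapply(
      seq_len(nrow(cells)),
      function(i) grid$precip[, cells$lat_idx[i], cells$lon_idx[i]],
      numeric(n_t)
    ))
  )
  df <- df[order(df$date, df$lat, df$lon), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a precipitation grid from CSV
#'
#' Validates the long-format grid file: required columns, nonnegative values,
#' full lat-by-lon coverage on every date, and gap-free consecutive dates
#' (gaps are reported).
#'
#' @param path CSV file as written by [write_precip_grid].
#' @return A [precip_grid].
#' @export
read_precip_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "lat", "lon", "precip_mm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "grid file lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(df$precip_mm < 0)) {
    stop("grid file contains negative precipitation", call. = FALSE)
  }
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  time <- sort(unique(as.Date(df$date)))
  if (nrow(df) != length(lat) * length(lon) * length(time)) {
    stop("grid file is not a complete lat x lon x date cube", call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(length(time), length(lat), length(lon)))
  ti <- match(as.Date(df$date), time)
  li <- match(df$lat, lat)
  gi <- match(df$lon, lon)
  arr[cbind(ti, li, gi)] <- df$precip_mm
  precip_grid(lat, lon, time, arr)
}

#' Read/write facility tables, service-count panels and closure registries
#'
#' Plain headered CSV. Panels store missing reports as empty `anc_count`
#' cells; `missing_flag` is reconstructed on read.
#'
#' @param x The object to write.
#' @param path CSV file path.
#' @return The object read, or `path` invisibly for writers.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_facilities <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_facilities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("facility_id", "lon", "lat", "zone", "setting", "owner")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "facility file lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$facility_id)) {
    stop("facility_id values are not unique", call. = FALSE)
  }
  df
}

#' @rdname table_io
#' @export
write_anc_panel <- function(x, path) {
  out <- x[, c("facility_id", "year", "month", "anc_count")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname table_io
#' @export
read_anc_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("facility_id", "year", "month", "anc_count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "panel file lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(df$facility_id, df$year, df$month)
  if (anyDuplicated(key)) {
    stop("panel has duplicate facility-month rows", call. = FALSE)
  }
  df$anc_count <- suppressWarnings(as.integer(df$anc_count))
  if (any(df$anc_count < 0, na.rm = TRUE)) {
    stop("panel has negative service counts", call. = FALSE)
  }
  df$missing_flag <- is.na(df$anc_count)
  structure(df, class = c("anc_panel", "data.frame"))
}

#' @rdname table_io
#' @export
write_closures <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_closures <- function(path) {
  closure_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname table_io
#' @export
write_index_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "year", "month", "cumulative", "rx5day")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "index file lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  structure(df, class = c("precip_index_table", "data.frame"))
}

#' Serialise a fitted model to JSON (and back)
#'
#' @param model A `fitted_model`.
#' @param path JSON file path.
#' @return The model read back, or `path` invisibly.
#' @export
write_fitted_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  x <- unclass(model)
  # named numeric vectors serialise as bare arrays; keep names via lists
  for (f in c("coefficients", "se", "p_values")) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fitted_model
#' @export
read_fitted_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  x$se <- unlist(x$se)
  x$p_values <- unlist(x$p_values)
  structure(x, class = "fitted_model")
}

#' Read a scenario-ensemble manifest
#'
#' The manifest is a CSV with columns `scenario`, `member`, `path`, one row
#' per ensemble member grid file (paths relative to the manifest's
#' directory). Returns one [scenario_ensemble] per scenario.
#'
#' @param path Manifest CSV path.
#' @return Named list of `scenario_ensemble` objects.
#' @export
read_scenario_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("scenario", "member", "path")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "manifest lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  base <- dirname(path)
  out <- lapply(split(df, df$scenario), function(sub) {
    members <- lapply(sub$path, function(p) {
      read_precip_grid(if (file.exists(p)) p else file.path(base, p))
    })
    names(members) <- sub$member
    scenario_ensemble(sub$scenario[1L], members)
  })
  out
}
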