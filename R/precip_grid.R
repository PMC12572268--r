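#' Daily precipitation grid
#'
#' Container for a lat/lon/time cube of daily precipitation (mm/day), the raw
#' climate input of the pipeline. Values are stored as a 3-d array indexed
#' `[time, lat, lon]`.
#'
#' @param lat Numeric vector of grid-cell centre latitudes (degrees), strictly
#'   increasing.
#' @param lon Numeric vector of grid-cell centre longitudes (degrees), strictly
#'   increasing.
#' @param time `Date` vector of consecutive calendar days (no gaps).
#' @param precip Numeric array `length(time) x length(lat) x length(lon)` of
#'   nonnegative precipitation in mm/day.
#'
#' @return An object of class `precip_grid`.
#' @export
precip_grid <- function(lat, lon, time, precip) {
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  time <- as.Date(time)
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0)) {
    stop("lat and lon must be strictly increasing", call. = FALSE)
  }
  if (length(time) > 1L) {
    gaps <- which(diff(time) != 1L)
    if (length(gaps) > 0L) {
      stop(
        "time must be consecutive daily dates; gaps after: ",
        paste(format(time[utils::head(gaps, 5L)]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  precip <- array(as.numeric(precip), dim = c(length(time), length(lat), length(lon)))
  if (anyNA(precip)) stop("precipitation values must not be missing", call. = FALSE)
  if (any(precip < 0)) {
    stop("precipitation values must be nonnegative; min = ", min(precip), call. = FALSE)
  }
  structure(
    list(lat = lat, lon = lon, time = time, precip = precip),
    class = "precip_grid"
  )
}

#' @export
print.precip_grid <- function(x, ...) {
  cat(
    "precip_grid:", length(x$time), "days x", length(x$lat), "lat x",
    length(x$lon), "lon cells\n"
  )
  cat(
    "  time:", format(min(x$time)), "to", format(max(x$time)), "\n",
    " lat:", min(x$lat), "to", max(x$lat), " lon:", min(x$lon), "to", max(x$lon), "\n"
  )
  cat("  mean daily precip:", round(mean(x$precip), 3), "mm\n")
  invisible(x)
}

#' Enumerate the cells of a precipitation grid
#'
#' Cells are numbered row-major over latitude then longitude
#' (`cell_id = (lat_index - 1) * n_lon + lon_index`); this ordering is the
#' tie-break reference for nearest-cell assignment.
#'
#' @param grid A [precip_grid].
#' @return A data.frame with columns `cell_id`, `lat_idx`, `lon_idx`, `lat`,
#'   `lon`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "precip_grid"))
  n_lat <- length(grid$lat)
  n_lon <- length(grid$lon)
  lat_idx <- rep(seq_len(n_lat), each = n_lon)
  lon_idx <- rep(seq_len(n_lon), times = n_lat)
  data.frame(
    cell_id = seq_len(n_lat * n_lon),
    lat_idx = lat_idx,
    lon_idx = lon_idx,
    lat = grid$lat[lat_idx],
    lon = grid$lon[lon_idx]
  )
}

# Daily series (dates, values) for one cell_id.
cell_series <- function(grid, cell_id) {
  cells <- grid_cells(grid)
  if (!cell_id %in% cells$cell_id) {
    stop("cell_id ", cell_id, " outside grid (", nrow(cells), " cells)", call. = FALSE)
  }
  row <- cells[cells$cell_id == cell_id, ]
  list(dates = grid$time, values = grid$precip[, row$lat_idx, row$lon_idx])
}
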