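# Nearest-cell assignment and inter-facility distance covariates.
#
# A small 2-d k-d tree handles nearest-neighbour queries over grid-cell
# centres in raw degree space. Ties on distance are broken towards the lowest
# cell id, so results are reproducible regardless of tree layout.

# Build a k-d tree over points (x, y) with payload ids. Returns a nested list;
# depth alternates the split axis. Median split on the current axis.
kd_build <- function(x, y, ids, depth = 0L) {
  n <- length(ids)
  if (n == 0L) return(NULL)
  axis <- depth %% 2L
  key <- if (axis == 0L) x else y
  ord <- order(key, ids)
  x <- x[ord]; y <- y[ord]; ids <- ids[ord]
  m <- (n + 1L) %/% 2L
  list(
    x = x[m], y = y[m], id = ids[m], axis = axis,
    left = kd_build(x[seq_len(m - 1L)], y[seq_len(m - 1L)], ids[seq_len(m - 1L)], depth + 1L),
    right = if (m < n) kd_build(x[(m + 1L):n], y[(m + 1L):n], ids[(m + 1L):n], depth + 1L)
  )
}

# Nearest neighbour of (qx, qy). best = list(d2, id); a candidate wins on
# strictly smaller squared distance, or equal distance with a smaller id.
kd_nearest <- function(node, qx, qy, best = list(d2 = Inf, id = NA_integer_)) {
  if (is.null(node)) return(best)
  d2 <- (node$x - qx)^2 + (node$y - qy)^2
  if (d2 < best$d2 || (d2 == best$d2 && node$id < best$id)) {
    best <- list(d2 = d2, id = node$id)
  }
  diff <- if (node$axis == 0L) qx - node$x else qy - node$y
  near <- if (diff < 0) node$left else node$right
  far <- if (diff < 0) node$right else node$left
  best <- kd_nearest(near, qx, qy, best)
  if (diff^2 <= best$d2) best <- kd_nearest(far, qx, qy, best)
  best
}

#' Nearest grid cell for facility coordinates
#'
#' Assigns each point to the grid cell whose centre is closest in degree
#' space, via a k-d tree over the cell centres. Exact distance ties go to the
#' lowest cell id. Points outside the grid's bounding box are still assigned
#' to the nearest cell, with a warning.
#'
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @param grid A [precip_grid], or a data.frame of cells as from [grid_cells].
#' @return Integer vector of cell ids.
#' @export
nearest_grid_cell <- function(lon, lat, grid) {
  cells <- if (inherits(grid, "precip_grid")) grid_cells(grid) else grid
  if (nrow(cells) == 0L) stop("grid has no cells", call. = FALSE)
  if (length(lon) != length(lat)) stop("lon and lat lengths differ", call. = FALSE)
  tree <- kd_build(cells$lon, cells$lat, as.integer(cells$cell_id))
  outside <- lon < min(cells$lon) | lon > max(cells$lon) |
    lat < min(cells$lat) | lat > max(cells$lat)
  if (any(outside)) {
    warning(
      sum(outside), " point(s) outside the grid hull; assigned to nearest cell",
      call. = FALSE
    )
  }
  vapply(
    seq_along(lon),
    function(i) kd_nearest(tree, lon[i], lat[i])$id,
    integer(1L)
  )
}

#' Attach grid-cell assignment to a facility table
#'
#' @param facilities Facility data.frame with `lon` and `lat` columns.
#' @param grid A [precip_grid].
#' @return `facilities` with a `cell_id` column appended (replaced if present).
#' @export
assign_grid_cells <- function(facilities, grid) {
  facilities$cell_id <- nearest_grid_cell(facilities$lon, facilities$lat, grid)
  facilities
}

# Equirectangular degree -> metre projection about the mean latitude.
project_to_metres <- function(lon, lat, metres_per_degree = 111320) {
  lat0 <- mean(lat) * pi / 180
  list(x = lon * metres_per_degree * cos(lat0), y = lat * metres_per_degree)
}

#' Distance to the closest other facility
#'
#' For each facility, the minimum Euclidean distance (metres) to any other
#' facility, after an equirectangular local projection of degrees to metres
#' (longitude scaled by the cosine of the mean latitude). The projection
#' convention is configurable via `metres_per_degree`.
#'
#' @param facilities Facility data.frame with `lon` and `lat` columns; at
#'   least 2 rows.
#' @param metres_per_degree Metres per degree of latitude.
#' @return Numeric vector of per-facility minimum distances (m).
#' @export
min_distance_to_closest <- function(facilities, metres_per_degree = 111320) {
  n <- nrow(facilities)
  if (n < 2L) stop("need at least 2 facilities to compute distances", call. = FALSE)
  p <- project_to_metres(facilities$lon, facilities$lat, metres_per_degree)
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}
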