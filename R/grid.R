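#' Define a longitude/latitude grid
#'
#' A grid specification fixes the cell size and the bounding rectangle of the
#' analysis grid. Cells are half-open squares \code{[x, x + size) x [y, y + size)}
#' identified by the coordinates of their south-west corner; the default size
#' of 1 degree matches the common resolution of basin-scale occurrence
#' gridding.
#'
#' @param cell_size cell edge in degrees; must divide 360 evenly.
#' @param lon_range numeric length 2, west and east bounds in [-180, 180].
#' @param lat_range numeric length 2, south and north bounds in [-90, 90].
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(cell_size = 1, lon_range = c(-180, 180),
                      lat_range = c(-90, 90)) {
  stopifnot(length(cell_size) == 1L, cell_size > 0)
  if (abs(360 / cell_size - round(360 / cell_size)) > 1e-9)
    stop("cell_size must divide 360 evenly")
  stopifnot(length(lon_range) == 2L, length(lat_range) == 2L,
            lon_range[1] < lon_range[2], lat_range[1] < lat_range[2])
  structure(list(cell_size = cell_size,
                 lon_range = as.numeric(lon_range),
                 lat_range = as.numeric(lat_range)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %g deg cells, lon [%g, %g], lat [%g, %g]\n",
              x$cell_size, x$lon_range[1], x$lon_range[2],
              x$lat_range[1], x$lat_range[2]))
  invisible(x)
}

#' Wrap longitudes into [-180, 180)
#'
#' All longitude arithmetic in the package goes through this helper so the
#' dateline convention is applied in exactly one place.
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return longitudes wrapped into [-180, 180).
#' @export
wrap_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  # %% can return 360 for inputs like -1e-14 due to floating point
  out[out >= 180] <- out[out >= 180] - 360
  out
}

#' Cell id from coordinates
#'
#' @param lon,lat coordinates in degrees; longitudes are wrapped first.
#' @param spec a \code{grid_spec}.
#' @return character cell ids of the form \code{"<lon>:<lat>"} naming the
#'   south-west corner.
#' @export
cell_id_from_coords <- function(lon, lat, spec = grid_spec()) {
  lon <- wrap_lon(lon)
  sz <- spec$cell_size
  x <- floor(lon / sz) * sz
  y <- floor(lat / sz) * sz
  # latitude 90 (north pole) belongs to the topmost cell
  y[lat >= 90] <- 90 - sz
  make_cell_id(x, y)
}

make_cell_id <- function(x, y) sprintf("%g:%g", x, y)

#' Parse cell ids back into south-west corner coordinates
#'
#' @param cell_id character vector of cell ids.
#' @return data.frame with columns \code{cell_id}, \code{lon}, \code{lat}
#'   (south-west corners).
#' @export
cell_sw_corner <- function(cell_id) {
  parts <- strsplit(as.character(cell_id), ":", fixed = TRUE)
  data.frame(cell_id = as.character(cell_id),
             lon = vapply(parts, function(p) as.numeric(p[1]), 0),
             lat = vapply(parts, function(p) as.numeric(p[2]), 0),
             stringsAsFactors = FALSE)
}

#' Cell centers
#'
#' @inheritParams cell_sw_corner
#' @param spec a \code{grid_spec}; supplies the cell size.
#' @return data.frame with columns \code{cell_id}, \code{lon}, \code{lat}
#'   (cell centers).
#' @export
cell_center <- function(cell_id, spec = grid_spec()) {
  sw <- cell_sw_corner(cell_id)
  sw$lon <- wrap_lon(sw$lon + spec$cell_size / 2)
  sw$lat <- sw$lat + spec$cell_size / 2
  sw
}

#' Enumerate all cells of a grid
#'
#' @param spec a \code{grid_spec}.
#' @return data.frame of cell_id and south-west corners, ordered
#'   lat-major then lon.
#' @export
grid_cells <- function(spec = grid_spec()) {
  sz <- spec$cell_size
  xs <- seq(spec$lon_range[1], spec$lon_range[2] - sz, by = sz)
  ys <- seq(spec$lat_range[1], spec$lat_range[2] - sz, by = sz)
  g <- expand.grid(lon = xs, lat = ys, KEEP.OUT.ATTRS = FALSE)
  data.frame(cell_id = make_cell_id(g$lon, g$lat),
             lon = g$lon, lat = g$lat, stringsAsFactors = FALSE)
}

#' Spherical area of a grid cell
#'
#' Area of the spherical quadrangle between two parallels and two meridians:
#' \eqn{R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)} with \eqn{\Delta\lambda}
#' the longitudinal width in radians.
#'
#' @param lat_south southern latitude of the cell (degrees).
#' @param cell_size cell edge in degrees.
#' @param radius sphere radius in km (default mean Earth radius 6371).
#' @return area in square kilometres.
#' @export
cell_area <- function(lat_south, cell_size = 1, radius = 6371) {
  phi1 <- lat_south * pi / 180
  phi2 <- pmin(lat_south + cell_size, 90) * pi / 180
  radius^2 * (cell_size * pi / 180) * (sin(phi2) - sin(phi1))
}

#' Great-circle distance between points (haversine)
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectors recycle.
#' @param radius sphere radius in km.
#' @return distances in km.
#' @export
gc_dist <- function(lon1, lat1, lon2, lat2, radius = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (wrap_lon(lon2 - lon1)) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * radius * asin(sqrt(a))
}
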