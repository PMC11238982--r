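#' Read polygons from a GeoJSON file
#'
#' Minimal reader for region masks: supports FeatureCollection, Feature and
#' bare geometry objects holding Polygon or MultiPolygon geometries. Only
#' outer rings and holes are kept (holes are rings after the first within a
#' polygon). Coordinates are treated as plain lon/lat degrees.
#'
#' @param path GeoJSON file.
#' @return named list of regions; each region is a list of rings, each ring a
#'   two-column matrix (lon, lat) with attribute \code{hole}.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(gj$type,
                  FeatureCollection = gj$features,
                  Feature = list(gj),
                  list(list(geometry = gj, properties = list())))
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- if (!is.null(f$geometry)) f$geometry else f
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("region_", i)
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type))
    rings <- list()
    for (poly in polys) {
      for (r in seq_along(poly)) {
        m <- do.call(rbind, lapply(poly[[r]], function(pt)
          c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
        attr(m, "hole") <- r > 1
        rings[[length(rings) + 1L]] <- m
      }
    }
    out[[nm]] <- rings
  }
  out
}

# even-odd ray casting for one ring; vertices (n x 2), points vectorized
.in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Test points against one polygon (list of rings)
#'
#' @param lon,lat point coordinates (degrees); NA gives FALSE.
#' @param rings a region entry from \code{\link{read_geojson_polygons}} —
#'   list of ring matrices, holes flagged by their \code{hole} attribute.
#' @return logical vector: inside an outer ring and not in a hole.
#' @export
point_in_polygon <- function(lon, lat, rings) {
  ok <- !is.na(lon) & !is.na(lat)
  res <- rep(FALSE, length(lon))
  if (!any(ok)) return(res)
  inside <- rep(FALSE, sum(ok)); inhole <- rep(FALSE, sum(ok))
  for (ring in rings) {
    hit <- .in_ring(lon[ok], lat[ok], ring)
    if (isTRUE(attr(ring, "hole"))) inhole <- inhole | hit
    else inside <- inside | hit
  }
  res[ok] <- inside & !inhole
  res
}

#' Test points against a set of regions
#'
#' @inheritParams point_in_polygon
#' @param regions list of regions (each a list of rings).
#' @return logical: inside any region.
#' @export
point_in_polygons <- function(lon, lat, regions) {
  res <- rep(FALSE, length(lon))
  for (rings in regions) res <- res | point_in_polygon(lon, lat, rings)
  res
}
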