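#' Define an equal-angle latitude-longitude grid
#'
#' Cells are squares of `resolution_deg` degrees on a side, indexed by
#' integer ids in row-major order starting from the south-west corner
#' (id 1 = southernmost row, westernmost column). Cell registration is
#' centre-based: the centroid of the cell in (0-based) row `r`, column `c`
#' is `(lon_min + (c + 0.5) * res, lat_min + (r + 0.5) * res)`.
#'
#' The default grid is global (longitudes `[-180, 180)`, latitudes
#' `(-90, 90)`). A rectangular sub-window can be requested instead, which
#' keeps regional experiments small; the resolution must divide the window
#' extents exactly.
#'
#' @param resolution_deg cell edge in degrees (must divide both window
#'   extents exactly; for the global grid, divides 360 and 180).
#' @param lon_min,lon_max,lat_min,lat_max window bounds in degrees.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(5)
#' g$n_lon # 72
#' cell_centroid(g, 1) # south-west corner cell
#' @export
grid_spec <- function(resolution_deg = 1,
                      lon_min = -180, lon_max = 180,
                      lat_min = -90, lat_max = 90) {
  stopifnot(resolution_deg > 0, lon_max > lon_min, lat_max > lat_min,
            lat_min >= -90, lat_max <= 90)
  wx <- lon_max - lon_min
  wy <- lat_max - lat_min
  if (abs(wx / resolution_deg - round(wx / resolution_deg)) > 1e-9 ||
      abs(wy / resolution_deg - round(wy / resolution_deg)) > 1e-9)
    stop("resolution_deg must divide the window extents exactly")
  spec <- list(res = resolution_deg,
               lon_min = lon_min, lon_max = lon_max,
               lat_min = lat_min, lat_max = lat_max,
               n_lon = as.integer(round(wx / resolution_deg)),
               n_lat = as.integer(round(wy / resolution_deg)),
               global = isTRUE(all.equal(wx, 360)))
  spec$n_cell <- spec$n_lon * spec$n_lat
  class(spec) <- "grid_spec"
  spec
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %g deg, %d x %d cells, lon [%g, %g), lat [%g, %g)%s\n",
              x$res, x$n_lon, x$n_lat, x$lon_min, x$lon_max,
              x$lat_min, x$lat_max, if (x$global) " (global)" else ""))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("res", "lon_min", "lat_min", "n_lon", "n_lat")],
                   unclass(b)[c("res", "lon_min", "lat_min", "n_lon", "n_lat")]))
}

valid_cells <- function(spec, ids) {
  is.numeric(ids) && all(ids == floor(ids)) &&
    all(ids >= 1) && all(ids <= spec$n_cell)
}

#' Cell centroids
#'
#' @param spec a [grid_spec()].
#' @param ids integer cell ids (1-based, row-major from the south-west).
#' @return two-column matrix of centroid `lon`, `lat` in degrees;
#'   longitudes of a global grid lie in `[-180, 180)`.
#' @export
cell_centroid <- function(spec, ids) {
  stopifnot(valid_cells(spec, ids))
  row <- (ids - 1) %/% spec$n_lon
  col <- (ids - 1) %% spec$n_lon
  cbind(lon = spec$lon_min + (col + 0.5) * spec$res,
        lat = spec$lat_min + (row + 0.5) * spec$res)
}

#' Cell id containing a lon/lat point
#'
#' @param spec a [grid_spec()].
#' @param lon,lat coordinates in degrees; longitudes are wrapped into the
#'   grid window when the grid is global.
#' @return integer cell ids; `NA` for points outside a non-global window.
#' @export
cell_at <- function(spec, lon, lat) {
  if (spec$global)
    lon <- ((lon - spec$lon_min) %% 360) + spec$lon_min
  col <- floor((lon - spec$lon_min) / spec$res)
  row <- floor((lat - spec$lat_min) / spec$res)
  # points exactly on the top/right boundary belong to the last cell
  col[lon == spec$lon_max] <- spec$n_lon - 1L
  row[lat == spec$lat_max] <- spec$n_lat - 1L
  bad <- col < 0 | col >= spec$n_lon | row < 0 | row >= spec$n_lat
  id <- as.integer(row * spec$n_lon + col + 1)
  id[bad] <- NA_integer_
  id
}
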