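# Local tangent-plane projection anchored at the study origin. Over the
# ~100 km extent of a winter wolf study the error versus a conformal
# projection is well under the GPS error of a collar fix, and the mapping
# is linear, so means of projected coordinates correspond to means of
# geographic coordinates.

# meters per degree of latitude (WGS84 mean)
.M_PER_DEG_LAT <- 111132.954

#' Define a local tangent-plane projection
#'
#' @param origin_lat,origin_lon geographic origin, decimal degrees.
#' @param origin_easting,origin_northing projected coordinates (m) assigned
#'   to the origin.
#' @return A list of class `tangent_projection`.
#' @export
tangent_projection <- function(origin_lat = 56.4, origin_lon = -111.1,
                               origin_easting = 500000, origin_northing = 6250000) {
  stopifnot(abs(origin_lat) < 89)
  structure(
    list(
      origin_lat = origin_lat, origin_lon = origin_lon,
      origin_easting = origin_easting, origin_northing = origin_northing,
      m_per_deg_lon = .M_PER_DEG_LAT * cos(origin_lat * pi / 180)
    ),
    class = "tangent_projection"
  )
}

#' Project geographic coordinates to local plane meters
#' @param proj a [tangent_projection()].
#' @param lat,lon decimal degrees.
#' @return tibble with `easting`, `northing` (m).
#' @export
project_to_plane <- function(proj, lat, lon) {
  stopifnot(inherits(proj, "tangent_projection"))
  tibble::tibble(
    easting = proj$origin_easting + (lon - proj$origin_lon) * proj$m_per_deg_lon,
    northing = proj$origin_northing + (lat - proj$origin_lat) * .M_PER_DEG_LAT
  )
}

#' Unproject plane meters to geographic coordinates
#' @param proj a [tangent_projection()].
#' @param easting,northing meters.
#' @return tibble with `lat`, `lon` (decimal degrees).
#' @export
plane_to_geographic <- function(proj, easting, northing) {
  stopifnot(inherits(proj, "tangent_projection"))
  tibble::tibble(
    lat = proj$origin_lat + (northing - proj$origin_northing) / .M_PER_DEG_LAT,
    lon = proj$origin_lon + (easting - proj$origin_easting) / proj$m_per_deg_lon
  )
}
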