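# GeoJSON input/output for target areas and buffers (FeatureCollections of
# Point/Polygon features; coordinates are taken verbatim, so files must be in
# a projected metric system unless reprojected via 'origin').

#' Read park target areas from GeoJSON
#'
#' Expects a FeatureCollection whose features carry `park_id` and `area_id`
#' properties and Point or Polygon geometries.
#'
#' @param path GeoJSON file path.
#' @param origin optional `c(lon0, lat0)`: if supplied, coordinates are
#'   interpreted as WGS84 longitude/latitude and reprojected to local meters
#'   via [lonlat_to_local()].
#' @return a [target_areas()] data frame.
#' @export
read_target_areas <- function(path, origin = NULL) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("target-area file not found: %s", path))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    pa_stop_structural("target-area GeoJSON must be a FeatureCollection")
  }
  feats <- gj$features
  if (length(feats) == 0L) pa_stop_structural("target-area GeoJSON has no features")
  park_id <- character(length(feats))
  area_id <- character(length(feats))
  geometry <- vector("list", length(feats))
  reproj <- function(coords) {
    if (is.null(origin)) return(coords)
    p <- lonlat_to_local(coords[, 1L], coords[, 2L], origin)
    cbind(p$x, p$y)
  }
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    props <- f$properties
    if (is.null(props$park_id) || is.null(props$area_id)) {
      pa_stop_structural(sprintf("feature %d lacks park_id/area_id properties", k))
    }
    park_id[k] <- as.character(props$park_id)
    area_id[k] <- as.character(props$area_id)
    g <- f$geometry
    if (identical(g$type, "Point")) {
      xy <- reproj(matrix(as.numeric(unlist(g$coordinates)), 1L))
      geometry[[k]] <- geom_point(xy[1L, 1L], xy[1L, 2L])
    } else if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1L]], function(p) {
        as.numeric(unlist(p))
      }))
      geometry[[k]] <- geom_polygon(reproj(ring))
    } else {
      pa_stop_structural(sprintf(
        "unsupported geometry type '%s' in feature %d", g$type %||% "NULL", k
      ))
    }
  }
  target_areas(park_id, area_id, geometry = geometry)
}

geojson_geometry <- function(geom) {
  if (geom$type == "point") {
    list(type = "Point", coordinates = as.numeric(geom$coords))
  } else {
    ring <- rbind(geom$coords, geom$coords[1L, , drop = FALSE])
    list(type = "Polygon",
         coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
           as.numeric(ring[i, ])
         })))
  }
}

#' Write park target areas as GeoJSON
#'
#' @param areas a [target_areas()] data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_target_areas <- function(areas, path) {
  feats <- lapply(seq_len(nrow(areas)), function(i) {
    list(
      type = "Feature",
      properties = list(park_id = areas$park_id[[i]],
                        area_id = areas$area_id[[i]]),
      geometry = geojson_geometry(as_pa_geometry(areas$geometry[[i]]))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

circle_ring <- function(cx, cy, r, n_segments) {
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Write park buffers as GeoJSON
#'
#' Each buffer is written as one Feature with a MultiPolygon of the
#' per-target-area discs (polygonized circles; overlapping members together
#' represent the union). Only point-target-area buffers are supported for
#' export.
#'
#' @param buffers list of [build_buffer()] results.
#' @param path output file path.
#' @param n_segments circle polygonization density (default 128).
#' @return `path`, invisibly.
#' @export
write_buffers <- function(buffers, path, n_segments = 128) {
  feats <- lapply(buffers, function(b) {
    types <- vapply(b$geoms, function(g) g$type, character(1))
    if (!all(types == "point")) {
      pa_stop_structural(
        "GeoJSON export of polygon-target-area buffers is not supported"
      )
    }
    polys <- lapply(b$geoms, function(g) {
      ring <- circle_ring(g$coords[["x"]], g$coords[["y"]], b$radius_m,
                          n_segments)
      list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
    })
    list(
      type = "Feature",
      properties = list(park_id = b$park_id, radius_m = b$radius_m),
      geometry = list(type = "MultiPolygon", coordinates = polys)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
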