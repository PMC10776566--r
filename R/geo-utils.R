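# Spherical-geometry helpers shared by the dispersal, telemetry and fixture
# code. All distances use a spherical Earth of radius 6371.0 km (haversine).

#' Mean Earth radius used throughout the package (metres)
#' @keywords internal
EARTH_RADIUS_M <- 6371000

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees. Vectorised.
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / 1000
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule on a simple (non-self-intersecting) polygon ring. Points on
#' an edge are treated as inside.
#'
#' @param lon,lat Query coordinates (vectorised).
#' @param ring Two-column matrix of polygon vertices (lon, lat); closure is
#'   implicit (last vertex need not repeat the first).
#' @return Logical vector.
#' @export
point_in_ring <- function(lon, lat, ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 &&
      all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  nv <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(lon)
  inside <- logical(n)
  on_edge <- logical(n)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # edge hit: collinear and within bounding box
    cross <- (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi)
    on_seg <- abs(cross) < 1e-12 &
      lon >= pmin(xi, xj) - 1e-12 & lon <= pmax(xi, xj) + 1e-12 &
      lat >= pmin(yi, yj) - 1e-12 & lat <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# TRUE if any point of `a` lies inside `b`, any of `b` inside `a`, or any two
# edges properly intersect. Complete for simple polygons.
rings_overlap <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (any(point_in_ring(a[, 1], a[, 2], b))) return(TRUE)
  if (any(point_in_ring(b[, 1], b[, 2], a))) return(TRUE)
  seg <- function(r) {
    if (all(r[1, ] == r[nrow(r), ])) r else rbind(r, r[1, ])
  }
  a <- seg(a); b <- seg(b)
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      p1 <- a[i, ]; p2 <- a[i + 1, ]; q1 <- b[j, ]; q2 <- b[j + 1, ]
      o1 <- orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
      o2 <- orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
      o3 <- orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
      o4 <- orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
      if (o1 != o2 && o3 != o4) return(TRUE)
    }
  }
  FALSE
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Minimal reader for the dialect this package writes: Polygon features with
#' \code{name} (and optionally \code{season_start_doy}, \code{season_end_doy})
#' properties. Only the outer ring of each polygon is used.
#'
#' @param path GeoJSON file.
#' @return Named list of features; each has \code{name}, \code{ring}
#'   (lon/lat matrix) and any further properties.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  feats <- lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    out <- f$properties
    out$ring <- ring
    out
  })
  names(feats) <- vapply(feats, function(f) f$name, character(1))
  feats
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polys Named list; each element has a \code{ring} matrix and any
#'   scalar properties (e.g. season day-of-year bounds).
#' @param path Output file.
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(polys, function(p) {
    ring <- as.matrix(p$ring)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    props <- p[setdiff(names(p), "ring")]
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Hashes a stage/stream name together with the master seed into an integer
#' below 2^31, so every stage of a run draws reproducible, independent
#' randomness and adding a stream never shifts the others.
#'
#' @param master Integer master seed.
#' @param stage Character stream name.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
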