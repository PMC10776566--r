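#' Telemetry track for one tagged fish
#'
#' Time-ordered position records merged from acoustic detections and
#' satellite-tag position estimates. Positions are consumed as given (no
#' geolocation modelling); an optional per-record positional uncertainty is
#' carried through to outputs.
#'
#' @param id Fish id.
#' @param time Strictly increasing \code{POSIXct}/\code{Date} timestamps.
#' @param lon,lat Positions in decimal degrees.
#' @param source Per-record source, \code{"acoustic"} or \code{"psat"}.
#' @param pos_sd_km Optional per-record positional uncertainty (km).
#' @return Object of class \code{telemetry_track}.
#' @export
telemetry_track <- function(id, time, lon, lat,
                            source = "acoustic", pos_sd_km = NA_real_) {
  time <- as.POSIXct(time, tz = "UTC")
  n <- length(time)
  stopifnot(length(lon) == n, length(lat) == n)
  if (n > 1 && any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(lon < -180 | lon > 360 | lat < -90 | lat > 90))
    stop("positions outside plausible lon/lat bounds")
  source <- rep_len(as.character(source), n)
  if (!all(source %in% c("acoustic", "psat")))
    stop("source must be 'acoustic' or 'psat'")
  structure(list(id = as.character(id),
                 records = data.frame(time = time, lon = lon, lat = lat,
                                      source = source,
                                      pos_sd_km = rep_len(pos_sd_km, n))),
            class = "telemetry_track")
}

#' Build a synthetic track through waypoints
#'
#' Positions at the given timestamps, optionally jittered with isotropic
#' Gaussian noise of a stated standard deviation (in km, converted locally
#' to degrees).
#'
#' @param config A \code{\link{fixture_config}} (seed source).
#' @param waypoints Two-column matrix (lon, lat).
#' @param times Strictly increasing timestamps, one per waypoint.
#' @param id Fish id.
#' @param noise_sd_km Positional noise standard deviation; 0 = exact.
#' @param source Record source label(s).
#' @return A \code{\link{telemetry_track}}.
#' @export
make_track <- function(config, waypoints, times, id = "fish1",
                       noise_sd_km = 0, source = "acoustic") {
  waypoints <- rbind(waypoints)
  if (nrow(waypoints) != length(times))
    stop("waypoints and times must have equal length")
  lon <- waypoints[, 1]; lat <- waypoints[, 2]
  if (noise_sd_km > 0) {
    with_seed(fixture_seed(config, paste0("track_", id)), {
      lat <- lat + rnorm(length(lat), 0, noise_sd_km / 111.19)
      lon <- lon + rnorm(length(lon), 0,
                         noise_sd_km / (111.19 * cos(lat * pi / 180)))
    })
  }
  telemetry_track(id, times, lon, lat, source,
                  pos_sd_km = if (noise_sd_km > 0) noise_sd_km else NA_real_)
}

#' Distances travelled along a track
#'
#' Haversine leg distances between consecutive records, their cumulative
#' sum, and the maximum great-circle displacement over all record pairs.
#'
#' @param track A \code{\link{telemetry_track}}.
#' @return List with \code{cumulative_km}, \code{max_displacement_km} and a
#'   \code{legs} data frame (from/to indices, leg km).
#' @export
track_distances <- function(track) {
  r <- track$records
  n <- nrow(r)
  if (n < 1) stop("track has no records")
  if (n == 1)
    return(list(cumulative_km = 0, max_displacement_km = 0,
                legs = data.frame(from = integer(), to = integer(),
                                  km = numeric())))
  legs <- haversine_km(r$lon[-n], r$lat[-n], r$lon[-1], r$lat[-1])
  ij <- utils::combn(n, 2)
  disp <- haversine_km(r$lon[ij[1, ]], r$lat[ij[1, ]],
                       r$lon[ij[2, ]], r$lat[ij[2, ]])
  list(cumulative_km = sum(legs),
       max_displacement_km = max(disp),
       legs = data.frame(from = seq_len(n - 1), to = 2:n, km = legs))
}

#' Maximum distance covered within any sliding 365-day window
#'
#' Sum of leg distances whose start and end records both fall inside a
#' 365-day window, maximised over windows anchored at each record.
#'
#' @param track A \code{\link{telemetry_track}}.
#' @return Kilometres (0 for a single-record track).
#' @export
annual_distance_km <- function(track) {
  r <- track$records
  n <- nrow(r)
  if (n < 2) return(0)
  legs <- haversine_km(r$lon[-n], r$lat[-n], r$lon[-1], r$lat[-1])
  tnum <- as.numeric(r$time) / 86400
  best <- 0
  for (i in seq_len(n - 1)) {
    inwin <- which(tnum <= tnum[i] + 365)
    j <- max(inwin)
    if (j > i) best <- max(best, sum(legs[i:(j - 1)]))
  }
  best
}

#' Zone occupancy and zone-to-zone transition events
#'
#' Classifies every record by containing zone (records outside all zones are
#' \code{"offshore"}) and lists transitions — consecutive records whose zone
#' differs.
#'
#' @param track A \code{\link{telemetry_track}}.
#' @param zones Named list of lon/lat polygon rings; zones must not overlap.
#' @return List with \code{zone} (per-record labels), \code{transitions}
#'   (data frame: time, from, to) and \code{counts} (table over ordered zone
#'   pairs).
#' @export
zone_transitions <- function(track, zones) {
  stopifnot(length(zones) >= 1, !is.null(names(zones)))
  if (length(zones) > 1) {
    cmb <- utils::combn(length(zones), 2)
    for (k in seq_len(ncol(cmb)))
      if (rings_overlap(zones[[cmb[1, k]]], zones[[cmb[2, k]]]))
        stop("zones must not overlap: ", names(zones)[cmb[1, k]], " / ",
             names(zones)[cmb[2, k]])
  }
  r <- track$records
  zone <- rep("offshore", nrow(r))
  for (nm in names(zones)) {
    inz <- point_in_ring(r$lon, r$lat, zones[[nm]])
    zone[inz & zone == "offshore"] <- nm
  }
  chg <- which(zone[-1] != zone[-length(zone)])
  transitions <- data.frame(time = r$time[chg + 1],
                            from = zone[chg], to = zone[chg + 1])
  counts <- if (nrow(transitions))
    as.data.frame(table(from = transitions$from, to = transitions$to),
                  stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), Freq = integer())
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  list(zone = zone, transitions = transitions, counts = counts)
}

#' Write tracks as a detections CSV
#' @param tracks List of \code{\link{telemetry_track}} objects.
#' @param path Output CSV (columns id, timestamp ISO-8601, lon, lat, source).
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = tr$id,
               timestamp = format(tr$records$time, "%Y-%m-%dT%H:%M:%SZ"),
               lon = tr$records$lon, lat = tr$records$lat,
               source = tr$records$source)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a detections CSV into a list of tracks
#' @param path CSV path as written by \code{\link{write_tracks_csv}}.
#' @return Named list of \code{\link{telemetry_track}} objects.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$timestamp), ]
    telemetry_track(d$id[1],
                    as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC"),
                    d$lon, d$lat, d$source)
  })
  out
}
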