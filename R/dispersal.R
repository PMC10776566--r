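#' Spawning site with release cells and settlement target
#'
#' A spawning location: a lon/lat polygon, a day-of-year spawning season,
#' a set of ~3 km release cells rasterised inside the polygon, and the
#' settlement polygon that counts as "reached" for connectivity (default:
#' the spawning polygon buffered outward by a configurable distance, an
#' operational reading of the coastal area around a spawning location).
#'
#' @param name Site label.
#' @param polygon Two-column lon/lat ring.
#' @param season Integer length-2 day-of-year window \code{c(start, end)},
#'   start <= end.
#' @param settlement_polygon Optional explicit settlement ring; default is
#'   \code{polygon} buffered by \code{settlement_buffer_km}.
#' @param settlement_buffer_km Radial buffer applied to the spawning polygon
#'   to form the settlement polygon (km; approximate radial expansion about
#'   the centroid). Default 10.
#' @param release_cell_km Side of the square release cells (km). Default 3.
#' @param field Optional \code{\link{velocity_field}}; release cells whose
#'   centroid falls on a land cell are dropped.
#' @return Object of class \code{spawning_site} with a \code{release_cells}
#'   matrix of cell centroids.
#' @export
spawning_site <- function(name, polygon, season,
                          settlement_polygon = NULL,
                          settlement_buffer_km = 10,
                          release_cell_km = 3,
                          field = NULL) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, length(season) == 2)
  if (season[1] > season[2]) stop("season start must be <= season end")
  if (is.null(settlement_polygon))
    settlement_polygon <- buffer_ring(polygon, settlement_buffer_km)
  settlement_polygon <- as.matrix(settlement_polygon)

  # rasterise at ~release_cell_km in a local equal-area approximation
  latc <- mean(polygon[, 2])
  dlat <- release_cell_km / 111.19
  dlon <- release_cell_km / (111.19 * cos(latc * pi / 180))
  span_seq <- function(lo, hi, by) {
    if (lo + by / 2 > hi) (lo + hi) / 2 else seq(lo + by / 2, hi, by = by)
  }
  lons <- span_seq(min(polygon[, 1]), max(polygon[, 1]), dlon)
  lats <- span_seq(min(polygon[, 2]), max(polygon[, 2]), dlat)
  cells <- as.matrix(expand.grid(lon = lons, lat = lats))
  keep <- point_in_ring(cells[, 1], cells[, 2], polygon)
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) {                 # polygon smaller than one cell
    ctr <- colMeans(polygon)
    if (point_in_ring(ctr[1], ctr[2], polygon))
      cells <- matrix(ctr, 1, 2, dimnames = list(NULL, c("lon", "lat")))
  }
  if (!is.null(field) && nrow(cells)) {
    ok <- vapply(seq_len(nrow(cells)), function(i) {
      s <- interpolate_velocity(field, cells[i, 1], cells[i, 2], 0)
      s$status == "ok"
    }, logical(1))
    cells <- cells[ok, , drop = FALSE]
  }
  if (nrow(cells) == 0)
    stop("spawning_site '", name, "': no ocean release cells inside polygon")
  structure(list(name = as.character(name), polygon = polygon,
                 season = as.integer(season),
                 settlement_polygon = settlement_polygon,
                 release_cells = cells),
            class = "spawning_site")
}

# approximate outward buffer: move each vertex radially from the centroid by
# `km` in local-metric kilometres (adequate for the compact convex-ish site
# polygons used here; not a general-purpose geodesic buffer)
buffer_ring <- function(ring, km) {
  ring <- as.matrix(ring)
  if (km == 0) return(ring)
  c0 <- colMeans(ring)
  kx <- 111.19 * cos(c0[2] * pi / 180)
  ky <- 111.19
  dx <- (ring[, 1] - c0[1]) * kx
  dy <- (ring[, 2] - c0[2]) * ky
  r <- sqrt(dx^2 + dy^2)
  r[r == 0] <- 1e-9
  scale <- (r + km) / r
  cbind(c0[1] + dx * scale / kx, c0[2] + dy * scale / ky)
}

#' Interpolate currents at arbitrary positions
#'
#' Bilinear interpolation in space over the four surrounding grid nodes and
#' piecewise-constant (nearest preceding day) in time. Land nodes are
#' excluded from the stencil with weight renormalisation; a stencil that is
#' entirely land yields the land signal, and a query outside the grid the
#' out-of-domain signal.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param lon,lat Query positions (vectorised).
#' @param t Time as days since the first field day (numeric, may be
#'   fractional) or a \code{Date}.
#' @return List of vectors \code{u}, \code{v} (m/s; \code{NA} where not
#'   \code{"ok"}) and \code{status} (\code{"ok"}, \code{"land"},
#'   \code{"outside"}).
#' @export
interpolate_velocity <- function(field, lon, lat, t) {
  if (inherits(t, "Date")) t <- as.numeric(t - field$time[1])
  nt <- length(field$time)
  ti <- min(max(floor(t[1]) + 1L, 1L), nt)
  nl <- length(field$lon); nm <- length(field$lat)
  dx <- field$lon[2] - field$lon[1]
  dy <- field$lat[2] - field$lat[1]
  fx <- (lon - field$lon[1]) / dx
  fy <- (lat - field$lat[1]) / dy
  n <- length(lon)
  status <- rep("ok", n)
  outside <- fx < 0 | fx > nl - 1 | fy < 0 | fy > nm - 1 |
    !is.finite(fx) | !is.finite(fy)
  status[outside] <- "outside"
  i0 <- pmin(pmax(floor(fx), 0), nl - 2) + 1L
  j0 <- pmin(pmax(floor(fy), 0), nm - 2) + 1L
  ax <- fx - (i0 - 1L); ay <- fy - (j0 - 1L)
  u <- v <- rep(NA_real_, n)
  ok <- !outside
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; axk <- ax[ok]; ayk <- ay[ok]
    idx <- function(ii, jj) cbind(ii, jj)
    m <- field$land_mask
    uslab <- field$u[, , ti]; vslab <- field$v[, , ti]
    w00 <- (1 - axk) * (1 - ayk); w10 <- axk * (1 - ayk)
    w01 <- (1 - axk) * ayk;       w11 <- axk * ayk
    o00 <- !m[idx(i0k, j0k)];     o10 <- !m[idx(i0k + 1, j0k)]
    o01 <- !m[idx(i0k, j0k + 1)]; o11 <- !m[idx(i0k + 1, j0k + 1)]
    wsum <- w00 * o00 + w10 * o10 + w01 * o01 + w11 * o11
    land <- wsum <= 0
    val <- function(slab) {
      g <- function(ii, jj, oo) { x <- slab[idx(ii, jj)]; x[!oo] <- 0; x }
      (w00 * o00 * g(i0k, j0k, o00) + w10 * o10 * g(i0k + 1, j0k, o10) +
       w01 * o01 * g(i0k, j0k + 1, o01) +
       w11 * o11 * g(i0k + 1, j0k + 1, o11)) / wsum
    }
    uu <- val(uslab); vv <- val(vslab)
    uu[land] <- NA_real_; vv[land] <- NA_real_
    u[ok] <- uu; v[ok] <- vv
    st <- status[ok]; st[land] <- "land"; status[ok] <- st
  }
  list(u = u, v = v, status = status)
}

# degree displacement for (u, v) m/s over dt seconds at latitude `lat`
uv_to_deg <- function(u, v, lat, dt) {
  dlat <- v * dt / EARTH_RADIUS_M * 180 / pi
  dlon <- u * dt / (EARTH_RADIUS_M * cos(lat * pi / 180)) * 180 / pi
  cbind(dlon, dlat)
}

#' Advect a single larva through the current field
#'
#' Forward-Euler (default) or classical 4th-order Runge-Kutta integration at
#' a fixed step, converting m/s velocities to degrees with a cos-latitude
#' metric. The fate is the first event among: entry into a settlement
#' polygon (\code{settled}; re-entry into the source's own polygon counts
#' only after the particle has first left it), an all-land interpolation
#' stencil (\code{beached}), exit from the grid (\code{lost_open_ocean}), or
#' reaching the maximum drift duration (\code{expired}).
#'
#' @param field A \code{\link{velocity_field}}.
#' @param site The source \code{\link{spawning_site}}.
#' @param release_time \code{Date} of release (within field coverage).
#' @param release_lonlat Release position; default the site's first release
#'   cell. Must be an ocean position.
#' @param step_h Integration step in hours (default 1).
#' @param max_days Maximum drift duration in days (default 30).
#' @param sites_all List of all \code{\link{spawning_site}}s whose
#'   settlement polygons are active targets; defaults to \code{list(site)}.
#' @param method \code{"euler"} or \code{"rk4"}.
#' @param record_positions Keep the full hourly position sequence?
#' @return A particle: list with \code{source_site}, \code{release_time},
#'   \code{fate}, \code{settle_site}, \code{dispersal_km}, final
#'   \code{position}, elapsed \code{hours} and (optionally)
#'   \code{positions}.
#' @export
advect <- function(field, site, release_time,
                   release_lonlat = NULL, step_h = 1, max_days = 30,
                   sites_all = list(site), method = c("euler", "rk4"),
                   record_positions = FALSE) {
  method <- match.arg(method)
  stopifnot(max_days >= 1)
  if (is.null(release_lonlat)) release_lonlat <- site$release_cells[1, ]
  pos <- as.numeric(release_lonlat)
  t0 <- as.numeric(as.Date(release_time) - field$time[1])
  if (t0 < 0 || t0 > length(field$time) - 1)
    stop("release_time outside field time coverage")
  s0 <- interpolate_velocity(field, pos[1], pos[2], t0)
  if (s0$status == "land") stop("release position is on land")
  if (s0$status == "outside") stop("release position outside grid")

  dt <- step_h * 3600
  n_steps <- ceiling(max_days * 24 / step_h)
  has_exited_source <- !point_in_ring(pos[1], pos[2],
                                      site$settlement_polygon)
  positions <- if (record_positions)
    matrix(NA_real_, n_steps + 1, 2) else NULL
  if (record_positions) positions[1, ] <- pos
  release_pos <- pos
  fate <- "expired"; settle_site <- NA_character_; hours_done <- 0

  rate <- function(p, tdays) {
    s <- interpolate_velocity(field, p[1], p[2], tdays)
    if (s$status != "ok") return(NULL)
    c(s$u, s$v)
  }

  for (k in seq_len(n_steps)) {
    tk <- t0 + (k - 1) * step_h / 24
    v1 <- rate(pos, tk)
    if (is.null(v1)) { fate <- "beached"; hours_done <- (k - 1) * step_h; break }
    if (method == "euler") {
      disp <- uv_to_deg(v1[1], v1[2], pos[2], dt)
    } else {
      half <- uv_to_deg(v1[1], v1[2], pos[2], dt / 2)
      p2 <- pos + half
      v2 <- rate(p2, tk + step_h / 48)
      v3 <- if (!is.null(v2)) {
        p3 <- pos + uv_to_deg(v2[1], v2[2], p2[2], dt / 2)
        rate(p3, tk + step_h / 48)
      } else NULL
      v4 <- if (!is.null(v3)) {
        p4 <- pos + uv_to_deg(v3[1], v3[2], pos[2], dt)
        rate(p4, tk + step_h / 24)
      } else NULL
      disp <- if (is.null(v2) || is.null(v3) || is.null(v4)) {
        uv_to_deg(v1[1], v1[2], pos[2], dt)
      } else {
        vb <- (v1 + 2 * v2 + 2 * v3 + v4) / 6
        uv_to_deg(vb[1], vb[2], pos[2], dt)
      }
    }
    newpos <- pos + as.numeric(disp)
    hours_done <- k * step_h
    if (record_positions) positions[k + 1, ] <- newpos
    st <- interpolate_velocity(field, newpos[1], newpos[2],
                               tk + step_h / 24)$status
    if (st == "outside") { pos <- newpos; fate <- "lost_open_ocean"; break }
    # settlement has precedence over beaching at the same hour
    settled <- FALSE
    for (s in sites_all) {
      inside <- point_in_ring(newpos[1], newpos[2], s$settlement_polygon)
      if (s$name == site$name) {
        if (!inside) has_exited_source <- TRUE
        else if (has_exited_source) {
          settled <- TRUE; settle_site <- s$name; break
        }
      } else if (inside) {
        settled <- TRUE; settle_site <- s$name; break
      }
    }
    pos <- newpos
    if (settled) { fate <- "settled"; break }
    if (st == "land") { fate <- "beached"; break }
  }
  if (record_positions)
    positions <- positions[!is.na(positions[, 1]), , drop = FALSE]
  list(source_site = site$name,
       release_time = as.Date(release_time),
       fate = fate,
       settle_site = settle_site,
       dispersal_km = haversine_km(release_pos[1], release_pos[2],
                                   pos[1], pos[2]),
       position = pos,
       hours = hours_done,
       positions = positions)
}

#' Run the full release design
#'
#' For every site, year, in-season day and release cell, releases
#' \code{release_per_day} particles and advects each for up to
#' \code{max_days}. All particle records are retained.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param sites List of \code{\link{spawning_site}}s.
#' @param years Integer years to simulate; default all years present in the
#'   field's time axis. Each site's whole season (plus nothing more) must be
#'   covered by the field.
#' @param release_per_day Particles per cell per in-season day.
#' @inheritParams advect
#' @return A \code{trajectory_set}: list of particles plus site labels;
#'   coerce with \code{as.data.frame}.
#' @export
run_simulation <- function(field, sites, years = NULL, release_per_day = 1,
                           step_h = 1, max_days = 30,
                           method = c("euler", "rk4"),
                           record_positions = FALSE) {
  method <- match.arg(method)
  if (is.null(years))
    years <- sort(unique(as.integer(format(field$time, "%Y"))))
  particles <- list()
  for (site in sites) {
    doys <- site$season[1]:site$season[2]
    for (yr in years) {
      dates <- as.Date(paste0(yr, "-01-01")) + doys - 1L
      if (any(dates < field$time[1]) ||
          any(dates > field$time[length(field$time)]))
        stop("season of site '", site$name,
             "' outside field time coverage for year ", yr)
      for (d in seq_along(dates)) {
        for (c_i in seq_len(nrow(site$release_cells))) {
          for (rep_i in seq_len(release_per_day)) {
            particles[[length(particles) + 1L]] <-
              advect(field, site, dates[d],
                     release_lonlat = site$release_cells[c_i, ],
                     step_h = step_h, max_days = max_days,
                     sites_all = sites, method = method,
                     record_positions = record_positions)
          }
        }
      }
    }
  }
  structure(list(particles = particles,
                 sites = vapply(sites, `[[`, character(1), "name")),
            class = "trajectory_set")
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  data.frame(id = seq_along(x$particles),
             source = vapply(x$particles, `[[`, character(1), "source_site"),
             release_time = as.Date(vapply(x$particles, function(p)
               format(p$release_time), character(1))),
             fate = vapply(x$particles, `[[`, character(1), "fate"),
             settle_site = vapply(x$particles, `[[`, character(1),
                                  "settle_site"),
             dispersal_km = vapply(x$particles, `[[`, numeric(1),
                                   "dispersal_km"))
}

#' Dispersal-distance statistics
#'
#' Mean, standard deviation, 95th percentile (linear-interpolation quantile)
#' and maximum of per-particle dispersal distance, per source site and
#' pooled.
#'
#' @param trajs A \code{trajectory_set} (or its data-frame form).
#' @param by_site Include per-site rows in addition to the pooled row?
#' @return Data frame with columns site, n, mean_km, sd_km, q95_km, max_km.
#' @export
dispersal_stats <- function(trajs, by_site = TRUE) {
  df <- if (is.data.frame(trajs)) trajs else as.data.frame(trajs)
  if (nrow(df) == 0) stop("no particles in trajectory set")
  one <- function(d, label) {
    data.frame(site = label, n = nrow(d),
               mean_km = mean(d$dispersal_km),
               sd_km = stats::sd(d$dispersal_km),
               q95_km = unname(stats::quantile(d$dispersal_km, 0.95,
                                               type = 7)),
               max_km = max(d$dispersal_km))
  }
  out <- one(df, "pooled")
  if (by_site) {
    per <- do.call(rbind, lapply(split(df, df$source),
                                 function(d) one(d, d$source[1])))
    out <- rbind(per, out)
  }
  rownames(out) <- NULL
  out
}

#' Pairwise oceanographic-connectivity matrix
#'
#' \code{P[i, j]} is the proportion of particles released at site i whose
#' fate was settlement in site j's settlement polygon; the diagonal is local
#' retention. Rows for sites with zero releases are \code{NA} (undefined),
#' not zero.
#'
#' @param trajs A \code{trajectory_set} (or its data-frame form).
#' @param sites List of \code{\link{spawning_site}}s or character site
#'   labels fixing row/column order.
#' @return Object of class \code{connectivity_matrix}: list with
#'   \code{sites}, \code{P} and \code{n_released}.
#' @export
connectivity_matrix <- function(trajs, sites) {
  labels <- if (is.character(sites)) sites
            else vapply(sites, `[[`, character(1), "name")
  df <- if (is.data.frame(trajs)) trajs else as.data.frame(trajs)
  if (!all(df$source %in% labels))
    stop("trajectory source labels not all present in `sites`")
  k <- length(labels)
  P <- matrix(0, k, k, dimnames = list(labels, labels))
  n_rel <- vapply(labels, function(s) sum(df$source == s), numeric(1))
  for (i in seq_len(k)) {
    if (n_rel[i] == 0) { P[i, ] <- NA_real_; next }
    sub <- df[df$source == labels[i] & df$fate == "settled", ]
    if (nrow(sub))
      P[i, ] <- as.numeric(table(factor(sub$settle_site,
                                        levels = labels))) / n_rel[i]
  }
  structure(list(sites = labels, P = P, n_released = n_rel),
            class = "connectivity_matrix")
}

#' Fate counts per source site
#' @param trajs A \code{trajectory_set} (or data frame form).
#' @return Table of counts, sites by fate.
#' @export
fate_counts <- function(trajs) {
  df <- if (is.data.frame(trajs)) trajs else as.data.frame(trajs)
  table(source = df$source,
        fate = factor(df$fate, levels = c("settled", "beached",
                                          "lost_open_ocean", "expired")))
}
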