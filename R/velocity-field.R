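#' Gridded ocean-velocity field
#'
#' Container for daily eastward/northward current components on a regular
#' lon/lat grid with a land mask — the physical forcing for larval drift.
#'
#' @param lon,lat Strictly increasing, uniformly spaced coordinates
#'   (degrees).
#' @param time Vector of \code{Date}s, one per daily frame.
#' @param u,v Arrays of dimension \code{c(length(lon), length(lat),
#'   length(time))}, in m/s. \code{NA} on land.
#' @param land_mask Logical matrix \code{length(lon) x length(lat)};
#'   \code{TRUE} marks land.
#' @return Object of class \code{velocity_field}.
#' @export
velocity_field <- function(lon, lat, time, u, v, land_mask = NULL) {
  stopifnot(length(lon) >= 2, length(lat) >= 2,
            all(diff(lon) > 0), all(diff(lat) > 0))
  if ((length(lon) > 2 && max(abs(diff(diff(lon)))) > 1e-8) ||
      (length(lat) > 2 && max(abs(diff(diff(lat)))) > 1e-8))
    stop("lon/lat must be uniformly spaced")
  dm <- c(length(lon), length(lat), length(time))
  stopifnot(identical(dim(u), dm), identical(dim(v), dm))
  if (is.null(land_mask))
    land_mask <- matrix(FALSE, length(lon), length(lat))
  stopifnot(identical(dim(land_mask), dm[1:2]))
  ocean <- !land_mask
  if (any(!is.finite(u[rep(ocean, length(time))])) ||
      any(!is.finite(v[rep(ocean, length(time))])))
    stop("u/v must be finite on ocean cells")
  structure(list(lon = lon, lat = lat, time = as.Date(time),
                 u = u, v = v, land_mask = land_mask),
            class = "velocity_field")
}

#' Generate a synthetic velocity field
#'
#' Builds the daily u/v forcing on the configured grid from one of several
#' analytic or random prescriptions:
#' \describe{
#'   \item{zero}{u = v = 0 everywhere.}
#'   \item{uniform}{constant \code{params$u}, \code{params$v} (m/s).}
#'   \item{double_gyre}{the classical two-cell recirculation, streamfunction
#'     \eqn{\psi = A \sin(\pi x)\sin(\pi y)} on the grid mapped to
#'     \eqn{[0,2]\times[0,1]}; \eqn{u = -\partial\psi/\partial y},
#'     \eqn{v = \partial\psi/\partial x}. \code{params$A} in m/s.}
#'   \item{solid_rotation}{rigid-body rotation about
#'     (\code{params$lon0}, \code{params$lat0}) at angular speed
#'     \code{params$omega} (rad/s): \eqn{u = -\omega \Delta y},
#'     \eqn{v = \omega \Delta x} with local-metric offsets in metres. A
#'     particle completes one revolution in \eqn{2\pi/\omega} seconds.}
#'   \item{random_smooth}{seeded sum of \code{params$n_modes} low-order
#'     Fourier modes of amplitude \code{params$amplitude} m/s, varying
#'     smoothly in space and from day to day.}
#' }
#'
#' @param config A \code{\link{fixture_config}}.
#' @param kind Field kind, see Details.
#' @param params Named list of field parameters.
#' @param land_polygons Optional list of lon/lat rings; grid nodes inside any
#'   ring are masked as land.
#' @return A \code{\link{velocity_field}}.
#' @export
make_velocity_field <- function(config, kind = c("zero", "uniform",
                                                 "double_gyre",
                                                 "solid_rotation",
                                                 "random_smooth"),
                                params = list(), land_polygons = NULL) {
  kind <- match.arg(kind)
  need <- function(nm) {
    miss <- setdiff(nm, names(params))
    if (length(miss))
      stop("make_velocity_field: missing params for kind '", kind, "': ",
           paste(miss, collapse = ", "))
  }
  ext <- config$grid_extent
  lon <- seq(ext[1], ext[2], by = config$grid_step)
  lat <- seq(ext[3], ext[4], by = config$grid_step)
  time <- config$origin + seq_len(config$n_days) - 1L
  nl <- length(lon); nm <- length(lat); nt <- length(time)

  grid_uv <- switch(kind,
    zero = list(u = matrix(0, nl, nm), v = matrix(0, nl, nm)),
    uniform = {
      need(c("u", "v"))
      list(u = matrix(params$u, nl, nm), v = matrix(params$v, nl, nm))
    },
    double_gyre = {
      need("A")
      x <- 2 * (lon - ext[1]) / (ext[2] - ext[1])
      y <- (lat - ext[3]) / (ext[4] - ext[3])
      A <- params$A
      list(u = outer(x, y, function(x, y) -pi * A * sin(pi * x) * cos(pi * y)),
           v = outer(x, y, function(x, y)  pi * A * cos(pi * x) * sin(pi * y)))
    },
    solid_rotation = {
      need(c("lon0", "lat0", "omega"))
      dx <- outer(lon - params$lon0, cos(lat * pi / 180),
                  function(dl, cl) dl * pi / 180 * EARTH_RADIUS_M * cl)
      dy <- matrix((lat - params$lat0) * pi / 180 * EARTH_RADIUS_M,
                   nl, nm, byrow = TRUE)
      list(u = -params$omega * dy, v = params$omega * dx)
    },
    random_smooth = NULL)

  if (kind == "random_smooth") {
    amp <- if (is.null(params$amplitude)) 0.1 else params$amplitude
    nmodes <- if (is.null(params$n_modes)) 3L else params$n_modes
    u <- array(0, c(nl, nm, nt)); v <- array(0, c(nl, nm, nt))
    with_seed(fixture_seed(config, "velocity"), {
      xs <- (lon - ext[1]) / (ext[2] - ext[1])
      ys <- (lat - ext[3]) / (ext[4] - ext[3])
      for (comp in 1:2) {
        fld <- array(0, c(nl, nm, nt))
        for (m in seq_len(nmodes)) {
          kx <- sample(1:3, 1); ky <- sample(1:3, 1)
          phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
          pht <- runif(1, 0, 2 * pi)
          a <- rnorm(1, 0, amp / sqrt(nmodes))
          sp <- outer(sin(kx * pi * xs + phx), sin(ky * pi * ys + phy))
          tmod <- cos(2 * pi * seq_len(nt) / max(nt, 2) + pht)
          for (k in seq_len(nt)) fld[, , k] <- fld[, , k] + a * sp * tmod[k]
        }
        if (comp == 1) u <- fld else v <- fld
      }
    })
  } else {
    u <- array(rep(grid_uv$u, nt), c(nl, nm, nt))
    v <- array(rep(grid_uv$v, nt), c(nl, nm, nt))
  }

  mask <- matrix(FALSE, nl, nm)
  if (!is.null(land_polygons)) {
    pts <- expand.grid(lon = lon, lat = lat)
    for (ring in land_polygons)
      mask <- mask | matrix(point_in_ring(pts$lon, pts$lat, ring), nl, nm)
    u[rep(mask, nt)] <- NA_real_
    v[rep(mask, nt)] <- NA_real_
  }
  velocity_field(lon, lat, time, u, v, mask)
}

#' Write a velocity field as plain-text gridded CSV
#'
#' One long-format CSV: columns \code{time} (ISO date), \code{lon},
#' \code{lat}, \code{u}, \code{v}; land cells carry \code{NA}. The regular
#' grid is reconstructed from the coordinate columns on reading.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param path Output CSV path.
#' @export
write_velocity_field <- function(field, path) {
  g <- expand.grid(lon = field$lon, lat = field$lat,
                   time = format(field$time), stringsAsFactors = FALSE)
  df <- data.frame(time = g$time, lon = g$lon, lat = g$lat,
                   u = as.vector(field$u), v = as.vector(field$v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a velocity field written by \code{\link{write_velocity_field}}
#' @param path CSV path.
#' @return A \code{\link{velocity_field}}.
#' @export
read_velocity_field <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  time <- as.Date(sort(unique(df$time)))
  dm <- c(length(lon), length(lat), length(time))
  o <- order(match(df$time, format(time)), match(df$lat, lat),
             match(df$lon, lon))
  u <- array(df$u[o], dm); v <- array(df$v[o], dm)
  mask <- apply(is.na(u), c(1, 2), all)
  velocity_field(lon, lat, time, u, v, mask)
}
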