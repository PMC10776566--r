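test_that("bilinear interpolation honours node identity and hand values", {
  cfg <- tiny_config()
  f <- make_velocity_field(cfg, "random_smooth", list(amplitude = 0.2))
  # exact node queries return the node values
  for (idx in list(c(1, 1), c(7, 13), c(51, 51))) {
    s <- interpolate_velocity(f, f$lon[idx[1]], f$lat[idx[2]], 0)
    expect_equal(s$u, f$u[idx[1], idx[2], 1])
    expect_equal(s$v, f$v[idx[1], idx[2], 1])
  }
  fu <- make_velocity_field(cfg, "uniform", list(u = 0.1, v = 0))
  s <- interpolate_velocity(fu, -1.234, 0.567, 12.3)
  expect_equal(c(s$u, s$v), c(0.1, 0))

  # hand-built 2x2 stencil with u = {0, 0, 1, 1}: midpoint reads 0.5
  lon <- c(0, 1); lat <- c(0, 1)
  u <- array(c(0, 0, 1, 1), c(2, 2, 1))       # u varies along lat
  v <- array(0, c(2, 2, 1))
  fh <- velocity_field(lon, lat, as.Date("2008-01-01"), u, v)
  expect_equal(interpolate_velocity(fh, 0.5, 0.5, 0)$u, 0.5)

  expect_equal(interpolate_velocity(fu, 10, 0, 0)$status, "outside")
})

test_that("interpolation excludes land nodes and flags all-land stencils", {
  lon <- c(0, 1); lat <- c(0, 1)
  u <- array(c(1, NA, 1, NA), c(2, 2, 1))
  v <- array(0, c(2, 2, 1))
  mask <- matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2)
  f <- velocity_field(lon, lat, as.Date("2008-01-01"), u, v, mask)
  s <- interpolate_velocity(f, 0.5, 0.5, 0)
  expect_equal(s$status, "ok")
  expect_equal(s$u, 1)    # land nodes dropped, renormalised
  fall <- velocity_field(lon, lat, as.Date("2008-01-01"),
                         array(NA_real_, c(2, 2, 1)),
                         array(NA_real_, c(2, 2, 1)),
                         matrix(TRUE, 2, 2))
  expect_equal(interpolate_velocity(fall, 0.5, 0.5, 0)$status, "land")
})

test_that("advection reproduces speed x time and the zero-field identity", {
  cfg <- tiny_config()
  f <- make_velocity_field(cfg, "uniform", list(u = 0.1, v = 0))
  site <- square_site("A", 0, 0, field = f)
  p <- advect(f, site, as.Date("2008-01-05"), release_lonlat = c(0, 0),
              max_days = 1)
  expect_equal(p$dispersal_km, 8.64, tolerance = 0.1)
  expect_equal(p$fate, "expired")

  fz <- make_velocity_field(cfg, "zero")
  pz <- advect(fz, site, as.Date("2008-01-05"), release_lonlat = c(0, 0),
               max_days = 2)
  expect_equal(pz$dispersal_km, 0)
  expect_equal(pz$fate, "expired")

  expect_error(advect(f, site, as.Date("2030-01-01"),
                      release_lonlat = c(0, 0)), "coverage")
})

test_that("a particle crossing a downstream settlement polygon settles at first entry", {
  cfg <- tiny_config()
  f <- make_velocity_field(cfg, "uniform", list(u = 0.2, v = 0))
  src <- square_site("src", 0, 0, half = 0.05, field = f, buffer_km = 2)
  dst <- square_site("dst", 0.5, 0, half = 0.05, field = f, buffer_km = 2)
  p <- advect(f, src, as.Date("2008-01-03"), release_lonlat = c(0, 0),
              max_days = 10, sites_all = list(src, dst))
  expect_equal(p$fate, "settled")
  expect_equal(p$settle_site, "dst")
  # fine-step reference integration agrees on the entry hour: uniform flow,
  # entry when x(t) crosses the buffered west edge of dst
  west_edge_deg <- min(dst$settlement_polygon[, 1])
  deg_per_h <- 0.2 * 3600 / (meagreflow:::EARTH_RADIUS_M * pi / 180)
  entry_hour <- ceiling(west_edge_deg / deg_per_h)
  expect_equal(p$hours, entry_hour)
})

test_that("beaching and open-ocean loss are detected", {
  cfg <- tiny_config(grid_extent = c(-1, 1, -1, 1))
  land <- list(square_ring(0.6, 0, 0.35))
  f <- make_velocity_field(cfg, "uniform", list(u = 0.5, v = 0),
                           land_polygons = land)
  site <- square_site("A", -0.5, 0, half = 0.05, field = f, buffer_km = 2)
  p <- advect(f, site, as.Date("2008-01-03"), release_lonlat = c(-0.5, 0),
              max_days = 10)
  expect_equal(p$fate, "beached")

  f2 <- make_velocity_field(cfg, "uniform", list(u = 1.0, v = 0))
  p2 <- advect(f2, site, as.Date("2008-01-03"), release_lonlat = c(-0.5, 0),
               max_days = 30)
  expect_equal(p2$fate, "lost_open_ocean")
})

test_that("release design counting is exact", {
  cfg <- tiny_config(n_days = 40)
  fz <- make_velocity_field(cfg, "zero")
  # 1 site restricted to 1 cell x 10-day season x 1 year x 1/day
  s1 <- spawning_site("one", square_ring(0, 0, 0.02), c(1, 10),
                      release_cell_km = 10, field = fz)
  expect_equal(nrow(s1$release_cells), 1)
  tr <- run_simulation(fz, list(s1), years = 2008, release_per_day = 1,
                       max_days = 1)
  expect_length(tr$particles, 10)
  expect_true(all(as.data.frame(tr)$fate == "expired"))
  expect_true(all(as.data.frame(tr)$dispersal_km == 0))

  # 2 sites x 5 days x 2/day (cells fixed by construction)
  s2 <- spawning_site("two", square_ring(1, 1, 0.02), c(3, 7),
                      release_cell_km = 10, field = fz)
  s3 <- spawning_site("three", square_ring(-1, -1, 0.02), c(3, 7),
                      release_cell_km = 10, field = fz)
  tr2 <- run_simulation(fz, list(s2, s3), years = 2008,
                        release_per_day = 2, max_days = 1)
  expect_length(tr2$particles, 2 * 1 * 5 * 2)

  expect_error(run_simulation(fz, list(s1), years = 2009),
               "coverage")
})

test_that("fates partition releases and connectivity rows are sub-stochastic", {
  cfg <- tiny_config(seed = 21)
  land <- list(square_ring(1.2, 0.5, 0.3))
  f <- make_velocity_field(cfg, "random_smooth", list(amplitude = 0.6),
                           land_polygons = land)
  sA <- square_site("A", -0.5, -0.5, half = 0.08, season = c(1, 4),
                    field = f)
  sB <- square_site("B", 0.5, 0.5, half = 0.08, season = c(1, 4),
                    field = f)
  tr <- run_simulation(f, list(sA, sB), release_per_day = 1, max_days = 8)
  df <- as.data.frame(tr)
  fc <- fate_counts(tr)
  for (s in c("A", "B"))
    expect_equal(sum(fc[s, ]), sum(df$source == s))
  expect_true(all(df$fate %in% c("settled", "beached", "lost_open_ocean",
                                 "expired")))
  expect_true(all((df$fate == "settled") == !is.na(df$settle_site)))

  cm <- connectivity_matrix(tr, list(sA, sB))
  expect_true(all(rowSums(cm$P) <= 1 + 1e-12))
  expect_true(all(cm$P >= 0 & cm$P <= 1))
  # settled proportions match the matrix entries
  expect_equal(cm$P["A", "B"],
               sum(df$source == "A" & df$fate == "settled" &
                     df$settle_site == "B") / sum(df$source == "A"))

  # zero-release row is undefined, not 0/0
  cm2 <- connectivity_matrix(tr, c("A", "B", "C"))
  expect_true(all(is.na(cm2$P["C", ])))
})

test_that("halving the step changes smooth-field endpoints by < 1 km", {
  cfg <- tiny_config()
  f <- make_velocity_field(cfg, "double_gyre", list(A = 0.3))
  site <- square_site("A", -1, -1, half = 0.05, field = f)
  p1 <- advect(f, site, as.Date("2008-01-03"), release_lonlat = c(-1, -1),
               step_h = 1, max_days = 5, method = "rk4")
  p2 <- advect(f, site, as.Date("2008-01-03"), release_lonlat = c(-1, -1),
               step_h = 0.5, max_days = 5, method = "rk4")
  expect_lt(haversine_km(p1$position[1], p1$position[2],
                         p2$position[1], p2$position[2]), 1)
})

test_that("solid rotation returns the particle after one period", {
  cfg <- tiny_config()
  period_days <- 10
  om <- 2 * pi / (period_days * 86400)
  f <- make_velocity_field(cfg, "solid_rotation",
                           list(lon0 = 0, lat0 = 0, omega = om))
  # site polygon sits at the rotation centre, well inside the 22 km orbit,
  # so the particle can complete its revolution without settling
  site <- square_site("A", 0, 0, half = 0.1, field = f)
  p <- advect(f, site, as.Date("2008-01-02"), release_lonlat = c(0.2, 0),
              max_days = period_days, method = "rk4")
  circumference <- 2 * pi * haversine_km(0, 0, 0.2, 0)
  ret <- haversine_km(0.2, 0, p$position[1], p$position[2])
  expect_lt(ret, 0.01 * circumference)
})

test_that("dispersal statistics match closed forms", {
  df1 <- data.frame(source = "A", fate = "expired",
                    settle_site = NA_character_, dispersal_km = 10)
  st1 <- dispersal_stats(df1, by_site = FALSE)
  expect_equal(st1$mean_km, 10)
  expect_equal(st1$sd_km, NA_real_)
  expect_equal(st1$max_km, 10)

  df3 <- data.frame(source = "A", fate = "expired",
                    settle_site = NA_character_, dispersal_km = c(1, 2, 3))
  st3 <- dispersal_stats(df3, by_site = FALSE)
  expect_equal(st3$mean_km, 2)
  expect_equal(st3$max_km, 3)

  # q95 of a half-normal against its analytic quantile
  sigma <- 30
  x <- abs(stats::qnorm(stats::ppoints(10000))) * sigma  # stratified draw
  dfh <- data.frame(source = "A", fate = "expired",
                    settle_site = NA_character_, dispersal_km = x)
  q95_true <- sigma * stats::qnorm(1 - 0.05 / 2)
  expect_equal(dispersal_stats(dfh, by_site = FALSE)$q95_km, q95_true,
               tolerance = 0.02)

  expect_error(dispersal_stats(df1[0, ]), "no particles")
})
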