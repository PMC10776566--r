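test_that("analytic field kinds match their closed forms at grid nodes", {
  cfg <- tiny_config()
  fz <- make_velocity_field(cfg, "zero")
  expect_true(all(fz$u == 0) && all(fz$v == 0))

  fu <- make_velocity_field(cfg, "uniform", list(u = 0.1, v = -0.05))
  expect_true(all(fu$u == 0.1) && all(fu$v == -0.05))

  # double gyre: compare against numerical differentiation of the
  # streamfunction (independent oracle for the analytic derivatives)
  A <- 0.3
  fg <- make_velocity_field(cfg, "double_gyre", list(A = A))
  ext <- cfg$grid_extent
  psi <- function(lon, lat) {
    x <- 2 * (lon - ext[1]) / (ext[2] - ext[1])
    y <- (lat - ext[3]) / (ext[4] - ext[3])
    A * sin(pi * x) * sin(pi * y)
  }
  h <- 1e-5
  for (idx in list(c(3, 5), c(10, 20), c(25, 40))) {
    lon0 <- fg$lon[idx[1]]; lat0 <- fg$lat[idx[2]]
    # d/dy in mapped units: lat span maps to [0,1]
    dpsidy <- (psi(lon0, lat0 + h) - psi(lon0, lat0 - h)) / (2 * h) *
      (ext[4] - ext[3])
    dpsidx <- (psi(lon0 + h, lat0) - psi(lon0 - h, lat0)) / (2 * h) *
      (ext[2] - ext[1]) / 2
    expect_equal(fg$u[idx[1], idx[2], 1], -dpsidy, tolerance = 1e-6)
    expect_equal(fg$v[idx[1], idx[2], 1], dpsidx, tolerance = 1e-6)
  }

  expect_error(make_velocity_field(cfg, "warp"), "arg")
  expect_error(make_velocity_field(cfg, "uniform", list(u = 0.1)),
               "missing params")
})

test_that("land polygons mask grid nodes and fixtures are seed-reproducible", {
  cfg <- tiny_config(seed = 5)
  land <- list(square_ring(1, 1, 0.5))
  f1 <- make_velocity_field(cfg, "random_smooth",
                            list(amplitude = 0.2, n_modes = 2),
                            land_polygons = land)
  f2 <- make_velocity_field(cfg, "random_smooth",
                            list(amplitude = 0.2, n_modes = 2),
                            land_polygons = land)
  expect_identical(f1$u, f2$u)
  expect_true(any(f1$land_mask))
  expect_true(all(is.na(f1$u[, , 1][f1$land_mask])))
  # inside the masked square
  i <- which.min(abs(f1$lon - 1)); j <- which.min(abs(f1$lat - 1))
  expect_true(f1$land_mask[i, j])

  gd1 <- make_genotypes(tiny_config(seed = 9, n_loci = 50))
  gd2 <- make_genotypes(tiny_config(seed = 9, n_loci = 50))
  expect_identical(gd1$dosage, gd2$dosage)
})

test_that("Balding-Nichols generator honours the F -> 0 limit and Beta variance", {
  cfg0 <- tiny_config(n_pops = 3, n_loci = 60, fst_target = 0)
  gd0 <- make_genotypes(cfg0)
  pk <- attr(gd0, "subpop_freq")
  expect_equal(pk[1, ], attr(gd0, "ancestral_freq"))
  expect_equal(pk[2, ], pk[3, ])

  # Var[p_k] = F p (1 - p): check by simulation at fixed ancestral p
  FF <- 0.2
  vars <- vapply(1:30, function(s) {
    cfg <- fixture_config(seed = s, n_pops = 2, n_loci = 400,
                          fst_target = FF,
                          ancestral_maf_range = c(0.3999, 0.4001))
    pk <- attr(make_genotypes(cfg), "subpop_freq")
    mean((pk - 0.4)^2)
  }, numeric(1))
  expect_equal(mean(vars), FF * 0.4 * 0.6, tolerance = 0.03)
})

test_that("genotype generator recovers the target F_ST (estimator oracle)", {
  th <- vapply(1:20, function(s) {
    cfg <- fixture_config(seed = 100 + s, n_pops = 2, n_loci = 1000,
                          n_ind_per_pop = 50, fst_target = 0.1)
    fst_wc(make_genotypes(cfg), "pop1", "pop2")$theta
  }, numeric(1))
  expect_lt(abs(mean(th) - 0.1), 0.02)
})

test_that("haplotype fixtures record their mutation structure truthfully", {
  cfg <- tiny_config(seed = 4)
  expect_error(make_haplotypes(cfg, 4, 2, matrix(0.25, 1, 4), 10),
               "seq_len")
  expect_error(make_haplotypes(cfg, 2, 10, matrix(c(0.6, 0.6), 1, 2), 10),
               "sum to 1")

  a1 <- make_haplotypes(cfg, 1, 20, matrix(1, 2, 1), c(5, 5))
  expect_length(unique(a1$sequences), 1)

  a2 <- make_haplotypes(cfg, 2, 20, matrix(c(0.5, 0.5), 1, 2), 10)
  hs <- attr(a2, "haplotype_seqs")
  expect_equal(meagreflow:::hamming_dist(hs[1], hs[2]), 1)

  # star genealogy of 4 haplotypes around one ancestor
  a4 <- make_haplotypes(cfg, 4, 30, matrix(0.25, 1, 4), 20)
  g <- attr(a4, "mutation_graph")
  expect_equal(g$from, rep(1L, 3))
  expect_equal(sort(g$to), 2:4)
  hs <- attr(a4, "haplotype_seqs")
  for (h in 2:4) expect_equal(meagreflow:::hamming_dist(hs[1], hs[h]), 1)
  expect_equal(meagreflow:::hamming_dist(hs[2], hs[3]), 2)
  # per-locality counts honoured
  expect_equal(length(a4$sequences), 20)
})

test_that("synthetic tracks respect waypoints and spherical geometry", {
  cfg <- tiny_config()
  t1 <- make_track(cfg, cbind(0, 0), as.POSIXct("2020-01-01", tz = "UTC"))
  expect_equal(track_distances(t1)$cumulative_km, 0)

  tms <- as.POSIXct("2020-01-01", tz = "UTC") + c(0, 3600)
  t2 <- make_track(cfg, rbind(c(0, 0), c(1, 0)), tms)
  expect_equal(track_distances(t2)$cumulative_km, 111.19, tolerance = 0.1)

  # noiseless 3-point track equals the leg-sum oracle
  wp <- rbind(c(0, 0), c(0.5, 0.3), c(1.2, -0.2))
  t3 <- make_track(cfg, wp, as.POSIXct("2020-01-01", tz = "UTC") +
                     c(0, 3600, 7200))
  legsum <- haversine_km(wp[1, 1], wp[1, 2], wp[2, 1], wp[2, 2]) +
    haversine_km(wp[2, 1], wp[2, 2], wp[3, 1], wp[3, 2])
  expect_equal(track_distances(t3)$cumulative_km, legsum)

  expect_error(make_track(cfg, rbind(c(0, 0), c(1, 0)), rev(tms)),
               "strictly increasing")
})

test_that("fixture round-trips through the text formats are faithful", {
  cfg <- tiny_config(seed = 2, grid_extent = c(-1, 0, 0, 1), n_days = 3)
  f <- make_velocity_field(cfg, "random_smooth", list(amplitude = 0.1),
                           land_polygons = list(square_ring(-0.5, 0.5, 0.2)))
  pth <- tempfile(fileext = ".csv")
  write_velocity_field(f, pth)
  f2 <- read_velocity_field(pth)
  expect_equal(f2$u, f$u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f2$land_mask, f$land_mask, ignore_attr = TRUE)
  expect_equal(f2$time, f$time)

  gd <- make_genotypes(tiny_config(seed = 3, n_loci = 30,
                                   missing_rate = 0.05))
  tsv <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(gd, tsv)
  gd2 <- read_genotypes_tsv(tsv)
  expect_equal(unname(gd2$dosage), unname(gd$dosage))
  expect_equal(gd2$locality, gd$locality)

  vcf <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(gd, vcf)
  gd3 <- read_genotypes_vcf(vcf, stats::setNames(gd$locality, gd$ind_id))
  expect_equal(unname(gd3$dosage), unname(gd$dosage))
  # cross-check the VCF dialect with an independent reader
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- t(apply(gt, 1, function(x)
    ifelse(x == "./.", NA_integer_,
           (substr(x, 1, 1) == "1") + (substr(x, 3, 3) == "1"))))
  expect_equal(unname(t(dos)), unname(gd$dosage))

  aln <- make_haplotypes(tiny_config(seed = 6), 3, 25,
                         matrix(c(0.5, 0.3, 0.2), 1, 3), 12)
  fa <- tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, fa)
  aln2 <- read_alignment_fasta(fa)
  expect_equal(aln2$sequences, aln$sequences)
  expect_equal(aln2$locality, aln$locality)

  trk <- make_track(tiny_config(), rbind(c(0, 0), c(1, 1)),
                    as.POSIXct("2020-06-01", tz = "UTC") + c(0, 86400))
  tcsv <- tempfile(fileext = ".csv")
  write_tracks_csv(list(trk), tcsv)
  trk2 <- read_tracks_csv(tcsv)[[1]]
  expect_equal(trk2$records$lon, trk$records$lon)
  expect_equal(trk2$records$time, trk$records$time)
})
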