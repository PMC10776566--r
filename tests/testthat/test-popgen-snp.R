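test_that("locus filters remove exactly the constructed failures", {
  # locus with 10/100 missing at threshold 0.95 is removed
  d <- matrix(1L, 100, 2)
  d[1:10, 1] <- NA
  gd <- genotype_dataset(d, rep("p1", 100))
  # both loci fail MAF (all-het -> maf 0.5 passes); make locus 2 pass all
  d2 <- cbind(d, rep(c(0L, 1L, 2L, 1L), 25))
  gd <- genotype_dataset(d2, rep("p1", 100))
  f <- filter_loci(gd, min_call_rate = 0.95, min_maf = 0.05)
  expect_equal(unname(f$removed["call_rate"]), 1)
  expect_false("L1" %in% f$data$locus_id)

  # pooled MAF 0.04 at min_maf 0.05 is removed
  d3 <- matrix(0L, 50, 1); d3[1:4, 1] <- 1L   # maf = 4/100 = 0.04
  gd3 <- genotype_dataset(d3, rep("p1", 50))
  expect_equal(suppressWarnings(filter_loci(gd3, min_maf = 0.05))$kept, 0)

  # 10-locus panel, 3 constructed failures, fixed filter order
  set.seed(42)
  base <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10)
  base[1:3, 1] <- NA                      # call rate 0.85 -> fails
  base[, 2] <- 0L; base[1, 2] <- 1L       # maf 1/40 -> fails
  repro <- rep(1, 10); repro[3] <- 0.9    # fails reproducibility
  gd10 <- genotype_dataset(base, rep("p1", 20), reproducibility = repro)
  f10 <- filter_loci(gd10, min_call_rate = 0.95, min_maf = 0.05,
                     min_reproducibility = 0.95)
  expect_equal(unname(f10$removed), c(1, 1, 1))
  expect_equal(f10$kept, 7)

  # idempotence: filtering a filtered dataset removes nothing
  f_again <- filter_loci(f10$data, 0.95, 0.05, 0.95)
  expect_equal(unname(f_again$removed), c(0, 0, 0))
  expect_equal(f_again$kept, 7)

  expect_warning(filter_loci(gd3, min_maf = 0.5), "all loci removed")
})

test_that("failed-sample exclusion reports per-locality sizes", {
  sizes <- c(Gironde = 12, Tejo = 23, Algarve = 12, Guadalquivir = 16,
             BancArguin = 17, Senegal = 7)
  set.seed(7)
  n <- sum(sizes)
  d <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  gd <- genotype_dataset(d, rep(names(sizes), sizes))
  ex <- exclude_failed_samples(gd, max_missing_per_ind = 0.2)
  expect_equal(length(ex$dropped), 0)
  expect_equal(sum(ex$n_by_locality), 87)
  expect_equal(as.numeric(ex$n_by_locality[names(sizes)]),
               unname(sizes))

  d[1, ] <- NA                            # fully missing individual
  gd2 <- genotype_dataset(d, rep(names(sizes), sizes))
  ex2 <- exclude_failed_samples(gd2, 0.5)
  expect_equal(length(ex2$dropped), 1)
  expect_equal(sum(ex2$n_by_locality), 86)
})

test_that("diversity indices match closed forms and exhaustive rarefaction", {
  # monomorphic locus: Na=1, Ar=1, Ho=0, He=0
  gd_mono <- genotype_dataset(matrix(0L, 10, 1), rep("p1", 10))
  dv <- diversity(gd_mono, rarefaction_g = 4)
  expect_equal(dv$Na, 1)
  expect_equal(dv$Ar, 1)
  expect_equal(dv$Ho, 0)
  expect_equal(dv$He, 0)
  expect_equal(dv$prop_polymorphic, 0)

  # everyone heterozygous: Ho = 1
  gd_het <- genotype_dataset(matrix(1L, 8, 1), rep("p1", 8))
  expect_equal(diversity(gd_het, 4)$Ho, 1)

  # rarefied richness equals the mean allele count over all C(N, g)
  # subsamples, enumerated exhaustively (N = 8 copies, minor count 3, g = 4)
  g <- 4
  copies <- c(rep(1, 3), rep(0, 5))
  subs <- utils::combn(8, g)
  n_alleles <- apply(subs, 2, function(ix) length(unique(copies[ix])))
  # dosage realising these copies: 4 individuals = pairs of copies
  d <- matrix(c(1L, 1L, 1L, 0L), 4, 1)   # 3 minor copies among 8
  gd_r <- genotype_dataset(d, rep("p1", 4))
  expect_equal(diversity(gd_r, rarefaction_g = g)$Ar, mean(n_alleles))
})

test_that("HWE exact test agrees with exhaustive enumeration", {
  for (cfg in list(c(25, 50, 25), c(5, 2, 8), c(3, 9, 1), c(0, 4, 8),
                   c(7, 0, 7))) {
    got <- hwe_exact_test(cfg[1], cfg[2], cfg[3])
    oracle <- hwe_enum_oracle(cfg[1], cfg[2], cfg[3])
    expect_equal(got$p, oracle$p_two, tolerance = 1e-10)
    expect_equal(got$p_deficiency, oracle$p_def, tolerance = 1e-10)
  }
  # modal configuration has p = 1 within tolerance
  expect_equal(hwe_exact_test(25, 50, 25)$p, 1, tolerance = 1e-9)
  # extreme heterozygote deficiency
  r <- hwe_exact_test(50, 0, 50)
  expect_lt(r$p, 1e-10)
  expect_true(r$het_deficiency)
  # monomorphic: p = 1
  expect_equal(hwe_exact_test(10, 0, 0)$p, 1)
  # fewer than 2 genotypes: undefined
  expect_true(is.na(hwe_exact_test(1, 0, 0)$p))

  # dataset-level driver covers loci x localities
  gd <- gd_from_blocks(matrix(c(0L, 1L, 2L, 1L), 4, 2),
                       matrix(c(2L, 2L, 1L, 0L), 4, 2))
  h <- hwe_exact(gd)
  expect_equal(nrow(h), 2 * 2)
})

test_that("LD exact test flags perfect association and ignores monomorphism", {
  set.seed(11)
  g1 <- rbinom(60, 2, 0.5)
  gd <- genotype_dataset(cbind(g1, g1, 0L), rep("p1", 60))
  res <- ld_pairwise(gd, pairs = rbind(c(1, 2)))
  expect_lt(res$p, 1e-6)                 # locus against itself
  res2 <- ld_pairwise(gd, pairs = rbind(c(1, 3)))
  expect_equal(res2$p, 1)                # vs monomorphic locus
})

test_that("LD exact test type-I rate is conservative-correct at alpha 0.01", {
  # independently simulated loci at equilibrium; Fisher's exact test is
  # discrete, hence at or below the nominal level
  set.seed(99)
  n_pairs <- 600
  d <- matrix(rbinom(100 * 2 * n_pairs, 2, 0.4), 100)
  gd <- genotype_dataset(d, rep("p1", 100))
  pairs <- cbind(seq(1, 2 * n_pairs, 2), seq(2, 2 * n_pairs, 2))
  res <- ld_pairwise(gd, pairs = pairs)
  rate <- mean(res$p < 0.01)
  upper <- 0.01 + 1.96 * sqrt(0.01 * 0.99 / n_pairs)
  expect_lte(rate, upper)
  expect_gte(rate, 0)
})

test_that("Weir-Cockerham theta matches the hand-computed fixture", {
  pop1 <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 2, 1), c(2, 2, 0))
  pop2 <- rbind(c(2, 0, 0), c(2, 1, 0), c(1, 0, 0), c(2, 1, 0))
  gd <- gd_from_blocks(pop1, pop2)
  r <- fst_wc(gd, "pop1", "pop2")
  # frozen from an explicit scalar evaluation of the variance components
  expect_equal(r$components$a,
               c(0.0842857143, 0.0307142857, -0.0014285714),
               tolerance = 1e-9)
  expect_equal(r$components$b,
               c(0.0434523810, 0.0246031746, 0.0007936508),
               tolerance = 1e-9)
  expect_equal(r$components$c,
               c(0.1666666667, 0.2222222222, 0.0555555556),
               tolerance = 1e-9)
  expect_equal(r$theta, 0.1811736406, tolerance = 1e-9)
})

test_that("theta null, maximal and invariance properties hold", {
  set.seed(5)
  block <- matrix(rbinom(100 * 50, 2, runif(50, 0.1, 0.9)), 100, 50,
                  byrow = TRUE)
  gd_dup <- gd_from_blocks(block, block)     # pop duplicated -> theta ~ 0
  expect_lt(abs(fst_wc(gd_dup, "pop1", "pop2")$theta), 0.01)

  gd_fix <- gd_from_blocks(matrix(0L, 10, 5), matrix(2L, 10, 5))
  expect_equal(fst_wc(gd_fix, "pop1", "pop2")$theta, 1)

  # allele-label swap at every locus leaves theta unchanged
  other <- matrix(rbinom(100 * 50, 2, 0.3), 100, 50)
  gd_a <- gd_from_blocks(block, other)
  gd_b <- gd_from_blocks(2L - block, 2L - other)
  expect_equal(fst_wc(gd_a, "pop1", "pop2")$theta,
               fst_wc(gd_b, "pop1", "pop2")$theta, tolerance = 1e-12)

  # permutation p is small for clearly differentiated pops
  cfg <- tiny_config(seed = 31, n_pops = 2, n_loci = 100,
                     n_ind_per_pop = 20, fst_target = 0.2)
  gd <- make_genotypes(cfg)
  r <- fst_wc(gd, "pop1", "pop2", n_perm = 99, seed = 1)
  expect_equal(r$p, 1 / 100)

  expect_error(fst_wc(gd_a, "pop1", "nope"), "localities")
})

test_that("standardised F_ST follows the maximal-differentiation bound", {
  expect_equal(fst_standardised(0, 0.3), 0)
  expect_equal(fst_standardised(0.4, 0), 0.4)     # theta_max = 1 at hs = 0
  expect_equal(fst_standardised(0.05, 0.3, k = 2),
               0.05 * (1 + 0.3) / (1 - 0.3))
  expect_true(is.na(fst_standardised(0.1, 1)))
  # transect driver returns one row per adjacent pair
  cfg <- tiny_config(seed = 13, n_pops = 3, n_loci = 150,
                     n_ind_per_pop = 15, fst_target = 0.1)
  gd <- make_genotypes(cfg)
  tr <- fst_transect(gd, c("pop1", "pop2", "pop3"), c(0, 100, 250))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$midpoint, c(50, 175))
  expect_true(all(tr$theta_std >= tr$theta - 1e-12))
})

test_that("Mantel statistic and permutation behave as a simple Mantel test", {
  set.seed(3)
  k <- 6
  M <- matrix(0, k, k); M[upper.tri(M)] <- runif(15, 1, 10)
  M <- M + t(M)
  dimnames(M) <- list(letters[1:k], letters[1:k])
  r <- ibd_mantel(M, M, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 100)

  Mneg <- max(M) - M; diag(Mneg) <- 0
  expect_equal(ibd_mantel(M, Mneg, n_perm = 99, seed = 1)$r, -1)

  # r agrees with an independent implementation
  G <- matrix(0, k, k); G[upper.tri(G)] <- runif(15, 1, 5)
  G <- G + t(G); dimnames(G) <- dimnames(M)
  r2 <- ibd_mantel(M, G, n_perm = 99, seed = 1)
  vg <- vegan::mantel(stats::as.dist(M), stats::as.dist(G),
                      permutations = 0)
  expect_equal(r2$r, unname(vg$statistic), tolerance = 1e-12)

  # r invariant under joint relabelling of both matrices
  pm <- sample(k)
  expect_equal(ibd_mantel(M[pm, pm], G[pm, pm], n_perm = 9, seed = 1)$r,
               r2$r, tolerance = 1e-12)

  expect_error(ibd_mantel(M[1:2, 1:2], G[1:2, 1:2]), "fewer than 3")
})

test_that("geographic distances use the stated projections", {
  co <- rbind(a = c(0, 0), b = c(1, 0))
  expect_equal(geo_distance_matrix(co)["a", "b"], 111.19, tolerance = 1e-6)
  expect_equal(geo_distance_matrix(co, "greatcircle")["a", "b"], 111.19,
               tolerance = 0.1)
})

test_that("the outlier scan recovers a spiked locus and enforces preconditions", {
  cfg <- tiny_config(seed = 17, n_pops = 2, n_loci = 120,
                     n_ind_per_pop = 25, fst_target = 0.05)
  gd <- make_genotypes(cfg)
  d <- gd$dosage
  d[, 1] <- rep(c(0L, 2L), c(25, 25))     # fixed difference at locus 1
  gd_spiked <- genotype_dataset(d, gd$locality)
  res <- outlier_scan(gd_spiked, n_perm = 99, seed = 2)
  expect_equal(res$p[1], min(res$p, na.rm = TRUE))
  expect_equal(res$p[1], 1 / 100)         # minimal attainable p
  expect_equal(res$q[1], min(res$q, na.rm = TRUE))

  gd_one <- genotype_dataset(d[1:25, , drop = FALSE], rep("p1", 25))
  expect_error(outlier_scan(gd_one), ">= 2 localities")
})
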