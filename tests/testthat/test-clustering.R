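test_that("admixture sampler honours K = 1 and membership constraints", {
  cfg <- tiny_config(seed = 2, n_loci = 40, n_ind_per_pop = 10)
  gd <- make_genotypes(cfg)
  f1 <- admixture_fit(gd, 1, iters = 50, burnin = 10, seed = 1)
  expect_true(all(f1$Q == 1))
  expect_equal(ncol(f1$Q), 1)
  expect_length(f1$loglik_trace, 50)

  f2 <- admixture_fit(gd, 2, iters = 200, burnin = 50, seed = 1)
  expect_equal(unname(rowSums(f2$Q)), rep(1, nrow(gd$dosage)),
               tolerance = 1e-9)
  expect_true(all(f2$Q >= 0))
  expect_length(f2$loglik_trace, 200)

  expect_error(admixture_fit(gd, 50, iters = 10, burnin = 1), "exceed")
  expect_error(admixture_fit(gd, 2, iters = 10, burnin = 20))
})

test_that("duplicated individuals receive exchangeable memberships", {
  cfg <- tiny_config(seed = 6, n_pops = 2, n_loci = 100,
                     n_ind_per_pop = 10, fst_target = 0.25)
  gd <- make_genotypes(cfg)
  dup <- genotype_dataset(rbind(gd$dosage, gd$dosage),
                          c(gd$locality, gd$locality))
  f <- admixture_fit(dup, 2, iters = 1500, burnin = 500, seed = 3)
  n <- nrow(gd$dosage)
  expect_equal(f$Q[1:n, ], f$Q[(n + 1):(2 * n), ], tolerance = 0.08,
               ignore_attr = TRUE)
})

test_that("the sampler improves on its random initial state in recovery fixtures", {
  cfg <- tiny_config(seed = 12, n_pops = 2, n_loci = 150,
                     n_ind_per_pop = 15, fst_target = 0.25)
  gd <- make_genotypes(cfg)
  f <- admixture_fit(gd, 2, iters = 800, burnin = 200, seed = 5)
  post <- mean(f$loglik_trace[201:800])
  expect_gte(post, f$loglik_trace[1])
})

test_that("Evanno Delta-K reproduces hand values and finds the elbow", {
  # exactly linear mean likelihoods: second difference vanishes
  lin <- list(`1` = c(-110, -100, -90), `2` = c(-60, -50, -40),
              `3` = c(-10, 0, 10))
  dk <- delta_k(lin)
  expect_equal(dk$delta_K[2], 0)
  expect_true(is.na(dk$delta_K[1]) && is.na(dk$delta_K[3]))

  # hand series: Delta-K(2) = |(-380) - 2(-400) + (-1000)| / 10 = 58
  hand <- list(`1` = c(-1010, -1000, -990), `2` = c(-410, -400, -390),
               `3` = c(-390, -380, -370), `4` = c(-380, -375, -370))
  dk2 <- delta_k(hand)
  expect_equal(dk2$sd_L[2], 10)
  expect_equal(dk2$delta_K[2], 58)
  expect_equal(attr(dk2, "best_K"), 2)

  # constructed elbow at K = 2 through the full scan driver
  expect_error(delta_k(list(`1` = c(-1, -2, -3), `3` = c(-1, -2, -3))),
               "contiguous")
  expect_error(delta_k(list(`1` = c(-1, -2), `2` = c(-1, -2))),
               "replicate")
  # zero sd -> undefined there
  z <- delta_k(list(`1` = c(-10, -10, -10), `2` = c(-5, -5, -5),
                    `3` = c(-4, -4, -4)))
  expect_true(is.na(z$delta_K[2]))
})

test_that("cluster label alignment is deterministic and fixes switching", {
  cfg <- tiny_config(seed = 14, n_pops = 2, n_loci = 120,
                     n_ind_per_pop = 12, fst_target = 0.25)
  gd <- make_genotypes(cfg)
  fa <- admixture_fit(gd, 2, iters = 600, burnin = 200, seed = 10)
  fb <- admixture_fit(gd, 2, iters = 600, burnin = 200, seed = 20)
  fb1 <- align_clusters(fb, fa)
  fb2 <- align_clusters(fb, fa)
  expect_identical(fb1$Q, fb2$Q)
  expect_lt(mean(abs(fb1$Q - fa$Q)), mean(abs(fb$Q[, 2:1] - fa$Q)) + 1e-12)
})

test_that("PCoA reproduces classical-scaling identities", {
  zero <- matrix(0, 4, 4)
  pz <- pcoa(zero, 2)
  expect_true(all(abs(pz$coords) < 1e-10))

  # collinear points: first axis recovers spacing, second eigenvalue ~ 0
  pts <- c(0, 1, 3)
  D <- abs(outer(pts, pts, "-"))
  pc <- pcoa(D, 2)
  ax1 <- pc$coords[, 1]
  expect_equal(abs(diff(ax1)), diff(pts), tolerance = 1e-8)
  expect_lt(abs(pc$eig[2]), 1e-8)

  # Euclidean inputs: non-negative leading eigenvalues and exact round-trip
  set.seed(4)
  X <- matrix(rnorm(24), 12, 2)
  DE <- as.matrix(stats::dist(X))
  pe <- pcoa(DE, 2)
  expect_true(all(pe$eig > -1e-8))
  pr <- vegan::procrustes(X, pe$coords)
  expect_lt(pr$ss, 1e-6)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(pcoa(matrix(c(1, 0, 0, 1), 2, 2)), "diagonal")
})

test_that("DAPC separates structured pops and stays at chance under the null", {
  cfg <- tiny_config(seed = 18, n_pops = 2, n_loci = 200,
                     n_ind_per_pop = 25, fst_target = 0.25)
  gd <- make_genotypes(cfg)
  dp <- dapc(gd)
  expect_gte(dp$accuracy, 0.95)
  expect_equal(sort(unique(dp$assigned)), c("pop1", "pop2"))

  # panmictic pop with random labels: cross-validated accuracy ~ chance
  cfg0 <- tiny_config(seed = 19, n_pops = 1, n_loci = 150,
                      n_ind_per_pop = 60, fst_target = 0)
  gd0 <- make_genotypes(cfg0)
  set.seed(1)
  fake <- sample(rep(c("a", "b"), 30))
  # leave-one-out: refit without individual i, predict it
  hits <- vapply(seq_len(60), function(i) {
    tr <- subset_ind <- setdiff(seq_len(60), i)
    gtr <- genotype_dataset(gd0$dosage[tr, ], fake[tr])
    cm <- colMeans(gtr$dosage, na.rm = TRUE)
    Xi <- gtr$dosage
    pcf <- stats::prcomp(Xi, center = TRUE)
    np <- which(cumsum(pcf$sdev^2) / sum(pcf$sdev^2) >= 0.9)[1]
    ld <- MASS::lda(pcf$x[, 1:np, drop = FALSE], grouping = fake[tr])
    new <- stats::predict(pcf, newdata = rbind(gd0$dosage[i, ]))
    as.character(stats::predict(ld, new[, 1:np, drop = FALSE])$class) ==
      fake[i]
  }, logical(1))
  acc <- mean(hits)
  ci <- 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / 60)
  expect_gte(acc, ci[1] - 1e-9)
  expect_lte(acc, ci[2] + 1e-9)

  expect_error(dapc(gd, groups = rep("one", nrow(gd$dosage))),
               ">= 2 groups")
  expect_warning(dapc(gd, groups = c("solo", gd$locality[-1])),
                 "single member")
})

test_that("allele-sharing distances are metric-like and missing-tolerant", {
  d <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L))
  gd <- genotype_dataset(d, rep("p", 3))
  D <- allele_sharing_dist(gd)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], (2 / 2 + 2 / 2 + 0) / 3)
  dm <- d; dm[1, 1] <- NA
  Dm <- allele_sharing_dist(genotype_dataset(dm, rep("p", 3)))
  expect_equal(Dm[1, 3], (2 / 2 + 0) / 2)
})
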