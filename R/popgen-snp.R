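#' Quality-filter SNP loci
#'
#' Removes loci failing, in this fixed order: call rate, pooled minor-allele
#' frequency, then reproducibility. Order affects only the per-criterion
#' removal counts, not the surviving set.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param min_call_rate Minimum fraction of non-missing calls (default
#'   0.95).
#' @param min_maf Minimum pooled minor-allele frequency, computed over all
#'   non-missing dosages (default 0.05). A locus passes when MAF >
#'   \code{min_maf} would fail it: the threshold is inclusive
#'   (\code{maf >= min_maf} kept).
#' @param min_reproducibility Minimum per-locus reproducibility; \code{NULL}
#'   skips the criterion.
#' @return List: \code{data} (filtered \code{genotype_dataset}),
#'   \code{removed} (named counts per criterion), \code{kept} (number of
#'   surviving loci).
#' @export
filter_loci <- function(gd, min_call_rate = 0.95, min_maf = 0.05,
                        min_reproducibility = NULL) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  meta <- gd$locus_meta
  alive <- rep(TRUE, nrow(meta))
  fail_cr <- alive & (meta$call_rate < min_call_rate)
  alive <- alive & !fail_cr
  maf <- meta$maf
  fail_maf <- alive & (is.na(maf) | maf < min_maf)
  alive <- alive & !fail_maf
  fail_rep <- rep(FALSE, nrow(meta))
  if (!is.null(min_reproducibility)) {
    stopifnot(min_reproducibility >= 0, min_reproducibility <= 1)
    fail_rep <- alive & (meta$reproducibility < min_reproducibility)
    alive <- alive & !fail_rep
  }
  removed <- c(call_rate = sum(fail_cr), maf = sum(fail_maf),
               reproducibility = sum(fail_rep))
  if (!any(alive))
    warning("filter_loci: all loci removed")
  out <- subset_genotypes(gd, loci = which(alive))
  list(data = out, removed = removed, kept = sum(alive))
}

#' Drop individuals with poor genotyping
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param max_missing_per_ind Maximum tolerated fraction of missing calls
#'   per individual.
#' @return List: \code{data}, \code{dropped} (ids), \code{n_by_locality}
#'   (surviving sample sizes).
#' @export
exclude_failed_samples <- function(gd, max_missing_per_ind = 0.5) {
  stopifnot(max_missing_per_ind >= 0, max_missing_per_ind <= 1)
  miss <- rowMeans(is.na(gd$dosage))
  keep <- miss <= max_missing_per_ind
  out <- subset_genotypes(gd, ind = which(keep))
  list(data = out,
       dropped = gd$ind_id[!keep],
       n_by_locality = table(out$locality))
}

# per-locality allele counts: list with n (2 x non-missing genotypes),
# count of minor alleles, het counts; each localities x loci
pop_counts <- function(gd) {
  pops <- sort(unique(gd$locality))
  f <- factor(gd$locality, levels = pops)
  X <- gd$dosage
  nonmiss <- !is.na(X)
  X0 <- X; X0[!nonmiss] <- 0L
  n_gen <- rowsum(nonmiss + 0L, f)          # genotypes per pop x locus
  minor <- rowsum(X0, f)                    # minor allele copies
  het <- rowsum((X == 1L & nonmiss) + 0L, f)
  list(pops = pops, n_gen = n_gen, minor = minor, het = het)
}

#' Per-locality diversity indices
#'
#' Mean over loci, per locality, of: observed number of alleles (Na),
#' rarefied allelic richness (Ar, hypergeometric rarefaction to \code{g}
#' gene copies), observed heterozygosity (Ho), unbiased expected
#' heterozygosity (He = 2p(1-p) corrected by 2n/(2n-1)), plus the fraction
#' of loci polymorphic in the locality.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param rarefaction_g Gene-copy count to rarefy to; loci where a locality
#'   has fewer than \code{g} non-missing copies are skipped for that
#'   locality's Ar.
#' @return Data frame, one row per locality.
#' @export
diversity <- function(gd, rarefaction_g = NULL) {
  pc <- pop_counts(gd)
  n2 <- 2 * pc$n_gen                       # allele copies
  if (is.null(rarefaction_g)) rarefaction_g <- max(2L, min(n2[n2 > 0]))
  g <- rarefaction_g
  out <- lapply(seq_along(pc$pops), function(i) {
    N <- n2[i, ]; A1 <- pc$minor[i, ]; A2 <- N - A1
    usable <- N >= 2
    p <- A1[usable] / N[usable]
    Na <- (A1[usable] > 0) + (A2[usable] > 0)
    Ho <- pc$het[i, usable] / pc$n_gen[i, usable]
    He <- 2 * p * (1 - p) * N[usable] / (N[usable] - 1)
    can_rar <- usable & N >= g
    Ar <- if (any(can_rar)) {
      Nr <- N[can_rar]; a1 <- A1[can_rar]; a2 <- Nr - a1
      arr <- (1 - exp(lchoose(Nr - a1, g) - lchoose(Nr, g))) +
             (1 - exp(lchoose(Nr - a2, g) - lchoose(Nr, g)))
      mean(arr)
    } else NA_real_
    data.frame(locality = pc$pops[i],
               n = max(pc$n_gen[i, ]),
               Na = mean(Na), Ar = Ar, Ho = mean(Ho), He = mean(He),
               prop_polymorphic = mean(Na == 2))
  })
  do.call(rbind, out)
}

#' Exact test of Hardy-Weinberg proportions for one biallelic locus
#'
#' Levene's exact conditional distribution of the heterozygote count given
#' the allele counts. The two-sided p-value sums the probabilities of all
#' configurations no more probable than the observed one; the one-sided
#' (heterozygote-deficiency) p-value sums configurations with at most the
#' observed heterozygote count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return List: \code{p} (two-sided), \code{p_deficiency} (one-sided),
#'   \code{het_deficiency} (observed < conditionally expected heterozygotes).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 2) return(list(p = NA_real_, p_deficiency = NA_real_,
                         het_deficiency = NA))
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_Aa)
  p_two <- sum(pr[pr <= pr[obs] * (1 + 1e-9)])
  p_def <- sum(pr[hets <= n_Aa])
  e_het <- sum(hets * pr)
  list(p = min(p_two, 1), p_deficiency = min(p_def, 1),
       het_deficiency = n_Aa < e_het)
}

#' Hardy-Weinberg exact tests across loci and localities
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param per_locality Test within each locality (the default) rather than
#'   pooled.
#' @param alpha Significance level for the heterozygote-deficiency flag.
#' @return Data frame: locus, locality, genotype counts, two-sided p,
#'   one-sided deficiency p, deficiency flag (one-sided p < alpha and
#'   observed < expected heterozygotes). Loci/localities with fewer than two
#'   non-missing genotypes get \code{NA} p-values.
#' @export
hwe_exact <- function(gd, per_locality = TRUE, alpha = 0.05) {
  scopes <- if (per_locality) sort(unique(gd$locality)) else "pooled"
  out <- list()
  for (sc in scopes) {
    rows <- if (per_locality) gd$locality == sc else rep(TRUE, nrow(gd$dosage))
    X <- gd$dosage[rows, , drop = FALSE]
    for (l in seq_len(ncol(X))) {
      g <- X[, l]
      nAA <- sum(g == 2, na.rm = TRUE)
      nAa <- sum(g == 1, na.rm = TRUE)
      naa <- sum(g == 0, na.rm = TRUE)
      r <- hwe_exact_test(nAA, nAa, naa)
      out[[length(out) + 1L]] <-
        data.frame(locus = gd$locus_id[l], locality = sc,
                   n_AA = nAA, n_Aa = nAa, n_aa = naa,
                   p = r$p, p_deficiency = r$p_deficiency,
                   het_deficiency = isTRUE(r$het_deficiency) &
                     !is.na(r$p_deficiency) & r$p_deficiency < alpha)
    }
  }
  do.call(rbind, out)
}

#' Pairwise linkage-disequilibrium exact tests
#'
#' Genotypic association between locus pairs tested per locality with
#' Fisher's exact test on the 3 x 3 genotype contingency table (an
#' approximation to a Markov-chain unphased exact test). Degenerate tables
#' (either locus effectively monomorphic in the locality) give p = 1.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param pairs Two-column matrix of locus indices; default all pairs (use
#'   \code{n_pairs} to subsample).
#' @param n_pairs If \code{pairs} is \code{NULL}, number of random pairs to
#'   test (seeded); \code{NULL} = all pairs.
#' @param seed Seed for pair subsampling.
#' @return Data frame: locus indices, locality, p; plus BH-adjusted q.
#' @export
ld_pairwise <- function(gd, pairs = NULL, n_pairs = NULL, seed = 1) {
  L <- ncol(gd$dosage)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(L, 2))
    if (!is.null(n_pairs) && n_pairs < nrow(pairs)) {
      pairs <- with_seed(seed,
                         pairs[sample(nrow(pairs), n_pairs), , drop = FALSE])
    }
  }
  pairs <- rbind(pairs)
  pops <- sort(unique(gd$locality))
  res <- list()
  for (pp in pops) {
    X <- gd$dosage[gd$locality == pp, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      g1 <- X[, pairs[k, 1]]; g2 <- X[, pairs[k, 2]]
      ok <- !is.na(g1) & !is.na(g2)
      tab <- table(factor(g1[ok], 0:2), factor(g2[ok], 0:2))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      p <- if (nrow(tab) < 2 || ncol(tab) < 2) 1 else
        tryCatch(stats::fisher.test(tab, workspace = 2e6)$p.value,
                 error = function(e)
                   stats::fisher.test(tab, simulate.p.value = TRUE,
                                      B = 2000)$p.value)
      res[[length(res) + 1L]] <-
        data.frame(locus1 = gd$locus_id[pairs[k, 1]],
                   locus2 = gd$locus_id[pairs[k, 2]],
                   locality = pp, p = p)
    }
  }
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

# Weir-Cockerham (1984) variance components per locus, any number of pops.
# Input: localities x loci matrices of genotype counts / minor copies / hets.
# Returns per-locus a, b, c (NA where undefined or monomorphic).
wc_components <- function(n_gen, minor, het) {
  use_pop <- n_gen > 0
  r_l <- colSums(use_pop)
  n <- n_gen
  p <- ifelse(n > 0, minor / (2 * n), NA)
  h <- ifelse(n > 0, het / n, NA)
  nbar <- colSums(n) / r_l
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r_l - 1)
  pbar <- colSums(minor) / (2 * colSums(n))
  s2 <- colSums(n * (p - rep(pbar, each = nrow(n)))^2, na.rm = TRUE) /
    ((r_l - 1) * nbar)
  hbar <- colSums(het) / colSums(n)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r_l - 1) / r_l * s2 -
                          hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r_l - 1) / r_l * s2 -
                            (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r_l < 2 | nbar <= 1 | pbar <= 0 | pbar >= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  data.frame(a = a, b = b, c = cc)
}

# multilocus theta from component sums
theta_from_components <- function(comp) {
  s <- colSums(comp[stats::complete.cases(comp), , drop = FALSE])
  unname(s["a"] / (s["a"] + s["b"] + s["c"]))
}

#' Weir-Cockerham F_ST between two localities
#'
#' Multilocus theta from the Weir-Cockerham (1984) variance components
#' (theta = sum(a) / sum(a + b + c) over loci; loci monomorphic across the
#' pair are excluded), with an optional permutation test shuffling
#' individuals between the two localities.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param pop_a,pop_b Locality labels.
#' @param n_perm Number of permutations (0 = no test).
#' @param seed Permutation seed.
#' @return List: \code{theta}, \code{p} ((1 + #{theta* >= theta}) /
#'   (1 + n_perm); \code{NA} if untested), \code{n_loci_used},
#'   \code{components} (per-locus a, b, c).
#' @export
fst_wc <- function(gd, pop_a, pop_b, n_perm = 0, seed = 1) {
  sel <- gd$locality %in% c(pop_a, pop_b)
  if (sum(gd$locality == pop_a) < 2 || sum(gd$locality == pop_b) < 2)
    stop("both localities need >= 2 individuals")
  gd2 <- subset_genotypes(gd, ind = which(sel))
  theta_of <- function(labels) {
    f <- factor(labels, levels = c(pop_a, pop_b))
    X <- gd2$dosage
    nonmiss <- !is.na(X)
    X0 <- X; X0[!nonmiss] <- 0L
    comp <- wc_components(rowsum(nonmiss + 0L, f),
                          rowsum(X0, f),
                          rowsum((X == 1L & nonmiss) + 0L, f))
    comp
  }
  comp <- theta_of(gd2$locality)
  theta <- theta_from_components(comp)
  p <- NA_real_
  if (n_perm > 0) {
    p <- with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        th_b <- theta_from_components(theta_of(sample(gd2$locality)))
        if (!is.na(th_b) && th_b >= theta) cnt <- cnt + 1L
      }
      (1 + cnt) / (1 + n_perm)
    })
  }
  list(theta = theta, p = p,
       n_loci_used = sum(stats::complete.cases(comp)),
       components = comp)
}

#' All pairwise F_ST values among localities
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param n_perm Permutations per pair (0 = none).
#' @param seed Base seed; each pair uses a derived seed.
#' @return List of symmetric matrices \code{fst} and \code{p} (zero /
#'   \code{NA} diagonals).
#' @export
pairwise_fst <- function(gd, n_perm = 0, seed = 1) {
  pops <- sort(unique(gd$locality))
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- fst_wc(gd, pops[i], pops[j], n_perm = n_perm,
                seed = derive_seed(seed, paste0(pops[i], pops[j])))
    fst[i, j] <- fst[j, i] <- r$theta
    pv[i, j] <- pv[j, i] <- r$p
  }
  list(fst = fst, p = pv)
}

#' Standardised F_ST (Hedrick-style)
#'
#' Divides theta by its maximum attainable value given the mean within-
#' population gene diversity \eqn{H_S}:
#' \eqn{\theta_{max} = (k-1)(1-H_S) / (k-1+H_S)} for \eqn{k} populations.
#'
#' @param theta Estimated F_ST.
#' @param hs Mean within-population expected heterozygosity in [0, 1).
#' @param k Number of populations (default 2).
#' @return Standardised value (\code{NA} when \code{hs} is at/above 1).
#' @export
fst_standardised <- function(theta, hs, k = 2) {
  if (any(hs < 0)) stop("hs must be >= 0")
  tmax <- (k - 1) * (1 - hs) / (k - 1 + hs)
  out <- theta / tmax
  out[hs >= 1] <- NA_real_
  out
}

# mean unbiased within-population He over loci used for a pair
mean_hs <- function(gd, pops) {
  sel <- gd$locality %in% pops
  gd2 <- subset_genotypes(gd, ind = which(sel))
  pc <- pop_counts(gd2)
  n2 <- 2 * pc$n_gen
  p <- ifelse(n2 > 0, pc$minor / n2, NA)
  he <- 2 * p * (1 - p) * ifelse(n2 > 1, n2 / (n2 - 1), NA)
  mean(colMeans(he), na.rm = TRUE)
}

#' Standardised-F_ST transect between coastline-ordered localities
#'
#' For each adjacent locality pair along a supplied coastline order,
#' computes theta, the pair's mean within-population gene diversity, the
#' standardised F_ST, and the geographic midpoint position — the
#' along-coast differentiation profile.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param order Locality labels in coastline order.
#' @param positions Numeric along-coast positions (e.g. km), one per
#'   locality in \code{order}.
#' @return Data frame with one row per adjacent pair.
#' @export
fst_transect <- function(gd, order, positions) {
  stopifnot(length(order) == length(positions))
  out <- list()
  for (i in seq_len(length(order) - 1)) {
    a <- order[i]; b <- order[i + 1]
    th <- fst_wc(gd, a, b)$theta
    hs <- mean_hs(gd, c(a, b))
    out[[i]] <- data.frame(pair = paste(a, b, sep = "-"),
                           midpoint = (positions[i] + positions[i + 1]) / 2,
                           theta = th, hs = hs,
                           theta_std = fst_standardised(th, hs, k = 2))
  }
  do.call(rbind, out)
}

#' Simple Mantel test of isolation by distance
#'
#' Pearson correlation between the upper-triangle entries of two labelled
#' distance matrices; significance by simultaneous row/column permutation
#' of one matrix, with the (1 + count) / (1 + n_perm) p-value convention.
#'
#' @param genetic,geographic Symmetric matrices with matching dimnames.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Permutation seed.
#' @return List: \code{r}, \code{p}, \code{n_perm}.
#' @export
ibd_mantel <- function(genetic, geographic, n_perm = 1000, seed = 1) {
  genetic <- as.matrix(genetic); geographic <- as.matrix(geographic)
  k <- nrow(genetic)
  if (k < 3) stop("Mantel test undefined for fewer than 3 localities")
  stopifnot(identical(dim(genetic), dim(geographic)),
            isTRUE(all.equal(genetic, t(genetic))),
            isTRUE(all.equal(geographic, t(geographic))))
  if (!is.null(dimnames(genetic)[[1]]) &&
      !is.null(dimnames(geographic)[[1]]))
    geographic <- geographic[rownames(genetic), rownames(genetic)]
  ut <- upper.tri(genetic)
  x <- genetic[ut]
  r_obs <- stats::cor(x, geographic[ut])
  p <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample(k)
      if (stats::cor(x, geographic[pm, pm][ut]) >= r_obs) cnt <- cnt + 1L
    }
    (1 + cnt) / (1 + n_perm)
  })
  list(r = r_obs, p = p, n_perm = n_perm)
}

#' Geographic distance matrix between localities
#'
#' Euclidean distance on locally projected (equirectangular about the mean
#' latitude) coordinates by default, or great-circle (haversine) distance.
#'
#' @param coords Data frame / matrix with rownames = locality labels and
#'   columns lon, lat (degrees).
#' @param method \code{"euclidean"} (default) or \code{"greatcircle"}.
#' @return Symmetric matrix of kilometres.
#' @export
geo_distance_matrix <- function(coords, method = c("euclidean",
                                                   "greatcircle")) {
  method <- match.arg(method)
  coords <- as.matrix(coords[, c(1, 2)])
  k <- nrow(coords)
  D <- matrix(0, k, k, dimnames = list(rownames(coords), rownames(coords)))
  if (method == "euclidean") {
    latc <- mean(coords[, 2])
    x <- coords[, 1] * 111.19 * cos(latc * pi / 180)
    y <- coords[, 2] * 111.19
    D[] <- as.matrix(stats::dist(cbind(x, y)))
  } else {
    for (i in seq_len(k)) for (j in seq_len(k))
      D[i, j] <- haversine_km(coords[i, 1], coords[i, 2],
                              coords[j, 1], coords[j, 2])
  }
  D
}

#' Permutation F_ST-outlier scan
#'
#' Per-locus multi-population theta compared to a null distribution built by
#' permuting locality labels across individuals (the same label permutation
#' applied to every locus per replicate). The two-sided test statistic is
#' the absolute deviation of theta from the permutation-ensemble mean, so
#' loci extreme in either direction (unusually high or unusually low
#' differentiation) are flagged; p-values use the
#' (1 + count)/(1 + n_perm) convention with a seeded uniform tie-break that
#' keeps the null p exactly uniform despite the discreteness of theta under
#' label permutation. Benjamini-Hochberg q-values are reported; loci
#' monomorphic overall are excluded.
#'
#' @param gd A \code{\link{genotype_dataset}} with >= 2 localities.
#' @param n_perm Number of label permutations (default 199).
#' @param seed Permutation seed.
#' @return Data frame: locus, theta_locus, p, q (NA rows for excluded
#'   loci).
#' @export
outlier_scan <- function(gd, n_perm = 199, seed = 1) {
  pops <- sort(unique(gd$locality))
  if (length(pops) < 2) stop("outlier scan needs >= 2 localities")
  X <- gd$dosage
  nonmiss <- !is.na(X)
  X0 <- X; X0[!nonmiss] <- 0L
  het <- (X == 1L & nonmiss) + 0L
  theta_per_locus <- function(labels) {
    f <- factor(labels, levels = pops)
    comp <- wc_components(rowsum(nonmiss + 0L, f), rowsum(X0, f),
                          rowsum(het, f))
    comp$a / (comp$a + comp$b + comp$c)
  }
  th_obs <- theta_per_locus(gd$locality)
  L <- length(th_obs)
  p <- with_seed(seed, {
    TB <- matrix(NA_real_, L, n_perm)
    for (b in seq_len(n_perm))
      TB[, b] <- theta_per_locus(sample(gd$locality))
    m <- (th_obs + rowSums(TB)) / (n_perm + 1)
    dev_obs <- abs(th_obs - m)
    u_obs <- stats::runif(L)
    cnt <- integer(L)
    for (b in seq_len(n_perm)) {
      dev_b <- abs(TB[, b] - m)
      u_b <- stats::runif(L)
      d <- dev_b - dev_obs
      inc <- d > 1e-12 | (abs(d) <= 1e-12 & u_b >= u_obs)
      inc[is.na(inc)] <- FALSE
      cnt <- cnt + inc
    }
    (1 + cnt) / (1 + n_perm)
  })
  p[is.na(th_obs)] <- NA_real_
  out <- data.frame(locus = gd$locus_id, theta_locus = th_obs, p = p,
                    q = NA_real_)
  ok <- !is.na(p)
  out$q[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
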