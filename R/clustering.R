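#' Admixture-model Gibbs sampler
#'
#' Bayesian clustering of individuals from biallelic dosages under an
#' admixture model with independent allele frequencies: each of an
#' individual's two allele copies at a locus has a latent cluster of origin
#' drawn from its membership vector \eqn{q_i}, and is the minor allele with
#' that cluster's frequency \eqn{p_{kl}}. A Gibbs sweep alternates (i)
#' allele-origin assignments given \eqn{q} and \eqn{p}, (ii) frequency
#' updates from their conjugate Beta(1, 1) posteriors, and (iii) membership
#' updates from their conjugate Dirichlet(1, ..., 1) posteriors. The
#' observed-data log-likelihood \eqn{\sum_{il} \log
#' \mathrm{Binom}(x_{il} \mid 2, \sum_k q_{ik} p_{kl})} is recorded every
#' iteration; posterior means of Q and p are accumulated after burn-in.
#'
#' @param gd A \code{\link{genotype_dataset}} (or a dosage matrix).
#' @param K Number of clusters (>= 1).
#' @param iters Total Gibbs iterations (default 2000).
#' @param burnin Burn-in iterations discarded from posterior means
#'   (default 500; must be < iters).
#' @param seed RNG seed.
#' @return Object of class \code{admixture_fit}: \code{K}, \code{Q}
#'   (individuals x K posterior-mean memberships, rows sum to 1),
#'   \code{allele_freqs} (K x loci), \code{loglik_trace}, \code{iters},
#'   \code{burnin}, \code{seed}.
#' @export
admixture_fit <- function(gd, K, iters = 2000, burnin = 500, seed = 1) {
  X <- if (inherits(gd, "genotype_dataset")) gd$dosage else as.matrix(gd)
  N <- nrow(X); L <- ncol(X)
  stopifnot(K >= 1, iters > burnin, burnin >= 0)
  if (K > N) stop("K cannot exceed the number of individuals")
  if (K == 1) {
    p <- colMeans(X, na.rm = TRUE) / 2
    pi1 <- matrix(p, N, L, byrow = TRUE)
    ll <- sum(stats::dbinom(X, 2, pi1, log = TRUE), na.rm = TRUE)
    return(structure(list(K = 1L,
                          Q = matrix(1, N, 1,
                                     dimnames = list(rownames(X), "k1")),
                          allele_freqs = matrix(p, 1, L),
                          loglik_trace = rep(ll, iters),
                          iters = iters, burnin = burnin, seed = seed),
                     class = "admixture_fit"))
  }
  minor <- X; minor[is.na(minor)] <- 0L        # minor-allele copies
  major <- 2L - X; major[is.na(major)] <- 0L   # major-allele copies
  with_seed(seed, {
    q <- matrix(stats::rgamma(N * K, 1), N, K)
    q <- q / rowSums(q)
    p <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    Qsum <- matrix(0, N, K); Psum <- matrix(0, K, L)
    ll_trace <- numeric(iters)
    kept <- 0L
    for (it in seq_len(iters)) {
      # P(copy of allele a at locus l in individual i came from cluster k)
      wmin <- lapply(seq_len(K), function(k) tcrossprod(q[, k], p[k, ]))
      wmaj <- lapply(seq_len(K), function(k) tcrossprod(q[, k], 1 - p[k, ]))
      smin <- Reduce(`+`, wmin); smaj <- Reduce(`+`, wmaj)
      rem_min <- minor; rem_maj <- major
      rmin_w <- smin; rmaj_w <- smaj
      cnt_min <- vector("list", K); cnt_maj <- vector("list", K)
      for (k in seq_len(K)) {
        if (k < K) {
          pr1 <- pmin(pmax(wmin[[k]] / rmin_w, 0), 1)
          pr2 <- pmin(pmax(wmaj[[k]] / rmaj_w, 0), 1)
          cmin <- matrix(stats::rbinom(N * L, rem_min, pr1), N, L)
          cmaj <- matrix(stats::rbinom(N * L, rem_maj, pr2), N, L)
        } else {
          cmin <- rem_min; cmaj <- rem_maj
        }
        cnt_min[[k]] <- cmin; cnt_maj[[k]] <- cmaj
        rem_min <- rem_min - cmin; rem_maj <- rem_maj - cmaj
        rmin_w <- rmin_w - wmin[[k]]; rmaj_w <- rmaj_w - wmaj[[k]]
      }
      for (k in seq_len(K)) {
        p[k, ] <- stats::rbeta(L, 1 + colSums(cnt_min[[k]]),
                               1 + colSums(cnt_maj[[k]]))
        q[, k] <- stats::rgamma(N, 1 + rowSums(cnt_min[[k]]) +
                                     rowSums(cnt_maj[[k]]))
      }
      q <- q / rowSums(q)
      pi_mix <- Reduce(`+`, lapply(seq_len(K), function(k)
        tcrossprod(q[, k], p[k, ])))
      ll_trace[it] <- sum(stats::dbinom(X, 2, pi_mix, log = TRUE),
                          na.rm = TRUE)
      if (it > burnin) { Qsum <- Qsum + q; Psum <- Psum + p; kept <- kept + 1L }
    }
    Q <- Qsum / kept
    dimnames(Q) <- list(rownames(X), paste0("k", seq_len(K)))
    structure(list(K = as.integer(K), Q = Q, allele_freqs = Psum / kept,
                   loglik_trace = ll_trace, iters = iters, burnin = burnin,
                   seed = seed),
              class = "admixture_fit")
  })
}

#' Align cluster labels across runs
#'
#' Greedy matching of Q columns (largest-correlation first) of \code{fit}
#' onto \code{reference}; resolves the label-switching indeterminacy before
#' cross-run comparison. Deterministic.
#'
#' @param fit,reference \code{admixture_fit} objects with equal K and N.
#' @return \code{fit} with columns of Q and rows of allele_freqs permuted.
#' @export
align_clusters <- function(fit, reference) {
  K <- fit$K
  stopifnot(K == reference$K, nrow(fit$Q) == nrow(reference$Q))
  sim <- crossprod(reference$Q, fit$Q)   # K x K column agreement
  perm <- integer(K)
  used_r <- used_f <- logical(K)
  for (step in seq_len(K)) {
    idx <- which(sim == max(sim[!used_r, !used_f, drop = FALSE])[1] &
                 !outer(used_r, used_f, `|`), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    used_r[idx[1]] <- TRUE; used_f[idx[2]] <- TRUE
    sim[idx[1], ] <- -Inf; sim[, idx[2]] <- -Inf
  }
  fit$Q <- fit$Q[, perm, drop = FALSE]
  colnames(fit$Q) <- paste0("k", seq_len(K))
  fit$allele_freqs <- fit$allele_freqs[perm, , drop = FALSE]
  fit
}

#' Evanno Delta-K criterion
#'
#' Second-order rate of change of the model log-likelihood across K over
#' replicate runs: \eqn{\Delta K = |\bar L(K+1) - 2\bar L(K) +
#' \bar L(K-1)| / \mathrm{sd}(L(K))}, defined for interior K only;
#' undefined (NA) where the replicate sd is zero.
#'
#' @param runs Named list: element \code{"k"} holds the replicate
#'   log-likelihoods (numeric vector, >= 3 replicates) for that K; K values
#'   must be contiguous.
#' @return Data frame: K, mean_L, sd_L, delta_K; attribute \code{best_K}
#'   (argmax of delta_K).
#' @export
delta_k <- function(runs) {
  ks <- sort(as.integer(names(runs)))
  if (any(diff(ks) != 1)) stop("K range must be contiguous")
  if (any(vapply(runs, length, integer(1)) < 3))
    stop("need >= 3 replicate runs per K")
  mL <- vapply(as.character(ks), function(k) mean(runs[[k]]), numeric(1))
  sL <- vapply(as.character(ks), function(k) stats::sd(runs[[k]]),
               numeric(1))
  dK <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    if (sL[i] > 0)
      dK[i] <- abs(mL[i + 1] - 2 * mL[i] + mL[i - 1]) / sL[i]
  }
  out <- data.frame(K = ks, mean_L = mL, sd_L = sL, delta_K = dK,
                    row.names = NULL)
  attr(out, "best_K") <- if (all(is.na(dK))) NA_integer_ else
    ks[which.max(dK)]
  out
}

#' Run the admixture sampler over a K range with replicates
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param k_range Integer vector of K values (contiguous).
#' @param replicates Replicate runs per K (>= 3 for \code{\link{delta_k}}).
#' @param iters,burnin Sampler settings per run.
#' @param seed Base seed; each (K, replicate) uses a derived seed.
#' @return List: \code{fits} (nested list by K then replicate),
#'   \code{selection} (the \code{\link{delta_k}} table). Replicate
#'   log-likelihood is the post-burn-in mean of the trace.
#' @export
admixture_scan <- function(gd, k_range = 1:4, replicates = 3,
                           iters = 2000, burnin = 500, seed = 1) {
  fits <- list(); ll <- list()
  for (K in k_range) {
    fits_k <- vector("list", replicates)
    ll_k <- numeric(replicates)
    for (r in seq_len(replicates)) {
      f <- admixture_fit(gd, K, iters = iters, burnin = burnin,
                         seed = derive_seed(seed, paste0("K", K, "r", r)))
      fits_k[[r]] <- f
      ll_k[r] <- mean(f$loglik_trace[(burnin + 1):iters])
    }
    fits[[as.character(K)]] <- fits_k
    ll[[as.character(K)]] <- ll_k
  }
  list(fits = fits, selection = delta_k(ll))
}

#' Principal Coordinates Analysis
#'
#' Classical metric scaling: Gower double-centring of the squared distance
#' matrix followed by eigendecomposition (via \code{stats::cmdscale}).
#' Negative eigenvalues are reported, never silently dropped.
#'
#' @param dist_mat Symmetric zero-diagonal distance matrix.
#' @param n_axes Number of axes to return.
#' @return List: \code{coords} (n x n_axes), \code{eig} (all eigenvalues),
#'   \code{prop_explained} (relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(dist_mat, n_axes = 2) {
  dist_mat <- as.matrix(dist_mat)
  if (!isTRUE(all.equal(dist_mat, t(dist_mat))))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dist_mat)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  n_axes <- min(n_axes, nrow(dist_mat) - 1)
  # cmdscale warns when fewer than n_axes positive eigenvalues exist; the
  # full eigenvalue vector is reported below, so the warning is redundant
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist_mat),
                                          k = n_axes, eig = TRUE))
  coords <- fit$points
  if (is.null(dim(coords)) || ncol(coords) < n_axes) {
    pad <- matrix(0, nrow(dist_mat), n_axes - NCOL(coords))
    coords <- cbind(coords, pad)
  }
  pos <- sum(fit$eig[fit$eig > 0])
  list(coords = coords, eig = fit$eig,
       prop_explained = if (pos > 0) fit$eig / pos else fit$eig * 0)
}

#' Allele-sharing distance between individuals
#'
#' \eqn{d_{ij}} = mean over non-missing loci of |dosage difference| / 2;
#' a simple missing-tolerant genetic distance for individual-level
#' ordination.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @return Symmetric distance matrix.
#' @export
allele_sharing_dist <- function(gd) {
  X <- gd$dosage
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(gd$ind_id, gd$ind_id))
  for (i in seq_len(n - 1)) {
    di <- abs(sweep(X[(i + 1):n, , drop = FALSE], 2, X[i, ])) / 2
    D[i, (i + 1):n] <- D[(i + 1):n, i] <- rowMeans(di, na.rm = TRUE)
  }
  D
}

#' Discriminant Analysis of Principal Components
#'
#' Centred (mean-imputed) dosages are reduced to \code{n_pcs} principal
#' components, then linear discriminant analysis separates the predefined
#' groups; returns individual discriminant scores and posterior group
#' memberships.
#'
#' @param gd A \code{\link{genotype_dataset}}.
#' @param groups Group labels (default the dataset's localities); >= 2
#'   groups required. Single-member groups draw a warning (covariance is
#'   pooled).
#' @param n_pcs Number of retained PCs; default the smallest number
#'   explaining >= 90\% of variance.
#' @param n_da Number of discriminant axes (default \code{groups - 1}).
#' @return List: \code{scores}, \code{posterior}, \code{assigned},
#'   \code{accuracy} (self-assignment rate), \code{n_pcs}.
#' @export
dapc <- function(gd, groups = NULL, n_pcs = NULL, n_da = NULL) {
  X <- gd$dosage
  if (is.null(groups)) groups <- gd$locality
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("DAPC needs >= 2 groups")
  if (any(table(groups) == 1))
    warning("group(s) with a single member; covariance pooled")
  stopifnot(length(groups) == nrow(X))
  # mean-impute missing, centre
  cm <- colMeans(X, na.rm = TRUE)
  Xi <- X
  for (l in which(colSums(is.na(X)) > 0)) Xi[is.na(X[, l]), l] <- cm[l]
  pc <- stats::prcomp(Xi, center = TRUE, scale. = FALSE)
  if (is.null(n_pcs)) {
    vf <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- which(vf >= 0.9)[1]
  }
  n_pcs <- min(n_pcs, nrow(X) - 1, ncol(pc$x))
  scores_pc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  if (is.null(n_da)) n_da <- nlevels(groups) - 1
  fit <- MASS::lda(scores_pc, grouping = groups)
  pred <- stats::predict(fit, scores_pc)
  list(scores = pred$x[, seq_len(min(n_da, ncol(pred$x))), drop = FALSE],
       posterior = pred$posterior,
       assigned = as.character(pred$class),
       accuracy = mean(pred$class == groups),
       n_pcs = n_pcs)
}
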