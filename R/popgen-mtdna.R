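# Hamming distance between aligned sequences; sites where either sequence
# is ambiguous (N or gap) are excluded pairwise.
hamming_dist <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- !(av %in% c("N", "-")) & !(bv %in% c("N", "-"))
  sum(av[ok] != bv[ok])
}

# full pairwise Hamming matrix over character sequences
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  M <- matrix(0L, n, n)
  if (n < 2) return(M)
  sp <- strsplit(seqs, "")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    av <- sp[[i]]; bv <- sp[[j]]
    ok <- !(av %in% c("N", "-")) & !(bv %in% c("N", "-"))
    M[i, j] <- M[j, i] <- sum(av[ok] != bv[ok])
  }
  M
}

#' Collapse an alignment to haplotypes
#'
#' Identical sequences share a haplotype; haplotypes are labelled H1, H2,
#' ... in order of first appearance. Under the default \code{"merge"}
#' policy, a sequence containing N or gap characters is merged into the
#' first existing haplotype that matches it at every resolved site (and
#' founds its own haplotype otherwise).
#'
#' @param aln A \code{\link{haplotype_alignment}}.
#' @param ambiguous_policy \code{"merge"} (default) or \code{"strict"}
#'   (ambiguous characters treated as ordinary states).
#' @return Object of class \code{haplotype_table}: \code{haplotypes}
#'   (label, sequence), \code{counts} (haplotype x locality matrix) and
#'   \code{assignment} (per-sample haplotype label).
#' @export
collapse_haplotypes <- function(aln, ambiguous_policy = c("merge",
                                                          "strict")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  seqs <- aln$sequences
  if (length(seqs) == 0) stop("empty alignment")
  hap_seq <- character(0)
  assign_idx <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    hit <- which(hap_seq == s)
    if (!length(hit) && ambiguous_policy == "merge" &&
        grepl("[N-]", s)) {
      # match on resolved sites only
      sv <- strsplit(s, "")[[1]]
      res <- !(sv %in% c("N", "-"))
      hit <- which(vapply(hap_seq, function(h) {
        hv <- strsplit(h, "")[[1]]
        ok <- res & !(hv %in% c("N", "-"))
        all(sv[ok] == hv[ok])
      }, logical(1)))[1]
      hit <- hit[!is.na(hit)]
    }
    if (length(hit)) {
      assign_idx[i] <- hit[1]
    } else {
      hap_seq <- c(hap_seq, s)
      assign_idx[i] <- length(hap_seq)
    }
  }
  labels <- paste0("H", seq_along(hap_seq))
  locs <- sort(unique(aln$locality))
  counts <- table(factor(labels[assign_idx], levels = labels),
                  factor(aln$locality, levels = locs))
  counts <- matrix(counts, nrow = length(labels),
                   dimnames = list(labels, locs))
  structure(list(haplotypes = data.frame(label = labels,
                                         sequence = hap_seq,
                                         row.names = NULL),
                 counts = counts,
                 assignment = labels[assign_idx]),
            class = "haplotype_table")
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased haplotype diversity
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}: the probability
#' that two randomly drawn samples carry different haplotypes.
#'
#' @param table A \code{\link{collapse_haplotypes}} result, or a numeric
#'   vector of haplotype counts.
#' @param locality Locality label, or \code{"pooled"} (default) for all
#'   samples.
#' @return h in [0, 1]; \code{NA} when fewer than 2 samples.
#' @export
haplotype_diversity <- function(table, locality = "pooled") {
  cnt <- if (is.numeric(table)) table
  else if (locality == "pooled") rowSums(table$counts)
  else table$counts[, locality]
  n <- sum(cnt)
  if (n < 2) return(NA_real_)
  p <- cnt / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Haplotype-frequency F_ST between two localities
#'
#' Frequency-based fixation index \eqn{F_{ST} = (H_T - H_S)/H_T} with
#' unbiased gene-diversity estimates: \eqn{H_S} is the sample-size-weighted
#' mean of the localities' unbiased diversities and \eqn{H_T} the unbiased
#' diversity of the pooled sample. Significance by permuting samples
#' between the two localities.
#'
#' @param table A \code{haplotype_table}.
#' @param pop_a,pop_b Locality labels.
#' @param n_perm Number of permutations (default 1000; 0 = no test).
#' @param seed Permutation seed.
#' @return List: \code{fst}, \code{p}, \code{h_t}, \code{h_s}. Both
#'   localities monomorphic for the same haplotype gives \code{fst = 0}.
#' @export
fst_haplotype <- function(table, pop_a, pop_b, n_perm = 1000, seed = 1) {
  ca <- table$counts[, pop_a]; cb <- table$counts[, pop_b]
  if (sum(ca) < 2 || sum(cb) < 2)
    stop("both localities need >= 2 samples")
  fst_of <- function(ca, cb) {
    na <- sum(ca); nb <- sum(cb)
    hs <- (na * haplotype_diversity(ca) + nb * haplotype_diversity(cb)) /
      (na + nb)
    ht <- haplotype_diversity(ca + cb)
    if (ht == 0) return(c(0, 0, 0))
    c((ht - hs) / ht, ht, hs)
  }
  obs <- fst_of(ca, cb)
  p <- NA_real_
  if (n_perm > 0) {
    # rebuild the sample list and permute membership
    hap_idx <- c(rep(seq_along(ca), ca), rep(seq_along(cb), cb))
    na <- sum(ca)
    p <- with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        pm <- sample(length(hap_idx))
        ia <- hap_idx[pm[seq_len(na)]]
        ib <- hap_idx[pm[-seq_len(na)]]
        f_b <- fst_of(tabulate(ia, length(ca)),
                      tabulate(ib, length(cb)))[1]
        if (f_b >= obs[1]) cnt <- cnt + 1L
      }
      (1 + cnt) / (1 + n_perm)
    })
  }
  list(fst = obs[1], p = p, h_t = obs[2], h_s = obs[3])
}

#' Pairwise haplotype F_ST among all localities
#' @param table A \code{haplotype_table}.
#' @param n_perm Permutations per pair.
#' @param seed Base seed (per-pair seeds derived).
#' @return List of symmetric matrices \code{fst} and \code{p}.
#' @export
pairwise_fst_haplotype <- function(table, n_perm = 1000, seed = 1) {
  pops <- colnames(table$counts)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- fst_haplotype(table, pops[i], pops[j], n_perm = n_perm,
                       seed = derive_seed(seed, paste0(pops[i], pops[j])))
    fst[i, j] <- fst[j, i] <- r$fst
    pv[i, j] <- pv[j, i] <- r$p
  }
  list(fst = fst, p = pv)
}

# minimum spanning network: edge (a, b, w) is retained iff a and b lie in
# different components of the graph restricted to edges of weight
# < w - epsilon (epsilon = 0 gives the union of all minimum spanning trees)
min_spanning_network <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n < 2)
    return(list(edges = data.frame(from = integer(), to = integer(),
                                   weight = numeric()), cost = 0))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  o <- order(w, ij[, 1], ij[, 2])
  ij <- ij[o, , drop = FALSE]; w <- w[o]
  comps_below <- function(thr) {
    comp <- seq_len(n)
    for (e in which(w < thr)) {
      a <- comp[ij[e, 1]]; b <- comp[ij[e, 2]]
      if (a != b) comp[comp == max(a, b)] <- min(a, b)
    }
    comp
  }
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    comp <- comps_below(w[e] - epsilon)
    keep[e] <- comp[ij[e, 1]] != comp[ij[e, 2]]
    # stop once everything below this level is already connected
    if (length(unique(comp)) == 1) break
  }
  edges <- data.frame(from = ij[keep, 1], to = ij[keep, 2],
                      weight = w[keep])
  list(edges = edges, cost = mst_cost(D))
}

# plain MST cost via Prim
mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- D[1, ]
  total <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(mind[cand])]
    total <- total + mind[j]
    intree[j] <- TRUE
    mind <- pmin(mind, D[j, ])
  }
  total
}

# majority-consensus median candidates for a triple of variable-site vectors
median_candidates <- function(a, b, c) {
  S <- length(a)
  fixed <- character(S)
  free <- list()
  for (s in seq_len(S)) {
    st <- c(a[s], b[s], c[s])
    tb <- sort(table(st), decreasing = TRUE)
    if (tb[1] >= 2) fixed[s] <- names(tb)[1]
    else free[[length(free) + 1L]] <- list(site = s, states = sort(unique(st)))
  }
  if (!length(free)) return(list(fixed))
  if (length(free) > 2) {  # cap the expansion; keep first state per site
    for (f in free) fixed[f$site] <- f$states[1]
    return(list(fixed))
  }
  grids <- expand.grid(lapply(free, function(f) f$states),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(grids))
  for (g in seq_len(nrow(grids))) {
    v <- fixed
    for (fi in seq_along(free)) v[free[[fi]]$site] <- grids[g, fi]
    out[[g]] <- v
  }
  out
}

#' Median-joining haplotype network
#'
#' Builds the relatedness network over observed haplotypes following the
#' median-joining procedure: repeatedly add the inferred intermediate
#' (median/consensus) sequence that most reduces the minimum-spanning cost
#' of the node set, then prune medians that no longer reduce the cost, and
#' return the minimum-spanning network (all tied spanning edges within the
#' \code{epsilon} tolerance) over the final node set. Medians are computed
#' on variable sites only; tie-breaks are lexicographic, so the output is
#' deterministic. Edge weights are Hamming distances (mutation counts).
#'
#' @param table A \code{haplotype_table} (needs >= 2 haplotypes).
#' @param epsilon Non-negative weight tolerance for retaining near-minimal
#'   connections (default 0).
#' @return Object of class \code{haplo_network}: \code{nodes} (label, type
#'   observed/median, sequence, total count), \code{edges} (from, to,
#'   weight labels), \code{cost} (sum of spanning-tree edge weights over the
#'   final node set).
#' @export
median_joining <- function(table, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  hseq <- table$haplotypes$sequence
  k <- length(hseq)
  if (k < 2) stop("need >= 2 haplotypes")
  sp <- strsplit(hseq, "")
  S <- nchar(hseq[1])
  varsite <- which(vapply(seq_len(S), function(s)
    length(unique(vapply(sp, `[`, character(1), s))) > 1, logical(1)))
  obs <- lapply(sp, function(v) v[varsite])
  const_part <- sp[[1]]

  nodes <- obs                       # variable-site vectors
  is_obs <- rep(TRUE, k)
  key <- vapply(nodes, paste, character(1), collapse = "")

  dist_mat <- function(nodes) {
    n <- length(nodes)
    M <- matrix(0L, n, n)
    if (n > 1)
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        M[i, j] <- M[j, i] <- sum(nodes[[i]] != nodes[[j]])
    M
  }

  repeat {
    D <- dist_mat(nodes)
    base_cost <- mst_cost(D)
    best <- NULL; best_cost <- base_cost; best_key <- NULL
    n <- length(nodes)
    if (n >= 3) {
      trips <- utils::combn(n, 3)
      cand_seen <- character(0)
      for (tcol in seq_len(ncol(trips))) {
        tri <- trips[, tcol]
        for (cand in median_candidates(nodes[[tri[1]]], nodes[[tri[2]]],
                                       nodes[[tri[3]]])) {
          ck <- paste(cand, collapse = "")
          if (ck %in% key || ck %in% cand_seen) next
          cand_seen <- c(cand_seen, ck)
          dvec <- vapply(nodes, function(x) sum(x != cand), integer(1))
          D2 <- rbind(cbind(D, dvec), c(dvec, 0L))
          cost2 <- mst_cost(D2)
          if (cost2 < best_cost - 1e-9 ||
              (cost2 < best_cost + 1e-9 && !is.null(best_key) &&
               ck < best_key && cost2 < base_cost - 1e-9)) {
            best <- cand; best_cost <- cost2; best_key <- ck
          }
        }
      }
    }
    if (is.null(best)) break
    nodes[[length(nodes) + 1L]] <- best
    is_obs <- c(is_obs, FALSE)
    key <- c(key, best_key)
  }

  # prune medians whose removal leaves the spanning cost unchanged
  repeat {
    D <- dist_mat(nodes)
    cost_now <- mst_cost(D)
    removed <- FALSE
    for (i in rev(which(!is_obs))) {
      Dm <- dist_mat(nodes[-i])
      if (mst_cost(Dm) <= cost_now + 1e-9) {
        nodes <- nodes[-i]; is_obs <- is_obs[-i]; key <- key[-i]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  D <- dist_mat(nodes)
  msn <- min_spanning_network(D, epsilon)
  n_med <- sum(!is_obs)
  labels <- character(length(nodes))
  labels[is_obs] <- table$haplotypes$label
  labels[!is_obs] <- paste0("mv", seq_len(n_med))
  full_seq <- vapply(nodes, function(v) {
    s <- const_part; s[varsite] <- v; paste(s, collapse = "")
  }, character(1))
  count <- rep(0, length(nodes))
  count[is_obs] <- rowSums(table$counts)
  edges <- msn$edges
  out_edges <- data.frame(from = labels[edges$from], to = labels[edges$to],
                          weight = edges$weight)
  structure(list(nodes = data.frame(label = labels,
                                    type = ifelse(is_obs, "observed",
                                                  "median"),
                                    sequence = full_seq, count = count,
                                    row.names = NULL),
                 edges = out_edges,
                 cost = msn$cost),
            class = "haplo_network")
}

#' Convert a haplotype network to an igraph object
#' @param net A \code{haplo_network}.
#' @return An \code{igraph} graph with node/edge attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a haplotype network as GraphML (and optionally an edge-list CSV)
#' @param net A \code{haplo_network}.
#' @param path Output GraphML path.
#' @param edges_csv Optional edge-list CSV path.
#' @export
write_network <- function(net, path, edges_csv = NULL) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  if (!is.null(edges_csv))
    utils::write.csv(net$edges, edges_csv, row.names = FALSE)
  invisible(path)
}
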