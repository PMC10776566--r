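# Shared builders for small in-code fixtures.

# 4x4 degree grid centred on the equator, 40 daily frames
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed,
                                 grid_extent = c(-2, 2, -2, 2),
                                 grid_step = 0.08, n_days = 40),
                            list(...))
  do.call(fixture_config, args)
}

# small square spawning polygon centred at (cx, cy), half-width `half` deg
square_ring <- function(cx, cy, half = 0.1) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

square_site <- function(name, cx, cy, half = 0.1, season = c(1, 10),
                        field = NULL, buffer_km = 5) {
  spawning_site(name, square_ring(cx, cy, half), season,
                settlement_buffer_km = buffer_km, field = field)
}

# genotype dataset from an explicit dosage matrix, one locality per block
gd_from_blocks <- function(...) {
  blocks <- list(...)
  dosage <- do.call(rbind, blocks)
  locality <- rep(paste0("pop", seq_along(blocks)),
                  vapply(blocks, nrow, integer(1)))
  genotype_dataset(dosage, locality)
}

# DP-style exhaustive-enumeration oracle for the HWE exact distribution:
# counts weighted arrangements of genotype pairs (AA uses two A copies,
# Aa one with slot multiplicity 2, aa none) and conditions on the A count.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  # w[pairs][a_used+1][hets+1] accumulated recursively
  counts <- new.env()
  rec <- function(pairs_left, a_left, hets) {
    key <- paste(pairs_left, a_left, hets)
    if (!is.null(counts[[key]])) return(counts[[key]])
    if (pairs_left == 0) {
      res <- if (a_left == 0) stats::setNames(1, hets) else numeric(0)
    } else {
      res <- numeric(0)
      add <- function(x, mult) {
        for (nm in names(x)) {
          res[nm] <<- (if (is.na(res[nm])) 0 else res[nm]) + mult * x[nm]
        }
      }
      if (a_left >= 2) add(rec(pairs_left - 1, a_left - 2, hets), 1)
      if (a_left >= 1) add(rec(pairs_left - 1, a_left - 1, hets + 1), 2)
      add(rec(pairs_left - 1, a_left, hets), 1)
    }
    counts[[key]] <- res
    res
  }
  w <- rec(n, nA, 0)
  hs <- as.integer(names(w))
  pr <- w / sum(w)
  obs <- which(hs == n_Aa)
  list(p_two = sum(pr[pr <= pr[obs] * (1 + 1e-9)]),
       p_def = sum(pr[hs <= n_Aa]))
}

# exhaustive Steiner-optimal network cost over observed haplotypes:
# tries every subset (up to `max_medians`) of candidate median sequences
# built from the observed states at variable sites
steiner_optimum_cost <- function(seqs, max_medians = 2) {
  sp <- strsplit(seqs, "")
  S <- nchar(seqs[1])
  varsite <- which(vapply(seq_len(S), function(s)
    length(unique(vapply(sp, `[`, character(1), s))) > 1, logical(1)))
  obs <- lapply(sp, function(v) v[varsite])
  states <- lapply(seq_along(varsite), function(s)
    unique(vapply(obs, `[`, character(1), s)))
  cand <- expand.grid(states, stringsAsFactors = FALSE)
  cand <- apply(cand, 1, paste, collapse = "")
  obs_key <- vapply(obs, paste, character(1), collapse = "")
  cand <- setdiff(cand, obs_key)
  cost_of <- function(node_keys) {
    vecs <- strsplit(node_keys, "")
    n <- length(vecs)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sum(vecs[[i]] != vecs[[j]])
    meagreflow:::mst_cost(D)
  }
  best <- cost_of(obs_key)
  for (m in seq_len(min(max_medians, length(cand)))) {
    subs <- utils::combn(length(cand), m)
    for (k in seq_len(ncol(subs)))
      best <- min(best, cost_of(c(obs_key, cand[subs[, k]])))
  }
  best
}
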