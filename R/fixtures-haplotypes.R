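#' Aligned mtDNA haplotype sequences
#'
#' Equal-length nucleotide sequences (alphabet A/C/G/T/N/-) with sample ids
#' and locality labels, as obtained from aligned control-region Sanger
#' sequences.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param sample_id Sample ids.
#' @param locality Locality labels.
#' @return Object of class \code{haplotype_alignment}.
#' @export
haplotype_alignment <- function(sequences, sample_id = NULL, locality) {
  sequences <- toupper(as.character(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("all sequences must have the same length")
  if (any(grepl("[^ACGTN-]", sequences)))
    stop("sequences restricted to alphabet A,C,G,T,N,-")
  if (is.null(sample_id)) sample_id <- paste0("s", seq_along(sequences))
  stopifnot(length(locality) == length(sequences))
  structure(list(sequences = sequences,
                 sample_id = as.character(sample_id),
                 locality = as.character(locality)),
            class = "haplotype_alignment")
}

#' Simulate a haplotype alignment with known mutation structure
#'
#' Haplotype 1 is a random ancestral sequence; each further haplotype is
#' derived from a recorded parent by one substitution at a previously
#' unmutated site, so the true mutation graph (returned as ground truth) is
#' a tree with unit branch lengths and every pairwise Hamming distance is
#' the tree path length. Samples are then assigned to localities with the
#' requested haplotype frequencies.
#'
#' @param config A \code{\link{fixture_config}} (seed source).
#' @param n_haplotypes Number of distinct haplotypes.
#' @param seq_len Alignment length (must be at least
#'   \code{n_haplotypes - 1} so every mutation gets its own site).
#' @param freq_by_pop Matrix of haplotype frequencies, one row per locality
#'   (rows sum to 1), columns = haplotypes.
#' @param n_per_pop Integer sample sizes per locality.
#' @param parents Optional integer vector: \code{parents[h]} is the
#'   haplotype that haplotype \code{h} (h >= 2) mutates from; default is a
#'   star around haplotype 1.
#' @return A \code{\link{haplotype_alignment}} with attributes
#'   \code{haplotype_seqs}, \code{mutation_graph} (edge data frame) and
#'   \code{true_haplotype} (per-sample index).
#' @export
make_haplotypes <- function(config, n_haplotypes, seq_len, freq_by_pop,
                            n_per_pop, parents = NULL) {
  freq_by_pop <- rbind(freq_by_pop)
  if (ncol(freq_by_pop) != n_haplotypes)
    stop("freq_by_pop must have one column per haplotype")
  if (any(abs(rowSums(freq_by_pop) - 1) > 1e-8))
    stop("rows of freq_by_pop must sum to 1")
  if (seq_len < n_haplotypes - 1)
    stop("seq_len must be >= n_haplotypes - 1")
  if (is.null(parents)) parents <- c(NA, rep(1L, n_haplotypes - 1L))
  stopifnot(length(parents) == n_haplotypes)
  n_pop <- nrow(freq_by_pop)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pop)
  with_seed(fixture_seed(config, "haplotypes"), {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, seq_len, replace = TRUE)
    haps <- vector("list", n_haplotypes)
    haps[[1]] <- anc
    mut_site <- if (n_haplotypes > 1)
      sample(seq_len, n_haplotypes - 1) else integer()
    edges <- NULL
    for (h in seq_len(n_haplotypes)[-1]) {
      s <- haps[[parents[h]]]
      site <- mut_site[h - 1]
      s[site] <- sample(setdiff(bases, s[site]), 1)
      haps[[h]] <- s
      edges <- rbind(edges, data.frame(from = parents[h], to = h,
                                       site = site))
    }
    hap_str <- vapply(haps, paste, character(1), collapse = "")
    seqs <- character(0); locs <- character(0); truth <- integer(0)
    pops <- paste0("pop", seq_len(n_pop))
    for (i in seq_len(n_pop)) {
      # deterministic rounded counts honouring the sample size
      cnt <- floor(freq_by_pop[i, ] * n_per_pop[i])
      rem <- n_per_pop[i] - sum(cnt)
      if (rem > 0) {
        frac <- freq_by_pop[i, ] * n_per_pop[i] - cnt
        cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
          cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
      }
      idx <- rep(seq_len(n_haplotypes), cnt)
      seqs <- c(seqs, hap_str[idx])
      locs <- c(locs, rep(pops[i], length(idx)))
      truth <- c(truth, idx)
    }
    aln <- haplotype_alignment(seqs, paste0(locs, "_",
                                            unlist(lapply(table(factor(locs, levels = pops)), seq_len))),
                               locs)
    attr(aln, "haplotype_seqs") <- hap_str
    attr(aln, "mutation_graph") <- edges
    attr(aln, "true_haplotype") <- truth
    aln
  })
}

#' Write an alignment as FASTA (id and locality in the header)
#' @param aln A \code{\link{haplotype_alignment}}.
#' @param path Output FASTA path.
#' @export
write_alignment_fasta <- function(aln, path) {
  x <- Biostrings::DNAStringSet(gsub("-", "-", aln$sequences))
  names(x) <- paste(aln$sample_id, aln$locality)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA alignment written by \code{\link{write_alignment_fasta}}
#' @param path FASTA path.
#' @param locality Optional locality labels; if missing they are taken from
#'   the second whitespace-separated token of each header.
#' @return A \code{\link{haplotype_alignment}}.
#' @export
read_alignment_fasta <- function(path, locality = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  if (is.null(locality))
    locality <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 2)
  haplotype_alignment(as.character(x), ids, locality)
}
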