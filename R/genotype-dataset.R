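#' Biallelic SNP genotype dataset
#'
#' Individuals by loci minor-allele dosage matrix ({0,1,2}, \code{NA} for
#' missing calls) with locality labels and per-locus QC metadata.
#'
#' @param dosage Integer matrix, individuals in rows, loci in columns.
#' @param locality Character vector of locality labels, one per individual.
#' @param ind_id Individual ids (defaults to \code{ind1..indN}).
#' @param locus_id Locus ids (defaults to \code{L1..LL}).
#' @param reproducibility Optional per-locus reproducibility fraction in
#'   [0, 1] (an assay-quality score consumed as given); defaults to 1.
#' @return Object of class \code{genotype_dataset} with a \code{locus_meta}
#'   data frame (\code{call_rate}, \code{maf}, \code{reproducibility});
#'   call rate and MAF are computed from the dosage matrix.
#' @export
genotype_dataset <- function(dosage, locality, ind_id = NULL, locus_id = NULL,
                             reproducibility = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosage values must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage); L <- ncol(dosage)
  stopifnot(length(locality) == n)
  if (is.null(ind_id)) ind_id <- paste0("ind", seq_len(n))
  if (is.null(locus_id)) locus_id <- paste0("L", seq_len(L))
  if (is.null(reproducibility)) reproducibility <- rep(1, L)
  rownames(dosage) <- ind_id; colnames(dosage) <- locus_id
  call_rate <- colMeans(!is.na(dosage))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA_real_
  structure(list(dosage = dosage,
                 ind_id = as.character(ind_id),
                 locality = as.character(locality),
                 locus_id = as.character(locus_id),
                 locus_meta = data.frame(locus = as.character(locus_id),
                                         call_rate = call_rate,
                                         maf = maf,
                                         reproducibility = reproducibility,
                                         row.names = NULL)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "loci;",
      length(unique(x$locality)), "localities\n")
  invisible(x)
}

# subset helper keeping metadata consistent
subset_genotypes <- function(gd, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_along(gd$ind_id)
  if (is.null(loci)) loci <- seq_along(gd$locus_id)
  genotype_dataset(gd$dosage[ind, loci, drop = FALSE],
                   gd$locality[ind],
                   ind_id = gd$ind_id[ind],
                   locus_id = gd$locus_id[loci],
                   reproducibility = gd$locus_meta$reproducibility[loci])
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Draws an ancestral minor-allele frequency \eqn{p} per locus, then a
#' subpopulation frequency \eqn{p_k \sim
#' \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)} per population (so
#' \eqn{E[p_k]=p}, \eqn{\mathrm{Var}[p_k]=F\,p(1-p)} and the expected
#' Wright fixation index among populations equals \eqn{F}), and finally two
#' binomial allele copies per individual. \eqn{F = 0} is the exact limit
#' \eqn{p_k = p}. Missing calls are injected uniformly at random at
#' \code{config$missing_rate}; per-locus reproducibility scores are drawn in
#' [0.95, 1].
#'
#' @param config A \code{\link{fixture_config}}; uses \code{n_pops},
#'   \code{n_loci}, \code{n_ind_per_pop}, \code{fst_target},
#'   \code{ancestral_maf_range}, \code{missing_rate} and the seed.
#' @param pop_names Optional locality names (default \code{pop1..popK}).
#' @return A \code{\link{genotype_dataset}} with attributes
#'   \code{ancestral_freq} and \code{subpop_freq} (the simulation truth).
#' @export
make_genotypes <- function(config, pop_names = NULL) {
  K <- config$n_pops; L <- config$n_loci
  sizes <- config$n_ind_per_pop
  FF <- config$fst_target
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(K))
  stopifnot(length(pop_names) == K)
  with_seed(fixture_seed(config, "genotypes"), {
    p <- runif(L, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
    pk <- matrix(NA_real_, K, L)
    for (k in seq_len(K)) {
      pk[k, ] <- if (FF == 0) p else
        rbeta(L, p * (1 - FF) / FF, (1 - p) * (1 - FF) / FF)
    }
    n <- sum(sizes)
    dosage <- matrix(NA_integer_, n, L)
    locality <- rep(pop_names, sizes)
    row0 <- 0L
    for (k in seq_len(K)) {
      dosage[row0 + seq_len(sizes[k]), ] <-
        matrix(rbinom(sizes[k] * L, 2, rep(pk[k, ], each = sizes[k])),
               sizes[k], L)
      row0 <- row0 + sizes[k]
    }
    if (config$missing_rate > 0) {
      miss <- runif(n * L) < config$missing_rate
      dosage[miss] <- NA_integer_
    }
    repro <- round(runif(L, 0.95, 1), 3)
    gd <- genotype_dataset(dosage, locality,
                           ind_id = paste0(locality, "_",
                                           unlist(lapply(sizes, seq_len))),
                           reproducibility = repro)
    attr(gd, "ancestral_freq") <- p
    attr(gd, "subpop_freq") <- pk
    gd
  })
}

#' Write genotypes as a TSV dosage matrix
#'
#' Rows are individuals; first columns \code{ind} and \code{locality}, then
#' one column per locus with dosage 0/1/2 and \code{NA} for missing.
#' @param gd A \code{\link{genotype_dataset}}.
#' @param path Output TSV path.
#' @export
write_genotypes_tsv <- function(gd, path) {
  df <- data.frame(ind = gd$ind_id, locality = gd$locality,
                   gd$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV dosage matrix written by \code{\link{write_genotypes_tsv}}
#' @param path TSV path.
#' @return A \code{\link{genotype_dataset}}.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  genotype_dataset(as.matrix(df[, -(1:2), drop = FALSE]),
                   df$locality, ind_id = df$ind,
                   locus_id = colnames(df)[-(1:2)])
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Biallelic records on a dummy chromosome, REF=A, ALT=T; the ALT allele is
#' the minor (counted) allele, so dosage equals the ALT-allele count of the
#' unphased GT.
#' @param gd A \code{\link{genotype_dataset}}.
#' @param path Output VCF path (plain text).
#' @export
write_genotypes_vcf <- function(gd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=meagreflow",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gd$ind_id), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (l in seq_along(gd$locus_id)) {
    g <- gd$dosage[, l]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c("1", l, gd$locus_id[l], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-only VCF into a genotype dataset
#'
#' Dosage is the ALT-allele count; any non-biallelic record is rejected.
#' Locality labels must be supplied separately (e.g. from a locality CSV).
#' @param path VCF path.
#' @param locality Character vector of locality labels in sample order, or a
#'   named vector matched to sample ids.
#' @return A \code{\link{genotype_dataset}}.
#' @export
read_genotypes_vcf <- function(path, locality) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(lines[1], "\t")[[1]]
  samples <- hdr[-(1:9)]
  body <- strsplit(lines[-1], "\t")
  if (!is.null(names(locality))) locality <- unname(locality[samples])
  dosage <- matrix(NA_integer_, length(samples), length(body))
  ids <- character(length(body))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (grepl(",", f[5])) stop("non-biallelic record in VCF")
    ids[i] <- f[3]
    gt <- sub(":.*", "", f[-(1:9)])
    a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
    d <- ifelse(a == "." | b == ".", NA_integer_,
                as.integer(a == "1") + as.integer(b == "1"))
    dosage[, i] <- d
  }
  genotype_dataset(dosage, locality, ind_id = samples, locus_id = ids)
}
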