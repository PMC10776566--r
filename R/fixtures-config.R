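#' Configuration for synthetic fixtures
#'
#' Bundles every knob of the synthetic-data generators: the gridded current
#' field (extent, step, length), the genotype panel (populations, loci,
#' sample sizes, target differentiation) and the master seed. One named RNG
#' stream per fixture kind is derived from the master seed, so adding one
#' fixture never shifts another.
#'
#' @param seed Master integer seed.
#' @param grid_extent Numeric length-4: \code{c(lon_min, lon_max, lat_min,
#'   lat_max)} in degrees.
#' @param grid_step Grid spacing in degrees. Default 0.08, the resolution of
#'   the ocean-reanalysis forcing the synthetic fields emulate.
#' @param n_days Number of daily velocity frames.
#' @param origin First day of the field (a \code{Date}).
#' @param n_pops Number of subpopulations for the genotype generator.
#' @param n_loci Number of biallelic loci.
#' @param n_ind_per_pop Integer vector of per-population sample sizes
#'   (recycled to \code{n_pops}).
#' @param fst_target Balding-Nichols differentiation parameter F in [0, 1).
#' @param ancestral_maf_range Range the ancestral minor-allele frequency is
#'   drawn from.
#' @param missing_rate Fraction of genotype calls set missing, uniformly at
#'   random.
#' @return An object of class \code{fixture_config}.
#' @export
fixture_config <- function(seed = 1L,
                           grid_extent = c(-10, -6, 36, 40),
                           grid_step = 0.08,
                           n_days = 40L,
                           origin = as.Date("2008-01-01"),
                           n_pops = 2L,
                           n_loci = 200L,
                           n_ind_per_pop = 20L,
                           fst_target = 0.1,
                           ancestral_maf_range = c(0.1, 0.5),
                           missing_rate = 0) {
  stopifnot(length(grid_extent) == 4,
            grid_extent[2] > grid_extent[1],
            grid_extent[4] > grid_extent[3])
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (n_days < 1) stop("n_days must be >= 1")
  if (fst_target < 0 || fst_target >= 1) stop("fst_target must be in [0, 1)")
  stopifnot(length(ancestral_maf_range) == 2,
            all(ancestral_maf_range > 0), all(ancestral_maf_range < 1),
            missing_rate >= 0, missing_rate < 1)
  cfg <- list(seed = as.integer(seed),
              grid_extent = as.numeric(grid_extent),
              grid_step = grid_step,
              n_days = as.integer(n_days),
              origin = as.Date(origin),
              n_pops = as.integer(n_pops),
              n_loci = as.integer(n_loci),
              n_ind_per_pop = rep_len(as.integer(n_ind_per_pop), n_pops),
              fst_target = fst_target,
              ancestral_maf_range = as.numeric(ancestral_maf_range),
              missing_rate = missing_rate)
  class(cfg) <- "fixture_config"
  cfg
}

# per-fixture-kind RNG stream
fixture_seed <- function(config, kind) derive_seed(config$seed, kind)
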