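# Shared settings for the analysis scripts. Everything downstream is
# deterministic in MASTER_SEED; outputs land under results/.
library(meagreflow)

MASTER_SEED <- 20260901L
RESULTS_DIR <- "results"
FIXTURES_DIR <- file.path(RESULTS_DIR, "fixtures")

# synthetic coastal sea: 4 x 4 degrees, 0.08 degree step, 60 daily frames
sea_config <- function() {
  fixture_config(seed = derive_seed(MASTER_SEED, "sea"),
                 grid_extent = c(-10, -6, 35, 39), grid_step = 0.08,
                 n_days = 70, origin = as.Date("2008-04-25"))
}

# a north-south chain of four small estuarine spawning sites with
# staggered spawning seasons (day-of-year windows within the field window)
study_sites <- function(field) {
  mk <- function(nm, cx, cy, season) {
    spawning_site(nm, cbind(c(cx - 0.07, cx + 0.07, cx + 0.07, cx - 0.07),
                            c(cy - 0.07, cy - 0.07, cy + 0.07, cy + 0.07)),
                  season = season, settlement_buffer_km = 10,
                  field = field)
  }
  # seasons follow the study pattern (northern sites spawn Jun - mid Jul,
  # the southern bank from May), trimmed to the 70-day toy field window
  list(mk("north_estuary",  -8.2, 38.6, c(153, 167)),
       mk("mid_estuary",    -8.6, 37.9, c(153, 174)),
       mk("south_estuary",  -7.6, 36.9, c(146, 174)),
       mk("bank_south",     -9.0, 35.8, c(122, 153)))
}

# genotype panel shaped like the study: 1,534 loci, 87 retained samples
panel_config <- function() {
  fixture_config(seed = derive_seed(MASTER_SEED, "panel"),
                 n_pops = 6, n_loci = 1700,
                 n_ind_per_pop = c(12, 23, 13, 16, 17, 8),
                 fst_target = 0.05, ancestral_maf_range = c(0.03, 0.5),
                 missing_rate = 0.03)
}

locality_names <- c("Gironde", "Tejo", "Algarve", "Guadalquivir",
                    "BancArguin", "Senegal")
# along-coast positions (km) used for the IBD / transect analyses
locality_positions <- c(0, 950, 1230, 1430, 2900, 3400)
locality_coords <- cbind(lon = c(-1.1, -9.2, -8.0, -6.3, -16.5, -17.2),
                         lat = c(45.6, 38.7, 37.0, 36.8, 20.1, 14.7))
rownames(locality_coords) <- locality_names
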