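# meagreflow

An R package and analysis workflow for assessing the population structure
and connectivity of a coastal marine fish from three independent lines of
evidence, the combination used in modern stock-structure studies of species
such as the Atlantic meagre:

1. **Larval dispersal** — a Lagrangian biophysical model: passive particles
   released daily from ~3 km cells inside spawning-site polygons during each
   site's spawning season, advected hourly over gridded daily ocean-current
   fields (bilinear interpolation in space, cos-latitude spherical metric,
   up to 30 days of drift), classified as settled / beached / lost /
   expired, and aggregated into dispersal-distance statistics and a pairwise
   oceanographic-connectivity matrix *P*, where *P[i, j]* is the proportion
   of particles released at site *i* that reached site *j* (the diagonal is
   local retention).
2. **Population genetics** — for biallelic SNP panels: quality filtering
   (call rate, MAF, reproducibility), diversity indices (Na, rarefied Ar,
   Ho, unbiased He), Levene exact Hardy–Weinberg tests, Fisher-exact
   linkage-disequilibrium tests, pairwise Weir–Cockerham
   θ = Σaₗ / Σ(aₗ+bₗ+cₗ) with permutation significance, Hedrick-style
   standardised F_ST (θ/θ_max with θ_max = (k−1)(1−H_S)/(k−1+H_S)), a
   simple Mantel test of isolation by distance, and a permutation
   F_ST-outlier scan with Benjamini–Hochberg correction. For mtDNA
   control-region alignments: haplotype collapse, Nei's haplotype diversity
   h = n/(n−1)(1−Σpᵢ²), frequency-based pairwise F_ST = (H_T−H_S)/H_T, and
   median-joining haplotype networks.
3. **Clustering and ordination** — an admixture-model Gibbs sampler with
   the Evanno ΔK criterion for the number of clusters, PCoA on
   allele-sharing distances, and DAPC.
4. **Telemetry** — per-fish great-circle track summaries (cumulative km,
   maximum displacement, distance within any 365-day window) and
   zone-to-zone movement events.

Every input the pipeline needs — current fields, spawning geometries,
Balding–Nichols genotype panels with controlled F_ST, haplotype alignments
with a recorded mutation tree, telemetry tracks — can be generated
synthetically with seeded reproducibility, so the whole workflow runs and
is tested end to end without any external data. It is aimed at researchers
who want a transparent, fully scriptable re-implementation of this
multi-evidence workflow, or a harness for method checks on data with known
ground truth.

## Worked example

```r
library(meagreflow)

# 1. simulate a 2-population SNP panel with known differentiation
cfg <- fixture_config(seed = 7, n_pops = 2, n_loci = 1000,
                      n_ind_per_pop = 50, fst_target = 0.1)
gd <- make_genotypes(cfg)
res <- fst_wc(gd, "pop1", "pop2", n_perm = 999, seed = 1)
cat(sprintf("Weir-Cockerham theta = %.4f (P = %.3f, %d loci)\n",
            res$theta, res$p, res$n_loci_used))

# 2. drift a larva eastward at 0.1 m/s for one day
field <- make_velocity_field(
  fixture_config(seed = 1, grid_extent = c(-2, 2, -2, 2), n_days = 10),
  "uniform", list(u = 0.1, v = 0))
site <- spawning_site("origin",
                      cbind(c(-0.1, 0.1, 0.1, -0.1),
                            c(-0.1, -0.1, 0.1, 0.1)),
                      season = c(1, 5), field = field)
p <- advect(field, site, as.Date("2008-01-02"),
            release_lonlat = c(0, 0), max_days = 1)
cat(sprintf("fate = %s, dispersal = %.2f km\n", p$fate, p$dispersal_km))

# 3. collapse control-region sequences and build the haplotype network
aln <- make_haplotypes(fixture_config(seed = 3), n_haplotypes = 4,
                       seq_len = 330,
                       freq_by_pop = rbind(c(.4, .3, .2, .1),
                                           c(.1, .2, .3, .4)),
                       n_per_pop = c(20, 20))
tab <- collapse_haplotypes(aln)
net <- median_joining(tab)
cat(sprintf("%d haplotypes, pooled diversity h = %.3f, network cost = %d\n",
            nrow(tab$haplotypes), haplotype_diversity(tab), net$cost))
```

This prints:

```
Weir-Cockerham theta = 0.0898 (P = 0.001, 1000 loci)
fate = expired, dispersal = 8.64 km
4 haplotypes, pooled diversity h = 0.769, network cost = 3
```

The recovered θ sits within sampling error of the generator's target of
0.1 and is significant against 999 permutations; the 0.1 m/s current moves
the larva 0.1 × 86 400 m = 8.64 km in a day (it stays inside the grid and
never leaves its source's settlement polygon, so it expires rather than
settles); and the four simulated haplotypes collapse exactly and connect in
a network whose total cost equals their three generating mutations.

## The analysis workflow

The numbered scripts under `analysis/` run the study-shaped workflow on
synthetic inputs and write their tables under `results/`:

```sh
Rscript analysis/01_fixtures.R      # current field, sites, 1,700-locus panel,
                                    # 16-haplotype mtDNA alignment, 11 tracks
Rscript analysis/02_dispersal.R     # drift simulation, stats, connectivity
Rscript analysis/03_popgen_snp.R    # QC, diversity, HWE/LD, F_ST, IBD, outliers
Rscript analysis/04_popgen_mtdna.R  # haplotypes, diversity, F_ST, MJ network
Rscript analysis/05_clustering.R    # admixture + Delta-K, PCoA, DAPC
Rscript analysis/06_telemetry.R     # track distances and zone transitions
```

Each script is a thin narrative driver over the package functions; the
whole sequence takes a few minutes on one core. `run_all()` offers the same
pipeline as a single call from one YAML configuration with derived
per-stage seeds and a checksummed run manifest.

## Repository layout

```
R/                  package code (fixtures, dispersal, popgen, clustering,
                    telemetry, pipeline orchestration)
analysis/           numbered workflow drivers writing results/
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance test suites
vignettes/          methods vignette (models, parameters, design choices)
```
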