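#!/usr/bin/env Rscript
# Build every synthetic input of the study emulation and write it under
# results/fixtures: the gridded current field, the spawning-site polygons,
# the SNP genotype panel (with two deliberately failed samples), the mtDNA
# control-region alignment and the telemetry tracks.

source("analysis/00_config.R")
dir.create(FIXTURES_DIR, recursive = TRUE, showWarnings = FALSE)

## current field over a synthetic coastal sea with a small landmass
cfg <- sea_config()
land <- list(cbind(c(-7.1, -6.2, -6.2, -7.1), c(37.3, 37.3, 38.2, 38.2)))
field <- make_velocity_field(cfg, "random_smooth",
                             list(amplitude = 0.35, n_modes = 4),
                             land_polygons = land)
write_velocity_field(field, file.path(FIXTURES_DIR, "field.csv"))
sites <- study_sites(field)
write_polygons_geojson(
  lapply(sites, function(s) list(name = s$name,
                                 season_start_doy = s$season[1],
                                 season_end_doy = s$season[2],
                                 ring = s$polygon)),
  file.path(FIXTURES_DIR, "sites.geojson"))
cat("field:", length(field$lon), "x", length(field$lat), "nodes,",
    length(field$time), "days;", sum(field$land_mask), "land cells\n")
cat("sites:", paste(vapply(sites, `[[`, character(1), "name"),
                    collapse = ", "), "\n")

## genotype panel, with one sample in each of two localities degraded so the
## missingness filter removes them downstream (as happens with real plates)
gd <- make_genotypes(panel_config(), pop_names = locality_names)
bad <- c(which(gd$locality == "Algarve")[1],
         which(gd$locality == "Senegal")[1])
dos <- gd$dosage
set.seed(derive_seed(MASTER_SEED, "failed_samples"))
for (i in bad) dos[i, sample(ncol(dos), round(0.7 * ncol(dos)))] <- NA
gd <- genotype_dataset(dos, gd$locality, ind_id = gd$ind_id,
                       locus_id = gd$locus_id,
                       reproducibility = gd$locus_meta$reproducibility)
write_genotypes_tsv(gd, file.path(FIXTURES_DIR, "genotypes.tsv"))
write_genotypes_vcf(gd, file.path(FIXTURES_DIR, "genotypes.vcf"))
utils::write.csv(data.frame(ind = gd$ind_id, locality = gd$locality,
                            lon = locality_coords[gd$locality, "lon"],
                            lat = locality_coords[gd$locality, "lat"]),
                 file.path(FIXTURES_DIR, "localities.csv"),
                 row.names = FALSE)
cat("genotypes:", nrow(gd$dosage), "individuals x", ncol(gd$dosage),
    "loci (", length(bad), "samples degraded )\n")

## mtDNA control-region alignment: 16 haplotypes, 86 samples, ~330 bp;
## four widespread haplotypes plus two locally concentrated ones per site
fr <- t(vapply(1:6, function(i) {
  w <- c(rep(0.125, 4), rep(0, 12))
  w[4 + c(2 * i - 1, 2 * i)] <- 0.25
  w / sum(w)
}, numeric(16)))
aln <- make_haplotypes(fixture_config(seed = derive_seed(MASTER_SEED, "mtdna"),
                                      n_pops = 6),
                       n_haplotypes = 16, seq_len = 330, freq_by_pop = fr,
                       n_per_pop = c(12, 23, 12, 16, 17, 6))
aln$locality <- locality_names[match(aln$locality,
                                     paste0("pop", 1:6))]
write_alignment_fasta(aln, file.path(FIXTURES_DIR, "mtdna.fasta"))
cat("mtDNA:", length(aln$sequences), "sequences,",
    length(unique(aln$sequences)), "distinct haplotypes\n")

## telemetry: 11 fish tagged off the southern coast, most commuting to a
## western estuary and back, detected over roughly a year
tcfg <- fixture_config(seed = derive_seed(MASTER_SEED, "telemetry"))
south <- c(-7.9, 36.95); west <- c(-9.15, 38.6)
tracks <- lapply(1:11, function(i) {
  t0 <- as.POSIXct("2018-09-20", tz = "UTC") + (i - 1) * 5 * 86400
  if (i <= 9) {   # commuters: south -> west -> south
    wps <- rbind(south, south + c(-0.4, 0.1), west, west + c(0.05, 0.05),
                 south + c(-0.2, 0.05), south)
    tms <- t0 + c(0, 30, 90, 150, 230, 300) * 86400
  } else {        # residents staying on the south coast
    wps <- rbind(south, south + c(-0.3, 0.02), south + c(0.2, -0.02),
                 south)
    tms <- t0 + c(0, 60, 160, 280) * 86400
  }
  make_track(tcfg, wps, tms, id = sprintf("fish%02d", i),
             noise_sd_km = 2, source = "psat")
})
write_tracks_csv(tracks, file.path(FIXTURES_DIR, "tracks.csv"))
cat("telemetry:", length(tracks), "tracks written\n")
cat("fixtures complete ->", FIXTURES_DIR, "\n")
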