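# schema of the run configuration: known keys per block; unknown keys are
# rejected outright
.config_schema <- list(
  version = NULL, seed = NULL, out_dir = NULL,
  fixtures = list(grid_extent = NULL, grid_step = NULL, n_days = NULL,
                  origin = NULL, n_pops = NULL, n_loci = NULL,
                  n_ind_per_pop = NULL, fst_target = NULL,
                  ancestral_maf_range = NULL, missing_rate = NULL,
                  n_haplotypes = NULL, seq_len = NULL, hap_n_per_pop = NULL),
  dispersal = list(enabled = NULL, kind = NULL, params = "any",
                   release_per_day = NULL, step_h = NULL, max_days = NULL,
                   sites = "any"),
  popgen_snp = list(enabled = NULL, min_call_rate = NULL, min_maf = NULL,
                    min_reproducibility = NULL, n_perm = NULL,
                    coords = "any"),
  popgen_mtdna = list(enabled = NULL, n_perm = NULL),
  clustering = list(enabled = NULL, k_range = NULL, replicates = NULL,
                    iters = NULL, burnin = NULL),
  telemetry = list(enabled = NULL, waypoints = "any", times = "any",
                   zones = "any")
)

#' Validate a run configuration
#'
#' Checks the configuration against the published schema: required
#' top-level fields present, no unknown keys anywhere, and basic type
#' sanity. Returns the (normalised) config or stops with itemised
#' messages.
#'
#' @param config Named list (e.g. from \code{yaml::read_yaml}).
#' @return The validated config, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  for (req in c("version", "seed", "out_dir"))
    if (is.null(config[[req]]))
      errs <- c(errs, paste0("missing required field '", req, "'"))
  unknown_top <- setdiff(names(config), names(.config_schema))
  if (length(unknown_top))
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown_top, collapse = ", ")))
  for (blk in intersect(names(config), names(.config_schema))) {
    sch <- .config_schema[[blk]]
    if (is.list(sch) && is.list(config[[blk]])) {
      unknown <- setdiff(names(config[[blk]]), names(sch))
      if (length(unknown))
        errs <- c(errs, paste0("unknown key(s) in '", blk, "': ",
                               paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(config$version) && config$version != 1)
    errs <- c(errs, "unsupported config version (expected 1)")
  if (length(errs))
    stop("invalid run configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  config
}

#' Load a run configuration from YAML
#' @param path YAML file.
#' @return Validated config list.
#' @export
load_config <- function(path) validate_config(yaml::read_yaml(path))

default_toy_config <- function(out_dir, seed = 1) {
  list(version = 1, seed = as.integer(seed), out_dir = out_dir,
       fixtures = list(grid_extent = c(-10, -8, 36, 38), grid_step = 0.08,
                       n_days = 20, n_pops = 2, n_loci = 120,
                       n_ind_per_pop = 15, fst_target = 0.15,
                       ancestral_maf_range = c(0.1, 0.5),
                       missing_rate = 0.02,
                       n_haplotypes = 4, seq_len = 40,
                       hap_n_per_pop = 12),
       dispersal = list(enabled = TRUE, kind = "uniform",
                        params = list(u = 0.1, v = 0.02),
                        release_per_day = 1, step_h = 1, max_days = 5),
       popgen_snp = list(enabled = TRUE, min_call_rate = 0.9,
                         min_maf = 0.05, n_perm = 99),
       popgen_mtdna = list(enabled = TRUE, n_perm = 99),
       clustering = list(enabled = TRUE, k_range = 1:3, replicates = 3,
                         iters = 300, burnin = 100),
       telemetry = list(enabled = TRUE))
}

#' Write the bundled toy configuration to a YAML file
#'
#' A small end-to-end configuration exercising every stage in minutes on a
#' single core.
#' @param path Output YAML path.
#' @param out_dir Output directory recorded in the config.
#' @param seed Master seed.
#' @export
write_toy_config <- function(path, out_dir = tempfile("run"), seed = 1) {
  yaml::write_yaml(default_toy_config(out_dir, seed), path)
  invisible(path)
}

#' Run the full pipeline from one configuration
#'
#' Executes, in dependency order: fixtures, dispersal, SNP population
#' genetics, mtDNA analyses, clustering, telemetry. Every stage draws its
#' seed deterministically from the master seed; any stage failure is
#' recorded in the manifest and downstream dependents are skipped. All
#' tabular outputs are written under \code{out_dir}; the manifest (stage
#' statuses, output paths, md5 checksums, package version, timings) is
#' written as \code{manifest.json} and returned.
#'
#' @param config A validated config list or a YAML path.
#' @return The run manifest (list), invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(config_echo = config,
                   package_version = as.character(
                     utils::packageVersion("meagreflow")),
                   stages = list())
  t_start <- Sys.time()
  state <- new.env()

  run_stage <- function(name, deps, fun) {
    blk <- config[[name]]
    if (!is.null(blk) && isFALSE(blk$enabled)) {
      manifest$stages[[name]] <<- list(status = "skipped",
                                       reason = "disabled in config")
      return(invisible(NULL))
    }
    for (d in deps) {
      st <- manifest$stages[[d]]$status
      if (is.null(st) || st != "complete") {
        manifest$stages[[name]] <<- list(status = "skipped",
                                         reason = paste("dependency", d,
                                                        "not complete"))
        return(invisible(NULL))
      }
    }
    t0 <- Sys.time()
    res <- tryCatch(list(ok = TRUE, outputs = fun()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (res$ok) {
      outs <- res$outputs
      manifest$stages[[name]] <<- list(
        status = "complete", seconds = round(el, 2),
        outputs = outs,
        checksums = as.list(tools::md5sum(unlist(outs))))
    } else {
      manifest$stages[[name]] <<- list(status = "failed", seconds =
                                         round(el, 2), error = res$msg)
    }
    invisible(NULL)
  }

  fx <- config$fixtures
  run_stage("fixtures", character(0), function() {
    cfg <- fixture_config(seed = derive_seed(seed, "fixtures"),
                          grid_extent = as.numeric(fx$grid_extent),
                          grid_step = fx$grid_step, n_days = fx$n_days,
                          n_pops = fx$n_pops, n_loci = fx$n_loci,
                          n_ind_per_pop = fx$n_ind_per_pop,
                          fst_target = fx$fst_target,
                          ancestral_maf_range =
                            as.numeric(fx$ancestral_maf_range),
                          missing_rate = fx$missing_rate)
    state$cfg <- cfg
    d <- config$dispersal
    state$field <- make_velocity_field(cfg,
                                       kind = if (is.null(d$kind)) "uniform"
                                              else d$kind,
                                       params = if (is.null(d$params))
                                         list(u = 0.1, v = 0) else d$params)
    gd <- make_genotypes(cfg)
    state$gd <- gd
    K <- if (is.null(fx$n_haplotypes)) 4L else fx$n_haplotypes
    freq <- matrix(1 / K, cfg$n_pops, K)
    state$aln <- make_haplotypes(cfg, K,
                                 if (is.null(fx$seq_len)) 40L else fx$seq_len,
                                 freq,
                                 if (is.null(fx$hap_n_per_pop)) 12L
                                 else fx$hap_n_per_pop)
    times <- as.POSIXct("2019-01-01", tz = "UTC") + 86400 * seq(0, 90, 10)
    ext <- cfg$grid_extent
    wl <- cbind(seq(ext[1] + 0.2, ext[2] - 0.2, length.out = length(times)),
                seq(ext[3] + 0.2, ext[4] - 0.2, length.out = length(times)))
    state$tracks <- list(make_track(cfg, wl, times, id = "fish1"))
    fdir <- file.path(out_dir, "fixtures")
    dir.create(fdir, showWarnings = FALSE)
    paths <- list(field = file.path(fdir, "field.csv"),
                  genotypes_tsv = file.path(fdir, "genotypes.tsv"),
                  genotypes_vcf = file.path(fdir, "genotypes.vcf"),
                  alignment = file.path(fdir, "alignment.fasta"),
                  tracks = file.path(fdir, "tracks.csv"))
    write_velocity_field(state$field, paths$field)
    write_genotypes_tsv(gd, paths$genotypes_tsv)
    write_genotypes_vcf(gd, paths$genotypes_vcf)
    write_alignment_fasta(state$aln, paths$alignment)
    write_tracks_csv(state$tracks, paths$tracks)
    paths
  })

  run_stage("dispersal", "fixtures", function() {
    d <- config$dispersal
    cfg <- state$cfg
    ext <- cfg$grid_extent
    mk_site <- function(name, cx, cy) {
      half <- 0.08
      spawning_site(name,
                    cbind(c(cx - half, cx + half, cx + half, cx - half),
                          c(cy - half, cy - half, cy + half, cy + half)),
                    season = c(1L, 5L), settlement_buffer_km = 5,
                    field = state$field)
    }
    sites <- list(mk_site("siteA", ext[1] + 0.4, ext[3] + 0.4),
                  mk_site("siteB", ext[1] + 0.8, ext[3] + 0.6))
    trajs <- run_simulation(state$field, sites,
                            release_per_day = d$release_per_day,
                            step_h = d$step_h, max_days = d$max_days)
    ddir <- file.path(out_dir, "dispersal")
    dir.create(ddir, showWarnings = FALSE)
    paths <- list(trajectories = file.path(ddir, "trajectories.csv"),
                  stats = file.path(ddir, "dispersal_stats.csv"),
                  connectivity = file.path(ddir, "connectivity.csv"))
    utils::write.csv(as.data.frame(trajs), paths$trajectories,
                     row.names = FALSE)
    utils::write.csv(dispersal_stats(trajs), paths$stats, row.names = FALSE)
    cm <- connectivity_matrix(trajs, sites)
    utils::write.csv(data.frame(site = cm$sites, cm$P,
                                n_released = cm$n_released),
                     paths$connectivity, row.names = FALSE)
    paths
  })

  run_stage("popgen_snp", "fixtures", function() {
    ps <- config$popgen_snp
    gd <- state$gd
    filt <- filter_loci(gd,
                        min_call_rate = ps$min_call_rate,
                        min_maf = ps$min_maf,
                        min_reproducibility = ps$min_reproducibility)
    gd2 <- exclude_failed_samples(filt$data, 0.5)$data
    state$gd_filtered <- gd2
    pdir <- file.path(out_dir, "popgen_snp")
    dir.create(pdir, showWarnings = FALSE)
    np <- if (is.null(ps$n_perm)) 99 else ps$n_perm
    pw <- pairwise_fst(gd2, n_perm = np,
                       seed = derive_seed(seed, "pairwise_fst"))
    div <- diversity(gd2)
    outl <- outlier_scan(gd2, n_perm = np,
                         seed = derive_seed(seed, "outlier"))
    pops <- sort(unique(gd2$locality))
    coords <- cbind(lon = seq(-9, -7, length.out = length(pops)),
                    lat = seq(44, 36, length.out = length(pops)))
    rownames(coords) <- pops
    geo <- geo_distance_matrix(coords)
    mant <- if (length(pops) >= 3)
      ibd_mantel(pw$fst, geo, n_perm = max(np, 99),
                 seed = derive_seed(seed, "mantel")) else NULL
    paths <- list(diversity = file.path(pdir, "diversity.csv"),
                  fst = file.path(pdir, "pairwise_fst.csv"),
                  outliers = file.path(pdir, "outliers.csv"),
                  summary = file.path(pdir, "summary.json"))
    utils::write.csv(div, paths$diversity, row.names = FALSE)
    utils::write.csv(data.frame(locality = rownames(pw$fst), pw$fst),
                     paths$fst, row.names = FALSE)
    utils::write.csv(outl, paths$outliers, row.names = FALSE)
    jsonlite::write_json(list(removed = as.list(filt$removed),
                              kept = filt$kept,
                              mantel = mant),
                         paths$summary, auto_unbox = TRUE, digits = NA)
    paths
  })

  run_stage("popgen_mtdna", "fixtures", function() {
    pm <- config$popgen_mtdna
    tab <- collapse_haplotypes(state$aln)
    np <- if (is.null(pm$n_perm)) 99 else pm$n_perm
    pw <- pairwise_fst_haplotype(tab, n_perm = np,
                                 seed = derive_seed(seed, "mtdna_fst"))
    net <- median_joining(tab)
    mdir <- file.path(out_dir, "popgen_mtdna")
    dir.create(mdir, showWarnings = FALSE)
    paths <- list(haplotypes = file.path(mdir, "haplotype_counts.csv"),
                  fst = file.path(mdir, "pairwise_fst.csv"),
                  network = file.path(mdir, "network_edges.csv"),
                  diversity = file.path(mdir, "diversity.csv"))
    utils::write.csv(data.frame(haplotype = rownames(tab$counts),
                                tab$counts), paths$haplotypes,
                     row.names = FALSE)
    utils::write.csv(data.frame(locality = rownames(pw$fst), pw$fst),
                     paths$fst, row.names = FALSE)
    utils::write.csv(net$edges, paths$network, row.names = FALSE)
    hdiv <- data.frame(
      locality = c(colnames(tab$counts), "pooled"),
      h = c(vapply(colnames(tab$counts), function(l)
        haplotype_diversity(tab, l), numeric(1)),
        haplotype_diversity(tab)))
    utils::write.csv(hdiv, paths$diversity, row.names = FALSE)
    paths
  })

  run_stage("clustering", "popgen_snp", function() {
    cl <- config$clustering
    gd2 <- state$gd_filtered
    scan <- admixture_scan(gd2, k_range = cl$k_range,
                           replicates = cl$replicates, iters = cl$iters,
                           burnin = cl$burnin,
                           seed = derive_seed(seed, "admixture"))
    D <- allele_sharing_dist(gd2)
    pc <- pcoa(D, n_axes = 2)
    dp <- dapc(gd2)
    cdir <- file.path(out_dir, "clustering")
    dir.create(cdir, showWarnings = FALSE)
    best_k <- attr(scan$selection, "best_K")
    bk <- if (is.na(best_k)) cl$k_range[1] else best_k
    Q <- scan$fits[[as.character(bk)]][[1]]$Q
    qlong <- data.frame(ind = rep(gd2$ind_id, ncol(Q)),
                        locality = rep(gd2$locality, ncol(Q)),
                        cluster = rep(colnames(Q), each = nrow(Q)),
                        q = as.vector(Q))
    paths <- list(delta_k = file.path(cdir, "delta_k.csv"),
                  q_matrix = file.path(cdir, "q_matrix_long.csv"),
                  pcoa = file.path(cdir, "pcoa.csv"),
                  dapc = file.path(cdir, "dapc.csv"))
    utils::write.csv(scan$selection, paths$delta_k, row.names = FALSE)
    utils::write.csv(qlong, paths$q_matrix, row.names = FALSE)
    utils::write.csv(data.frame(ind = gd2$ind_id,
                                locality = gd2$locality, pc$coords),
                     paths$pcoa, row.names = FALSE)
    utils::write.csv(data.frame(ind = gd2$ind_id,
                                locality = gd2$locality,
                                assigned = dp$assigned, dp$scores),
                     paths$dapc, row.names = FALSE)
    paths
  })

  run_stage("telemetry", "fixtures", function() {
    tl <- config$telemetry
    tdir <- file.path(out_dir, "telemetry")
    dir.create(tdir, showWarnings = FALSE)
    summ <- do.call(rbind, lapply(state$tracks, function(tr) {
      d <- track_distances(tr)
      data.frame(id = tr$id, n_records = nrow(tr$records),
                 cumulative_km = d$cumulative_km,
                 max_displacement_km = d$max_displacement_km,
                 annual_km = annual_distance_km(tr))
    }))
    paths <- list(summary = file.path(tdir, "track_summary.csv"))
    utils::write.csv(summ, paths$summary, row.names = FALSE)
    paths
  })

  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs")), 2)
  mpath <- file.path(out_dir, "manifest.json")
  # timestamps/timings excluded from the reproducibility contract; the
  # checksums of stage outputs are the determinism surface
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
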