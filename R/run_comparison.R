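#' End-to-end run configuration
#'
#' Bundles every knob of a comparison run. Serialises losslessly to JSON
#' via [save_config()] / [load_config()]; every pipeline output records
#' the exact configuration used.
#'
#' @param half_life_h isotope half-life, hours.
#' @param range_mm maximum beta range in soft tissue, mm (Y-90: 11.3).
#' @param isotope spectrum id.
#' @param voxel_mm voxel size of the study grid.
#' @param source_edge stride (source-patch edge) in voxels.
#' @param overlap per-face overlap; `NULL` sizes it from the range via
#'   [min_overlap_voxels()].
#' @param n_primaries total primaries per method.
#' @param n_batches batches per simulation.
#' @param kernel_edge,kernel_primaries voxel S-value kernel settings.
#' @param cutoff_kev transport cutoff.
#' @param seed master seed.
#' @export
run_config <- function(half_life_h = 64.2, range_mm = 11.3,
                       isotope = "Y90", voxel_mm = 9.59,
                       source_edge = 32, overlap = NULL,
                       n_primaries = 1e6, n_batches = 10,
                       kernel_edge = 25, kernel_primaries = 1e6,
                       cutoff_kev = 15, seed = 1) {
  if (is.null(overlap)) overlap <- min_overlap_voxels(range_mm, voxel_mm)
  structure(list(half_life_h = half_life_h, range_mm = range_mm,
                 isotope = isotope, voxel_mm = voxel_mm,
                 source_edge = as.integer(source_edge),
                 overlap = as.integer(overlap),
                 n_primaries = n_primaries, n_batches = as.integer(n_batches),
                 kernel_edge = as.integer(kernel_edge),
                 kernel_primaries = kernel_primaries,
                 cutoff_kev = cutoff_kev, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full method comparison on one study
#'
#' Executes whole-volume Monte Carlo (the reference), kernel-convolution
#' dosimetry, and the patch-based Monte Carlo under all three cropping
#' layouts at matched total primaries, then evaluates VOI mean doses,
#' voxel-wise PD maps and overlap-region statistics (all layouts share
#' the overlap bands of the overlap-average layout, so the comparison
#' region is identical across methods).
#'
#' @param tia `voxel_grid` of decays.
#' @param ct `voxel_grid` of HU.
#' @param vois `voxel_grid` of integer VOI labels (1 = liver, 2 = lungs,
#'   3 = remainder of body), or `NULL` to skip VOI tables.
#' @param config a [run_config()].
#' @param layouts character subset of `c("cl1","cl2","cl3")`.
#' @return a `dose_report` bundle: dose and uncertainty grids per method,
#'   PD maps, VOI table, region statistics, mean uncertainties and the
#'   configuration.
#' @export
run_comparison <- function(tia, ct, vois = NULL, config = run_config(),
                           layouts = c("cl1", "cl2", "cl3")) {
  density <- hu_to_density(ct)
  cfg_mc <- transport_config(cutoff_kev = config$cutoff_kev)
  spectrum <- beta_spectrum(config$isotope)
  eval_mask <- evaluation_mask(density)

  ref_tally <- run_simulation(tia, density, config$n_primaries,
                              config$n_batches, cfg_mc, config$seed,
                              spectrum)
  ref_m <- merge_batches(ref_tally)
  ref_dose <- scale_to_absolute(
    grid_like(tia, ref_m$mean, "dose_per_primary"), sum(tia$values))
  ref_unc <- grid_like(tia, ref_m$uncertainty_pct, "uncertainty")

  kern <- generate_vsv(edge = config$kernel_edge,
                       voxel_mm = config$voxel_mm,
                       n_primaries = config$kernel_primaries,
                       seed = config$seed, spectrum = spectrum)
  kdose <- kernel_dose(tia, kern, density)

  doses <- list(mc = ref_dose, kernel = kdose)
  uncs <- list(mc = ref_unc)
  patchsets <- list()
  for (ly in layouts) {
    layout <- if (ly == "cl1") layout_spec("cl1", config$source_edge) else
      layout_spec(ly, config$source_edge, config$overlap)
    run <- patch_mc_dose(tia, density, layout, config$n_primaries,
                         config$n_batches, cfg_mc, config$seed, spectrum)
    doses[[ly]] <- run$dose
    uncs[[ly]] <- run$uncertainty_pct
    patchsets[[ly]] <- run$patchset
  }

  band <- overlap_region_mask(layout_spec("cl2", config$source_edge,
                                          config$overlap),
                              dim(tia$values))
  methods <- setdiff(names(doses), "mc")
  pd_maps <- lapply(doses[methods], function(d) pd_map(ref_dose, d))
  region <- lapply(pd_maps, region_statistics, eval_mask = eval_mask,
                   overlap_mask = band)

  voi_table <- NULL
  if (!is.null(vois)) {
    labels <- c(liver = 1L, lungs = 2L, rob = 3L)
    voi_table <- do.call(rbind, lapply(names(doses), function(m) {
      do.call(rbind, lapply(names(labels), function(vn) {
        mask <- vois$values == labels[[vn]] & eval_mask
        md <- if (any(mask)) voi_mean_dose(doses[[m]], mask) else NA_real_
        data.frame(method = m, voi = vn, mean_dose_gy = md,
                   pd_vs_mc = NA_real_)
      }))
    }))
    for (r in seq_len(nrow(voi_table))) {
      refrow <- voi_table$method == "mc" & voi_table$voi == voi_table$voi[r]
      dref <- voi_table$mean_dose_gy[refrow]
      if (voi_table$method[r] != "mc" && is.finite(dref) && dref > 0)
        voi_table$pd_vs_mc[r] <-
          percentage_difference(dref, voi_table$mean_dose_gy[r])
    }
  }

  mean_unc <- vapply(uncs, function(u) {
    m <- eval_mask & u$values > 0
    if (any(m)) mean(u$values[m]) else NA_real_
  }, numeric(1))

  structure(list(doses = doses, uncertainties = uncs, pd_maps = pd_maps,
                 region_statistics = region, voi_table = voi_table,
                 mean_uncertainty_pct = mean_unc, overlap_mask = band,
                 eval_mask = eval_mask, patchsets = patchsets,
                 config = config),
            class = "dose_report")
}

#' Write a comparison bundle to disk
#'
#' Emits a machine-readable JSON summary, CSV tables (VOI doses, region
#' statistics) and, optionally, the dose / uncertainty / PD volumes as
#' NIfTI.
#'
#' @param report a `dose_report` from [run_comparison()].
#' @param dir output directory (created if missing).
#' @param volumes also write NIfTI volumes.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, volumes = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  region_df <- do.call(rbind, lapply(names(report$region_statistics),
    function(m) {
      df <- report$region_statistics[[m]]
      data.frame(method = m, region = rownames(df), df, row.names = NULL)
    }))
  summary <- list(
    config = unclass(report$config),
    mean_uncertainty_pct = as.list(report$mean_uncertainty_pct),
    region_statistics = region_df)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, jp)
  rp <- file.path(dir, "region_statistics.csv")
  write.csv(region_df, rp, row.names = FALSE)
  paths <- c(paths, rp)
  if (!is.null(report$voi_table)) {
    vp <- file.path(dir, "voi_doses.csv")
    write.csv(report$voi_table, vp, row.names = FALSE)
    paths <- c(paths, vp)
  }
  if (volumes) {
    for (m in names(report$doses)) {
      p <- file.path(dir, sprintf("dose_%s.nii.gz", m))
      write_volume(report$doses[[m]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
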