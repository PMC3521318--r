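#' Load and validate a pipeline run configuration
#'
#' The run configuration is a YAML file (or equivalent named list) with
#' blocks: `paths` (`out_dir`, optional `genotype_dir`), `experiment`
#' (`stages`, `genotypes`, `replicates`, `seed`), `light` (`n_zenith`,
#' `n_azimuth`, `rays_per_sector`), `scene` (`plot_x`, `plot_y`, `inter_row`,
#' `density_wheat`, `density_pea`) and `flags` (`export_meshes`, `plots`).
#' Unknown keys are rejected.
#'
#' @param config path to a YAML file or a named list.
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- list(
    paths = c("out_dir", "genotype_dir"),
    experiment = c("stages", "genotypes", "replicates", "seed"),
    light = c("n_zenith", "n_azimuth", "rays_per_sector"),
    scene = c("plot_x", "plot_y", "inter_row", "density_wheat", "density_pea"),
    flags = c("export_meshes", "plots"))
  bad <- setdiff(names(config), names(known))
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    extra <- setdiff(names(config[[blk]]), known[[blk]])
    if (length(extra))
      stop("unknown keys in '", blk, "': ", paste(extra, collapse = ", "))
  }
  defaults <- list(
    paths = list(out_dir = "canopymix_out", genotype_dir = NULL),
    experiment = list(stages = c(300, 600, 1240, 1560),
                      genotypes = unname(genotype_names()),
                      replicates = 8, seed = 1),
    light = list(n_zenith = 5, n_azimuth = 4, rays_per_sector = 1e5),
    scene = list(plot_x = 0.68, plot_y = 0.68, inter_row = 0.17,
                 density_wheat = 125, density_pea = 45),
    flags = list(export_meshes = FALSE, plots = FALSE))
  out <- defaults
  for (blk in names(config))
    out[[blk]] <- utils::modifyList(defaults[[blk]], config[[blk]])
  if (out$experiment$replicates < 1)
    stop("experiment$replicates must be >= 1")
  if (out$light$rays_per_sector < 1) stop("light$rays_per_sector must be >= 1")
  structure(out, class = "run_config")
}

config_scene_spec <- function(cfg, seed) {
  do.call(scene_spec, c(cfg$scene, list(seed = seed)))
}

config_sky <- function(cfg) {
  build_sky(cfg$light$n_zenith, cfg$light$n_azimuth)
}

config_genotypes <- function(cfg) {
  if (!is.null(cfg$paths$genotype_dir)) {
    files <- list.files(cfg$paths$genotype_dir, pattern = "\\.yaml$",
                        full.names = TRUE)
    specs <- lapply(files, load_genotype_spec)
    names(specs) <- vapply(specs, `[[`, "", "name")
    missing <- setdiff(cfg$experiment$genotypes, names(specs))
    if (length(missing))
      stop("genotype file(s) not found in ", cfg$paths$genotype_dir, ": ",
           paste(missing, collapse = ", "))
    specs[cfg$experiment$genotypes]
  } else {
    stats::setNames(lapply(cfg$experiment$genotypes, pea_genotype),
                    cfg$experiment$genotypes)
  }
}

log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Generate mock-ups and scene summaries for all configured stages
#'
#' Builds every configured genotype's mixture scene at every stage (seeded,
#' deterministic), writes `scene_summary.csv` to the output directory and,
#' with `flags$export_meshes`, an OBJ mesh per scene.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return The scene summary data.frame, invisibly.
#' @export
cmd_generate <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- config_genotypes(cfg)
  scenes <- list()
  for (stage in cfg$experiment$stages) {
    wstage <- wheat_stage(stage)
    for (gspec in specs) {
      seed <- derive_seed(cfg$experiment$seed,
                          1000L * match(gspec$name, names(specs)) + stage)
      pea <- mockup_variants(function(s) build_pea(gspec, stage, s),
                             n = 8, seed = derive_seed(seed, 1))
      wheat <- mockup_variants(function(s) build_wheat(wstage, s),
                               n = 8, seed = derive_seed(seed, 2))
      sspec <- config_scene_spec(cfg, derive_seed(seed, 3))
      nm <- sprintf("%s_%04d", gsub("/", "-", gspec$name), stage)
      scenes[[nm]] <- assemble_mixture(pea, wheat, sspec)
      if (isTRUE(cfg$flags$export_meshes))
        write_obj(scenes[[nm]], file.path(cfg$paths$out_dir,
                                          paste0(nm, ".obj")))
      log_msg("generated scene ", nm)
    }
  }
  out <- write_scene_summary_csv(scenes,
                                 file.path(cfg$paths$out_dir, "scene_summary.csv"))
  invisible(out)
}

#' Simulate light sharing for all configured stages
#'
#' Runs [run_stage_experiment()] per stage and writes `records.csv`.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return The records data.frame, invisibly.
#' @export
cmd_simulate <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- config_genotypes(cfg)
  sky <- config_sky(cfg)
  all_records <- list()
  for (stage in cfg$experiment$stages) {
    log_msg("simulating stage ", stage, " DD")
    recs <- run_stage_experiment(
      stage, specs, spec = config_scene_spec(cfg, 1L), sky = sky,
      seeds = derive_seed(cfg$experiment$seed, stage) +
        seq_len(cfg$experiment$replicates),
      n_rays_per_sector = cfg$light$rays_per_sector,
      on_error = "record")
    all_records[[as.character(stage)]] <- recs
  }
  records <- do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  class(records) <- c("simulation_records", "data.frame")
  write_records_csv(records, file.path(cfg$paths$out_dir, "records.csv"))
  invisible(records)
}

#' Analyze simulated light-sharing records
#'
#' Reads `records.csv` from the configured output directory, writes the
#' per-stage regression summary (`regressions.csv`) and the deviation vs
#' height-ratio fit (`height_curve.csv`), and with `flags$plots` a PDF of the
#' share scatter and isolines.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return List with `regressions` and `height_curve`, invisibly.
#' @export
cmd_analyze <- function(config) {
  cfg <- run_config(config)
  rec_path <- file.path(cfg$paths$out_dir, "records.csv")
  if (!file.exists(rec_path))
    stop("missing upstream output ", rec_path, "; run cmd_simulate first")
  records <- read_records_csv(rec_path)
  reg <- stage_regression_summary(records)
  utils::write.csv(reg, file.path(cfg$paths$out_dir, "regressions.csv"),
                   row.names = FALSE)
  hc <- tryCatch(height_ratio_curve(records), error = function(e) NULL)
  hc_df <- if (is.null(hc)) {
    data.frame(asymptote = NA_real_, rate = NA_real_, r2 = NA_real_,
               n = 0L, saturating = NA)
  } else {
    data.frame(asymptote = hc$asymptote, rate = hc$rate, r2 = hc$r2,
               n = hc$n, saturating = hc$saturating)
  }
  utils::write.csv(hc_df, file.path(cfg$paths$out_dir, "height_curve.csv"),
                   row.names = FALSE)
  if (isTRUE(cfg$flags$plots)) {
    grDevices::pdf(file.path(cfg$paths$out_dir, "analysis_plots.pdf"),
                   width = 7, height = 5)
    on.exit(grDevices::dev.off())
    plot(isolines(), col = "grey70", main = "Light-sharing isolines")
    graphics::points(records$p_pea, records$share_computed, pch = 19,
                     col = factor(records$stage))
    plot(records$share_theoretical, records$share_computed,
         xlab = "Theoretical pea share (well-mixed)",
         ylab = "Computed pea share (ray cast)",
         col = factor(records$stage), pch = 19)
    graphics::abline(0, 1, lty = 3)
    plot(records$height_ratio, records$deviation,
         xlab = "Height ratio (wheat/pea)",
         ylab = "Deviation (computed - theoretical)",
         col = factor(records$stage), pch = 19)
  }
  invisible(list(regressions = reg, height_curve = hc_df))
}

#' Fit the Schnute model to a phytomer-series CSV, Table-style output
#'
#' Reads `plant_id`, `thermal_time_dd`, `phytomer_count` (optionally a
#' `cultivar` column grouping plants) from `series_csv`, fits every plant and
#' writes the per-cultivar summary table.
#'
#' @param series_csv input CSV path.
#' @param out_csv output CSV path.
#' @return The summary data.frame, invisibly.
#' @export
cmd_fit_schnute <- function(series_csv, out_csv) {
  if (!file.exists(series_csv))
    stop("missing input ", series_csv)
  df <- utils::read.csv(series_csv, stringsAsFactors = FALSE)
  series <- read_phytomer_series(series_csv)
  labels <- if ("cultivar" %in% names(df)) {
    map <- unique(df[, c("plant_id", "cultivar")])
    stats::setNames(map$cultivar, map$plant_id)[names(series)]
  } else {
    names(series)
  }
  fits <- lapply(series, schnute_fit)
  out <- schnute_table(fits, unname(labels), path = out_csv)
  invisible(out)
}

#' Write the theoretical isoline grid for the configured sky
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return The isoline data.frame, invisibly.
#' @export
cmd_isolines <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- isolines()
  invisible(write_isolines_csv(grid, file.path(cfg$paths$out_dir,
                                               "isolines.csv")))
}
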