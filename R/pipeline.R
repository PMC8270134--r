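# End-to-end orchestration: from a habitat map and tracking points to
# ranges, selection surfaces, occupancy, complexity and integrity outputs,
# with per-stage error context and a re-derivable report.

#' Pipeline configuration
#'
#' Bundles the inputs and the method constants of a monitoring run. The
#' defaults are the framework's standard settings: individuals retained
#' with more than 10 observations, 95% range isopleth, probability
#' threshold 0.5, 30 m aggregation cells.
#'
#' @param habitat [habitat_map()] or path readable by [read_raster()].
#' @param tracking [tracking_table()] or CSV path for [read_tracking_csv()].
#' @param boundary [boundary_polygon()], GeoJSON path, or NULL (grid
#'   envelope).
#' @param species Character vector; NULL = every species in the tracking
#'   data.
#' @param min_obs Strict minimum observations per individual (default 10).
#' @param threshold Occupancy probability threshold in (0, 1); default 0.5.
#' @param isopleth Range volume-contour level (default 0.95).
#' @param agg_cell_size Aggregation cell size in metres (default 30).
#' @param bandwidth KDE bandwidth policy (`"auto"` = Scott's rule, or
#'   metres).
#' @param n_trees Selection-model ensemble size (default 500).
#' @param denominator_mode Percent denominator for complexity tables
#'   (`"site"` or `"predicted"`).
#' @param seed Integer master seed.
#' @param outdir Optional output directory for artifact files.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(habitat, tracking, boundary = NULL,
                            species = NULL, min_obs = 10L, threshold = 0.5,
                            isopleth = 0.95, agg_cell_size = 30,
                            bandwidth = "auto", n_trees = 500L,
                            denominator_mode = "site", seed = 1L,
                            outdir = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (!is.numeric(isopleth) || isopleth <= 0 || isopleth >= 1)
    stop("isopleth must lie strictly between 0 and 1")
  if (min_obs < 1) stop("min_obs must be >= 1")
  if (agg_cell_size <= 0) stop("agg_cell_size must be > 0")
  denominator_mode <- match.arg(denominator_mode, c("site", "predicted"))
  structure(list(habitat = habitat, tracking = tracking, boundary = boundary,
                 species = species, min_obs = as.integer(min_obs),
                 threshold = threshold, isopleth = isopleth,
                 agg_cell_size = agg_cell_size, bandwidth = bandwidth,
                 n_trees = as.integer(n_trees),
                 denominator_mode = denominator_mode,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage <- function(name, species = NULL, expr) {
  tryCatch(expr, error = function(e) {
    ctx <- if (is.null(species)) name else paste0(name, " [", species, "]")
    stop("pipeline stage '", ctx, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the monitoring pipeline end-to-end
#'
#' For every species: filter individuals, estimate the range (pooled KDE
#' isopleth + median individual range), generate pseudo-absences, build the
#' buffer-proportion training set, fit the selection model, predict the
#' probability surface, and classify occupancy. Then tally faunal
#' complexity, score ecological integrity before and after rewilding, and
#' assemble area tables. Identical config + seed gives identical output.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` (see [render_report()]); if `config$outdir` is
#'   set, rasters, GeoJSON ranges, CSV tables and the resolved config are
#'   written there as a side effect.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  habitat <- stage("load-habitat", NULL,
    if (inherits(config$habitat, "habitat_map")) config$habitat
    else read_raster(config$habitat, "habitat_map"))
  tracking <- stage("load-tracking", NULL,
    if (inherits(config$tracking, "data.frame")) config$tracking
    else read_tracking_csv(config$tracking))
  boundary <- stage("load-boundary", NULL,
    if (is.null(config$boundary)) boundary_from_grid(habitat$grid)
    else if (inherits(config$boundary, "boundary_polygon")) config$boundary
    else read_boundary(config$boundary))
  species <- config$species %||% sort(unique(tracking$species))
  if (!length(species)) stop("pipeline stage 'validate' failed: empty species list")

  factor <- max(1L, as.integer(ceiling(config$agg_cell_size /
                                         habitat$grid$cell_size)))
  proportions <- stage("aggregate", NULL,
                       aggregate_proportions(habitat, factor))

  per_species <- list()
  dropped <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    sp_seed <- config$seed + 1000L * i
    kept <- stage("filter", sp,
      filter_individuals(tracking, sp, boundary, config$min_obs))
    rng <- stage("range", sp,
      species_range(kept, sp, cell_size = config$agg_cell_size,
                    bandwidth = config$bandwidth, level = config$isopleth))
    pa <- stage("pseudoabs", sp,
      generate_pseudo_absences(kept, rng$median_individual_area_km2,
                               boundary, seed = sp_seed, species = sp))
    rows <- stage("features", sp,
      build_training_set(kept, pa, proportions,
                         rng$median_individual_area_km2))
    model <- stage("select", sp,
      fit_selection_model(rows, n_trees = config$n_trees, seed = sp_seed))
    surface <- stage("predict", sp,
      predict_surface(model, proportions, species = sp))
    occ <- stage("occupancy", sp,
      classify_occupancy(surface, rng, config$threshold))
    occ_table <- stage("areas", sp,
      area_summary(occ, boundary, denominator_mode = "site"))
    per_species[[sp]] <- list(
      species = sp, n_points = nrow(kept),
      n_individuals = length(unique(kept$individual_id)),
      range = rng, pseudo_absences = pa, training = rows, model = model,
      surface = surface, occupancy = occ, occupancy_table = occ_table)
    dropped[[sp]] <- data.frame(
      species = sp,
      outside_boundary = attr(kept, "dropped_outside_boundary") %||% 0L,
      individuals_below_min_obs = attr(kept, "dropped_individuals") %||% 0L)
  }

  occ_maps <- lapply(per_species, `[[`, "occupancy")
  complexity <- stage("complexity", NULL, faunal_complexity(occ_maps))
  before <- stage("integrity", NULL,
                  ecological_integrity(occ_maps, "before"))
  after <- stage("integrity", NULL,
                 ecological_integrity(occ_maps, "after"))
  delta <- stage("integrity", NULL, integrity_delta(before, after, boundary))

  occupancy_table <- do.call(rbind, lapply(per_species, function(ps) {
    tab <- ps$occupancy_table
    rk <- tab$area_km2[tab$label == "REALIZED"]
    pk <- tab$area_km2[tab$label == "POTENTIAL"]
    data.frame(species = ps$species, realized_km2 = rk,
               realized_pct = if (rk + pk > 0) realized_fraction(rk, pk)
                              else NA_real_,
               potential_km2 = pk,
               potential_pct = if (rk + pk > 0) realized_fraction(pk, rk)
                               else NA_real_)
  }))
  rownames(occupancy_table) <- NULL

  report <- structure(list(
    config = config, species = species,
    per_species = per_species,
    habitat_table = area_summary(habitat, boundary),
    occupancy_table = occupancy_table,
    complexity = complexity,
    complexity_realized = area_summary(complexity, boundary,
                                       config$denominator_mode, "realized"),
    complexity_potential = area_summary(complexity, boundary,
                                        config$denominator_mode, "potential"),
    integrity_before = before, integrity_after = after,
    integrity_tables = delta,
    dropped = do.call(rbind, dropped)), class = "run_report")
  rownames(report$dropped) <- NULL

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    render_report(report, config$outdir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("rewilding monitoring run:", length(x$species), "species\n")
  print(x$occupancy_table)
  cat(sprintf("high ecological integrity: %.1f%% before, %.1f%% after\n",
              x$integrity_tables$high_integrity_before_pct,
              x$integrity_tables$high_integrity_after_pct))
  invisible(x)
}

write_area_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
}

#' Render a run report to files
#'
#' Always writes the CSV tables (per-species occupancy in the
#' species/realized/potential layout, complexity score areas, integrity
#' before/after bins, dropped-record log), the per-species rasters and
#' range polygons, and the resolved configuration. `format = "png"` also
#' draws quick-look maps.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param format `"csv"` or `"png"` (tables plus figures).
#' @return `outdir`, invisibly.
#' @export
render_report <- function(report, outdir, format = "csv") {
  stopifnot(inherits(report, "run_report"))
  if (!format %in% c("csv", "png")) stop("unknown format: ", format)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_area_csv(report$occupancy_table, file.path(outdir, "occupancy.csv"))
  write_area_csv(report$habitat_table, file.path(outdir, "habitat_areas.csv"))
  write_area_csv(report$complexity_realized,
                 file.path(outdir, "complexity_realized.csv"))
  write_area_csv(report$complexity_potential,
                 file.path(outdir, "complexity_potential.csv"))
  it <- merge(report$integrity_tables$before, report$integrity_tables$after,
              by = "label", suffixes = c("_before", "_after"), sort = FALSE)
  write_area_csv(it, file.path(outdir, "integrity.csv"))
  write_area_csv(report$dropped, file.path(outdir, "dropped_records.csv"))
  for (ps in report$per_species) {
    slug <- gsub("[^A-Za-z0-9]+", "_", ps$species)
    write_raster(ps$surface, file.path(outdir, paste0("surface_", slug)))
    write_raster(ps$occupancy, file.path(outdir, paste0("occupancy_", slug)))
    if (length(ps$range$polygons))
      write_geojson(ps$range, file.path(outdir, paste0("range_", slug,
                                                       ".geojson")),
                    properties = list(species = ps$species,
                                      isopleth = ps$range$isopleth))
    utils::write.csv(ps$training,
                     file.path(outdir, paste0("training_", slug, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(species = ps$species, seed = ps$model$seed,
           n_trees = ps$model$n_trees, auc_train = ps$model$auc_train,
           auc_cv = ps$model$auc_cv,
           buffer_radius_m = ps$pseudo_absences$exclusion_radius_m,
           bandwidth_m = ps$range$bandwidth,
           median_individual_area_km2 = ps$range$median_individual_area_km2),
      file.path(outdir, paste0("model_", slug, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_raster(report$complexity, file.path(outdir, "complexity"))
  write_raster(report$integrity_before, file.path(outdir, "integrity_before"))
  write_raster(report$integrity_after, file.path(outdir, "integrity_after"))
  cfg <- report$config
  cfg_out <- cfg[!vapply(cfg, function(f)
    inherits(f, c("grid_raster", "data.frame", "boundary_polygon")), TRUE)]
  yaml::write_yaml(cfg_out, file.path(outdir, "config_resolved.yaml"))
  if (format == "png") {
    plot_raster_png <- function(obj, path, main) {
      grDevices::png(path, width = 800, height = 800)
      on.exit(grDevices::dev.off())
      v <- if (is.matrix(obj$values)) obj$values else obj$values[, , 1]
      graphics::image(cell_centres_x(obj$grid),
                      rev(cell_centres_y(obj$grid)),
                      t(v[obj$grid$n_rows:1, , drop = FALSE]),
                      asp = 1, xlab = "x (m)", ylab = "y (m)", main = main,
                      useRaster = TRUE)
    }
    for (ps in report$per_species) {
      slug <- gsub("[^A-Za-z0-9]+", "_", ps$species)
      plot_raster_png(ps$surface,
                      file.path(outdir, paste0("surface_", slug, ".png")),
                      paste("P(presence):", ps$species))
    }
    plot_raster_png(report$integrity_after,
                    file.path(outdir, "integrity_after.png"),
                    "Ecological integrity (after)")
  }
  invisible(outdir)
}
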