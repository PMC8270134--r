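# Raster containers. All hold a grid_spec plus a values matrix (rows =
# northing, cols = easting) or a [rows, cols, bands] array; NODATA is NA.

new_grid_raster <- function(values, grid, class, ...) {
  dims <- dim(values)
  if (is.null(dims) || dims[1] != grid$n_rows || dims[2] != grid$n_cols)
    stop("values dimensions do not match the grid (", grid$n_rows, " x ",
         grid$n_cols, ")")
  structure(list(values = values, grid = grid, ...),
            class = c(class, "grid_raster"))
}

#' Categorical habitat map
#'
#' Per-cell habitat class over a [class_catalogue()]. Labels are 1-based
#' indices into the catalogue; `NA` marks NODATA cells (e.g. an unclassifiable
#' burn scar), which are excluded from every downstream denominator.
#'
#' @param labels Integer matrix (`n_rows x n_cols`) of catalogue indices or NA.
#' @param grid A [grid_spec()].
#' @param catalogue A [class_catalogue()].
#' @return Object of class `habitat_map`.
#' @export
habitat_map <- function(labels, grid, catalogue = class_catalogue()) {
  storage.mode(labels) <- "integer"
  rng <- range(labels, na.rm = !all(is.na(labels)))
  if (!all(is.na(labels)) && (rng[1] < 1L || rng[2] > length(catalogue)))
    stop("labels must index the catalogue (1..", length(catalogue), ")")
  new_grid_raster(labels, grid, "habitat_map", catalogue = catalogue)
}

#' Fractional land-cover raster
#'
#' Per-cell fractional cover over the catalogue classes. Each non-NODATA
#' cell's fractions are >= 0 and sum to 1 within 1e-6 (the simplex
#' invariant); a cell is NODATA when all its bands are NA.
#'
#' @param values Numeric array `n_rows x n_cols x n_classes`, band order =
#'   catalogue order.
#' @inheritParams habitat_map
#' @return Object of class `proportion_raster`.
#' @export
proportion_raster <- function(values, grid, catalogue = class_catalogue()) {
  if (length(dim(values)) != 3L || dim(values)[3] != length(catalogue))
    stop("values must be an array with one band per catalogue class")
  v <- matrix(values, ncol = dim(values)[3])
  ok <- !is.na(v[, 1])
  if (any(ok)) {
    s <- rowSums(v[ok, , drop = FALSE])
    if (any(v[ok, ] < -1e-9) || any(abs(s - 1) > 1e-6))
      stop("fractions must be >= 0 and sum to 1 within 1e-6 in every cell")
  }
  new_grid_raster(values, grid, "proportion_raster", catalogue = catalogue)
}

#' Predicted probability-of-presence surface
#'
#' @param values Numeric matrix of probabilities in `[0, 1]` or NA.
#' @inheritParams habitat_map
#' @param species Species name.
#' @return Object of class `selection_surface`.
#' @export
selection_surface <- function(values, grid, species = "species") {
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  new_grid_raster(values, grid, "selection_surface", species = species)
}

OCC_NOT_PREDICTED <- 0L
OCC_REALIZED <- 1L
OCC_POTENTIAL <- 2L

occupancy_levels <- function() c("NOT_PREDICTED", "REALIZED", "POTENTIAL")

#' Per-species occupancy categories
#'
#' Cells are REALIZED (predicted and inside the species range), POTENTIAL
#' (predicted, outside the range) or NOT_PREDICTED (probability <= threshold).
#' Built by [classify_occupancy()].
#'
#' @param categories Integer matrix with codes 0 = NOT_PREDICTED,
#'   1 = REALIZED, 2 = POTENTIAL, NA = NODATA.
#' @inheritParams selection_surface
#' @param threshold Probability cut used (strict `>`).
#' @return Object of class `occupancy_map`.
#' @export
occupancy_map <- function(categories, grid, species = "species",
                          threshold = 0.5) {
  storage.mode(categories) <- "integer"
  if (!all(categories %in% c(0L, 1L, 2L, NA)))
    stop("categories must be 0 (not predicted), 1 (realized) or 2 (potential)")
  new_grid_raster(categories, grid, "occupancy_map", species = species,
                  threshold = threshold)
}

#' Faunal complexity map
#'
#' Per-cell counts of species with realized and with potential occupancy,
#' tallied over per-species occupancy maps by [faunal_complexity()].
#'
#' @param realized,potential Integer count matrices in `0..n_species`.
#' @inheritParams habitat_map
#' @param n_species Number of species tallied.
#' @return Object of class `complexity_map`.
#' @export
complexity_map <- function(realized, potential, grid, n_species) {
  storage.mode(realized) <- "integer"; storage.mode(potential) <- "integer"
  if (any(realized + potential > n_species, na.rm = TRUE))
    stop("realized + potential counts cannot exceed n_species")
  new_grid_raster(realized, grid, "complexity_map", potential = potential,
                  n_species = as.integer(n_species))
}

#' Ecological integrity map
#'
#' Per-cell mean over species of an indicator that is 0 for unrealized
#' predicted occupancy (POTENTIAL) and 1 otherwise (REALIZED or
#' NOT_PREDICTED); values lie on the lattice k / n_species. Built by
#' [ecological_integrity()].
#'
#' @param values Numeric matrix of scores on the `k / n_species` lattice.
#' @inheritParams complexity_map
#' @param scenario `"before"` or `"after"` rewilding.
#' @return Object of class `integrity_map`.
#' @export
integrity_map <- function(values, grid, n_species, scenario = "after") {
  scenario <- match.arg(scenario, c("before", "after"))
  lattice <- (0:n_species) / n_species
  v <- values[!is.na(values)]
  if (length(v) && any(apply(abs(outer(v, lattice, "-")), 1, min) > 1e-9))
    stop("integrity values must lie on the k/n_species lattice")
  new_grid_raster(values, grid, "integrity_map",
                  n_species = as.integer(n_species), scenario = scenario)
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells @ %g m (%d NODATA)\n", class(x)[1],
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(is.na(if (is.matrix(x$values)) x$values else x$values[, , 1]))))
  invisible(x)
}
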