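# Area accounting shared by every stage. All areas are cell counts times
# cell area; cells belong to a polygon iff their centre does (centre rule);
# NODATA cells never enter numerators or denominators.

inside_mask <- function(grid, boundary) {
  if (is.null(boundary))
    return(matrix(TRUE, grid$n_rows, grid$n_cols))
  cx <- cell_centres_x(grid); cy <- cell_centres_y(grid)
  pts_x <- rep(cx, each = grid$n_rows)
  pts_y <- rep(cy, times = grid$n_cols)
  matrix(boundary_contains(boundary, pts_x, pts_y),
         grid$n_rows, grid$n_cols)
}

new_area_table <- function(label, cells, cell_km2, denominator_km2,
                           total_label = "Total", add_total = TRUE) {
  area <- cells * cell_km2
  if (add_total) {
    label <- c(label, total_label)
    area <- c(area, sum(area))
  }
  tab <- data.frame(label = label, area_km2 = area,
                    percent = 100 * area / denominator_km2,
                    stringsAsFactors = FALSE)
  attr(tab, "denominator_km2") <- denominator_km2
  class(tab) <- c("area_table", "data.frame")
  tab
}

#' Area table per category or score
#'
#' Tabulates the area (km\eqn{^2}) and percentage of each label of a
#' categorical raster inside a boundary. Cells count by the centre rule;
#' NODATA cells are excluded from numerator and denominator. For
#' occupancy, complexity and integrity maps the labels are the categories,
#' scores 1..S, and the k/S lattice values respectively; for habitat maps
#' they are the catalogue classes.
#'
#' @param map A `habitat_map`, `occupancy_map`, `complexity_map` or
#'   `integrity_map`.
#' @param boundary Optional [boundary_polygon()]; NULL uses the whole grid.
#' @param denominator_mode `"site"`: percents are relative to all mapped
#'   (non-NODATA, in-boundary) cells. `"predicted"`: relative to the cells
#'   carrying a positive label (complexity maps: score >= 1; occupancy maps:
#'   REALIZED + POTENTIAL).
#' @param which For complexity maps, `"realized"` or `"potential"` layer.
#' @return An `area_table` data frame with columns `label`, `area_km2`,
#'   `percent` and a totals row; the denominator is attached as attribute
#'   `denominator_km2`.
#' @export
area_summary <- function(map, boundary = NULL,
                         denominator_mode = c("site", "predicted"),
                         which = c("realized", "potential")) {
  denominator_mode <- match.arg(denominator_mode)
  which <- match.arg(which)
  if (!inherits(map, "grid_raster")) stop("map is not a raster object")
  ck <- cell_area_km2(map$grid)
  inb <- inside_mask(map$grid, boundary)
  vals <- if (inherits(map, "complexity_map") && which == "potential")
    map$potential else map$values
  mapped <- inb & !is.na(vals)
  if (!any(mapped)) stop("empty intersection between map and boundary")
  site_km2 <- sum(mapped) * ck
  v <- vals[mapped]
  if (inherits(map, "habitat_map")) {
    cells <- tabulate(v, nbins = length(map$catalogue))
    tab <- new_area_table(as.character(map$catalogue), cells, ck, site_km2)
  } else if (inherits(map, "occupancy_map")) {
    cells <- c(sum(v == OCC_REALIZED), sum(v == OCC_POTENTIAL),
               sum(v == OCC_NOT_PREDICTED))
    den <- if (denominator_mode == "predicted")
      (cells[1] + cells[2]) * ck else site_km2
    if (den == 0) stop("no predicted cells: denominator is zero")
    tab <- new_area_table(c("REALIZED", "POTENTIAL", "NOT_PREDICTED"),
                          cells, ck, den)
  } else if (inherits(map, "complexity_map")) {
    s <- map$n_species
    cells <- tabulate(v, nbins = s)   # scores 1..S; zero-score cells excluded
    den <- if (denominator_mode == "predicted") sum(cells) * ck else site_km2
    if (den == 0) stop("no cells with species: denominator is zero")
    tab <- new_area_table(paste(seq_len(s), "species"), cells, ck, den)
  } else if (inherits(map, "integrity_map")) {
    s <- map$n_species
    lattice <- (0:s) / s
    cells <- vapply(lattice, function(l) sum(abs(v - l) < 1e-9), 0L)
    tab <- new_area_table(as.character(lattice), cells, ck, site_km2)
  } else {
    stop("area_summary is not defined for ", class(map)[1])
  }
  tab
}

#' Proportion of predicted area already occupied
#'
#' `100 * realized / (realized + potential)`, the percentage of the area
#' predicted to be selected by a species (probability of presence above the
#' threshold) that falls inside its current range. Reported to one decimal.
#'
#' @param realized_km2,potential_km2 Areas in km\eqn{^2}.
#' @return Percentage (one decimal).
#' @export
realized_fraction <- function(realized_km2, potential_km2) {
  stopifnot(is.numeric(realized_km2), is.numeric(potential_km2),
            realized_km2 >= 0, potential_km2 >= 0)
  den <- realized_km2 + potential_km2
  if (any(den <= 0)) stop("realized + potential must be > 0")
  round(100 * realized_km2 / den, 1)
}
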