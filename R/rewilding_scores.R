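# The scoring algebra: realized/potential occupancy per species, faunal
# complexity tallies, and the ecological-integrity score before vs after
# reintroduction.

#' Classify cells into realized / potential / not-predicted occupancy
#'
#' A cell is REALIZED when its predicted probability of presence is
#' strictly greater than `threshold` and its centre lies inside the species
#' range; POTENTIAL when the probability exceeds the threshold outside the
#' range; NOT_PREDICTED otherwise (a probability exactly at the threshold is
#' NOT_PREDICTED). With an empty range (NULL) every predicted cell is
#' POTENTIAL — the before-rewilding state.
#'
#' @param surface A [selection_surface()].
#' @param range A `range_estimate`/`range_contour` from [species_range()],
#'   or NULL for an empty range.
#' @param threshold Probability cut in (0, 1); default 0.5.
#' @return An [occupancy_map()].
#' @export
classify_occupancy <- function(surface, range = NULL, threshold = 0.5) {
  stopifnot(inherits(surface, "selection_surface"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  g <- surface$grid
  predicted <- surface$values > threshold            # strict
  cat_m <- matrix(OCC_NOT_PREDICTED, g$n_rows, g$n_cols)
  if (any(predicted, na.rm = TRUE)) {
    cx <- rep(cell_centres_x(g), each = g$n_rows)
    cy <- rep(cell_centres_y(g), times = g$n_cols)
    inr <- matrix(range_contains(range, cx, cy), g$n_rows, g$n_cols)
    cat_m[predicted & inr] <- OCC_REALIZED
    cat_m[predicted & !inr] <- OCC_POTENTIAL
  }
  cat_m[is.na(surface$values)] <- NA_integer_
  occupancy_map(cat_m, g, species = surface$species, threshold = threshold)
}

check_shared_grid <- function(maps) {
  if (!length(maps)) stop("no occupancy maps supplied")
  g <- maps[[1]]$grid
  for (m in maps[-1])
    if (!grids_identical(g, m$grid)) stop("occupancy maps have mismatched grids")
  g
}

#' Faunal complexity: per-cell species tallies
#'
#' Counts, at every cell, how many species have realized occupancy and how
#' many have potential occupancy, over one occupancy map per species. The
#' score runs from 0 to the number of reintroduced species.
#'
#' @param maps List of [occupancy_map()]s (one per species, shared grid).
#' @return A [complexity_map()].
#' @export
faunal_complexity <- function(maps) {
  g <- check_shared_grid(maps)
  realized <- matrix(0L, g$n_rows, g$n_cols)
  potential <- matrix(0L, g$n_rows, g$n_cols)
  anyna <- matrix(FALSE, g$n_rows, g$n_cols)
  for (m in maps) {
    stopifnot(inherits(m, "occupancy_map"))
    v <- m$values
    anyna <- anyna | is.na(v)
    realized <- realized + (!is.na(v) & v == OCC_REALIZED)
    potential <- potential + (!is.na(v) & v == OCC_POTENTIAL)
  }
  realized[anyna] <- NA_integer_
  potential[anyna] <- NA_integer_
  complexity_map(realized, potential, g, n_species = length(maps))
}

#' Ecological integrity score
#'
#' Per species and cell, an indicator is 0 when the cell is predicted to be
#' occupied but lies outside the species range (POTENTIAL — unrealized
#' rewilding potential) and 1 otherwise: either the prediction is realized
#' (REALIZED) or the species is not predicted there, in which case the cell
#' already fulfils its rewilding potential. The integrity score is the mean
#' indicator over species, so it lies on the lattice k / n_species. Under
#' `scenario = "before"` every species' range is treated as empty, turning
#' all predicted cells into unrealized potential.
#'
#' @param maps List of [occupancy_map()]s (one per species, shared grid).
#' @param scenario `"after"` (use the ranges as classified) or `"before"`
#'   (empty ranges).
#' @return An [integrity_map()].
#' @export
ecological_integrity <- function(maps, scenario = c("after", "before")) {
  scenario <- match.arg(scenario)
  g <- check_shared_grid(maps)
  s <- length(maps)
  total <- matrix(0, g$n_rows, g$n_cols)
  anyna <- matrix(FALSE, g$n_rows, g$n_cols)
  for (m in maps) {
    stopifnot(inherits(m, "occupancy_map"))
    v <- m$values
    anyna <- anyna | is.na(v)
    unrealized <- if (scenario == "before") v %in% c(OCC_REALIZED, OCC_POTENTIAL)
                  else v %in% OCC_POTENTIAL
    indicator <- 1 - (matrix(unrealized, nrow(v), ncol(v)) & !is.na(v))
    total <- total + indicator
  }
  score <- total / s
  score[anyna] <- NA_real_
  integrity_map(score, g, n_species = s, scenario = scenario)
}

high_integrity_pct <- function(map, boundary = NULL) {
  inb <- inside_mask(map$grid, boundary)
  v <- map$values[inb & !is.na(map$values)]
  if (!length(v)) stop("empty intersection between map and boundary")
  100 * mean(v > 0.5)
}

#' Compare ecological integrity before and after rewilding
#'
#' Tabulates per-score areas and site percentages for both scenarios
#' ([area_summary()] on the k/S lattice bins) and reports the
#' high-integrity fraction — the percentage of the site with a score
#' strictly greater than 0.5 — for each, plus the per-bin change.
#'
#' @param before,after [integrity_map()]s on the same grid.
#' @param boundary Optional [boundary_polygon()].
#' @return List with `before` and `after` area tables, `delta` (after -
#'   before, per bin), `high_integrity_before_pct`,
#'   `high_integrity_after_pct`.
#' @export
integrity_delta <- function(before, after, boundary = NULL) {
  stopifnot(inherits(before, "integrity_map"), inherits(after, "integrity_map"))
  if (!grids_identical(before$grid, after$grid))
    stop("integrity maps have mismatched grids")
  tb <- area_summary(before, boundary)
  ta <- area_summary(after, boundary)
  delta <- data.frame(label = tb$label,
                      area_km2 = ta$area_km2 - tb$area_km2,
                      percent = ta$percent - tb$percent)
  list(before = tb, after = ta, delta = delta,
       high_integrity_before_pct = high_integrity_pct(before, boundary),
       high_integrity_after_pct = high_integrity_pct(after, boundary))
}
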