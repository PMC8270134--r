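#' Define a planar raster grid
#'
#' A `grid_spec` describes a north-up raster grid in a projected (metric)
#' coordinate reference system. `origin_x`/`origin_y` are the map coordinates
#' of the grid's top-left corner; rows increase southward, so the centre of
#' cell (r, c) is at
#' `(origin_x + (c - 0.5) * cell_size, origin_y - (r - 0.5) * cell_size)`.
#'
#' @param origin_x,origin_y Top-left corner, metres.
#' @param cell_size Cell edge length in metres (> 0).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param crs Free-text CRS declaration; any equal-area metric projection is
#'   acceptable. Geographic (degree) CRSs are rejected throughout the package.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                      crs = "local-metric") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), is.finite(origin_x),
            is.finite(origin_y))
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0 (metres)")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = n_rows, n_cols = n_cols,
                 crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' @rdname grid_spec
#' @param g A `grid_spec`.
#' @export
cell_centres_x <- function(g) g$origin_x + (seq_len(g$n_cols) - 0.5) * g$cell_size

#' @rdname grid_spec
#' @export
cell_centres_y <- function(g) g$origin_y - (seq_len(g$n_rows) - 0.5) * g$cell_size

#' @rdname grid_spec
#' @export
cell_area_km2 <- function(g) g$cell_size^2 / 1e6

# Map planar coordinates to (row, col); cells outside the grid get NA.
point_to_cell <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell_size) + 1
  row <- floor((g$origin_y - y) / g$cell_size) + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > g$n_cols | row < 1 | row > g$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

grids_identical <- function(a, b, tol = 1e-6) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

crs_is_geographic <- function(crs) {
  grepl("4326|longlat|long/lat|degree|wgs *84(?!.*utm)", tolower(crs %||% ""),
        perl = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Habitat class catalogue
#'
#' An ordered, unique list of land-cover class names. The order is fixed at
#' creation and defines channel order in every multi-band raster.
#'
#' @param classes Character vector of unique class names.
#' @return Object of class `class_catalogue` (a character vector).
#' @export
class_catalogue <- function(classes = default_habitat_classes()) {
  classes <- as.character(classes)
  if (length(classes) < 1L) stop("catalogue needs at least one class")
  if (anyDuplicated(classes)) stop("catalogue class names must be unique")
  if (any(!nzchar(classes))) stop("catalogue class names must be non-empty")
  structure(classes, class = "class_catalogue")
}

#' @rdname class_catalogue
#' @details `default_habitat_classes()` returns the ten-class catalogue used
#'   for a subtropical forest-savanna-grassland mosaic: aquatic vegetation,
#'   artificial surfaces, bare ground, broadleaf forest, free-standing trees,
#'   palms, short grassland, tall grassland, Vernonia shrubland, water.
#' @export
default_habitat_classes <- function() {
  c("aquatic vegetation", "artificial surfaces", "bare ground",
    "broadleaf forest", "free-standing trees", "palms", "short grassland",
    "tall grassland", "Vernonia shrubland", "water")
}

#' @rdname class_catalogue
#' @details `modelled_habitat_classes()` returns the four classes used as
#'   covariates in the habitat-selection models.
#' @export
modelled_habitat_classes <- function() {
  c("broadleaf forest", "free-standing trees", "short grassland",
    "tall grassland")
}
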