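# Species-range estimation: Gaussian kernel density surfaces evaluated on
# the analysis grid, 95% volume contours (smallest cell set holding the
# stated density mass), per-individual range areas, and exclusion-zone
# pseudo-absence generation.

#' Filter tracking records to well-sampled individuals
#'
#' Removes records outside the study boundary first, then keeps only
#' individuals with strictly more than `min_obs` remaining observations
#' (an individual with exactly `min_obs` points is excluded).
#'
#' @param table A [tracking_table()].
#' @param species Species to keep.
#' @param boundary Optional [boundary_polygon()]; applied before counting.
#' @param min_obs Minimum observation count (strict `>`); default 10.
#' @return The filtered [tracking_table()].
#' @export
filter_individuals <- function(table, species, boundary = NULL,
                               min_obs = 10L) {
  if (min_obs < 1L) stop("min_obs must be >= 1")
  tab <- table[table$species == species, , drop = FALSE]
  n_out <- 0L
  if (!is.null(boundary) && nrow(tab)) {
    inside <- boundary_contains(boundary, tab$x, tab$y)
    n_out <- sum(!inside)
    tab <- tab[inside, , drop = FALSE]
  }
  counts <- table(tab$individual_id)
  keep_ids <- names(counts)[counts > min_obs]
  if (!length(keep_ids))
    stop("no individual of '", species, "' retains more than ", min_obs,
         " in-boundary observations")
  out <- tab[tab$individual_id %in% keep_ids, , drop = FALSE]
  attr(out, "dropped_outside_boundary") <- n_out
  attr(out, "dropped_individuals") <-
    length(counts) - length(keep_ids)
  class(out) <- c("tracking_table", "data.frame")
  out
}

scott_bandwidth <- function(x, y) {
  n <- length(x)
  h <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  if (all(h == 0) || any(!is.finite(h)))
    stop("degenerate bandwidth: all points identical")
  if (h[1] == 0) h[1] <- h[2]
  if (h[2] == 0) h[2] <- h[1]
  h
}

#' Gaussian kernel density surface on a grid
#'
#' Evaluates a product-Gaussian kernel density at the cell centres of
#' `grid` and renormalises so that `sum(density) * cell_area = 1`. The
#' default bandwidth is Scott's rule per axis
#' (\eqn{h_j = s_j n^{-1/6}}); the bandwidth used is recorded on the
#' result for provenance.
#'
#' @param points Data frame (or list) with `x`, `y` in metres (>= 2 points).
#' @param grid A [grid_spec()].
#' @param bandwidth `"auto"` (Scott's rule) or a positive scalar / length-2
#'   vector of kernel standard deviations in metres.
#' @return A `density_surface` (values matrix, grid, bandwidth).
#' @export
kde_density <- function(points, grid, bandwidth = "auto") {
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  n <- length(x)
  if (n < 2L) stop("at least 2 points are required")
  h <- if (identical(bandwidth, "auto")) scott_bandwidth(x, y)
       else {
         bw <- rep(as.numeric(bandwidth), length.out = 2)
         if (any(!is.finite(bw)) || any(bw <= 0)) stop("bandwidth must be > 0")
         bw
       }
  cx <- cell_centres_x(grid); cy <- cell_centres_y(grid)
  kx <- stats::dnorm(outer(x, cx, "-") / h[1])   # n x n_cols
  ky <- stats::dnorm(outer(y, cy, "-") / h[2])   # n x n_rows
  dens <- crossprod(ky, kx) / (n * h[1] * h[2])  # n_rows x n_cols, per m^2
  total <- sum(dens) * grid$cell_size^2
  if (total <= 0) stop("density mass on the grid is zero; enlarge the grid")
  dens <- dens / total                            # mass exactly 1 on the grid
  structure(list(values = dens, grid = grid, bandwidth = h),
            class = c("density_surface", "grid_raster"))
}

density_mass <- function(d) d$values * d$grid$cell_size^2

#' Volume contour of a density surface
#'
#' Ranks cells by density and accumulates mass until at least `level` is
#' enclosed: the smallest-area cell set holding that fraction of the
#' probability mass. The cell set is polygonised into rings for export; the
#' enclosed mass lies in `[level, level + one cell's mass]`.
#'
#' @param density A `density_surface` from [kde_density()].
#' @param level Mass fraction in (0, 1); 0.95 for the standard isopleth.
#' @return A `range_contour`: logical `mask`, `grid`, `area_km2`, enclosed
#'   `mass` and `polygons` (list of ring matrices).
#' @export
volume_contour <- function(density, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  mass <- density_mass(density)
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(ord)  # grid holds < level of the mass
  mask <- matrix(FALSE, density$grid$n_rows, density$grid$n_cols)
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(mask = mask, grid = density$grid,
                 area_km2 = k * cell_area_km2(density$grid),
                 mass = cum[k],
                 polygons = mask_to_polygons(mask, density$grid)),
            class = "range_contour")
}

# Trace iso-lines of the 0/1 mask at 0.5 to get exportable rings.
mask_to_polygons <- function(mask, grid) {
  if (!any(mask)) return(list())
  z <- mask + 0
  cx <- cell_centres_x(grid)
  cy_inc <- rev(cell_centres_y(grid))
  z_inc <- t(z[grid$n_rows:1, , drop = FALSE])  # z[x, y] with increasing x, y
  cl <- grDevices::contourLines(x = cx, y = cy_inc, z = z_inc, levels = 0.5)
  lapply(cl, function(seg) close_ring(cbind(seg$x, seg$y)))
}

#' Does a range contain given points?
#'
#' Centre rule on the contour's own grid: a point is inside iff it falls in
#' a cell of the contour's cell set; points off the grid are outside.
#'
#' @param range A `range_contour` or `range_estimate` (or NULL = empty
#'   range, nothing contained).
#' @param x,y Point coordinates.
#' @return Logical vector.
#' @export
range_contains <- function(range, x, y) {
  if (is.null(range)) return(rep(FALSE, length(x)))
  if (inherits(range, "range_estimate")) range <- range$contour
  rc <- point_to_cell(range$grid, x, y)
  ok <- !is.na(rc$row)
  out <- rep(FALSE, length(x))
  out[ok] <- range$mask[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Build a range from an explicit cell mask
#'
#' Wraps a logical cell mask as a `range_contour`, e.g. to treat the full
#' predicted area of a surface as a hypothetical species range when
#' exploring how integrity would respond to complete range filling.
#'
#' @param mask Logical matrix on `grid` (TRUE = inside the range).
#' @param grid A [grid_spec()].
#' @return A `range_contour`.
#' @export
range_from_mask <- function(mask, grid) {
  stopifnot(is.logical(mask), nrow(mask) == grid$n_rows,
            ncol(mask) == grid$n_cols)
  structure(list(mask = mask, grid = grid,
                 area_km2 = sum(mask, na.rm = TRUE) * cell_area_km2(grid),
                 mass = NA_real_,
                 polygons = mask_to_polygons(!is.na(mask) & mask, grid)),
            class = "range_contour")
}

default_range_grid <- function(x, y, h, cell_size, crs = "local-metric") {
  pad <- 3 * max(h)
  x0 <- floor((min(x) - pad) / cell_size) * cell_size
  y1 <- ceiling((max(y) + pad) / cell_size) * cell_size
  n_cols <- ceiling((max(x) + pad - x0) / cell_size)
  n_rows <- ceiling((y1 - (min(y) - pad)) / cell_size)
  grid_spec(x0, y1, cell_size, n_rows, n_cols, crs = crs)
}

#' Estimate a species range from tracking data
#'
#' Pools all retained individuals' points into one kernel density
#' ([kde_density()]) and takes the `level` volume contour as the species
#' range (area of occupancy). Each individual's range area is computed the
#' same way from its own points, and the median of those areas — the median
#' individual range — parameterises pseudo-absence exclusion and buffer
#' extraction downstream. Apply [filter_individuals()] first.
#'
#' @param table A filtered [tracking_table()] (single species).
#' @param species Species name.
#' @param grid Optional [grid_spec()] for the KDE; by default the points'
#'   bounding box padded by 3 bandwidths at `cell_size` resolution.
#' @param cell_size Cell size of the default grid, metres (30 by default,
#'   matching the aggregated habitat raster).
#' @param bandwidth Passed to [kde_density()].
#' @param level Isopleth mass fraction (default 0.95).
#' @return A `range_estimate`: `species`, `contour`, `polygons`,
#'   `area_km2`, `per_individual_areas_km2`, `median_individual_area_km2`,
#'   `bandwidth`, `isopleth`.
#' @export
species_range <- function(table, species = table$species[1], grid = NULL,
                          cell_size = 30, bandwidth = "auto", level = 0.95) {
  tab <- table[table$species == species, , drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 points for '", species, "'")
  h <- if (identical(bandwidth, "auto")) scott_bandwidth(tab$x, tab$y)
       else rep(as.numeric(bandwidth), length.out = 2)
  if (is.null(grid))
    grid <- default_range_grid(tab$x, tab$y, h, cell_size)
  pooled <- kde_density(tab, grid, bandwidth = bandwidth)
  contour <- volume_contour(pooled, level)
  ids <- unique(tab$individual_id)
  per_ind <- vapply(ids, function(id) {
    pts <- tab[tab$individual_id == id, , drop = FALSE]
    hi <- if (identical(bandwidth, "auto")) scott_bandwidth(pts$x, pts$y)
          else h
    gi <- default_range_grid(pts$x, pts$y, hi, cell_size)
    volume_contour(kde_density(pts, gi, bandwidth = bandwidth), level)$area_km2
  }, 0)
  names(per_ind) <- ids
  structure(list(species = species, contour = contour,
                 polygons = contour$polygons, isopleth = level,
                 area_km2 = contour$area_km2,
                 per_individual_areas_km2 = per_ind,
                 median_individual_area_km2 = stats::median(per_ind),
                 bandwidth = pooled$bandwidth),
            class = "range_estimate")
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf(
    "range_estimate '%s': %.0f%% isopleth, %.2f km2 pooled, median individual %.2f km2 (%d individuals)\n",
    x$species, 100 * x$isopleth, x$area_km2, x$median_individual_area_km2,
    length(x$per_individual_areas_km2)))
  invisible(x)
}

#' Generate pseudo-absence points outside exclusion discs
#'
#' Places one exclusion disc on every presence point, with the disc area
#' equal to the median individual range
#' (radius \eqn{\sqrt{A \cdot 10^6 / \pi}} metres), and rejection-samples
#' uniform points inside the boundary but outside the disc union until the
#' pseudo-absence count equals the presence count. Accounts for spatial
#' sampling bias in ranger-collected presences.
#'
#' @param presences Data frame with `x`, `y` (presence points, metres).
#' @param median_area_km2 Median individual range area, km\eqn{^2} (> 0).
#' @param boundary A [boundary_polygon()].
#' @param seed Integer seed; output is reproducible given it.
#' @param species Species name carried on the result.
#' @param max_draws Rejection-sampling cap (default 1e6 candidate draws).
#' @return A `pseudo_absence_set`: `species`, `points` (data frame),
#'   `exclusion_radius_m`, `seed`.
#' @export
generate_pseudo_absences <- function(presences, median_area_km2, boundary,
                                     seed = 1L, species = "species",
                                     max_draws = 1e6) {
  if (!is.numeric(median_area_km2) || median_area_km2 <= 0)
    stop("median_area_km2 must be > 0")
  n <- nrow(presences)
  if (!n) stop("no presence points")
  radius <- sqrt(median_area_km2 * 1e6 / pi)
  rings <- unlist(lapply(boundary$polygons, function(p) p[1]),
                  recursive = FALSE)
  all_xy <- do.call(rbind, rings)
  xr <- range(all_xy[, 1]); yr <- range(all_xy[, 2])
  px <- presences$x; py <- presences$y
  accepted <- matrix(numeric(0), 0, 2)
  drawn <- 0L
  withr::with_seed(seed, {
    while (nrow(accepted) < n && drawn < max_draws) {
      m <- min(10000L, max_draws - drawn)
      drawn <- drawn + m
      cand <- cbind(stats::runif(m, xr[1], xr[2]),
                    stats::runif(m, yr[1], yr[2]))
      cand <- cand[boundary_contains(boundary, cand[, 1], cand[, 2]), ,
                   drop = FALSE]
      if (!nrow(cand)) next
      # squared distance to the nearest presence, blockwise
      d2min <- rep(Inf, nrow(cand))
      for (i in seq_len(ceiling(length(px) / 500))) {
        j <- ((i - 1) * 500 + 1):min(i * 500, length(px))
        d2 <- outer(cand[, 1], px[j], "-")^2 + outer(cand[, 2], py[j], "-")^2
        d2min <- pmin(d2min, apply(d2, 1, min))
      }
      cand <- cand[d2min > radius^2, , drop = FALSE]
      if (nrow(cand)) accepted <- rbind(accepted, cand)
    }
  })
  if (nrow(accepted) < n)
    stop("exclusion zone covers study area: could not place ", n,
         " pseudo-absences within ", format(max_draws), " draws")
  structure(list(species = species,
                 points = data.frame(x = accepted[seq_len(n), 1],
                                     y = accepted[seq_len(n), 2]),
                 exclusion_radius_m = radius, seed = as.integer(seed)),
            class = "pseudo_absence_set")
}
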