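# Boundary polygons and GeoJSON I/O. Geometry is kept deliberately small:
# polygons are lists of rings (closed coordinate matrices, first ring outer,
# later rings holes, GeoJSON convention); membership tests use even-odd
# crossing counts via mgcv::in.out, and areas use the shoelace formula.

#' Study-area boundary polygon
#'
#' @param polygons A single ring (2-column coordinate matrix, metres), or a
#'   list of polygons where each polygon is a list of rings (first ring
#'   outer, the rest holes).
#' @param crs CRS declaration (projected metric; degrees rejected).
#' @return Object of class `boundary_polygon` with an `area_km2` field.
#' @export
boundary_polygon <- function(polygons, crs = "local-metric") {
  if (is.matrix(polygons)) polygons <- list(list(polygons))
  if (is.list(polygons) && is.matrix(polygons[[1]]))
    polygons <- list(polygons)
  polygons <- lapply(polygons, function(poly) lapply(poly, close_ring))
  for (poly in polygons) for (ring in poly) {
    if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4)
      stop("each ring must be a closed 2-column matrix with >= 3 vertices")
    if (any(!is.finite(ring))) stop("ring coordinates must be finite")
    if (ring_self_intersects(ring))
      stop("invalid geometry: ring self-intersects")
  }
  area <- sum(vapply(polygons, function(poly) {
    abs(shoelace(poly[[1]])) -
      sum(vapply(poly[-1], function(h) abs(shoelace(h)), 0))
  }, 0)) / 1e6
  if (area <= 0) stop("boundary must have positive area")
  structure(list(polygons = polygons, area_km2 = area, crs = crs),
            class = "boundary_polygon")
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  unname(ring)
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# O(n^2) segment-pair check; boundaries are small hand-drawn polygons.
ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n > 2000L) return(FALSE)
  seg <- cbind(ring[1:n, , drop = FALSE], ring[2:(n + 1L), , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # first and last segment share a vertex
    for (j in js)
      if (segments_cross(seg[i, ], seg[j, ])) return(TRUE)
  }
  FALSE
}

segments_cross <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' @rdname boundary_polygon
#' @details `boundary_from_grid()` returns the rectangular envelope of a grid
#'   as a boundary, the default study area for synthetic scenarios.
#' @param g A [grid_spec()].
#' @export
boundary_from_grid <- function(g) {
  x0 <- g$origin_x; y0 <- g$origin_y
  x1 <- x0 + g$n_cols * g$cell_size; y1 <- y0 - g$n_rows * g$cell_size
  boundary_polygon(rbind(c(x0, y1), c(x1, y1), c(x1, y0), c(x0, y0)),
                   crs = g$crs)
}

#' Test points for boundary membership
#'
#' Even-odd rule over all rings, so holes are excluded. Used everywhere the
#' centre rule applies: a cell is inside a polygon iff its centre is.
#'
#' @param boundary A [boundary_polygon()] (or NULL, in which case all points
#'   are inside).
#' @param x,y Point coordinates (metres).
#' @return Logical vector.
#' @export
boundary_contains <- function(boundary, x, y) {
  if (is.null(boundary)) return(rep(TRUE, length(x)))
  rings <- unlist(lapply(boundary$polygons, function(p) p), recursive = FALSE)
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' Read a boundary polygon from GeoJSON
#'
#' Accepts a Polygon or MultiPolygon geometry, bare or wrapped in a Feature
#' or FeatureCollection (the first polygonal feature is used). Coordinates
#' must be planar metres; a `crs` member naming a geographic CRS is rejected.
#'
#' @param path GeoJSON file path.
#' @param crs CRS to assume when the file declares none.
#' @return A [boundary_polygon()].
#' @export
read_boundary <- function(path, crs = "local-metric") {
  gj <- jsonlite::read_json(path)
  declared <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(declared)) {
    if (crs_is_geographic(declared))
      stop("projected CRS required: boundary declares ", declared)
    crs <- declared
  }
  geom <- extract_geometry(gj)
  if (is.null(geom)) stop("no Polygon or MultiPolygon geometry found in ", path)
  polys <- if (geom$type == "Polygon") list(geom$coordinates)
           else geom$coordinates
  polygons <- lapply(polys, function(poly)
    lapply(poly, function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))))
  boundary_polygon(polygons, crs = crs)
}

extract_geometry <- function(gj) {
  type <- gj$type %||% ""
  if (type %in% c("Polygon", "MultiPolygon")) return(gj)
  if (type == "Feature") return(extract_geometry(gj$geometry))
  if (type == "FeatureCollection")
    for (f in gj$features) {
      g <- extract_geometry(f)
      if (!is.null(g)) return(g)
    }
  NULL
}

#' Write polygons to GeoJSON
#'
#' Serialises a boundary, a range estimate's contour polygons, or a plain
#' list of rings as a GeoJSON FeatureCollection with the CRS declared in a
#' `crs` property.
#'
#' @param obj A [boundary_polygon()], a `range_estimate`/`range_contour`, or
#'   a list of 2-column ring matrices.
#' @param path Output path.
#' @param properties Named list of feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(obj, path, properties = list()) {
  polys <- if (inherits(obj, "boundary_polygon")) obj$polygons
    else if (inherits(obj, c("range_estimate", "range_contour")))
      lapply(obj$polygons, list)
    else if (is.list(obj) && length(obj) && is.matrix(obj[[1]]))
      lapply(obj, list)
    else stop("cannot serialise object of class ", class(obj)[1])
  coords <- lapply(polys, function(poly)
    lapply(poly, function(ring) {
      ring <- close_ring(ring)
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    }))
  feature <- list(type = "Feature",
                  properties = if (length(properties)) properties
                               else structure(list(), names = character()),
                  geometry = list(type = "MultiPolygon", coordinates = coords))
  fc <- list(type = "FeatureCollection", features = list(feature))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
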