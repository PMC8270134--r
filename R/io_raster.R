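# Raster I/O over ESRI ASCII Grid (.asc) with a JSON sidecar.
#
# Each raster object is stored as one .asc file per band (band order =
# catalogue order) plus "<stem>.json" holding kind, catalogue, CRS, species
# and NODATA metadata. ASCII Grid is a plain-text, single-band raster
# standard (GDAL driver "AAIGrid"); the sidecar makes the set of bands a
# typed multi-band raster. Integer rasters round-trip bit-exactly; floats
# are written with 10 significant digits (round-trip error < 1e-9 relative).

NODATA_SENTINEL <- -9999

raster_stem <- function(path) sub("\\.asc$", "", sub("\\.json$", "", path))

band_path <- function(stem, band, n_bands) {
  if (n_bands == 1L) paste0(stem, ".asc")
  else sprintf("%s_b%02d.asc", stem, band)
}

write_asc <- function(mat, grid, path, integer = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin_x, digits = 15)),
    paste("yllcorner", format(grid$origin_y - grid$n_rows * grid$cell_size,
                              digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", NODATA_SENTINEL)), con)
  m <- mat
  m[is.na(m)] <- NODATA_SENTINEL
  fmt <- if (integer) "%d" else "%.10g"
  for (r in seq_len(nrow(m)))
    writeLines(paste(sprintf(fmt, m[r, ]), collapse = " "), con)
  invisible(path)
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("corrupt .asc file: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% NODATA_SENTINEL
  m[m == nodata] <- NA
  grid <- grid_spec(origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize,
                    cell_size = hdr$cellsize, n_rows = nr, n_cols = nc)
  list(values = m, grid = grid)
}

#' Write a raster object to disk
#'
#' Writes any of the package's raster types (habitat map, proportion raster,
#' selection surface, occupancy/complexity/integrity map) as ESRI ASCII Grid
#' band files plus a JSON metadata sidecar. Multi-band rasters use one file
#' per band in catalogue order. Integer rasters round-trip bit-exactly.
#'
#' @param obj A raster object created by this package.
#' @param path Output path; the `.asc`/`.json` suffix is replaced by the
#'   band/sidecar naming scheme.
#' @return The sidecar path, invisibly.
#' @export
write_raster <- function(obj, path) {
  if (!inherits(obj, "grid_raster")) stop("obj is not a raster object")
  stem <- raster_stem(path)
  dir <- dirname(stem)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  kind <- class(obj)[1]
  integer_kinds <- c("habitat_map", "occupancy_map", "complexity_map")
  meta <- list(kind = kind, crs = obj$grid$crs)
  if (!is.null(obj$catalogue)) meta$catalogue <- as.character(obj$catalogue)
  if (!is.null(obj$species)) meta$species <- obj$species
  if (!is.null(obj$threshold)) meta$threshold <- obj$threshold
  if (!is.null(obj$n_species)) meta$n_species <- obj$n_species
  if (!is.null(obj$scenario)) meta$scenario <- obj$scenario
  if (kind == "proportion_raster") {
    nb <- dim(obj$values)[3]
    meta$n_bands <- nb
    for (b in seq_len(nb))
      write_asc(obj$values[, , b], obj$grid, band_path(stem, b, nb))
  } else if (kind == "complexity_map") {
    meta$n_bands <- 2L
    meta$bands <- c("realized", "potential")
    write_asc(obj$values, obj$grid, band_path(stem, 1L, 2L), integer = TRUE)
    write_asc(obj$potential, obj$grid, band_path(stem, 2L, 2L), integer = TRUE)
  } else {
    meta$n_bands <- 1L
    write_asc(obj$values, obj$grid, band_path(stem, 1L, 1L),
              integer = kind %in% integer_kinds)
  }
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Read a raster object from disk
#'
#' Counterpart of [write_raster()]. The expected kind is checked against the
#' sidecar when present; a raster whose declared CRS is geographic (degrees)
#' is rejected because all analysis assumes one projected metric CRS.
#'
#' @param path Path to the `.asc` band file or `.json` sidecar (or the stem).
#' @param expected_kind One of `"habitat_map"`, `"proportion_raster"`,
#'   `"selection_surface"`, `"occupancy_map"`, `"complexity_map"`,
#'   `"integrity_map"`. Optional when a sidecar declares the kind.
#' @return The typed raster object.
#' @export
read_raster <- function(path, expected_kind = NULL) {
  stem <- raster_stem(path)
  sidecar <- paste0(stem, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  kind <- meta$kind %||% expected_kind
  if (is.null(kind))
    stop("no metadata sidecar found; expected_kind must be given")
  if (!is.null(expected_kind) && !is.null(meta$kind) &&
      !identical(meta$kind, expected_kind))
    stop("raster on disk is a ", meta$kind, ", not a ", expected_kind)
  if (crs_is_geographic(meta$crs %||% ""))
    stop("projected CRS required: raster declares a geographic (degree) CRS")
  nb <- meta$n_bands %||% 1L
  first <- read_asc(band_path(stem, 1L, nb))
  if (!file.exists(sidecar) && first$grid$cell_size < 0.1)
    stop("projected CRS required: cell size of ", first$grid$cell_size,
         " suggests degree units")
  grid <- first$grid
  grid$crs <- meta$crs %||% grid$crs
  catalogue <- if (!is.null(meta$catalogue)) class_catalogue(meta$catalogue)
               else class_catalogue()
  switch(kind,
    habitat_map = habitat_map(first$values, grid, catalogue),
    proportion_raster = {
      if (nb != length(catalogue))
        stop("band count (", nb, ") inconsistent with catalogue of ",
             length(catalogue), " classes")
      arr <- array(NA_real_, c(grid$n_rows, grid$n_cols, nb))
      arr[, , 1] <- first$values
      for (b in seq_len(nb)[-1])
        arr[, , b] <- read_asc(band_path(stem, b, nb))$values
      proportion_raster(arr, grid, catalogue)
    },
    selection_surface = selection_surface(first$values, grid,
                                          meta$species %||% "species"),
    occupancy_map = occupancy_map(first$values, grid,
                                  meta$species %||% "species",
                                  meta$threshold %||% 0.5),
    complexity_map = complexity_map(first$values,
                                    read_asc(band_path(stem, 2L, 2L))$values,
                                    grid, meta$n_species %||% 1L),
    integrity_map = integrity_map(first$values, grid,
                                  meta$n_species %||% 1L,
                                  meta$scenario %||% "after"),
    stop("unknown raster kind: ", kind))
}
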