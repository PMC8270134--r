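# Two-step land-cover mapping: a fine-resolution pixel classifier, then a
# coarse-resolution fractional-cover regressor trained on the aggregated
# fine classification. The bundled backend is a single-hidden-layer
# feed-forward network with softmax output (nnet), regularised by weight
# decay; any probabilistic classifier meeting the softmax contract can
# stand in.

#' Multispectral image container
#'
#' @param values Numeric array `n_rows x n_cols x n_bands`; a cell is NODATA
#'   when its first band is NA.
#' @param grid A [grid_spec()].
#' @return Object of class `spectral_image`.
#' @export
spectral_image <- function(values, grid) {
  if (length(dim(values)) != 3L) stop("values must be a 3-d array")
  new_grid_raster(values, grid, "spectral_image")
}

#' Neural-classifier configuration
#'
#' Hyper-parameters of the land-cover models. The defaults follow the
#' fine-step architecture (two dense layers of 100 neurons, dropout 0.1,
#' 100 epochs, batch 1000, 80/20 split); `coarse = TRUE` switches to the
#' fractional-cover step's defaults (200 neurons, 200 epochs, batch 10000).
#' The bundled nnet backend fits a single hidden layer of
#' `neurons_per_layer` units for at most `epochs` iterations with weight
#' decay `decay`; `hidden_layers`, `dropout_rate` and `batch_size` are kept
#' as recorded provenance for backends that use them.
#'
#' @param neurons_per_layer Hidden units.
#' @param epochs Training iterations.
#' @param hidden_layers Dense layers (provenance).
#' @param dropout_rate In `[0, 1)` (provenance).
#' @param batch_size Mini-batch size (provenance).
#' @param validation_fraction Hold-out fraction in `(0, 1)`.
#' @param decay Weight-decay regularisation for the nnet backend.
#' @param seed Integer RNG seed.
#' @param coarse Use the coarse-step defaults.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(neurons_per_layer = if (coarse) 200L else 100L,
                              epochs = if (coarse) 200L else 100L,
                              hidden_layers = 2L,
                              dropout_rate = 0.1,
                              batch_size = if (coarse) 10000L else 1000L,
                              validation_fraction = 0.2,
                              decay = 1e-4,
                              seed = 1L,
                              coarse = FALSE) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  structure(list(neurons_per_layer = as.integer(neurons_per_layer),
                 epochs = as.integer(epochs),
                 hidden_layers = as.integer(hidden_layers),
                 dropout_rate = dropout_rate, batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction, decay = decay,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Balance training pixels across classes
#'
#' Downsamples common classes (without replacement) and upsamples rare ones
#' (with replacement) so that every class has exactly the median original
#' class count. Classes already at the target are left untouched.
#'
#' @param labels Vector of class labels (>= 2 classes present).
#' @param features Matrix or data frame of predictor rows.
#' @param seed Integer seed; the result is deterministic given it.
#' @return List with balanced `labels` and `features`.
#' @export
balance_training_pixels <- function(labels, features, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("labels and features differ in length")
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("at least two classes are required for balancing")
  if (any(counts == 0L)) stop("a class has zero examples")
  target <- as.integer(round(stats::median(counts)))
  idx <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      i <- which(labels == cl)
      if (length(i) == target) i
      else sample(i, target, replace = length(i) < target)
    }), use.names = FALSE)
  })
  list(labels = labels[idx], features = features[idx, , drop = FALSE])
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

stratified_split <- function(groups, fraction, seed) {
  withr::with_seed(seed, {
    hold <- unlist(lapply(split(seq_along(groups), groups), function(i) {
      k <- max(1L, round(length(i) * fraction))
      sample(i, k)
    }), use.names = FALSE)
  })
  hold
}

#' Fit the fine-resolution pixel classifier
#'
#' Balances the training pixels ([balance_training_pixels()]), centres and
#' scales the predictors, holds out a stratified validation fraction, and
#' fits a softmax-output network predicting habitat class from the band
#' vector. The fit report carries overall accuracy and Cohen's kappa on the
#' hold-out.
#'
#' @param features Numeric matrix of band values (one row per training pixel).
#' @param labels Class labels; must all appear in `catalogue`.
#' @param config A [classifier_config()].
#' @param catalogue A [class_catalogue()]; fixes output channel order.
#' @return A `fine_classifier` with elements `net`, `scaler`, `catalogue`
#'   and `report` (a `fit_report`).
#' @export
fit_fine_classifier <- function(features, labels,
                                config = classifier_config(),
                                catalogue = class_catalogue()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (!all(labels %in% catalogue))
    stop("labels outside the catalogue: ",
         paste(setdiff(labels, catalogue), collapse = ", "))
  bal <- balance_training_pixels(labels, features, seed = config$seed)
  if (min(table(bal$labels)) < 10L)
    stop("fewer than 10 pixels per class after balancing")
  present <- intersect(as.character(catalogue), unique(bal$labels))
  f <- factor(bal$labels, levels = present)
  sc <- scale_fit(bal$features)
  xs <- scale_apply(bal$features, sc)
  hold <- stratified_split(f, config$validation_fraction, config$seed + 1L)
  y <- nnet::class.ind(f)
  net <- withr::with_seed(config$seed + 2L,
    nnet::nnet(xs[-hold, , drop = FALSE], y[-hold, , drop = FALSE],
               size = config$neurons_per_layer, softmax = TRUE,
               decay = config$decay, maxit = config$epochs,
               MaxNWts = 100000L, trace = FALSE))
  pv <- predict(net, xs[hold, , drop = FALSE])
  pred <- colnames(y)[max.col(pv, ties.method = "first")]
  report <- structure(list(overall_accuracy =
                             overall_accuracy(pred, as.character(f)[hold]),
                           kappa = cohens_kappa(pred, as.character(f)[hold]),
                           n_validation = length(hold)),
                      class = "fit_report")
  structure(list(net = net, scaler = sc, classes = present,
                 catalogue = catalogue, n_bands = ncol(features),
                 config = config, report = report),
            class = "fine_classifier")
}

#' Per-class probabilities from a fine classifier
#'
#' @param object A `fine_classifier`.
#' @param newdata Band-value matrix.
#' @param ... Unused.
#' @return Probability matrix, one column per catalogue class (classes not
#'   in training get probability 0); rows sum to 1 within 1e-5.
#' @export
predict.fine_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_bands)
    stop("band count (", ncol(newdata), ") does not match training (",
         object$n_bands, ")")
  p <- predict(object$net, scale_apply(newdata, object$scaler))
  full <- matrix(0, nrow(p), length(object$catalogue),
                 dimnames = list(NULL, as.character(object$catalogue)))
  full[, object$classes] <- p
  full
}

#' Classify an image pixel-by-pixel
#'
#' Applies the fine classifier to every non-NODATA cell and assigns the
#' argmax class; probability ties go to the lowest catalogue index.
#'
#' @param classifier A `fine_classifier`.
#' @param image A [spectral_image()].
#' @return A [habitat_map()].
#' @export
classify_fine <- function(classifier, image) {
  stopifnot(inherits(classifier, "fine_classifier"),
            inherits(image, "spectral_image"))
  g <- image$grid
  flat <- matrix(image$values, ncol = dim(image$values)[3])
  ok <- !is.na(flat[, 1])
  labels <- matrix(NA_integer_, g$n_rows, g$n_cols)
  if (any(ok)) {
    p <- predict(classifier, flat[ok, , drop = FALSE])
    labels[ok] <- max.col(p, ties.method = "first")
  }
  habitat_map(labels, g, classifier$catalogue)
}

block_sum <- function(m, f) {
  nr <- nrow(m); nc <- ncol(m)
  m1 <- matrix(colSums(matrix(m, nrow = f)), nrow = nr %/% f)
  t(matrix(colSums(matrix(t(m1), nrow = f)), nrow = nc %/% f))
}

#' Aggregate a fine habitat map into fractional cover
#'
#' Each coarse cell's vector is the fraction of each class among its
#' `factor^2` fine cells, ignoring fine NODATA cells; a coarse cell is
#' NODATA when more than half of its fine cells are. Trailing rows/columns
#' that do not fill a block are dropped with a warning.
#'
#' @param fine A [habitat_map()].
#' @param factor Integer aggregation factor >= 1 (e.g. 3 for 10 m to 30 m).
#' @return A [proportion_raster()] on the coarse grid.
#' @export
aggregate_proportions <- function(fine, factor) {
  stopifnot(inherits(fine, "habitat_map"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  g <- fine$grid
  nr <- (g$n_rows %/% factor) * factor
  nc <- (g$n_cols %/% factor) * factor
  if (nr < g$n_rows || nc < g$n_cols)
    warning("trailing partial blocks dropped (", g$n_rows - nr, " row(s), ",
            g$n_cols - nc, " col(s))")
  if (nr == 0L || nc == 0L) stop("grid smaller than one aggregation block")
  lab <- fine$values[seq_len(nr), seq_len(nc), drop = FALSE]
  k <- length(fine$catalogue)
  valid <- block_sum(!is.na(lab) + 0, factor)
  arr <- array(NA_real_, c(nr %/% factor, nc %/% factor, k))
  for (cl in seq_len(k)) {
    cnt <- block_sum((!is.na(lab) & lab == cl) + 0, factor)
    arr[, , cl] <- cnt / valid
  }
  nodata <- valid < factor^2 / 2          # > 50% fine NODATA
  for (cl in seq_len(k)) {
    band <- arr[, , cl]; band[nodata] <- NA_real_; arr[, , cl] <- band
  }
  coarse <- grid_spec(g$origin_x, g$origin_y, g$cell_size * factor,
                      nr %/% factor, nc %/% factor, crs = g$crs)
  proportion_raster(arr, coarse, fine$catalogue)
}

#' Fit the coarse fractional-cover regressor
#'
#' Trains a softmax-output network to map a coarse band vector to a
#' fractional-cover simplex vector, with targets taken from
#' [aggregate_proportions()] of the fine classification over the coarse
#' grid. The fit report carries the hold-out r-squared, overall and per
#' class; per-class r-squared is NA with a warning for zero-variance
#' classes.
#'
#' @param coarse_image A [spectral_image()] on the coarse grid.
#' @param target_proportions A [proportion_raster()] on the same grid.
#' @param config A [classifier_config()] (use `coarse = TRUE` defaults).
#' @return A `proportion_regressor` with elements `net`, `scaler`,
#'   `catalogue` and `report`.
#' @export
fit_proportion_regressor <- function(coarse_image, target_proportions,
                                     config = classifier_config(coarse = TRUE)) {
  stopifnot(inherits(coarse_image, "spectral_image"),
            inherits(target_proportions, "proportion_raster"))
  if (!grids_identical(coarse_image$grid, target_proportions$grid))
    stop("grid mismatch between image and target proportions")
  x <- matrix(coarse_image$values, ncol = dim(coarse_image$values)[3])
  y <- matrix(target_proportions$values,
              ncol = dim(target_proportions$values)[3])
  ok <- !is.na(x[, 1]) & !is.na(y[, 1])
  if (sum(ok) < 10L) stop("too few cells with both image and targets")
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  colnames(y) <- as.character(target_proportions$catalogue)
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  hold <- stratified_split(max.col(y, ties.method = "first"),
                           config$validation_fraction, config$seed + 1L)
  net <- withr::with_seed(config$seed + 2L,
    nnet::nnet(xs[-hold, , drop = FALSE], y[-hold, , drop = FALSE],
               size = config$neurons_per_layer, softmax = TRUE,
               decay = config$decay, maxit = config$epochs,
               MaxNWts = 100000L, trace = FALSE))
  pv <- predict(net, xs[hold, , drop = FALSE])
  yv <- y[hold, , drop = FALSE]
  constant <- apply(yv, 2, stats::sd) == 0
  per_class <- rep(NA_real_, ncol(y))
  for (j in which(!constant)) per_class[j] <- r_squared(pv[, j], yv[, j])
  if (any(constant))
    warning("per-class r-squared undefined for zero-variance class(es): ",
            paste(colnames(y)[constant], collapse = ", "))
  names(per_class) <- colnames(y)
  report <- structure(list(r2_overall = r_squared(as.vector(pv), as.vector(yv)),
                           r2_per_class = per_class,
                           n_validation = length(hold)),
                      class = "fit_report")
  structure(list(net = net, scaler = sc,
                 catalogue = target_proportions$catalogue,
                 n_bands = ncol(x), config = config, report = report),
            class = "proportion_regressor")
}

#' Predict fractional cover over an image
#'
#' @param object A `proportion_regressor`.
#' @param newdata A [spectral_image()] (or band matrix).
#' @param ... Unused.
#' @return A [proportion_raster()] when `newdata` is an image, otherwise a
#'   simplex-row matrix.
#' @export
predict.proportion_regressor <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_image")) {
    g <- newdata$grid
    flat <- matrix(newdata$values, ncol = dim(newdata$values)[3])
    ok <- !is.na(flat[, 1])
    arr <- array(NA_real_, c(g$n_rows, g$n_cols, length(object$catalogue)))
    if (any(ok)) {
      p <- predict(object, flat[ok, , drop = FALSE])
      for (j in seq_len(ncol(p))) {
        band <- arr[, , j]; band[ok] <- p[, j]; arr[, , j] <- band
      }
    }
    return(proportion_raster(arr, g, object$catalogue))
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_bands)
    stop("band count does not match training")
  predict(object$net, scale_apply(newdata, object$scaler))
}

#' @export
print.fit_report <- function(x, ...) {
  for (nm in names(x))
    if (is.numeric(x[[nm]]) && length(x[[nm]]) == 1)
      cat(sprintf("%s: %.4f\n", nm, x[[nm]]))
  invisible(x)
}
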