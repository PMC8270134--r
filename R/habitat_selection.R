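# Used/available habitat-selection modelling: buffer-proportion features,
# a seeded bagged-tree ensemble (randomForest) for P(presence), surface
# prediction on the aggregated 30 m raster, and AUC evaluation.

feature_name <- function(class_names) gsub("[^A-Za-z0-9]+", "_", class_names)

#' Mean habitat proportions within a buffer disc
#'
#' Averages the fractional-cover vector over all non-NODATA cells whose
#' centres fall within a disc around the point. The disc area equals the
#' species' median individual range (`buffer_area_km2`), i.e. radius
#' \eqn{\sqrt{A \cdot 10^6 / \pi}} m. Only the modelled classes are
#' returned; NODATA cells are excluded from the mean (not zero-filled).
#'
#' @param point Length-2 numeric `c(x, y)` or a one-row data frame.
#' @param proportions A [proportion_raster()].
#' @param buffer_area_km2 Disc area, km\eqn{^2} (> 0).
#' @param classes Catalogue class names to report (default the four
#'   modelled habitats).
#' @return Named numeric vector of mean proportions.
#' @export
extract_buffer_proportions <- function(point, proportions, buffer_area_km2,
                                       classes = modelled_habitat_classes()) {
  if (is.data.frame(point)) point <- c(point$x[1], point$y[1])
  if (buffer_area_km2 <= 0) stop("buffer_area_km2 must be > 0")
  g <- proportions$grid
  radius <- sqrt(buffer_area_km2 * 1e6 / pi)
  cx <- cell_centres_x(g); cy <- cell_centres_y(g)
  ci <- which(abs(cx - point[1]) <= radius)
  ri <- which(abs(cy - point[2]) <= radius)
  if (!length(ci) || !length(ri))
    stop("no cell centre falls inside the buffer disc")
  d2 <- outer((cy[ri] - point[2])^2, (cx[ci] - point[1])^2, "+")
  sel <- d2 <= radius^2
  if (!any(sel)) stop("no cell centre falls inside the buffer disc")
  idx <- match(classes, as.character(proportions$catalogue))
  if (anyNA(idx))
    stop("classes missing from the catalogue: ",
         paste(classes[is.na(idx)], collapse = ", "))
  out <- vapply(idx, function(b) {
    band <- proportions$values[ri, ci, b, drop = FALSE]
    dim(band) <- dim(sel)
    mean(band[sel], na.rm = TRUE)
  }, 0)
  if (any(!is.finite(out)))
    stop("buffer contains only NODATA cells")
  names(out) <- feature_name(classes)
  out
}

#' Assemble the presence/pseudo-absence training set
#'
#' One feature row per point: label (presence = 1, pseudo-absence = 0) plus
#' the buffer-mean proportions of the modelled habitats. The same buffer
#' size is used for both classes.
#'
#' @param presences,pseudo_absences Data frames with `x`, `y` (both
#'   non-empty). A `pseudo_absence_set` is accepted for the latter.
#' @inheritParams extract_buffer_proportions
#' @return Data frame with columns `label` and one per modelled class.
#' @export
build_training_set <- function(presences, pseudo_absences, proportions,
                               buffer_area_km2,
                               classes = modelled_habitat_classes()) {
  if (inherits(pseudo_absences, "pseudo_absence_set"))
    pseudo_absences <- pseudo_absences$points
  if (!nrow(presences)) stop("empty presence set")
  if (!nrow(pseudo_absences)) stop("empty pseudo-absence set")
  pts <- rbind(data.frame(x = presences$x, y = presences$y, label = 1L),
               data.frame(x = pseudo_absences$x, y = pseudo_absences$y,
                          label = 0L))
  feats <- t(vapply(seq_len(nrow(pts)), function(i)
    extract_buffer_proportions(c(pts$x[i], pts$y[i]), proportions,
                               buffer_area_km2, classes),
    numeric(length(classes))))
  cbind(data.frame(label = pts$label), as.data.frame(feats))
}

#' Fit the habitat-selection model
#'
#' A seeded bagged-tree ensemble (random forest) predicting the probability
#' of presence from the buffer habitat proportions. Both the resubstitution
#' AUC and a stratified 5-fold cross-validated AUC are computed; the
#' cross-validated value is the headline figure since resubstitution AUC of
#' a flexible ensemble is near 1 by construction.
#'
#' @param rows Training set from [build_training_set()] (both labels
#'   present, >= 10 rows per label).
#' @param n_trees Trees in the ensemble (default 500).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param k_folds Cross-validation folds (default 5).
#' @return A `selection_model` with `forest`, `feature_names`, `n_trees`,
#'   `seed`, `auc_train`, `auc_cv`.
#' @export
fit_selection_model <- function(rows, n_trees = 500L, seed = 1L,
                                k_folds = 5L) {
  if (!"label" %in% names(rows)) stop("rows must have a 'label' column")
  y <- factor(rows$label, levels = c(0, 1))
  if (any(table(y) == 0)) stop("both labels must be present")
  if (any(table(y) < 10L)) stop("need at least 10 rows per label")
  x <- rows[, setdiff(names(rows), "label"), drop = FALSE]
  forest <- withr::with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees))
  p_train <- predict(forest, newdata = x, type = "prob")[, "1"]
  auc_train <- auc(p_train, rows$label)
  folds <- withr::with_seed(seed + 1L, {
    f <- integer(nrow(rows))
    for (lab in levels(y)) {
      i <- which(y == lab)
      f[i] <- sample(rep_len(seq_len(k_folds), length(i)))
    }
    f
  })
  p_cv <- numeric(nrow(rows))
  for (k in seq_len(k_folds)) {
    te <- folds == k
    fit <- withr::with_seed(seed + 1L + k,
      randomForest::randomForest(x[!te, , drop = FALSE], y[!te],
                                 ntree = n_trees))
    p_cv[te] <- predict(fit, newdata = x[te, , drop = FALSE],
                        type = "prob")[, "1"]
  }
  structure(list(forest = forest, feature_names = names(x),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 auc_train = auc_train, auc_cv = auc(p_cv, rows$label)),
            class = "selection_model")
}

#' @export
predict.selection_model <- function(object, newdata, ...) {
  if (!all(object$feature_names %in% names(newdata)))
    stop("newdata lacks feature column(s): ",
         paste(setdiff(object$feature_names, names(newdata)), collapse = ", "))
  predict(object$forest,
          newdata = newdata[, object$feature_names, drop = FALSE],
          type = "prob")[, "1"]
}

#' Predict the probability-of-presence surface
#'
#' Applies the selection model cell-by-cell to the aggregated fractional
#' cover raster (the 30 m grid). NODATA propagates.
#'
#' @param model A `selection_model`.
#' @param aggregated A [proportion_raster()] carrying the modelled classes.
#' @param classes Catalogue classes matching the model's features, in order.
#' @param species Species name carried on the surface.
#' @return A [selection_surface()].
#' @export
predict_surface <- function(model, aggregated,
                            classes = modelled_habitat_classes(),
                            species = "species") {
  stopifnot(inherits(model, "selection_model"),
            inherits(aggregated, "proportion_raster"))
  idx <- match(classes, as.character(aggregated$catalogue))
  if (anyNA(idx))
    stop("missing class channel(s): ",
         paste(classes[is.na(idx)], collapse = ", "))
  g <- aggregated$grid
  flat <- matrix(aggregated$values, ncol = dim(aggregated$values)[3])
  ok <- !is.na(flat[, 1])
  prob <- matrix(NA_real_, g$n_rows, g$n_cols)
  if (any(ok)) {
    nd <- as.data.frame(flat[ok, idx, drop = FALSE])
    names(nd) <- feature_name(classes)
    prob[ok] <- predict(model, nd)
  }
  selection_surface(prob, g, species = species)
}
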