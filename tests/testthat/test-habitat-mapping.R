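# Two-step land-cover mapping: balancing, classifiers, aggregation.

test_that("balancing equalises every class at the median count", {
  set.seed(1)
  labels <- rep(c("A", "B", "C"), c(100, 10, 4))
  feats <- matrix(stats::rnorm(length(labels) * 2), ncol = 2)
  bal <- balance_training_pixels(labels, feats, seed = 5)
  expect_equal(unname(table(bal$labels)), rep(10L, 3),
               ignore_attr = TRUE)
  expect_equal(nrow(bal$features), 30)
  # already-equal counts: multiset sizes unchanged
  eq <- balance_training_pixels(rep(c("A", "B"), each = 20),
                                matrix(0, 40, 1), seed = 1)
  expect_equal(unname(table(eq$labels)), rep(20L, 2), ignore_attr = TRUE)
  # deterministic given seed
  bal2 <- balance_training_pixels(labels, feats, seed = 5)
  expect_identical(bal$features, bal2$features)
  expect_error(balance_training_pixels(rep("A", 10), matrix(0, 10, 1)),
               "two classes")
})

make_separable_pixels <- function(n_per = 500, sd = 0.01, seed = 3) {
  withr::with_seed(seed, {
    feats <- rbind(cbind(stats::rnorm(n_per, 0, sd), stats::rnorm(n_per, 0.5, sd)),
                   cbind(stats::rnorm(n_per, 1, sd), stats::rnorm(n_per, 0.5, sd)))
    labels <- rep(c("broadleaf forest", "tall grassland"), each = n_per)
    list(features = feats, labels = labels)
  })
}

test_that("the fine classifier separates disjoint band values", {
  px <- make_separable_pixels()
  cfg <- classifier_config(neurons_per_layer = 8, epochs = 60, seed = 2)
  clf <- fit_fine_classifier(px$features, px$labels, cfg)
  expect_gte(clf$report$overall_accuracy, 0.99)
  # softmax contract on arbitrary inputs
  p <- predict(clf, matrix(stats::runif(40, -2, 2), ncol = 2))
  expect_true(all(abs(rowSums(p) - 1) < 1e-5))
  expect_equal(ncol(p), 10)
})

test_that("shuffled labels give chance-level validation kappa", {
  kappas <- vapply(1:5, function(s) {
    px <- withr::with_seed(s, {
      feats <- matrix(stats::rnorm(2000 * 2), ncol = 2)
      labels <- sample(rep(c("palms", "water"), each = 1000))
      list(features = feats, labels = labels)
    })
    cfg <- classifier_config(neurons_per_layer = 3, epochs = 30, seed = s)
    fit_fine_classifier(px$features, px$labels, cfg)$report$kappa
  }, 0)
  expect_true(all(abs(kappas) < 0.15))
})

test_that("classify_fine reproduces separable training labels", {
  px <- make_separable_pixels(n_per = 200)
  cfg <- classifier_config(neurons_per_layer = 8, epochs = 60, seed = 2)
  clf <- fit_fine_classifier(px$features, px$labels, cfg)
  g <- grid_spec(0, 20 * 1.2, 1.2, 20, 20)
  arr <- array(px$features[1:400, ], c(20, 20, 2))
  truth <- matrix(match(px$labels[1:400], default_habitat_classes()), 20, 20)
  hm <- classify_fine(clf, spectral_image(arr, g))
  expect_gte(mean(hm$values == truth), 0.99)
  # NODATA propagates
  arr[1, 1, ] <- NA
  hm2 <- classify_fine(clf, spectral_image(arr, g))
  expect_true(is.na(hm2$values[1, 1]))
  # band mismatch is rejected
  expect_error(classify_fine(clf, spectral_image(array(0, c(2, 2, 3)),
                                                 grid_spec(0, 2, 1, 2, 2))),
               "band count")
})

test_that("probability ties resolve to the lowest catalogue index", {
  registerS3method("predict", "tie_net",
                   function(object, newdata, ...)
                     matrix(0.5, nrow(newdata), 2,
                            dimnames = list(NULL, c("palms", "water"))),
                   envir = asNamespace("stats"))
  clf <- structure(list(net = structure(list(), class = "tie_net"),
                        scaler = list(mu = 0, sd = 1),
                        classes = c("palms", "water"),
                        catalogue = class_catalogue(), n_bands = 1L),
                   class = "fine_classifier")
  g <- grid_spec(0, 2, 1, 2, 2)
  hm <- classify_fine(clf, spectral_image(array(0, c(2, 2, 1)), g))
  expect_true(all(hm$values == match("palms", default_habitat_classes())))
})

test_that("aggregation counts class fractions per block", {
  g <- grid_spec(0, 90, 10, 3, 3)
  lab <- matrix(c(4L, 4L, 4L, 4L, 4L, 4L, 8L, 8L, 8L), 3, 3)
  pr <- aggregate_proportions(habitat_map(lab, g), 3)
  expect_equal(pr$values[1, 1, 4], 2 / 3)
  expect_equal(pr$values[1, 1, 8], 1 / 3)
  expect_equal(sum(pr$values[1, 1, ]), 1)
  # uniform map gives one-hot vectors
  uni <- aggregate_proportions(habitat_map(matrix(7L, 6, 6), tiny_grid(6)), 2)
  expect_true(all(uni$values[, , 7] == 1))
  # checkerboard halves with factor 2
  cb <- matrix(rep(c(4L, 8L), 18), 6, 6)
  prc <- aggregate_proportions(habitat_map(cb, tiny_grid(6)), 2)
  expect_true(all(prc$values[, , 4] == 0.5) && all(prc$values[, , 8] == 0.5))
  expect_error(aggregate_proportions(habitat_map(cb, tiny_grid(6)), 0),
               "positive")
})

test_that("aggregation drops partial blocks and applies the NODATA rule", {
  g <- grid_spec(0, 70, 10, 7, 7)
  lab <- matrix(4L, 7, 7)
  lab[1:3, 1:2] <- NA           # 6 of 9 fine cells NODATA in block (1,1)
  lab[4:6, 1] <- NA             # 3 of 9 NODATA in block (2,1)
  expect_warning(pr <- aggregate_proportions(habitat_map(lab, g), 3),
                 "partial blocks")
  expect_equal(dim(pr$values)[1:2], c(2, 2))
  expect_true(is.na(pr$values[1, 1, 4]))        # > 50% NODATA
  expect_equal(pr$values[2, 1, 4], 1)           # <= 50% NODATA: mean of valid
})

test_that("aggregation conserves class areas", {
  study_map <- make_landscape(landscape_config(
    tiny_grid(60, cell = 10),
    c("broadleaf forest" = 0.3, "tall grassland" = 0.7),
    corr_length = 100, seed = 4))
  pr <- aggregate_proportions(study_map, 3)
  fine_area <- tabulate(study_map$values, 10) * cell_area_km2(study_map$grid)
  coarse_area <- apply(pr$values, 3, sum) * cell_area_km2(pr$grid)
  expect_lt(max(abs(fine_area - coarse_area)), cell_area_km2(pr$grid))
})

test_that("the proportion regressor recovers linear mixtures", {
  # coarse bands ARE exact linear mixtures of two class signatures
  withr::with_seed(9, {
    g <- tiny_grid(20, cell = 10)
    k <- 10
    frac <- stats::runif(400)
    arr <- array(0, c(20, 20, k))
    arr[, , 4] <- matrix(frac, 20, 20)
    arr[, , 8] <- matrix(1 - frac, 20, 20)
    targets <- proportion_raster(arr, g)
    sig_forest <- c(0.1, 0.9); sig_grass <- c(0.8, 0.2)
    bands <- array(0, c(20, 20, 2))
    bands[, , 1] <- frac * sig_forest[1] + (1 - frac) * sig_grass[1]
    bands[, , 2] <- frac * sig_forest[2] + (1 - frac) * sig_grass[2]
    img <- spectral_image(bands, g)
  })
  cfg <- classifier_config(neurons_per_layer = 6, epochs = 150, seed = 3,
                           coarse = FALSE)
  # classes absent from the scene have constant zero targets; their
  # per-class fit is legitimately undefined here
  suppressWarnings(reg <- fit_proportion_regressor(img, targets, cfg))
  expect_gte(reg$report$r2_overall, 0.95)
  pred <- predict(reg, matrix(stats::runif(20), ncol = 2))
  expect_true(all(abs(rowSums(pred) - 1) < 1e-5))
  pred_raster <- predict(reg, img)
  expect_s3_class(pred_raster, "proportion_raster")
})

test_that("zero-variance targets flag undefined per-class r-squared", {
  g <- tiny_grid(10, cell = 10)
  arr <- array(0, c(10, 10, 10))
  arr[, , 4] <- 0.5; arr[, , 8] <- 0.5          # constant everywhere
  targets <- proportion_raster(arr, g)
  img <- spectral_image(array(stats::rnorm(200), c(10, 10, 2)), g)
  cfg <- classifier_config(neurons_per_layer = 2, epochs = 20, seed = 1)
  expect_warning(reg <- fit_proportion_regressor(img, targets, cfg),
                 "zero-variance")
  expect_true(anyNA(reg$report$r2_per_class))
})

test_that("the two-step pipeline reproduces true coarse proportions", {
  # noiseless scene: spectra determined by class, so the chain
  # classify -> aggregate should match aggregation of the true map
  map <- make_landscape(landscape_config(
    tiny_grid(60, cell = 10),
    c("broadleaf forest" = 0.35, "short grassland" = 0.25,
      "tall grassland" = 0.4),
    corr_length = 120, seed = 21))
  sig <- matrix(c(0.1, 0.9, 0.5, 0.5, 0.9, 0.1), 3, 2, byrow = TRUE,
                dimnames = list(c("broadleaf forest", "short grassland",
                                  "tall grassland"), NULL))
  img <- make_spectra(map, sig, noise_sd = 0, seed = 2)
  px <- withr::with_seed(8, sample(3600, 600))
  feats <- matrix(img$values, ncol = 2)[px, ]
  labels <- as.character(map$catalogue)[map$values[px]]
  clf <- fit_fine_classifier(feats, labels,
                             classifier_config(neurons_per_layer = 6,
                                               epochs = 80, seed = 5))
  predicted <- classify_fine(clf, img)
  true_pr <- aggregate_proportions(map, 3)
  pred_pr <- aggregate_proportions(predicted, 3)
  mae <- apply(abs(true_pr$values - pred_pr$values), 3, mean)
  expect_lt(max(mae), 0.05)
})
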