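# Shared fixtures, built in code at test time.

tiny_grid <- function(n = 10, cell = 30, x0 = 0, y0 = n * cell) {
  grid_spec(x0, y0, cell, n, n)
}

# Habitat map with a vertical split: left half class a, right half class b.
split_map <- function(n = 10, a = 4L, b = 8L, cell = 30) {
  g <- tiny_grid(n, cell)
  lab <- matrix(b, n, n)
  lab[, seq_len(n %/% 2)] <- a
  habitat_map(lab, g)
}

# Occupancy map straight from a code matrix.
occ_from_codes <- function(codes, grid, species = "sp") {
  occupancy_map(codes, grid, species = species)
}

# Selection surface with given probabilities.
surface_from <- function(p, grid, species = "sp") {
  selection_surface(p, grid, species = species)
}

# Complexity map holding exact per-score cell counts (scores 1..S), padded
# with zero-score cells; realized and potential scores occupy disjoint
# cells so the per-cell realized + potential <= S invariant holds.
complexity_from_counts <- function(realized_cells, potential_cells,
                                   cell_size = 30) {
  s <- length(realized_cells)
  n_cells <- sum(realized_cells) + sum(potential_cells) + 100L
  side <- ceiling(sqrt(n_cells))
  g <- grid_spec(0, side * cell_size, cell_size, side, side)
  fill <- function(counts, offset) {
    v <- integer(side * side)
    v[offset + seq_len(sum(counts))] <- rep(seq_len(s), counts)
    matrix(v, side, side)
  }
  complexity_map(fill(realized_cells, 0L),
                 fill(potential_cells, sum(realized_cells)), g, s)
}

# Integrity map with exact cell counts per lattice score (0, 1/S, ..., 1).
integrity_from_counts <- function(counts, s = length(counts) - 1L,
                                  cell_size = 30, scenario = "after") {
  stopifnot(length(counts) == s + 1L)
  side <- ceiling(sqrt(sum(counts)))
  v <- rep(NA_real_, side * side)
  v[seq_len(sum(counts))] <- rep((0:s) / s, counts)
  g <- grid_spec(0, side * cell_size, cell_size, side, side)
  integrity_map(matrix(v, side, side), g, s, scenario = scenario)
}

# Brute-force AUC oracle: all presence/absence pairs.
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
}

# One species' selection stage on a synthetic study; returns the fitted
# model, surface and range. Shared by the selection and acceptance tests.
run_species_stage <- function(study, profile_index, proportions = NULL,
                              n_trees = 300, seed = 1) {
  prof <- study$profiles[[profile_index]]
  if (is.null(proportions)) proportions <- aggregate_proportions(study$map, 2)
  kept <- filter_individuals(study$tracking, prof$species, study$boundary, 10)
  rng <- species_range(kept, prof$species)
  pa <- generate_pseudo_absences(kept, rng$median_individual_area_km2,
                                 study$boundary, seed = seed,
                                 species = prof$species)
  rows <- build_training_set(kept, pa, proportions,
                             rng$median_individual_area_km2)
  model <- fit_selection_model(rows, n_trees = n_trees, seed = seed)
  surface <- predict_surface(model, proportions, species = prof$species)
  list(kept = kept, range = rng, rows = rows, model = model,
       surface = surface, proportions = proportions)
}
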