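# Shared fixtures: the standard synthetic forest and memoized trained fits
# (training is deterministic, so each (variant, seed) pair is fitted once
# per test run and reused across test files).

.fixture_env <- new.env(parent = emptyenv())

std_graph <- function() {
  if (is.null(.fixture_env$graph)) .fixture_env$graph <- make_forest(standard_forest())
  .fixture_env$graph
}

std_fit <- function(variant, seed) {
  key <- paste(variant, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- coneforest(
      std_graph(), train_config(seed = seed, variant = variant))
  }
  .fixture_env[[key]]
}

std_report <- function(variant, seed) {
  key <- paste("rep", variant, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- structure_report(std_fit(variant, seed))
  }
  .fixture_env[[key]]
}

# a small mixed graph for fast unit tests
tiny_graph <- function(seed = 5) {
  make_forest(forest_spec(n_trees = 2, branching = 2, depth = 2,
                          poly_prob = 0.3, n_nonhier = 6, attach_min = 1,
                          attach_max = 2, vv_prob = 0.3, seed = seed))
}
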