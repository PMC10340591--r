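# Lazily computed, session-cached fixture datasets. Feature extraction for
# the full 4 x 90 set takes about a minute, so it is done at most once per
# test run and shared between the protocol and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full-size learnable study set: 4 classes x 90 images
full_features <- function() {
  cached("full", extract_dataset(generate_dataset(per_class = 90, seed = 11)))
}

# degenerate control: four classes rendered from one identical recipe
degenerate_recipes <- function() {
  base <- default_recipes()$GS
  recs <- list(A = base, B = base, C = base, D = base)
  for (n in names(recs)) recs[[n]]$name <- n
  recs
}

degenerate_features <- function() {
  cached("degen", extract_dataset(
    generate_dataset(degenerate_recipes(), per_class = 90, seed = 11)))
}

# small 4 x 15 set for protocol smoke tests (grid, sweep)
small_features <- function() {
  cached("small", extract_dataset(generate_dataset(per_class = 15, seed = 7)))
}
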