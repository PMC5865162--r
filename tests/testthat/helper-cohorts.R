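# Shared synthetic fixtures, generated once per test session.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The discovery-scale cohort used for planted-subtype recovery and the
# distributional checks (balanced three archetypes, strong separation).
discovery_cohort <- function() {
  with_cache("discovery_cohort", {
    spec <- cohort_spec(120, volume_shape = c(40L, 40L, 40L), random_seed = 1)
    generate_cohort(spec)
  })
}

discovery_features <- function() {
  with_cache("discovery_features", extract_feature_table(discovery_cohort()))
}

discovery_model <- function() {
  with_cache("discovery_model", {
    suppressWarnings(discover_subtypes(discovery_features(), n_runs = 200L,
                                       seed = 1))
  })
}

# A small fully imaged cohort for feature/io unit tests.
small_cohort <- function() {
  with_cache("small_cohort", {
    spec <- cohort_spec(6, volume_shape = c(40L, 40L, 40L), random_seed = 5)
    generate_cohort(spec)
  })
}

# A mid-sized imaged cohort for pipeline orchestration tests.
midi_cohort <- function() {
  with_cache("midi_cohort", {
    spec <- cohort_spec(18, volume_shape = c(40L, 40L, 40L), random_seed = 6)
    generate_cohort(spec)
  })
}

# Well-separated Gaussian clusters in feature space (planted partition).
planted_gaussians <- function(n_per = 30L, p = 8L, sep = 8, seed = 3L) {
  set.seed(seed)
  centers <- diag(sep, 3, p)
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[k, ], "+")))
  list(X = X, labels = rep(1:3, each = n_per))
}
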