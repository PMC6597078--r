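# Small fixtures built in code at test time.

# deterministic random image
fix_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

# a dictionary with prescribed words (bypasses clustering)
fix_dictionary <- function(words) {
  structure(list(words = words, K = nrow(words), seed = 0L),
            class = "bow_dictionary")
}

# random unit-norm descriptors
fix_descriptors <- function(n, dim = 128, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(abs(rnorm(n * dim)), n, dim)
    x / sqrt(rowSums(x^2))
  })
}

# sift_features carrying explicit locations/words (for voting-geometry tests)
fix_features <- function(locations, words, dim = 128) {
  f <- endovote:::.sift_features(
    matrix(0, nrow(locations), dim), locations, grid_spec()
  )
  f$words <- as.integer(words)
  f
}

# a minimal query_patch with explicit displacement geometry
fix_query <- function(displacements, words, centroid = c(22, 22), K = 10) {
  structure(
    list(
      pixels = NULL,
      centroid = centroid,
      features = fix_features(sweep(displacements, 2, -centroid), words),
      displacements = displacements,
      histogram = tabulate(words, nbins = K)
    ),
    class = "query_patch"
  )
}

fix_weights <- function(d) {
  structure(list(alpha = d, delta = rep(1, length(d)), d = d),
            class = "discriminative_weights")
}

# scaled-down study conditions for property-style end-to-end tests
small_scene_spec <- function(seed = 1L, noise_sd = 0.05) {
  scene_spec(
    size = c(224L, 224L), n_rings = 3L, n_background = 3L,
    radius_range = c(9, 18), min_sep = 55, noise_sd = noise_sd, seed = seed
  )
}

small_config <- function(seed = 1L) {
  detector_config(K = 60L, M = 6L, N = 30L, seed = seed,
                  svm_C_grid = 2^seq(-4, 4, by = 2))
}

# train a small detector over a few scenes; returns list(detector, scenes)
small_detector <- function(seed = 1L, n_scenes = 3L, noise_sd = 0.05) {
  scenes <- lapply(seq_len(n_scenes), function(i) {
    generate_scene(small_scene_spec(seed = seed * 100L + i,
                                    noise_sd = noise_sd))
  })
  cfg <- small_config(seed)
  sets <- make_training_sets(scenes, M = cfg$M, N = cfg$N, seed = seed)
  list(
    detector = train_detector(sets$query, sets$background, cfg),
    scenes = scenes,
    config = cfg
  )
}
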