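#' Prepare a query patch for voting
#'
#' Extracts dense SIFT features from a query endosome patch, assigns them to
#' the dictionary words, and records each feature's displacement from the
#' patch centroid. The centroid of an h x w patch is
#' `(floor((h-1)/2), floor((w-1)/2))` (0-based).
#'
#' @param pixels Numeric matrix (normally 45 x 45) of patch intensities.
#' @param dictionary A [build_dictionary()] result.
#' @param spec A [grid_spec()].
#' @return An object of class `query_patch` with fields `pixels`, `centroid`,
#'   `features` (word-assigned `sift_features`), `displacements` (n x 2 matrix
#'   of `L(f) - L(c_Qm)`) and `histogram`.
#' @export
query_patch <- function(pixels, dictionary, spec = grid_spec()) {
  validate_raster(pixels)
  centroid <- c(floor((nrow(pixels) - 1) / 2), floor((ncol(pixels) - 1) / 2))
  feats <- assign_words(extract_dense(pixels, spec), dictionary)
  structure(
    list(
      pixels = pixels,
      centroid = centroid,
      features = feats,
      displacements = sweep(feats$locations, 2L, centroid),
      histogram = tabulate(feats$words, nbins = dictionary$K)
    ),
    class = "query_patch"
  )
}

.voting_map <- function(values, scale_index = NULL, scales = NULL,
                        n_discarded = 0) {
  structure(
    list(values = values, scale_index = scale_index, scales = scales,
         n_discarded = n_discarded),
    class = "voting_map"
  )
}

#' @export
print.voting_map <- function(x, ...) {
  cat(sprintf(
    "<voting_map %d x %d: max %.4g%s>\n",
    nrow(x$values), ncol(x$values), max(x$values),
    if (is.null(x$scale_index)) "" else ", fused over scales"
  ))
  invisible(x)
}

.check_test_features <- function(test_features) {
  stopifnot(inherits(test_features, "sift_features"))
  if (is.null(test_features$words)) {
    .stop_input("test features must be word-assigned; see assign_words()")
  }
  test_features
}

#' Voting map of one query patch at one scale
#'
#' Every feature pair (f in the query, g in the test image) sharing a visual
#' word k casts a vote of weight d(k) at the implied centroid location
#' `L(g) - s * (L(f) - L(c_Qm))`, rounded half-up per axis; votes landing
#' outside the image are discarded (counted in `n_discarded`).
#'
#' @param query A [query_patch()].
#' @param test_features Word-assigned `sift_features` of the test image.
#' @param weights A [discriminative_weights()] object (or a list with a `d`
#'   vector).
#' @param s Positive scaling factor.
#' @param shape Integer `(height, width)` of the test image.
#' @return A `voting_map` (values only, no scale index).
#' @export
vote_single <- function(query, test_features, weights, s, shape) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    .stop_input("scaling factor s must be a positive number")
  }
  .check_test_features(test_features)
  res <- cpp_vote_maps(
    query$features$words,
    as.numeric(query$displacements[, 1L]), as.numeric(query$displacements[, 2L]),
    test_features$words,
    as.integer(test_features$locations[, 1L]),
    as.integer(test_features$locations[, 2L]),
    as.numeric(weights$d), as.numeric(s),
    as.integer(shape[1L]), as.integer(shape[2L])
  )
  .voting_map(matrix(res$maps, shape[1L], shape[2L]),
              n_discarded = res$n_discarded)
}

#' Voting map summed over all query patches
#'
#' The scale-s voting map of the query set is the elementwise sum of the
#' single-query maps.
#'
#' @param queries Non-empty list of [query_patch()] objects.
#' @inheritParams vote_single
#' @return A `voting_map`.
#' @export
vote_all_queries <- function(queries, test_features, weights, s, shape) {
  if (length(queries) == 0L) .stop_input("query set is empty")
  maps <- lapply(queries, vote_single,
    test_features = test_features,
    weights = weights, s = s, shape = shape
  )
  .voting_map(
    Reduce(`+`, lapply(maps, `[[`, "values")),
    n_discarded = sum(vapply(maps, `[[`, numeric(1), "n_discarded"))
  )
}

#' Fuse per-scale voting maps
#'
#' Selects, per pixel, the scaling factor producing the maximum vote value:
#' the fused map holds that maximum, and `scale_index` the (1-based) index of
#' the chosen scale. Ties are broken towards the smallest scale.
#'
#' @param per_scale_maps List of `voting_map`s (or plain matrices), one per
#'   scale, all with identical shape.
#' @param scales Increasing positive scale factors, same length.
#' @return A `voting_map` with `values`, `scale_index` and `scales`.
#' @export
fuse_scales <- function(per_scale_maps, scales) {
  mats <- lapply(per_scale_maps, function(m) {
    if (inherits(m, "voting_map")) m$values else m
  })
  if (length(mats) != length(scales)) {
    .stop_input("need one voting map per scale")
  }
  dims <- lapply(mats, dim)
  if (length(unique(dims)) != 1L) .stop_input("voting map shapes differ")
  values <- mats[[1L]]
  idx <- matrix(1L, nrow(values), ncol(values))
  for (i in seq_along(mats)[-1L]) {
    better <- mats[[i]] > values   # strict: ties keep the smaller scale
    values[better] <- mats[[i]][better]
    idx[better] <- i
  }
  .voting_map(values, scale_index = idx, scales = scales)
}

#' Localization stage: fused voting map of a test image
#'
#' Runs the full localization loop: extract and word-assign dense SIFT
#' features of the test image, accumulate one voting map per scaling factor
#' from all query patches, and fuse the maps by per-pixel scale maximization.
#' Equivalent (up to floating-point summation order) to the literal
#' scales x words x queries x feature-pairs loop.
#'
#' @param test_image Numeric intensity matrix.
#' @param queries List of [query_patch()] objects.
#' @param dictionary A [build_dictionary()] result.
#' @param weights A [discriminative_weights()] object.
#' @param scales Increasing positive scaling factors (default
#'   `seq(0.5, 1.5, by = 0.1)`).
#' @param spec A [grid_spec()].
#' @param test_features Optionally, precomputed word-assigned features of
#'   `test_image` (skips extraction).
#' @return A fused `voting_map` with `values`, `scale_index` and `scales`.
#' @export
localize <- function(test_image, queries, dictionary, weights,
                     scales = seq(0.5, 1.5, by = 0.1), spec = grid_spec(),
                     test_features = NULL) {
  if (length(queries) == 0L) .stop_input("query set is empty")
  if (any(diff(scales) <= 0) || any(scales <= 0)) {
    .stop_input("scales must be positive and strictly increasing")
  }
  if (is.null(test_features)) {
    test_features <- assign_words(extract_dense(test_image, spec), dictionary)
  }
  .check_test_features(test_features)
  shape <- dim(test_image)
  # concatenate query features across patches (vote weight depends only on
  # the word, so queries can share one accumulation pass)
  q_word <- unlist(lapply(queries, function(q) q$features$words))
  q_dr <- unlist(lapply(queries, function(q) q$displacements[, 1L]))
  q_dc <- unlist(lapply(queries, function(q) q$displacements[, 2L]))
  res <- cpp_vote_maps(
    as.integer(q_word), as.numeric(q_dr), as.numeric(q_dc),
    test_features$words,
    as.integer(test_features$locations[, 1L]),
    as.integer(test_features$locations[, 2L]),
    as.numeric(weights$d), as.numeric(scales),
    as.integer(shape[1L]), as.integer(shape[2L])
  )
  maps <- lapply(seq_along(scales), function(i) res$maps[, , i])
  out <- fuse_scales(maps, scales)
  out$n_discarded <- res$n_discarded
  out
}
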