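#' Detector configuration
#'
#' All tunable parameters of the two-stage detector with their standard
#' defaults: 16 x 16 grids at 2 px spacing, 45 x 45 patches, a 400-word
#' dictionary built from M = 50 query and N = 200 background patches, scale
#' search over 0.5-1.5 in steps of 0.1, voting-map threshold gamma = 0.2,
#' LLC base size 5, SVM cost grid 2^-8..2^8 with 5-fold cross-validation,
#' and NMS overlap threshold 0.5.
#'
#' @param grid_size,grid_step Dense SIFT grid geometry (pixels).
#' @param patch_w,patch_h Training/query patch size (pixels).
#' @param K Dictionary size.
#' @param M,N Query and background training patch counts.
#' @param scales Scaling-factor search set.
#' @param gamma Normalized voting-map threshold in `[0, 1]`.
#' @param llc_C LLC base size.
#' @param svm_C_grid SVM regularization grid.
#' @param cv_folds Cross-validation folds.
#' @param nms_threshold NMS overlap threshold.
#' @param seed Master seed (dictionary, CV folds, sampling).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(grid_size = 16L, grid_step = 2L,
                            patch_w = 45L, patch_h = 45L, K = 400L,
                            M = 50L, N = 200L,
                            scales = seq(0.5, 1.5, by = 0.1), gamma = 0.2,
                            llc_C = 5L, svm_C_grid = 2^(-8:8),
                            cv_folds = 5L, nms_threshold = 0.5, seed = 1L) {
  if (any(scales <= 0) || any(diff(scales) <= 0)) {
    .stop_input("scales must be positive and strictly increasing")
  }
  structure(
    list(
      grid_size = as.integer(grid_size), grid_step = as.integer(grid_step),
      patch_w = as.integer(patch_w), patch_h = as.integer(patch_h),
      K = as.integer(K), M = as.integer(M), N = as.integer(N),
      scales = scales, gamma = gamma, llc_C = as.integer(llc_C),
      svm_C_grid = svm_C_grid, cv_folds = as.integer(cv_folds),
      nms_threshold = nms_threshold, seed = as.integer(seed)
    ),
    class = "detector_config"
  )
}

#' Train the full two-stage detector
#'
#' From query (ring) and background training patches: builds the visual-word
#' dictionary, the per-word discriminative capabilities, the voting-ready
#' query patch representations, and the LLC/SVM patch identifier.
#'
#' @param query_patches List of M query patch matrices (`M >= 2`).
#' @param background_patches List of N background patch matrices (`N >= 1`).
#' @param config A [detector_config()].
#' @param verbose Print per-stage progress to stderr.
#' @return An object of class `endosome_detector` with fields `dictionary`,
#'   `weights`, `queries`, `svm`, `config` and `version`.
#' @export
train_detector <- function(query_patches, background_patches,
                           config = detector_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- grid_spec(config$grid_size, config$grid_step)
  say("extracting dense SIFT from %d + %d training patches",
      length(query_patches), length(background_patches))
  qfeats <- lapply(query_patches, extract_dense, spec = spec)
  bfeats <- lapply(background_patches, extract_dense, spec = spec)
  all_desc <- do.call(rbind, c(
    lapply(qfeats, `[[`, "descriptors"),
    lapply(bfeats, `[[`, "descriptors")
  ))
  say("clustering %d descriptors into K = %d visual words",
      nrow(all_desc), config$K)
  dictionary <- build_dictionary(all_desc, K = config$K, seed = config$seed)
  qh <- do.call(rbind, lapply(qfeats, vq_histogram, dictionary = dictionary))
  bh <- do.call(rbind, lapply(bfeats, vq_histogram, dictionary = dictionary))
  weights <- discriminative_weights(qh, bh)
  queries <- lapply(query_patches, query_patch,
                    dictionary = dictionary, spec = spec)
  say("training the LLC/SVM identifier (%d-fold CV over %d costs)",
      config$cv_folds, length(config$svm_C_grid))
  svm <- train_identifier(
    query_patches, background_patches, dictionary,
    spec = spec, C_llc = config$llc_C, C_grid = config$svm_C_grid,
    cv_folds = config$cv_folds, seed = config$seed
  )
  say("chosen SVM cost: %g", svm$chosen_C)
  structure(
    list(dictionary = dictionary, weights = weights, queries = queries,
         svm = svm, config = config, version = 1L),
    class = "endosome_detector"
  )
}

#' @export
print.endosome_detector <- function(x, ...) {
  cat(sprintf(
    "<endosome_detector: K = %d words, %d query patches, SVM C = %g>\n",
    x$dictionary$K, length(x$queries), x$svm$chosen_C
  ))
  invisible(x)
}

#' Detect endosomes in one test image
#'
#' Runs the full cascade: localization (fused voting map), normalization and
#' gamma-thresholding, candidate box construction from the per-pixel optimal
#' scale, non-maximum suppression, and SVM classification of the surviving
#' candidates.
#'
#' @param image Numeric intensity matrix.
#' @param detector A [train_detector()] result.
#' @param keep_map Also return the fused voting map.
#' @return A list with `detections` (data frame: box corners, center, scale,
#'   vote `value`, SVM `score`, `label`) and `counts`, the per-stage
#'   candidate counts (`thresholded`, `after_nms`, `positive`). With
#'   `keep_map`, also `voting_map`.
#' @export
detect_image <- function(image, detector, keep_map = FALSE) {
  validate_raster(image)
  cfg <- detector$config
  spec <- grid_spec(cfg$grid_size, cfg$grid_step)
  vm <- localize(image, detector$queries, detector$dictionary,
                 detector$weights, scales = cfg$scales, spec = spec)
  peaks <- normalize_and_threshold(vm, cfg$gamma)
  if (nrow(peaks) > 0L) {
    cand <- build_candidate(peaks$x_o, peaks$y_o, peaks$s_star,
                            w = cfg$patch_w, h = cfg$patch_h,
                            image_shape = dim(image))
    cand$value <- peaks$value
    kept <- nms(cand, threshold = cfg$nms_threshold)
    det <- classify_candidates(
      image, kept, detector$dictionary, detector$svm, spec = spec,
      C_llc = cfg$llc_C, patch_w = cfg$patch_w, patch_h = cfg$patch_h
    )
  } else {
    kept <- det <- data.frame(
      x_min = integer(0), y_min = integer(0), x_max = integer(0),
      y_max = integer(0), x_o = integer(0), y_o = integer(0),
      s_star = numeric(0), value = numeric(0), score = numeric(0),
      label = character(0)
    )
  }
  out <- list(
    detections = det,
    counts = c(
      thresholded = nrow(peaks),
      after_nms = nrow(kept),
      positive = sum(det$label == "endosome")
    )
  )
  if (keep_map) out$voting_map <- vm
  out
}
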