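# Model container persistence. A trained detector is written as a directory
# of plain-text files: meta.json (config, seed, version, SVM scalars),
# dictionary.csv (K x 128 words), weights.csv (alpha/delta/d), svm_w.csv and
# queries.csv (per query feature: query id, word, displacement from the
# patch centroid) -- everything the detect stage needs without the training
# images.

.MODEL_VERSION <- 1L

#' Save a trained detector to a directory
#'
#' @param detector A [train_detector()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(detector, dir) {
  stopifnot(inherits(detector, "endosome_detector"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- detector$config
  meta <- list(
    format = "endovote-model",
    version = .MODEL_VERSION,
    K = detector$dictionary$K,
    kmeans_seed = detector$dictionary$seed,
    config = cfg[setdiff(names(cfg), c("scales", "svm_C_grid"))],
    scales = cfg$scales,
    svm_C_grid = cfg$svm_C_grid,
    svm = list(
      b = detector$svm$b, chosen_C = detector$svm$chosen_C,
      cv_folds = detector$svm$cv_folds
    ),
    patch_shapes = lapply(detector$queries, function(q) dim(q$pixels))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(data.table::as.data.table(detector$dictionary$words),
                     file.path(dir, "dictionary.csv"))
  data.table::fwrite(
    data.table::data.table(
      alpha = detector$weights$alpha,
      delta = detector$weights$delta,
      d = detector$weights$d
    ),
    file.path(dir, "weights.csv")
  )
  data.table::fwrite(data.table::data.table(w = detector$svm$w),
                     file.path(dir, "svm_w.csv"))
  qtab <- do.call(rbind, lapply(seq_along(detector$queries), function(m) {
    q <- detector$queries[[m]]
    data.table::data.table(
      query = m,
      word = q$features$words,
      disp_r = q$displacements[, 1L],
      disp_c = q$displacements[, 2L]
    )
  }))
  data.table::fwrite(qtab, file.path(dir, "queries.csv"))
  invisible(dir)
}

#' Load a detector saved by [save_model()]
#'
#' @param dir Model directory.
#' @return An `endosome_detector` (query pixel data is not stored; the
#'   reloaded queries carry only what voting needs: word assignments and
#'   centroid displacements).
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) .stop_input("no model found in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "endovote-model") ||
      !identical(as.integer(meta$version), .MODEL_VERSION)) {
    .stop_input("unsupported model container version in %s", dir)
  }
  cfg <- do.call(detector_config, c(
    meta$config[setdiff(names(meta$config), character(0))],
    list(scales = meta$scales, svm_C_grid = meta$svm_C_grid)
  ))
  words <- as.matrix(data.table::fread(file.path(dir, "dictionary.csv")))
  dimnames(words) <- NULL
  dictionary <- structure(
    list(words = words, K = as.integer(meta$K),
         seed = as.integer(meta$kmeans_seed)),
    class = "bow_dictionary"
  )
  wtab <- data.table::fread(file.path(dir, "weights.csv"))
  weights <- structure(
    list(alpha = wtab$alpha, delta = wtab$delta, d = wtab$d),
    class = "discriminative_weights"
  )
  svm_w <- data.table::fread(file.path(dir, "svm_w.csv"))$w
  svm <- structure(
    list(w = svm_w, b = meta$svm$b, chosen_C = meta$svm$chosen_C,
         cv_folds = meta$svm$cv_folds),
    class = "svm_model"
  )
  qtab <- data.table::fread(file.path(dir, "queries.csv"))
  queries <- lapply(sort(unique(qtab$query)), function(m) {
    qi <- qtab[qtab$query == m, ]
    structure(
      list(
        pixels = NULL,
        centroid = c(
          floor((meta$patch_shapes[[m]][1L] - 1) / 2),
          floor((meta$patch_shapes[[m]][2L] - 1) / 2)
        ),
        features = .sift_features(
          matrix(numeric(0), nrow(qi), 0L),
          cbind(qi$disp_r, qi$disp_c),  # displacements; locations not needed
          grid_spec(cfg$grid_size, cfg$grid_step),
          words = qi$word
        ),
        displacements = cbind(qi$disp_r, qi$disp_c),
        histogram = tabulate(qi$word, nbins = as.integer(meta$K))
      ),
      class = "query_patch"
    )
  })
  structure(
    list(dictionary = dictionary, weights = weights, queries = queries,
         svm = svm, config = cfg, version = .MODEL_VERSION),
    class = "endosome_detector"
  )
}
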