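#' Locality-constrained linear coding of one descriptor
#'
#' Encodes a SIFT descriptor as an affine combination of its C nearest visual
#' words: the sum-to-one constrained least-squares problem
#' `min ||f - B_f c||^2 s.t. 1' c = 1` is solved in closed form on the shifted
#' covariance system `(Z Z' + lambda I) c = 1`, `Z = B_f - f`, with ridge
#' `lambda = 1e-6 * trace(Z Z') / C` for invertibility, then the coefficients
#' are normalized to sum to one.
#'
#' @param feature Numeric descriptor (length matching the dictionary words).
#' @param dictionary A [build_dictionary()] result.
#' @param C Number of nearest words in the local base (default 5).
#' @return A list of class `llc_code` with `base_indices` (C word indices,
#'   nearest first) and `coefficients` (length C, summing to 1).
#' @export
llc_encode <- function(feature, dictionary, C = 5L) {
  f <- as.numeric(feature)
  words <- dictionary$words
  if (length(f) != ncol(words)) .stop_input("descriptor length mismatch")
  C <- as.integer(C)
  if (C < 1L || C > nrow(words)) {
    .stop_input("C must be between 1 and K = %d", nrow(words))
  }
  d2 <- rowSums(sweep(words, 2L, f)^2)
  base <- order(d2)[seq_len(C)]
  coef <- .llc_solve(words[base, , drop = FALSE], f)
  structure(list(base_indices = base, coefficients = coef), class = "llc_code")
}

.llc_solve <- function(B, f) {
  C <- nrow(B)
  z <- sweep(B, 2L, f)
  G <- z %*% t(z)
  tr <- sum(diag(G))
  if (tr <= 0) return(rep(1 / C, C))   # all base words coincide with f
  coef <- solve(G + diag(1e-6 * tr / C, C), rep(1, C))
  as.numeric(coef / sum(coef))
}

# Batch LLC encoding of an n x 128 descriptor matrix; returns base index and
# coefficient matrices (n x C).
.llc_encode_all <- function(descriptors, dictionary, C = 5L) {
  words <- dictionary$words
  n <- nrow(descriptors)
  C <- as.integer(C)
  cross <- descriptors %*% t(words)
  d2 <- outer(rowSums(descriptors^2), rowSums(words^2), `+`) - 2 * cross
  bases <- matrix(0L, n, C)
  coefs <- matrix(0, n, C)
  for (i in seq_len(n)) {
    base <- order(d2[i, ])[seq_len(C)]
    bases[i, ] <- base
    coefs[i, ] <- .llc_solve(words[base, , drop = FALSE], descriptors[i, ])
  }
  list(bases = bases, coefs = coefs)
}

#' Max-pool LLC codes into one patch descriptor
#'
#' Takes the component-wise maximum of the LLC coefficients over all codes of
#' a patch (words never selected by any code get 0), then L2-normalizes the
#' pooled K-vector.
#'
#' @param codes Non-empty list of `llc_code` objects.
#' @param K Dictionary size.
#' @return A numeric vector of length K with unit L2 norm (or all-zero).
#' @export
pool_codes <- function(codes, K) {
  if (length(codes) == 0L) .stop_input("no LLC codes to pool")
  pooled <- numeric(K)
  for (code in codes) {
    idx <- code$base_indices
    pooled[idx] <- pmax(pooled[idx], code$coefficients)
  }
  nrm <- sqrt(sum(pooled^2))
  if (nrm > 0) pooled <- pooled / nrm
  pooled
}

#' LLC + max-pooling patch descriptor
#'
#' Dense SIFT extraction, LLC encoding of every feature and max-pooling in one
#' call; this is the representation fed to the linear SVM.
#'
#' @param patch Numeric intensity matrix (normally 45 x 45).
#' @param dictionary A [build_dictionary()] result.
#' @param spec A [grid_spec()].
#' @param C LLC base size (default 5).
#' @return A numeric vector of length K (L2-normalized).
#' @export
encode_patch <- function(patch, dictionary, spec = grid_spec(), C = 5L) {
  feats <- extract_dense(patch, spec)
  if (nrow(feats$descriptors) == 0L) return(numeric(dictionary$K))
  enc <- .llc_encode_all(feats$descriptors, dictionary, C)
  pooled <- numeric(dictionary$K)
  for (i in seq_len(nrow(enc$bases))) {
    idx <- enc$bases[i, ]
    pooled[idx] <- pmax(pooled[idx], enc$coefs[i, ])
  }
  nrm <- sqrt(sum(pooled^2))
  if (nrm > 0) pooled <- pooled / nrm
  pooled
}

#' Train the patch identifier (linear SVM)
#'
#' Represents each training patch by its LLC max-pooled descriptor and trains
#' a binary linear-kernel SVM (endosome = positive class). The regularization
#' parameter is chosen by seeded 5-fold cross-validation over the grid
#' `2^-8, 2^-7, ..., 2^8` (ties towards the smallest value). The decision
#' function is reduced to an explicit weight vector and bias, oriented so
#' positive scores mean endosome.
#'
#' @param pos_patches,neg_patches Non-empty lists of patch matrices (or
#'   precomputed descriptor row-matrices via `descriptors = TRUE`).
#' @param dictionary A [build_dictionary()] result.
#' @param spec A [grid_spec()].
#' @param C_llc LLC base size.
#' @param C_grid SVM cost grid.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param descriptors If `TRUE`, `pos_patches`/`neg_patches` are already
#'   descriptor matrices (rows = patches).
#' @return An object of class `svm_model` with `w` (length K), `b`,
#'   `chosen_C`, `cv_folds` and `cv_accuracy` (per grid value).
#' @export
train_identifier <- function(pos_patches, neg_patches, dictionary,
                             spec = grid_spec(), C_llc = 5L,
                             C_grid = 2^(-8:8), cv_folds = 5L, seed = 1L,
                             descriptors = FALSE) {
  if (descriptors) {
    xpos <- pos_patches
    xneg <- neg_patches
  } else {
    xpos <- do.call(rbind, lapply(pos_patches, encode_patch,
      dictionary = dictionary, spec = spec, C = C_llc
    ))
    xneg <- do.call(rbind, lapply(neg_patches, encode_patch,
      dictionary = dictionary, spec = spec, C = C_llc
    ))
  }
  if (is.null(xpos) || is.null(xneg) || nrow(xpos) == 0L || nrow(xneg) == 0L) {
    .stop_input("both positive and negative training patches are required")
  }
  x <- rbind(xpos, xneg)
  y <- factor(
    c(rep("endosome", nrow(xpos)), rep("background", nrow(xneg))),
    levels = c("background", "endosome")
  )
  n <- nrow(x)
  folds <- withr::with_seed(as.integer(seed),
    sample(rep_len(seq_len(cv_folds), n))
  )
  cv_acc <- vapply(C_grid, function(cost) {
    correct <- 0L
    for (fold in seq_len(cv_folds)) {
      hold <- folds == fold
      if (all(hold) || !all(table(y[!hold]) > 0)) next
      fit <- e1071::svm(x[!hold, , drop = FALSE], y[!hold],
        kernel = "linear", cost = cost, scale = FALSE
      )
      pred <- predict(fit, x[hold, , drop = FALSE])
      correct <- correct + sum(pred == y[hold])
    }
    correct / n
  }, numeric(1))
  chosen_C <- C_grid[which.max(cv_acc)]   # which.max ties -> first = smallest
  fit <- e1071::svm(x, y, kernel = "linear", cost = chosen_C, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the hyperplane so endosomes score positive
  dec <- as.numeric(x %*% w + b)
  if (mean(dec[y == "endosome"]) < mean(dec[y == "background"])) {
    w <- -w
    b <- -b
  }
  structure(
    list(w = w, b = b, chosen_C = chosen_C, cv_folds = cv_folds,
         C_grid = C_grid, cv_accuracy = cv_acc),
    class = "svm_model"
  )
}

#' Signed SVM decision values
#'
#' @param model An [train_identifier()] result.
#' @param x Descriptor matrix (rows = patches) or single descriptor vector.
#' @return Numeric scores; positive means endosome.
#' @export
svm_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  as.numeric(x %*% model$w + model$b)
}

#' Threshold the normalized voting map
#'
#' Min-max normalizes the fused voting map to `[0, 1]` and retains the pixels
#' whose normalized value is strictly larger than `gamma`. A constant map
#' (including all-zero) yields no retained locations.
#'
#' @param voting_map A fused `voting_map` from [localize()] (or a plain
#'   matrix).
#' @param gamma Threshold in `[0, 1]` (default 0.2).
#' @return A data frame with 0-based pixel coordinates `x_o`, `y_o` (row,
#'   col), the normalized `value`, and `s_star` (the per-pixel optimal scale,
#'   when the map carries one).
#' @export
normalize_and_threshold <- function(voting_map, gamma = 0.2) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    .stop_input("gamma must lie in [0, 1]")
  }
  vm <- if (inherits(voting_map, "voting_map")) voting_map else .voting_map(voting_map)
  v <- vm$values
  rng <- range(v)
  if (rng[2] <= rng[1]) {
    return(data.frame(x_o = integer(0), y_o = integer(0),
                      value = numeric(0), s_star = numeric(0)))
  }
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  keep <- which(vn > gamma)
  rows <- (keep - 1L) %% nrow(v)         # 0-based
  cols <- (keep - 1L) %/% nrow(v)
  s_star <- if (!is.null(vm$scale_index)) {
    vm$scales[vm$scale_index[keep]]
  } else {
    rep(NA_real_, length(keep))
  }
  out <- data.frame(x_o = rows, y_o = cols, value = vn[keep], s_star = s_star)
  # row-major pixel order for determinism
  out[order(out$x_o, out$y_o), , drop = FALSE]
}

#' Candidate box around a voting-map peak
#'
#' Builds the candidate patch centered at `(x_o, y_o)` with the per-pixel
#' optimal scale `s*`: corners are
#' `x_min = ceil(x_o - s*/2 * w)`, `x_max = floor(x_o + s*/2 * w)` (likewise
#' for y with `h`), then clipped to the image bounds.
#'
#' @param x_o,y_o 0-based center pixel (row, col); vectorized.
#' @param s_star Positive optimal scale(s).
#' @param w,h Query patch width and height in pixels (defaults 45).
#' @param image_shape Integer `(height, width)` used for clipping; `NULL`
#'   skips clipping.
#' @return A data frame of candidates: `x_min`, `y_min`, `x_max`, `y_max`
#'   (0-based inclusive corners), `x_o`, `y_o`, `s_star`.
#' @export
build_candidate <- function(x_o, y_o, s_star, w = 45L, h = 45L,
                            image_shape = NULL) {
  if (any(s_star <= 0)) .stop_input("scale s* must be positive")
  if (w < 1L || h < 1L) .stop_input("patch size must be >= 1")
  x_min <- ceiling(x_o - 0.5 * s_star * w)
  y_min <- ceiling(y_o - 0.5 * s_star * h)
  x_max <- floor(x_o + 0.5 * s_star * w)
  y_max <- floor(y_o + 0.5 * s_star * h)
  if (!is.null(image_shape)) {
    x_min <- pmax(x_min, 0)
    y_min <- pmax(y_min, 0)
    x_max <- pmin(x_max, image_shape[1L] - 1)
    y_max <- pmin(y_max, image_shape[2L] - 1)
  }
  data.frame(
    x_min = as.integer(x_min), y_min = as.integer(y_min),
    x_max = as.integer(x_max), y_max = as.integer(y_max),
    x_o = x_o, y_o = y_o, s_star = s_star
  )
}

# Vectorized IoU of one box against many (inclusive-pixel convention).
.iou_one_vs_many <- function(box, boxes) {
  ix <- pmax(0, pmin(box[3L], boxes$x_max) - pmax(box[1L], boxes$x_min) + 1)
  iy <- pmax(0, pmin(box[4L], boxes$y_max) - pmax(box[2L], boxes$y_min) + 1)
  inter <- ix * iy
  a1 <- (box[3L] - box[1L] + 1) * (box[4L] - box[2L] + 1)
  a2 <- (boxes$x_max - boxes$x_min + 1) * (boxes$y_max - boxes$y_min + 1)
  inter / (a1 + a2 - inter)
}

#' Non-maximum suppression of candidate boxes
#'
#' Greedy suppression in descending vote-value order (ties broken by
#' row-major center order). A candidate is removed when it covers the same
#' target as an already-kept candidate, i.e. when its intersection-over-union
#' overlap with the kept box exceeds `threshold`, or (with
#' `suppress_contained`, the default) when its center lies inside the kept
#' box or the kept center lies inside its box. The containment clause removes
#' duplicate detections of one target at different scales: co-centered boxes
#' at neighboring scale factors overlap by just under 0.5 IoU, so an
#' overlap-only rule keeps them all.
#'
#' @param candidates Data frame with columns `x_min`, `y_min`, `x_max`,
#'   `y_max`, `value` and centers `x_o`, `y_o`.
#' @param threshold Overlap above which a candidate is suppressed
#'   (default 0.5).
#' @param suppress_contained Also suppress center-contained candidates
#'   (default `TRUE`).
#' @return The surviving rows, in descending-value order.
#' @export
nms <- function(candidates, threshold = 0.5, suppress_contained = TRUE) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$value, candidates$x_o, candidates$y_o)
  cand <- candidates[ord, , drop = FALSE]
  keep <- integer(0)
  alive <- seq_len(nrow(cand))
  while (length(alive) > 0L) {
    i <- alive[1L]
    keep <- c(keep, i)
    alive <- alive[-1L]
    if (length(alive) == 0L) break
    box <- c(cand$x_min[i], cand$y_min[i], cand$x_max[i], cand$y_max[i])
    rest <- cand[alive, , drop = FALSE]
    drop <- .iou_one_vs_many(box, rest) > threshold
    if (suppress_contained) {
      in_kept <- rest$x_o >= box[1L] & rest$x_o <= box[3L] &
        rest$y_o >= box[2L] & rest$y_o <= box[4L]
      kept_in <- cand$x_o[i] >= rest$x_min & cand$x_o[i] <= rest$x_max &
        cand$y_o[i] >= rest$y_min & cand$y_o[i] <= rest$y_max
      drop <- drop | in_kept | kept_in
    }
    alive <- alive[!drop]
  }
  cand[keep, , drop = FALSE]
}

#' Classify candidate patches with the trained SVM
#'
#' Crops each candidate box from the image (bilinearly resampling to the
#' native patch size when the box differs), encodes it with LLC +
#' max-pooling, and scores it with the linear SVM. A candidate is labeled
#' `endosome` when its signed decision value exceeds 0.
#'
#' @param image Numeric intensity matrix.
#' @param candidates Data frame from [nms()]/[build_candidate()].
#' @param dictionary A [build_dictionary()] result.
#' @param model An [train_identifier()] result.
#' @param spec A [grid_spec()].
#' @param C_llc LLC base size.
#' @param patch_w,patch_h Native patch size fed to the SVM (defaults 45).
#' @return A data frame of detections: the candidate columns plus `score` and
#'   `label` (`"endosome"` or `"background"`).
#' @export
classify_candidates <- function(image, candidates, dictionary, model,
                                spec = grid_spec(), C_llc = 5L,
                                patch_w = 45L, patch_h = 45L) {
  n <- nrow(candidates)
  scores <- numeric(n)
  ok <- rep(TRUE, n)
  h <- nrow(image)
  w <- ncol(image)
  for (i in seq_len(n)) {
    x1 <- candidates$x_min[i]
    y1 <- candidates$y_min[i]
    x2 <- candidates$x_max[i]
    y2 <- candidates$y_max[i]
    if (x2 < 0 || y2 < 0 || x1 > h - 1 || y1 > w - 1 || x1 > x2 || y1 > y2) {
      warning(sprintf("candidate %d lies outside the image; skipped", i))
      ok[i] <- FALSE
      next
    }
    crop <- image[(max(x1, 0) + 1):(min(x2, h - 1) + 1),
                  (max(y1, 0) + 1):(min(y2, w - 1) + 1), drop = FALSE]
    if (nrow(crop) != patch_h || ncol(crop) != patch_w) {
      crop <- .resize_bilinear(crop, patch_h, patch_w)
    }
    desc <- encode_patch(crop, dictionary, spec, C_llc)
    scores[i] <- svm_score(model, desc)
  }
  out <- candidates[ok, , drop = FALSE]
  out$score <- scores[ok]
  out$label <- ifelse(out$score > 0, "endosome", "background")
  out
}

# Bilinear resampling of a plain matrix to (h, w) via EBImage.
.resize_bilinear <- function(m, h, w) {
  out <- EBImage::resize(EBImage::Image(m), w = h, h = w, filter = "bilinear")
  matrix(EBImage::imageData(out), h, w)
}
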