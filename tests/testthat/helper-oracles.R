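# Independent brute-force reference implementations used as oracles.
# These deliberately mirror the definitions literally (loops, no shared code
# with the package internals).

# per-pixel finite differences, one pixel at a time
oracle_gradients <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  mag <- ori <- matrix(0, h, w)
  for (r in 1:h) {
    for (c in 1:w) {
      gr <- if (h == 1) 0
      else if (r == 1) img[2, c] - img[1, c]
      else if (r == h) img[h, c] - img[h - 1, c]
      else (img[r + 1, c] - img[r - 1, c]) / 2
      gc <- if (w == 1) 0
      else if (c == 1) img[r, 2] - img[r, 1]
      else if (c == w) img[r, w] - img[r, w - 1]
      else (img[r, c + 1] - img[r, c - 1]) / 2
      mag[r, c] <- sqrt(gr^2 + gc^2)
      ori[r, c] <- if (mag[r, c] == 0) 0 else (atan2(gr, gc) * 180 / pi) %% 360
    }
  }
  list(magnitude = mag, orientation = ori)
}

# all valid grid origins by exhaustive enumeration
oracle_grid_origins <- function(h, w, grid_size, step) {
  out <- NULL
  for (r0 in 0:max(0, h - grid_size)) {
    for (c0 in 0:max(0, w - grid_size)) {
      if (r0 %% step == 0 && c0 %% step == 0) out <- rbind(out, c(r0, c0))
    }
  }
  out
}

# histogram of one subgrid from per-pixel gradients, linear bin splitting
oracle_subgrid_histogram <- function(grads, rows, cols, n_bins = 8) {
  hist <- numeric(n_bins)
  for (r in rows) {
    for (c in cols) {
      m <- grads$magnitude[r, c]
      if (m == 0) next
      pos <- grads$orientation[r, c] / (360 / n_bins)
      i0 <- floor(pos) %% n_bins
      frac <- pos - floor(pos)
      hist[i0 + 1] <- hist[i0 + 1] + m * (1 - frac)
      hist[(i0 + 1) %% n_bins + 1] <- hist[(i0 + 1) %% n_bins + 1] + m * frac
    }
  }
  hist
}

# literal double loops for the similarity definitions
oracle_alpha <- function(H) {
  M <- nrow(H)
  K <- ncol(H)
  acc <- numeric(K)
  for (m in 1:M) for (l in 1:M) {
    if (l == m) next
    for (k in 1:K) acc[k] <- acc[k] + min(H[m, k], H[l, k])
  }
  acc / (M * (M - 1))
}

oracle_delta <- function(HQ, HB) {
  M <- nrow(HQ)
  N <- nrow(HB)
  K <- ncol(HQ)
  acc <- numeric(K)
  for (m in 1:M) for (n in 1:N) for (k in 1:K) {
    acc[k] <- acc[k] + min(HQ[m, k], HB[n, k])
  }
  acc / (M * N)
}

# exhaustive nearest-word scan, ties -> lowest index
oracle_vq <- function(desc, words) {
  apply(desc, 1, function(f) {
    d2 <- colSums((t(words) - f)^2)
    which(d2 == min(d2))[1]
  })
}

# the literal localization quadruple loop: scales x words x queries x pairs
oracle_localize <- function(test_feats, queries, d, scales, shape) {
  ns <- length(scales)
  maps <- lapply(seq_len(ns), function(i) matrix(0, shape[1], shape[2]))
  for (si in seq_len(ns)) {
    s <- scales[si]
    for (k in seq_along(d)) {
      for (q in queries) {
        qi <- which(q$features$words == k)
        ti <- which(test_feats$words == k)
        for (a in qi) {
          for (b in ti) {
            loc <- test_feats$locations[b, ] - s * q$displacements[a, ]
            r <- floor(loc[1] + 0.5)
            c <- floor(loc[2] + 0.5)
            if (r >= 0 && r < shape[1] && c >= 0 && c < shape[2]) {
              maps[[si]][r + 1, c + 1] <- maps[[si]][r + 1, c + 1] + d[k]
            }
          }
        }
      }
    }
  }
  # per-pixel scale max, ties to the smallest scale
  vals <- maps[[1]]
  idx <- matrix(1L, shape[1], shape[2])
  if (ns > 1) {
    for (i in 2:ns) {
      sel <- maps[[i]] > vals
      vals[sel] <- maps[[i]][sel]
      idx[sel] <- i
    }
  }
  list(per_scale = maps, values = vals, scale_index = idx)
}

# 1-D grid search over (c, 1 - c) for the 2-word constrained least squares
oracle_llc_c2 <- function(f, B, step = 1e-4) {
  cs <- seq(-2, 3, by = step)
  obj <- vapply(cs, function(c1) {
    resid <- f - (c1 * B[1, ] + (1 - c1) * B[2, ])
    sum(resid^2)
  }, numeric(1))
  c_best <- cs[which.min(obj)]
  c(c_best, 1 - c_best)
}

oracle_iou <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1]) + 1
  iy <- min(a[4], b[4]) - max(a[2], b[2]) + 1
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / ((a[3] - a[1] + 1) * (a[4] - a[2] + 1) +
           (b[3] - b[1] + 1) * (b[4] - b[2] + 1) - inter)
}

# quadratic-time greedy NMS reference (same suppression rule as the package)
oracle_nms <- function(cand, threshold = 0.5, contained = TRUE) {
  ord <- order(-cand$value, cand$x_o, cand$y_o)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  removed <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (removed[i]) next
    kept[i] <- TRUE
    if (i == nrow(cand)) break
    for (j in (i + 1):nrow(cand)) {
      if (removed[j]) next
      a <- c(cand$x_min[i], cand$y_min[i], cand$x_max[i], cand$y_max[i])
      b <- c(cand$x_min[j], cand$y_min[j], cand$x_max[j], cand$y_max[j])
      over <- oracle_iou(a, b) > threshold
      if (contained) {
        over <- over ||
          (cand$x_o[j] >= a[1] && cand$x_o[j] <= a[3] &&
           cand$y_o[j] >= a[2] && cand$y_o[j] <= a[4]) ||
          (cand$x_o[i] >= b[1] && cand$x_o[i] <= b[3] &&
           cand$y_o[i] >= b[2] && cand$y_o[i] <= b[4])
      }
      if (over) removed[j] <- TRUE
    }
  }
  cand[kept, , drop = FALSE]
}

# best one-to-one assignment of detections to ground truth by exhaustive
# search (maximizes TP under the > 0.5 overlap criterion); for <= 4 boxes
oracle_best_assignment_tp <- function(det, gt, min_overlap = 0.5) {
  nd <- nrow(det)
  ng <- nrow(gt)
  best <- 0
  assignments <- function(free_gt, i, tp) {
    best <<- max(best, tp)
    if (i > nd) return()
    assignments(free_gt, i + 1, tp)   # detection i unmatched
    for (g in which(free_gt)) {
      a <- c(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i])
      b <- c(gt$x_min[g], gt$y_min[g], gt$x_max[g], gt$y_max[g])
      if (oracle_iou(a, b) > min_overlap) {
        f2 <- free_gt
        f2[g] <- FALSE
        assignments(f2, i + 1, tp + 1)
      }
    }
  }
  assignments(rep(TRUE, ng), 1, 0)
  best
}
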