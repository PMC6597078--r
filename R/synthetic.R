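#' Specification of a synthetic fluorescence scene
#'
#' Parameters of the seeded scene generator. The defaults emulate widefield
#' fluorescence fields of view containing ring-like endosomes: Gaussian
#' annuli with radii 8-22 px (a radius-15 ring fills a 45 x 45 patch at unit
#' scale, so the radius range spans scale factors of roughly 0.5-1.5) amid
#' confounding bright structures (filled discs, partial arcs and blob
#' clusters) on a dim baseline with additive Gaussian sensor noise.
#'
#' @param size Image size `(height, width)` in pixels.
#' @param n_rings Number of ring targets.
#' @param radius_range Ring radius range (pixels).
#' @param sigma_r Radial Gaussian profile width of the annulus (pixels).
#' @param amplitude Ring peak intensity.
#' @param n_background Number of confounding background objects.
#' @param bg_amplitude Confounder peak intensity.
#' @param baseline Constant background level.
#' @param noise_sd Additive Gaussian noise standard deviation (the high-SNR
#'   default keeps object amplitudes well above this).
#' @param signal_noise Optional signal-dependent noise coefficient
#'   (`sd = signal_noise * sqrt(intensity)` added on top); 0 disables it.
#' @param min_sep Minimum distance between object centers (pixels).
#' @param seed Integer seed; every generator operation is deterministic
#'   given it.
#' @param max_tries Rejection-sampling cap per object placement.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(512L, 512L), n_rings = 8L,
                       radius_range = c(8, 22), sigma_r = 2,
                       amplitude = 1, n_background = 8L, bg_amplitude = 1,
                       baseline = 0.1, noise_sd = 0.05, signal_noise = 0,
                       min_sep = 60, seed = 1L, max_tries = 2000L) {
  structure(
    list(
      size = as.integer(size), n_rings = as.integer(n_rings),
      radius_range = radius_range, sigma_r = sigma_r, amplitude = amplitude,
      n_background = as.integer(n_background), bg_amplitude = bg_amplitude,
      baseline = baseline, noise_sd = noise_sd, signal_noise = signal_noise,
      min_sep = min_sep, seed = as.integer(seed),
      max_tries = as.integer(max_tries)
    ),
    class = "scene_spec"
  )
}

# Ground-truth box side for an object of radius R: scales linearly with the
# radius (a radius-15 ring gets the native 45 px box), rounded to odd so the
# box has an integer center pixel.
.gt_box_side <- function(radius) {
  as.integer(2 * round((45 * radius / 15 - 1) / 2) + 1)
}

# Squared distance of every pixel in a local window to `center`; used by all
# renderers. Returns list(rows, cols, r) with 1-based index ranges.
.radial_window <- function(shape, center, extent) {
  rows <- max(0, floor(center[1L] - extent)):min(shape[1L] - 1, ceiling(center[1L] + extent))
  cols <- max(0, floor(center[2L] - extent)):min(shape[2L] - 1, ceiling(center[2L] + extent))
  r <- sqrt(outer((rows - center[1L])^2, (cols - center[2L])^2, `+`))
  list(rows = rows + 1L, cols = cols + 1L, r = r)
}

#' Render a Gaussian annulus (ring target)
#'
#' Adds the radial profile `A * exp(-(r - R)^2 / (2 sigma_r^2))` around
#' `center`, where `r` is the Euclidean distance to the center: intensity
#' peaks at `A` on the radius-R circle and is essentially zero at the center
#' for `R >> sigma_r`.
#'
#' @param shape Image `(height, width)`.
#' @param center 0-based `(row, col)` ring center.
#' @param radius Ring radius R in pixels; must exceed `2 * sigma_r`.
#' @param sigma_r Radial profile width.
#' @param amplitude Peak intensity A.
#' @return A `shape[1] x shape[2]` additive intensity field.
#' @export
render_ring <- function(shape, center, radius, sigma_r = 2, amplitude = 1) {
  if (radius <= 2 * sigma_r) .stop_input("ring radius must exceed 2 * sigma_r")
  extent <- radius + 4 * sigma_r
  if (center[1L] - extent < 0 || center[2L] - extent < 0 ||
      center[1L] + extent > shape[1L] - 1 || center[2L] + extent > shape[2L] - 1) {
    .stop_input("ring does not fit inside the image")
  }
  field <- matrix(0, shape[1L], shape[2L])
  w <- .radial_window(shape, center, extent)
  field[w$rows, w$cols] <- amplitude * exp(-(w$r - radius)^2 / (2 * sigma_r^2))
  field
}

#' Render a confounding background object
#'
#' Three bright non-annular patterns that mimic endosome-like background
#' structures: a filled disc (flat top of the given radius with a Gaussian
#' edge falloff), a partial annular arc (the ring profile hard-masked to an
#' angular half-width below 90 degrees, leaving at least half the circle at
#' background level), and a cluster of small Gaussian blobs.
#'
#' @param shape Image `(height, width)`.
#' @param kind One of `"disc"`, `"arc"`, `"cluster"`.
#' @param center 0-based `(row, col)` object center.
#' @param radius Object radius in pixels.
#' @param amplitude Peak intensity.
#' @param sigma Edge / radial profile width (pixels).
#' @param arc_start Arc start angle in radians (kind `"arc"`).
#' @param arc_half Arc angular half-width in radians, `< pi/2`
#'   (kind `"arc"`).
#' @param blob_offsets For `"cluster"`: matrix of `(row, col)` blob offsets
#'   from the center (defaults to a fixed 4-blob diamond at half-radius).
#' @return A `shape[1] x shape[2]` additive intensity field.
#' @export
render_background <- function(shape, kind, center, radius, amplitude = 1,
                              sigma = 2, arc_start = 0, arc_half = pi / 3,
                              blob_offsets = NULL) {
  extent <- radius + 4 * sigma
  if (center[1L] - extent < 0 || center[2L] - extent < 0 ||
      center[1L] + extent > shape[1L] - 1 || center[2L] + extent > shape[2L] - 1) {
    .stop_input("background object does not fit inside the image")
  }
  field <- matrix(0, shape[1L], shape[2L])
  if (kind == "disc") {
    w <- .radial_window(shape, center, extent)
    field[w$rows, w$cols] <-
      amplitude * exp(-pmax(w$r - radius, 0)^2 / (2 * sigma^2))
  } else if (kind == "arc") {
    if (arc_half >= pi / 2) .stop_input("arc half-width must be below pi/2")
    rows <- max(0, floor(center[1L] - extent)):min(shape[1L] - 1, ceiling(center[1L] + extent))
    cols <- max(0, floor(center[2L] - extent)):min(shape[2L] - 1, ceiling(center[2L] + extent))
    dr <- outer(rows - center[1L], rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), cols - center[2L])
    r <- sqrt(dr^2 + dc^2)
    ang <- atan2(dr, dc)
    dang <- abs((ang - arc_start + pi) %% (2 * pi) - pi)
    mask <- dang <= arc_half
    field[rows + 1L, cols + 1L] <-
      amplitude * exp(-(r - radius)^2 / (2 * sigma^2)) * mask
  } else if (kind == "cluster") {
    if (is.null(blob_offsets)) {
      d <- radius / 2
      blob_offsets <- rbind(c(-d, 0), c(d, 0), c(0, -d), c(0, d))
    }
    for (i in seq_len(nrow(blob_offsets))) {
      w <- .radial_window(shape, center + blob_offsets[i, ], 4 * sigma)
      field[w$rows, w$cols] <- pmax(
        field[w$rows, w$cols],
        amplitude * exp(-w$r^2 / (2 * sigma^2))
      )
    }
  } else {
    .stop_input("unknown background kind '%s'", kind)
  }
  field
}

#' Generate an annotated synthetic scene
#'
#' Places `n_rings` annular targets and `n_background` confounders at
#' rejection-sampled centers respecting the minimum separation, sums the
#' rendered fields with the baseline, and adds seeded Gaussian noise
#' (clipped at zero). Ground-truth boxes are centered on each object with
#' side `45 * R / 15` rounded to odd, so ring sizes exercise the scale
#' search.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `annotated_scene`: a list with `image`, a
#'   `boxes` data frame (`object_id`, `label` in ring/background, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `x_c`, `y_c`, `radius`, `scale`) and `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1L]
  w <- spec$size[2L]
  withr::with_seed(spec$seed, {
    n_obj <- spec$n_rings + spec$n_background
    labels <- c(rep("ring", spec$n_rings), rep("background", spec$n_background))
    radii <- runif(n_obj, spec$radius_range[1L], spec$radius_range[2L])
    sides <- .gt_box_side(radii)
    margins <- pmax((sides - 1) / 2, radii + 4 * spec$sigma_r) + 1
    centers <- matrix(NA_real_, n_obj, 2L)
    for (i in seq_len(n_obj)) {
      placed <- FALSE
      for (try in seq_len(spec$max_tries)) {
        cand <- c(
          runif(1, margins[i], h - 1 - margins[i]),
          runif(1, margins[i], w - 1 - margins[i])
        )
        if (i == 1L || all(sqrt(rowSums(
          sweep(centers[seq_len(i - 1L), , drop = FALSE], 2L, cand)^2
        )) >= spec$min_sep)) {
          centers[i, ] <- round(cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        .stop_input(
          "could not place object %d under min_sep = %g within %d tries",
          i, spec$min_sep, spec$max_tries
        )
      }
    }
    img <- matrix(spec$baseline, h, w)
    kinds <- sample(c("disc", "arc", "cluster"),
                    spec$n_background, replace = TRUE)
    arc_starts <- runif(spec$n_background, 0, 2 * pi)
    for (i in seq_len(n_obj)) {
      if (labels[i] == "ring") {
        img <- img + render_ring(c(h, w), centers[i, ], radii[i],
                                 spec$sigma_r, spec$amplitude)
      } else {
        j <- i - spec$n_rings
        img <- img + render_background(
          c(h, w), kinds[j], centers[i, ], radii[i],
          amplitude = spec$bg_amplitude, sigma = spec$sigma_r,
          arc_start = arc_starts[j]
        )
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    if (spec$signal_noise > 0) {
      img <- img + matrix(rnorm(h * w, 0, 1), h, w) *
        spec$signal_noise * sqrt(pmax(img, 0))
    }
    img <- pmax(img, 0)
  })
  half <- (sides - 1) / 2
  boxes <- data.frame(
    object_id = seq_len(n_obj),
    label = labels,
    x_min = as.integer(centers[, 1L] - half),
    y_min = as.integer(centers[, 2L] - half),
    x_max = as.integer(centers[, 1L] + half),
    y_max = as.integer(centers[, 2L] + half),
    x_c = centers[, 1L], y_c = centers[, 2L],
    radius = radii, scale = radii / 15
  )
  structure(list(image = img, boxes = boxes, spec = spec),
            class = "annotated_scene")
}

#' Build query and background training patch sets from scenes
#'
#' Samples M 45 x 45 query patches centered on ring ground-truth boxes
#' (cropping the box and bilinearly resampling to 45 x 45 when its side
#' differs, so rings appear at a consistent radius of about 15 px) and N
#' background patches from confounder boxes plus empty regions. All sampling
#' is seeded; no crop crosses an image border.
#'
#' @param scenes List of [generate_scene()] results.
#' @param M Number of query (ring) patches.
#' @param N Number of background patches.
#' @param seed Sampling seed.
#' @param patch_size Output patch side (default 45).
#' @return A list with `query` and `background`, each a list of
#'   `patch_size` x `patch_size` matrices.
#' @export
make_training_sets <- function(scenes, M = 50L, N = 200L, seed = 1L,
                               patch_size = 45L) {
  if (M < 1L || N < 1L) .stop_input("M and N must be >= 1")
  ring_idx <- do.call(rbind, lapply(seq_along(scenes), function(s) {
    b <- scenes[[s]]$boxes
    b <- b[b$label == "ring", , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    cbind(scene = s, row = which(scenes[[s]]$boxes$label == "ring"))
  }))
  bg_idx <- do.call(rbind, lapply(seq_along(scenes), function(s) {
    b <- scenes[[s]]$boxes
    if (!any(b$label == "background")) return(NULL)
    cbind(scene = s, row = which(b$label == "background"))
  }))
  if (is.null(ring_idx) || nrow(ring_idx) < M) {
    .stop_input(
      "not enough annotated rings (%d) for M = %d query patches",
      if (is.null(ring_idx)) 0L else nrow(ring_idx), M
    )
  }
  crop_box <- function(scene, row) {
    b <- scene$boxes[row, ]
    crop <- scene$image[(b$x_min + 1):(b$x_max + 1),
                        (b$y_min + 1):(b$y_max + 1), drop = FALSE]
    if (nrow(crop) != patch_size || ncol(crop) != patch_size) {
      crop <- .resize_bilinear(crop, patch_size, patch_size)
    }
    crop
  }
  withr::with_seed(as.integer(seed), {
    qsel <- ring_idx[sample.int(nrow(ring_idx), M), , drop = FALSE]
    query <- lapply(seq_len(M), function(i) {
      crop_box(scenes[[qsel[i, "scene"]]], qsel[i, "row"])
    })
    background <- list()
    if (!is.null(bg_idx)) {
      n_bg_obj <- min(nrow(bg_idx), N)
      bsel <- bg_idx[sample.int(nrow(bg_idx), n_bg_obj), , drop = FALSE]
      background <- lapply(seq_len(n_bg_obj), function(i) {
        crop_box(scenes[[bsel[i, "scene"]]], bsel[i, "row"])
      })
    }
    # fill the remainder with empty-region crops away from annotated objects
    half <- (patch_size - 1) / 2
    guard <- 0L
    while (length(background) < N) {
      guard <- guard + 1L
      if (guard > 100L * N) {
        .stop_input("could not sample enough empty background regions")
      }
      s <- sample.int(length(scenes), 1L)
      scn <- scenes[[s]]
      hh <- nrow(scn$image)
      ww <- ncol(scn$image)
      cr <- round(runif(1, half, hh - 1 - half))
      cc <- round(runif(1, half, ww - 1 - half))
      dmin <- min(sqrt((scn$boxes$x_c - cr)^2 + (scn$boxes$y_c - cc)^2))
      if (dmin < patch_size) next
      background[[length(background) + 1L]] <-
        scn$image[(cr - half + 1):(cr + half + 1),
                  (cc - half + 1):(cc + half + 1), drop = FALSE]
    }
  })
  list(query = query, background = background)
}
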