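#' Dense-SIFT grid geometry
#'
#' Defines the lattice of overlapping square grids a dense SIFT descriptor is
#' computed on. Each `grid_size` x `grid_size` grid is divided into a fixed
#' 4 x 4 layout of subgrids and each subgrid contributes an 8-bin orientation
#' histogram, so the descriptor length is always 4^2 x 8 = 128.
#'
#' @param grid_size Side of a grid in pixels (default 16).
#' @param grid_step Spacing between neighboring grid origins in pixels
#'   (default 2).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(grid_size = 16L, grid_step = 2L) {
  grid_size <- as.integer(grid_size)
  grid_step <- as.integer(grid_step)
  subgrid_layout <- 4L
  n_orientations <- 8L
  if (grid_size < 1L || grid_size %% subgrid_layout != 0L) {
    .stop_input("grid_size must be a positive multiple of %d", subgrid_layout)
  }
  if (grid_step < 1L) .stop_input("grid_step must be >= 1")
  structure(
    list(
      grid_size = grid_size, grid_step = grid_step,
      subgrid_layout = subgrid_layout, n_orientations = n_orientations,
      descriptor_length = subgrid_layout * subgrid_layout * n_orientations
    ),
    class = "grid_spec"
  )
}

#' Per-pixel image gradients
#'
#' Computes gradient magnitude and orientation for every pixel: central
#' differences in the interior, one-sided differences at the borders. The
#' orientation is reported in degrees in `[0, 360)`, measured from the
#' increasing-column axis towards the increasing-row axis; zero-magnitude
#' pixels report orientation 0 by convention.
#'
#' @param image Numeric intensity matrix.
#' @return A list with matrices `magnitude` and `orientation`.
#' @export
compute_gradients <- function(image) {
  validate_raster(image)
  h <- nrow(image)
  w <- ncol(image)
  gr <- matrix(0, h, w)
  gc <- matrix(0, h, w)
  if (h > 1L) {
    gr[1L, ] <- image[2L, ] - image[1L, ]
    gr[h, ] <- image[h, ] - image[h - 1L, ]
    if (h > 2L) gr[2:(h - 1L), ] <- (image[3:h, ] - image[1:(h - 2L), ]) / 2
  }
  if (w > 1L) {
    gc[, 1L] <- image[, 2L] - image[, 1L]
    gc[, w] <- image[, w] - image[, w - 1L]
    if (w > 2L) gc[, 2:(w - 1L)] <- (image[, 3:w] - image[, 1:(w - 2L)]) / 2
  }
  magnitude <- sqrt(gr^2 + gc^2)
  orientation <- (atan2(gr, gc) * 180 / pi) %% 360
  orientation[magnitude == 0] <- 0
  list(magnitude = magnitude, orientation = orientation)
}

# Split each pixel's gradient magnitude between its two nearest orientation
# bins (centers at 0, 45, ..., 315 degrees) by linear interpolation on angular
# distance; returns one weight matrix per bin.
.orientation_channels <- function(gradients, n_bins = 8L) {
  bin_width <- 360 / n_bins
  pos <- gradients$orientation / bin_width
  lo <- floor(pos)
  frac <- pos - lo
  i0 <- as.integer(lo) %% n_bins           # 0-based lower bin
  i1 <- (i0 + 1L) %% n_bins
  w0 <- gradients$magnitude * (1 - frac)
  w1 <- gradients$magnitude * frac
  channels <- vector("list", n_bins)
  for (b in seq_len(n_bins) - 1L) {
    ch <- matrix(0, nrow(w0), ncol(w0))
    sel0 <- i0 == b
    sel1 <- i1 == b
    ch[sel0] <- ch[sel0] + w0[sel0]
    ch[sel1] <- ch[sel1] + w1[sel1]
    channels[[b + 1L]] <- ch
  }
  channels
}

# Zero-padded 2-D cumulative sum, so that box sums over pixel ranges
# [p..q] x [u..v] (1-based) are ii[q+1, v+1] - ii[p, v+1] - ii[q+1, u] + ii[p, u].
.integral_image <- function(m) {
  ii <- apply(m, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  rbind(0, cbind(0, ii))
}

#' Extract one SIFT descriptor from a grid
#'
#' Computes the 128-dimensional SIFT descriptor of the grid whose top-left
#' corner is at `grid_origin` (0-based row, col). Subgrid histograms are
#' concatenated in row-major subgrid order with bins in increasing angle, and
#' the descriptor is L2-normalized (an all-zero descriptor stays zero).
#'
#' @param image Numeric intensity matrix.
#' @param grid_origin Integer (row, col) of the grid's top-left pixel, 0-based.
#' @param spec A [grid_spec()].
#' @param normalize L2-normalize the descriptor (default `TRUE`).
#' @return A list with `descriptor` (length 128) and `location`, the grid's
#'   center pixel `(row, col)` = origin + grid_size/2 - 0.5, rounded down.
#' @export
extract_descriptor <- function(image, grid_origin, spec = grid_spec(),
                               normalize = TRUE) {
  validate_raster(image)
  gs <- spec$grid_size
  r0 <- as.integer(grid_origin[1L])
  c0 <- as.integer(grid_origin[2L])
  if (r0 < 0L || c0 < 0L || r0 + gs > nrow(image) || c0 + gs > ncol(image)) {
    .stop_input("grid at (%d, %d) extends past the image border", r0, c0)
  }
  grads <- compute_gradients(image)
  channels <- .orientation_channels(grads, spec$n_orientations)
  sub <- gs %/% spec$subgrid_layout
  desc <- numeric(spec$descriptor_length)
  i <- 0L
  for (a in seq_len(spec$subgrid_layout) - 1L) {
    for (b in seq_len(spec$subgrid_layout) - 1L) {
      rows <- (r0 + a * sub + 1L):(r0 + a * sub + sub)
      cols <- (c0 + b * sub + 1L):(c0 + b * sub + sub)
      for (j in seq_len(spec$n_orientations)) {
        i <- i + 1L
        desc[i] <- sum(channels[[j]][rows, cols])
      }
    }
  }
  if (normalize) {
    nrm <- sqrt(sum(desc^2))
    if (nrm > 0) desc <- desc / nrm
  }
  list(
    descriptor = desc,
    location = c(floor(r0 + gs / 2 - 0.5), floor(c0 + gs / 2 - 0.5))
  )
}

#' Extract dense SIFT features from an image
#'
#' Places grids at every origin in `{0, grid_step, 2*grid_step, ...}` along
#' each axis such that the grid lies fully inside the image, and computes one
#' L2-normalized 128-dimensional descriptor per grid. Features are ordered
#' row-major by grid origin.
#'
#' @inheritParams extract_descriptor
#' @return An object of class `sift_features`: a list with `descriptors`
#'   (n x 128 matrix), `locations` (n x 2 matrix of 0-based grid-center
#'   (row, col) pairs) and the `spec` used.
#' @export
extract_dense <- function(image, spec = grid_spec(), normalize = TRUE) {
  validate_raster(image)
  gs <- spec$grid_size
  h <- nrow(image)
  w <- ncol(image)
  if (h < gs || w < gs) {
    warning("image smaller than one grid; no features extracted")
    return(.sift_features(
      matrix(0, 0L, spec$descriptor_length), matrix(0L, 0L, 2L), spec
    ))
  }
  r0s <- seq.int(0L, h - gs, by = spec$grid_step)
  c0s <- seq.int(0L, w - gs, by = spec$grid_step)
  # row-major ordering: column origin varies fastest
  origins <- cbind(
    rep(r0s, each = length(c0s)),
    rep(c0s, times = length(r0s))
  )
  grads <- compute_gradients(image)
  channels <- .orientation_channels(grads, spec$n_orientations)
  iis <- lapply(channels, .integral_image)
  sub <- gs %/% spec$subgrid_layout
  n <- nrow(origins)
  desc <- matrix(0, n, spec$descriptor_length)
  col_i <- 0L
  for (a in seq_len(spec$subgrid_layout) - 1L) {
    for (b in seq_len(spec$subgrid_layout) - 1L) {
      p <- origins[, 1L] + a * sub + 1L
      q <- p + sub - 1L
      u <- origins[, 2L] + b * sub + 1L
      v <- u + sub - 1L
      for (j in seq_len(spec$n_orientations)) {
        col_i <- col_i + 1L
        ii <- iis[[j]]
        desc[, col_i] <- ii[cbind(q + 1L, v + 1L)] - ii[cbind(p, v + 1L)] -
          ii[cbind(q + 1L, u)] + ii[cbind(p, u)]
      }
    }
  }
  if (normalize) {
    nrm <- sqrt(rowSums(desc^2))
    nz <- nrm > 0
    desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  }
  centers <- cbind(
    floor(origins[, 1L] + gs / 2 - 0.5),
    floor(origins[, 2L] + gs / 2 - 0.5)
  )
  .sift_features(desc, centers, spec)
}

.sift_features <- function(descriptors, locations, spec, words = NULL) {
  structure(
    list(
      descriptors = descriptors,
      locations = locations,
      spec = spec,
      words = words
    ),
    class = "sift_features"
  )
}

#' @export
print.sift_features <- function(x, ...) {
  cat(sprintf(
    "<sift_features: %d descriptors of length %d%s>\n",
    nrow(x$descriptors), ncol(x$descriptors),
    if (is.null(x$words)) "" else ", word-assigned"
  ))
  invisible(x)
}
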