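test_that("rendered rings follow the Gaussian annulus closed form", {
  shape <- c(101, 101)
  ctr <- c(50, 50)
  f <- render_ring(shape, ctr, radius = 15, sigma_r = 2, amplitude = 0.8)
  # peak value A on the radius-R circle
  expect_equal(f[51, 66], 0.8, tolerance = 1e-9)   # (50, 65): r = 15 exactly
  # essentially zero at the center for R >> sigma_r
  expect_lt(f[51, 51], 0.8 * exp(-15^2 / (2 * 4)) + 1e-12)
  # closed form at sampled pixels
  for (px in list(c(50, 60), c(42, 47), c(60, 61))) {
    r <- sqrt(sum((px - ctr)^2))
    expect_equal(f[px[1] + 1, px[2] + 1],
                 0.8 * exp(-(r - 15)^2 / (2 * 4)), tolerance = 1e-9)
  }
  expect_error(render_ring(shape, c(5, 50), 15), "fit inside")
  expect_error(render_ring(shape, ctr, radius = 3, sigma_r = 2), "exceed")
})

test_that("background confounders are bright but non-annular", {
  shape <- c(101, 101)
  ctr <- c(50, 50)
  disc <- render_background(shape, "disc", ctr, radius = 10, amplitude = 0.9)
  expect_equal(disc[51, 51], 0.9)   # flat top at the center
  expect_equal(disc[51, 56], 0.9)   # still inside the plateau

  arc <- render_background(shape, "arc", ctr, radius = 12, amplitude = 1,
                           arc_start = 0, arc_half = pi / 3)
  # on-circle pixel inside the angular window is bright ...
  expect_equal(arc[51, 63], 1, tolerance = 1e-9)
  # ... and at least half of the circle stays at background level
  angles <- seq(0, 2 * pi, length.out = 360)
  on_circle <- vapply(angles, function(a) {
    arc[round(50 + 12 * sin(a)) + 1, round(50 + 12 * cos(a)) + 1]
  }, numeric(1))
  expect_gte(mean(on_circle < 1e-6), 0.5)

  cl <- render_background(shape, "cluster", ctr, radius = 12, amplitude = 1)
  expect_gt(max(cl), 0.99)
  expect_lt(cl[51, 51], 1)  # blobs sit away from the center

  expect_error(render_background(shape, "worm", ctr, 10), "unknown")
})

test_that("scene generation is seeded, annotated and exactly composable", {
  spec <- scene_spec(size = c(256L, 256L), n_rings = 4L, n_background = 3L,
                     min_sep = 55, seed = 5L)
  sc <- generate_scene(spec)
  expect_identical(sum(sc$boxes$label == "ring"), 4L)
  expect_identical(sum(sc$boxes$label == "background"), 3L)
  expect_true(all(sc$boxes$x_min >= 0 & sc$boxes$x_max <= 255))
  # one box per object, enclosing its support (odd side, tied to radius)
  side <- sc$boxes$x_max - sc$boxes$x_min + 1
  expect_true(all(side %% 2 == 1))
  expect_equal(side, 2 * round((45 * sc$boxes$radius / 15 - 1) / 2) + 1)

  sc2 <- generate_scene(spec)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$boxes, sc2$boxes)

  # zero noise: the image equals the analytic object sum plus baseline
  spec0 <- scene_spec(size = c(256L, 256L), n_rings = 2L, n_background = 1L,
                      min_sep = 70, noise_sd = 0, seed = 8L)
  sc0 <- generate_scene(spec0)
  manual <- matrix(spec0$baseline, 256, 256)
  for (i in seq_len(nrow(sc0$boxes))) {
    b <- sc0$boxes[i, ]
    if (b$label == "ring") {
      manual <- manual + render_ring(c(256, 256), c(b$x_c, b$y_c), b$radius,
                                     spec0$sigma_r, spec0$amplitude)
    }
  }
  ring_px <- sc0$boxes$label[1] == "ring"
  b1 <- sc0$boxes[1, ]
  w <- 3  # compare a small window centered on the first ring
  expect_equal(
    sc0$image[(b1$x_c - w):(b1$x_c + w) + 1, (b1$y_c - w):(b1$y_c + w) + 1],
    manual[(b1$x_c - w):(b1$x_c + w) + 1, (b1$y_c - w):(b1$y_c + w) + 1],
    tolerance = 1e-12
  )

  # infeasible placement fails with an informative error
  tight <- scene_spec(size = c(128L, 128L), n_rings = 20L, min_sep = 80,
                      max_tries = 50L, seed = 1L)
  expect_error(generate_scene(tight), "min_sep")
})

test_that("training-set construction yields exact counts of in-bounds patches", {
  scenes <- lapply(1:4, function(i) generate_scene(small_scene_spec(seed = i)))
  sets <- make_training_sets(scenes, M = 10, N = 25, seed = 2)
  expect_length(sets$query, 10)
  expect_length(sets$background, 25)
  expect_true(all(vapply(c(sets$query, sets$background),
                         function(p) all(dim(p) == c(45, 45)), logical(1))))
  expect_error(make_training_sets(scenes, M = 0, N = 5), "M and N")
  expect_error(make_training_sets(scenes, M = 100, N = 5), "not enough")

  # determinism
  sets2 <- make_training_sets(scenes, M = 10, N = 25, seed = 2)
  expect_identical(sets$query, sets2$query)
  expect_identical(sets$background, sets2$background)
})

test_that("voting localizes planted rings at the high-SNR preset", {
  # localization-only planted-object recovery across seeds
  hits <- 0
  total <- 0
  for (seed in 1:5) {
    fit <- small_detector(seed = seed, n_scenes = 3)
    probe <- generate_scene(small_scene_spec(seed = seed * 100L + 9L))
    vm <- localize(probe$image, fit$detector$queries,
                   fit$detector$dictionary, fit$detector$weights,
                   scales = fit$config$scales)
    peaks <- normalize_and_threshold(vm, gamma = 0.2)
    rings <- probe$boxes[probe$boxes$label == "ring", ]
    for (i in seq_len(nrow(rings))) {
      total <- total + 1
      dd <- sqrt((peaks$x_o - rings$x_c[i])^2 + (peaks$y_o - rings$y_c[i])^2)
      if (length(dd) > 0 && min(dd) <= 5) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("raising the noise level does not improve end-to-end F1", {
  # compare the high-SNR preset against a noise level of the same order as
  # the ring amplitude, where degradation dominates the seed-to-seed
  # variance of these small scenes
  f1_at <- function(noise_sd) {
    f1s <- numeric(5)
    for (seed in 1:5) {
      fit <- small_detector(seed = seed, n_scenes = 3, noise_sd = noise_sd)
      counts <- list(n_tp = 0, n_fp = 0, n_fn = 0)
      for (p in 7:8) {
        probe <- generate_scene(small_scene_spec(seed = seed * 100L + p,
                                                 noise_sd = noise_sd))
        res <- detect_image(probe$image, fit$detector)
        gt <- probe$boxes[probe$boxes$label == "ring", ]
        pos <- res$detections[res$detections$label == "endosome", ,
                              drop = FALSE]
        m <- match_detections(pos, gt)
        counts <- Map(`+`, counts, m[c("n_tp", "n_fp", "n_fn")])
      }
      f1s[seed] <- precision_recall_f1(counts)[["f1"]]
    }
    mean(f1s)
  }
  expect_lte(f1_at(0.9), f1_at(0.05) + 1e-9)
})
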