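test_that("LLC codes solve the sum-to-one constrained least squares", {
  words <- fix_descriptors(20, dim = 16, seed = 1)
  dict <- fix_dictionary(words)

  # a feature equal to a word recovers the indicator solution
  code <- llc_encode(words[4, ], dict, C = 5)
  expect_true(4L %in% code$base_indices)
  expect_gte(code$coefficients[which(code$base_indices == 4L)], 0.999)
  expect_equal(sum(code$coefficients), 1, tolerance = 1e-9)

  # C = 1: the constraint forces coefficient 1 on the nearest word
  f <- fix_descriptors(1, dim = 16, seed = 2)[1, ]
  c1 <- llc_encode(f, dict, C = 1)
  expect_identical(c1$base_indices, oracle_vq(matrix(f, 1), words))
  expect_equal(c1$coefficients, 1)

  # C = 2 matches a dense 1-D grid search over (c, 1 - c)
  for (seed in 3:6) {
    f <- fix_descriptors(1, dim = 16, seed = seed)[1, ]
    c2 <- llc_encode(f, dict, C = 2)
    ref <- oracle_llc_c2(f, words[c2$base_indices, ])
    expect_equal(c2$coefficients, ref, tolerance = 1e-3)
  }

  expect_error(llc_encode(f, dict, C = 21), "between 1 and K")
})

test_that("LLC coefficients sum to one across many random features", {
  words <- fix_descriptors(30, dim = 16, seed = 7)
  dict <- fix_dictionary(words)
  feats <- fix_descriptors(300, dim = 16, seed = 8)
  enc <- endovote:::.llc_encode_all(feats, dict, C = 5)
  expect_true(all(abs(rowSums(enc$coefs) - 1) < 1e-9))
  # batch path agrees with the single-feature path
  for (i in c(1, 150, 300)) {
    one <- llc_encode(feats[i, ], dict, C = 5)
    expect_identical(enc$bases[i, ], one$base_indices)
    expect_equal(enc$coefs[i, ], one$coefficients, tolerance = 1e-12)
  }
})

test_that("max-pooling scatters codes and L2-normalizes", {
  code <- structure(list(base_indices = c(3L, 7L, 1L),
                         coefficients = c(0.5, 0.3, 0.2)), class = "llc_code")
  p <- pool_codes(list(code), K = 10)
  expect_equal(which(p > 0), c(1L, 3L, 7L))
  expect_equal(sqrt(sum(p^2)), 1, tolerance = 1e-12)

  code2 <- structure(list(base_indices = c(2L, 9L),
                          coefficients = c(0.9, 0.1)), class = "llc_code")
  p2 <- pool_codes(list(code, code2), K = 10)
  raw <- numeric(10)
  raw[c(1, 3, 7)] <- c(0.2, 0.5, 0.3)
  raw[c(2, 9)] <- pmax(raw[c(2, 9)], c(0.9, 0.1))
  expect_equal(p2, raw / sqrt(sum(raw^2)), tolerance = 1e-12)
  expect_error(pool_codes(list(), 10), "no LLC codes")

  # many codes: equals the naive scatter-then-columnwise-max loop
  words <- fix_descriptors(25, dim = 16, seed = 9)
  dict <- fix_dictionary(words)
  feats <- fix_descriptors(225, dim = 16, seed = 10)
  codes <- lapply(seq_len(225), function(i) llc_encode(feats[i, ], dict, 5))
  p <- pool_codes(codes, K = 25)
  mat <- matrix(0, 225, 25)
  for (i in seq_len(225)) {
    mat[i, codes[[i]]$base_indices] <- codes[[i]]$coefficients
  }
  ref <- apply(mat, 2, max)
  ref <- pmax(ref, 0)
  expect_equal(p, ref / sqrt(sum(ref^2)), tolerance = 1e-12)
})

test_that("the SVM identifier separates toy classes deterministically", {
  withr::with_seed(11, {
    xpos <- matrix(rnorm(20 * 8, mean = 1), 20, 8)
    xneg <- matrix(rnorm(25 * 8, mean = -1), 25, 8)
  })
  m <- train_identifier(xpos, xneg, dictionary = NULL, descriptors = TRUE,
                        seed = 4)
  expect_true(m$chosen_C %in% 2^(-8:8))
  expect_true(all(svm_score(m, xpos) > 0))
  expect_true(all(svm_score(m, xneg) < 0))

  # flipping the classes negates the decision values
  mf <- train_identifier(xneg, xpos, dictionary = NULL, descriptors = TRUE,
                         seed = 4)
  expect_equal(svm_score(mf, rbind(xpos, xneg)),
               -svm_score(m, rbind(xpos, xneg)), tolerance = 1e-2)

  expect_error(
    train_identifier(xpos, xneg[0, , drop = FALSE], NULL,
                     descriptors = TRUE),
    "both positive and negative"
  )
})

test_that("voting-map thresholding retains strictly-above-gamma pixels", {
  expect_identical(nrow(normalize_and_threshold(matrix(0, 5, 5))), 0L)
  expect_identical(nrow(normalize_and_threshold(matrix(3.7, 5, 5))), 0L)

  m <- matrix(0, 6, 6)
  m[3, 5] <- 4
  out <- normalize_and_threshold(m, gamma = 0.2)
  expect_identical(nrow(out), 1L)
  expect_equal(out$x_o, 2)
  expect_equal(out$y_o, 4)
  expect_equal(out$value, 1)

  r <- fix_image(7, 7, seed = 12)
  out <- normalize_and_threshold(r, gamma = 0)
  expect_identical(nrow(out), sum(r > min(r)))

  expect_error(normalize_and_threshold(m, gamma = 1.5), "\\[0, 1\\]")
})

test_that("candidate boxes follow the ceiling/floor corner formulas", {
  b <- build_candidate(100, 100, 1, w = 45, h = 45)
  expect_equal(unlist(b[1, 1:4]),
               c(x_min = 78, y_min = 78, x_max = 122, y_max = 122))
  b <- build_candidate(100, 100, 0.5, w = 45, h = 45)
  expect_equal(unlist(b[1, 1:4]),
               c(x_min = 89, y_min = 89, x_max = 111, y_max = 111))

  withr::with_seed(13, {
    xo <- sample(20:200, 50, replace = TRUE)
    yo <- sample(20:200, 50, replace = TRUE)
    s <- runif(50, 0.5, 1.5)
  })
  b <- build_candidate(xo, yo, s, w = 45, h = 45)
  expect_equal(b$x_min, ceiling(xo - s * 45 / 2))
  expect_equal(b$y_max, floor(yo + s * 45 / 2))
  # width bounds before clipping
  expect_true(all(b$x_max - b$x_min >= floor(s * 45) - 1))
  expect_true(all(b$x_max - b$x_min <= ceiling(s * 45)))
  expect_error(build_candidate(10, 10, 0), "positive")

  clipped <- build_candidate(5, 5, 1, image_shape = c(50, 50))
  expect_equal(clipped$x_min, 0)
})

test_that("non-maximum suppression matches the quadratic greedy reference", {
  one <- data.frame(x_min = 0, y_min = 0, x_max = 9, y_max = 9,
                    x_o = 4, y_o = 4, value = 1)
  expect_identical(nrow(nms(one)), 1L)

  two <- rbind(one, one)
  two$value <- c(0.9, 0.4)
  kept <- nms(two)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$value, 0.9)

  for (seed in 14:16) {
    withr::with_seed(seed, {
      n <- 20
      xo <- sample(10:90, n, replace = TRUE)
      yo <- sample(10:90, n, replace = TRUE)
      side <- sample(8:30, n, replace = TRUE)
      cand <- data.frame(
        x_min = xo - side %/% 2, y_min = yo - side %/% 2,
        x_max = xo + side %/% 2, y_max = yo + side %/% 2,
        x_o = xo, y_o = yo, value = round(runif(n), 3)
      )
    })
    got <- nms(cand)
    ref <- oracle_nms(cand)
    expect_equal(got[, names(ref)], ref, ignore_attr = TRUE)
    # invariants: subset of input, top candidate kept, pairwise non-suppressing
    expect_lte(nrow(got), nrow(cand))
    expect_equal(got$value[1], max(cand$value))
    if (nrow(got) > 1) {
      for (i in seq_len(nrow(got) - 1)) {
        for (j in (i + 1):nrow(got)) {
          a <- unlist(got[i, c("x_min", "y_min", "x_max", "y_max")])
          b <- unlist(got[j, c("x_min", "y_min", "x_max", "y_max")])
          expect_lte(oracle_iou(a, b), 0.5)
          inside <- (got$x_o[j] >= a[1] && got$x_o[j] <= a[3] &&
                     got$y_o[j] >= a[2] && got$y_o[j] <= a[4]) ||
                    (got$x_o[i] >= b[1] && got$x_o[i] <= b[3] &&
                     got$y_o[i] >= b[2] && got$y_o[i] <= b[4])
          expect_false(inside)
        }
      }
    }
  }
})

test_that("candidate classification is a linear function of the encoding", {
  fit <- small_detector(seed = 3, n_scenes = 2)
  scene <- fit$scenes[[1]]
  gt <- scene$boxes[scene$boxes$label == "ring", ][1, ]
  cand <- data.frame(
    x_min = gt$x_min, y_min = gt$y_min, x_max = gt$x_max, y_max = gt$y_max,
    x_o = gt$x_c, y_o = gt$y_c, s_star = gt$scale, value = 1
  )
  det <- classify_candidates(scene$image, cand, fit$detector$dictionary,
                             fit$detector$svm)
  expect_identical(det$label, "endosome")

  # shifting the bias shifts all scores by that constant
  model2 <- fit$detector$svm
  model2$b <- model2$b + 0.7
  det2 <- classify_candidates(scene$image, cand, fit$detector$dictionary,
                              model2)
  expect_equal(det2$score, det$score + 0.7, tolerance = 1e-9)
})
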