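test_that("box overlap follows the inclusive-pixel IoU definition", {
  a <- c(0, 0, 9, 9)
  expect_equal(overlap_alpha0(a, a), 1)
  expect_equal(overlap_alpha0(a, c(20, 20, 29, 29)), 0)
  # 10x10 boxes offset by 5 columns: intersection 50, union 150
  expect_equal(overlap_alpha0(a, c(0, 5, 9, 14)), 1 / 3)
  expect_equal(overlap_alpha0(c(0, 5, 9, 14), a), 1 / 3)  # symmetric
  expect_error(overlap_alpha0(c(5, 0, 2, 9), a), "degenerate")
})

test_that("detection matching is greedy, one-to-one and above-half overlap", {
  gt <- data.frame(x_min = 10, y_min = 10, x_max = 54, y_max = 54)
  exact <- data.frame(x_min = 10, y_min = 10, x_max = 54, y_max = 54,
                      score = 1)
  m <- match_detections(exact, gt)
  expect_identical(c(m$n_tp, m$n_fp, m$n_fn), c(1L, 0L, 0L))

  # overlap 0.4 does not count as correct
  shifted <- data.frame(x_min = 10, y_min = 29, x_max = 54, y_max = 73,
                        score = 1)
  a0 <- overlap_alpha0(unlist(shifted[1, 1:4]), unlist(gt[1, 1:4]))
  expect_lt(a0, 0.5)
  expect_gt(a0, 0.3)
  m <- match_detections(shifted, gt)
  expect_identical(c(m$n_tp, m$n_fp, m$n_fn), c(0L, 1L, 1L))

  # two detections on one target: one TP, one FP
  dup <- rbind(exact, within(exact, score <- 0.5))
  m <- match_detections(dup, gt)
  expect_identical(c(m$n_tp, m$n_fp, m$n_fn), c(1L, 1L, 0L))
})

test_that("greedy matching attains the exhaustive-search TP count on small cases", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      ng <- sample(1:4, 1)
      nd <- sample(1:4, 1)
      mk <- function(n) {
        x <- sample(0:40, n, replace = TRUE)
        y <- sample(0:40, n, replace = TRUE)
        s <- sample(10:30, n, replace = TRUE)
        data.frame(x_min = x, y_min = y, x_max = x + s, y_max = y + s)
      }
      gt <- mk(ng)
      det <- mk(nd)
      det$score <- runif(nd)
    })
    m <- match_detections(det, gt)
    expect_identical(m$n_tp + m$n_fn, nrow(gt))
    expect_identical(m$n_tp + m$n_fp, nrow(det))
    # order invariance: permuting detection rows changes nothing
    perm <- withr::with_seed(seed + 50, sample(nrow(det)))
    m2 <- match_detections(det[perm, , drop = FALSE], gt)
    expect_identical(m2$n_tp, m$n_tp)
    # greedy equals the best assignment for these geometries
    expect_identical(m$n_tp, as.integer(oracle_best_assignment_tp(det, gt)))
  }
})

test_that("precision, recall and F1 follow their closed forms", {
  expect_equal(
    precision_recall_f1(list(n_tp = 1, n_fp = 0, n_fn = 0)),
    c(precision = 1, recall = 1, f1 = 1)
  )
  expect_equal(
    precision_recall_f1(list(n_tp = 0, n_fp = 3, n_fn = 2)),
    c(precision = 0, recall = 0, f1 = 0)
  )
  got <- precision_recall_f1(list(n_tp = 3, n_fp = 1, n_fn = 2))
  expect_equal(got[["precision"]], 0.75)
  expect_equal(got[["recall"]], 0.6)
  expect_equal(got[["f1"]], 2 * 0.75 * 0.6 / 1.35)
  # harmonic mean bound
  expect_lte(got[["f1"]], 2 * min(got[["precision"]], got[["recall"]]))
})

test_that("the MR-FPPI curve sweeps the distinct score thresholds", {
  gt <- data.frame(
    image_id = c("a", "a", "b"),
    x_min = c(0, 100, 0), y_min = c(0, 100, 0),
    x_max = c(44, 144, 44), y_max = c(44, 144, 44)
  )
  # perfect detector: every target hit, no false positives
  det <- gt
  det$score <- c(0.9, 0.8, 0.7)
  curve <- mr_fppi_curve(det, gt, n_images = 2)
  expect_equal(curve$mr[nrow(curve)], 0)
  expect_equal(curve$fppi[nrow(curve)], 0)
  expect_true(all(diff(curve$mr) <= 0))

  # no detections at all
  empty <- det[0, ]
  curve0 <- mr_fppi_curve(empty, gt, n_images = 2)
  expect_equal(nrow(curve0), 1L)
  expect_equal(curve0$mr, 1)
  expect_equal(curve0$fppi, 0)

  # hand-enumerated sweep: 2 TPs and 2 FPs with interleaved scores
  det2 <- rbind(
    data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 44, y_max = 44,
               score = 0.9),
    data.frame(image_id = "a", x_min = 300, y_min = 300, x_max = 344,
               y_max = 344, score = 0.6),
    data.frame(image_id = "b", x_min = 0, y_min = 0, x_max = 44, y_max = 44,
               score = 0.5),
    data.frame(image_id = "b", x_min = 300, y_min = 300, x_max = 344,
               y_max = 344, score = 0.3)
  )
  curve2 <- mr_fppi_curve(det2, gt, n_images = 2)
  expect_equal(curve2$threshold, c(0.9, 0.6, 0.5, 0.3))
  expect_equal(curve2$mr, c(2 / 3, 2 / 3, 1 / 3, 1 / 3))
  expect_equal(curve2$fppi, c(0, 0.5, 0.5, 1))

  expect_error(mr_fppi_curve(det2, gt[0, ]), "empty")
})

test_that("log-average miss rate samples nine log-spaced FPPI points", {
  flat <- data.frame(threshold = 1, fppi = 0.01, mr = 0.42)
  expect_equal(log_average_miss_rate(flat), 0.42, tolerance = 1e-12)
  expect_equal(log_average_miss_rate(flat, average = "arithmetic"), 0.42)

  perfect <- data.frame(threshold = 1, fppi = 0, mr = 0)
  expect_equal(log_average_miss_rate(perfect), 1e-10)

  # step curve: MR = 1 until FPPI = 0.1, then MR = 0.25
  step <- data.frame(threshold = c(2, 1), fppi = c(0.1, 1), mr = c(1, 0.25))
  refs <- 10^seq(-2, 0, by = 0.25)
  hand <- ifelse(refs < 0.1, 1, ifelse(refs >= 1, 0.25, 1))
  # achieved points: fppi 0.1 (mr 1) and fppi 1 (mr 0.25); refs in [0.1, 1)
  # fall back to the fppi = 0.1 point
  expect_equal(log_average_miss_rate(step), exp(mean(log(hand))))
  expect_equal(log_average_miss_rate(step, "arithmetic"), mean(hand))
})
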