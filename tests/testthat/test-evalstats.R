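ann_row <- function(slice, name, x, y, sid = "k1") {
  data.frame(series_id = sid, slice_index = slice, landmark_name = name,
             x_px = x, y_px = y, stringsAsFactors = FALSE)
}

test_that("landmark errors: exact match, fixed distances, brute-force pooled mean", {
  truth <- do.call(rbind, lapply(LANDMARK_NAMES, function(nm)
    ann_row(0, nm, 100, 100)))
  rep0 <- landmark_errors(truth, truth, spacing_cm = 0.04)
  expect_equal(rep0$pooled_mean_cm, 0)
  expect_equal(rep0$precision, 1)
  # distances 0.1, 0.3, 0.5, 0.7 cm at threshold 0.40 -> precision 0.5, mean 0.4
  truth4 <- do.call(rbind, lapply(1:4, function(k) ann_row(k, "A", 0, 0)))
  pred4 <- do.call(rbind, lapply(1:4, function(k)
    ann_row(k, "A", c(0.1, 0.3, 0.5, 0.7)[k] / 0.04, 0)))
  rep4 <- landmark_errors(pred4, truth4, spacing_cm = 0.04,
                          threshold_cm = 0.40)
  expect_equal(rep4$pooled_mean_cm, 0.4)
  expect_equal(rep4$precision, 0.5)
  # pooled mean equals a brute-force average over random pairs
  set.seed(20)
  truth_r <- do.call(rbind, lapply(0:9, function(k)
    do.call(rbind, lapply(LANDMARK_NAMES, function(nm)
      ann_row(k, nm, runif(1, 0, 500), runif(1, 0, 500))))))
  pred_r <- truth_r
  pred_r$x_px <- pred_r$x_px + rnorm(nrow(pred_r), 0, 4)
  pred_r$y_px <- pred_r$y_px + rnorm(nrow(pred_r), 0, 4)
  rep_r <- landmark_errors(pred_r, truth_r, spacing_cm = 0.04)
  brute <- mean(sqrt((pred_r$x_px - truth_r$x_px)^2 +
                       (pred_r$y_px - truth_r$y_px)^2) * 0.04)
  expect_equal(rep_r$pooled_mean_cm, brute, tolerance = 1e-12)
  expect_equal(rep_r$n_points, 70)
  # mismatched keys are an error
  expect_error(landmark_errors(pred_r[-1, ], truth_r, 0.04), "do not match")
})

test_that("precision is monotone non-decreasing in the threshold", {
  set.seed(21)
  truth <- do.call(rbind, lapply(0:19, function(k) ann_row(k, "A", 100, 100)))
  pred <- truth
  pred$x_px <- pred$x_px + rnorm(20, 0, 6)
  prec <- sapply(seq(0.05, 1, by = 0.05), function(th)
    landmark_errors(pred, truth, 0.04, threshold_cm = th)$precision)
  expect_true(all(diff(prec) >= 0))
})

test_that("paired t matches the closed form and flags degenerate input", {
  # constructed pairs: diffs {1,1,1,1} + jitter match t = mean / (sd / sqrt(n))
  set.seed(22)
  d <- c(1, 1, 1, 1, 1) + rnorm(5, 0, 0.05)
  y <- rnorm(5, 10, 2)
  x <- y + d
  res <- paired_t(x, y)
  t_closed <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_closed, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_closed), df = 4), tolerance = 1e-12)
  expect_false(res$degenerate)
  # near-zero differences -> p near 1
  y2 <- rnorm(8)
  res2 <- paired_t(y2 + rnorm(8, 0, 1e-9), y2)
  expect_gt(res2$p, 0.05)
  # exactly constant differences -> degenerate, no p
  res3 <- paired_t(y2 + 1, y2)
  expect_true(res3$degenerate)
  expect_true(is.na(res3$p))
  expect_equal(res3$mean_diff, 1)
  # invariant under adding a constant to both members of every pair
  res4 <- paired_t(x + 42, y + 42)
  expect_equal(res4$p, res$p, tolerance = 1e-12)
})

test_that("independent t matches the Welch closed form and is symmetric", {
  set.seed(23)
  a <- rnorm(10, 0, 1); b <- rnorm(12, 1, 2)
  res <- independent_t(a, b)
  se <- sqrt(var(a) / 10 + var(b) / 12)
  t_closed <- (mean(a) - mean(b)) / se
  df_closed <- se^4 / ((var(a) / 10)^2 / 9 + (var(b) / 12)^2 / 11)
  expect_equal(res$t, t_closed, tolerance = 1e-12)
  expect_equal(res$df, df_closed, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(t_closed), df_closed), tolerance = 1e-12)
  # swapped arguments give the same p
  expect_equal(independent_t(b, a)$p, res$p, tolerance = 1e-12)
  # identical groups -> t = 0, p = 1
  res_id <- independent_t(a, a)
  expect_equal(res_id$t, 0)
  expect_equal(res_id$p, 1)
  # pooled form matches the classic statistic
  resp <- independent_t(a, b, pooled = TRUE)
  sp2 <- (9 * var(a) + 11 * var(b)) / 20
  expect_equal(resp$t, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 10 + 1 / 12)),
               tolerance = 1e-12)
  # distinguishes the paired formula: same data, different statistic
  expect_false(isTRUE(all.equal(res$t, paired_t(a, b[1:10])$t)))
})

test_that("Bland-Altman limits, outliers and perfect agreement", {
  x <- c(5, 6, 7, 8)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(unname(ba0$limits), c(0, 0))
  expect_length(ba0$outlier_indices, 0)
  # one extreme difference among many zeros: direct mean/sd computation
  # flags exactly that index (with n = 13, |10 - mean| > 1.96 sd)
  truth <- rep(0, 13)
  pred <- c(rep(0, 12), 10)
  d <- pred - truth
  ba <- bland_altman(pred, truth)
  expect_equal(ba$mean_difference, mean(d))
  expect_equal(ba$sd_difference, sd(d))
  expect_equal(unname(ba$limits),
               mean(d) + c(-1.96, 1.96) * sd(d))
  expect_identical(ba$outlier_indices,
                   which(abs(d - mean(d)) > 1.96 * sd(d)))
  expect_equal(ba$outlier_indices, 13L)
})

test_that("compare_models orders a perfect stage above a noisy one", {
  set.seed(24)
  truth <- do.call(rbind, lapply(0:9, function(k)
    do.call(rbind, lapply(LANDMARK_NAMES, function(nm)
      ann_row(k, nm, runif(1, 100, 400), runif(1, 100, 400))))))
  aligner <- truth
  aligner$x_px <- aligner$x_px + rnorm(70, 0, 8)
  aligner$y_px <- aligner$y_px + rnorm(70, 0, 8)
  tab <- compare_models(aligner, truth, truth, spacing_cm = 0.04)
  expect_equal(tab$stage, c("aligner", "two_stage"))
  expect_lt(tab$mean_distance_cm[2], tab$mean_distance_cm[1])
  expect_gte(tab$precision[2], tab$precision[1])
  expect_lt(attr(tab, "p_value"), 0.001)
  # rows equal a per-report recomputation
  ea <- landmark_errors(aligner, truth, 0.04)
  expect_equal(tab$mean_distance_cm[1], ea$pooled_mean_cm)
  expect_equal(tab$precision[1], ea$precision)
  # identical prediction sets -> degenerate paired test
  tab_id <- compare_models(aligner, aligner, truth, spacing_cm = 0.04)
  expect_true(is.na(attr(tab_id, "p_value")))
})
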