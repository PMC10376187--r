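tiny_cfg <- function(n_out = 3L) {
  cfg <- net_config(12, n_out, seed = 5)
  cfg$stem_ch <- 2L
  cfg$stage_ch <- c(2L, 3L)
  cfg
}

cfg_list <- function(cfg) list(stem_ch = cfg$stem_ch, stage_ch = cfg$stage_ch,
                               n_out = cfg$n_out)

test_that("backbone outputs have the right arity and are finite on a zero image", {
  for (n_out in c(14L, 2L)) {
    cfg <- tiny_cfg(n_out)
    params <- init_weights(cfg)
    x <- array(0, dim = c(12, 12, 1))
    fw <- patellometry:::cpp_net_forward(params, cfg_list(cfg), x)
    expect_equal(ncol(fw$out), n_out)
    expect_true(all(is.finite(fw$out)))
    # multi-stage supervision: pooled features from every stage
    expect_equal(ncol(fw$feats), sum(cfg$stage_ch))
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  cl <- cfg_list(cfg)
  set.seed(7)
  info <- patellometry:::cpp_param_info(cl)
  params <- rnorm(info$n_params, 0, 0.3)
  x <- array(runif(12 * 12 * 2), dim = c(12, 12, 2))
  y <- matrix(runif(6), 2, 3)
  g <- patellometry:::cpp_net_grad_mse(params, cl, x, y)
  idx <- sort(sample(info$n_params, 60))
  eps <- 1e-5
  for (i in idx) {
    p1 <- params; p1[i] <- p1[i] + eps
    p2 <- params; p2[i] <- p2[i] - eps
    num <- (patellometry:::cpp_net_grad_mse(p1, cl, x, y)$loss -
              patellometry:::cpp_net_grad_mse(p2, cl, x, y)$loss) / (2 * eps)
    expect_equal(g$grad[i], num, tolerance = 1e-6)
  }
})

test_that("training descends, follows the lr schedule, and memorizes one sample", {
  set.seed(8)
  # learnable toy task: target is the mean intensity of each image half
  N <- 40
  x <- array(runif(12 * 12 * N), dim = c(12, 12, N))
  y <- cbind(apply(x[, 1:6, , drop = FALSE], 3, mean),
             apply(x[, 7:12, , drop = FALSE], 3, mean))
  cfg <- tiny_cfg(2L)
  cfg$epochs <- 12L
  model <- train_regressor(x, y, cfg)
  expect_lt(model$log$loss[12], model$log$loss[1])
  # exponential schedule: lr_k = lr * 0.95^(k-1)
  expect_equal(model$log$lr, 0.001 * 0.95^(0:11), tolerance = 1e-12)
  # single-sample memorization drives the loss toward zero
  cfg1 <- tiny_cfg(2L)
  cfg1$epochs <- 80L
  m1 <- train_regressor(x[, , 1, drop = FALSE], y[1, , drop = FALSE], cfg1)
  expect_lt(m1$log$loss[80], 1e-4)
  # empty dataset is rejected
  expect_error(train_regressor(array(0, c(12, 12, 0)),
                               matrix(0, 0, 2), cfg), "empty")
})

test_that("fixed seeds reproduce identical training logs", {
  set.seed(9)
  x <- array(runif(12 * 12 * 10), dim = c(12, 12, 10))
  y <- matrix(runif(20), 10, 2)
  cfg <- tiny_cfg(2L); cfg$epochs <- 4L
  m1 <- train_regressor(x, y, cfg)
  m2 <- train_regressor(x, y, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("NT-Xent matches the brute-force pairwise softmax oracle", {
  set.seed(30)
  z <- matrix(rnorm(4 * 8), 4, 8)
  pairs <- c(2L, 1L, 4L, 3L)
  res <- nt_xent(z, pairs, temperature = 0.5)
  zn <- z / sqrt(rowSums(z^2))
  s <- zn %*% t(zn) / 0.5
  brute <- mean(sapply(1:4, function(i)
    -log(exp(s[i, pairs[i]]) / sum(exp(s[i, -i])))))
  expect_equal(res$loss, brute, tolerance = 1e-9)
  # aligned positives with antipodal negatives attain the minimal loss
  # for a batch of 4 (positive similarity 1, every negative similarity -1)
  z_id <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  l_id <- nt_xent(z_id, pairs, temperature = 0.5)$loss
  expect_equal(l_id, -log(exp(2) / (exp(2) + 2 * exp(-2))),
               tolerance = 1e-12)
  set.seed(31)
  worse <- replicate(50, nt_xent(matrix(rnorm(8), 4, 2), pairs, 0.5)$loss)
  expect_true(all(l_id <= worse + 1e-9))
  # random high-dimensional embeddings: loss near log(2N - 2)
  set.seed(32)
  zr <- matrix(rnorm(16 * 256), 16, 256)
  pr <- as.vector(rbind(seq(2, 16, 2), seq(1, 16, 2)))
  expect_equal(nt_xent(zr, pr, temperature = 1)$loss, log(14),
               tolerance = 0.15)
  expect_error(nt_xent(z[1:2, ], c(2L, 1L), 0.5), "batch")
})

test_that("NT-Xent analytic gradient matches finite differences", {
  set.seed(33)
  z <- matrix(rnorm(6 * 4), 6, 4)
  pairs <- c(2L, 1L, 4L, 3L, 6L, 5L)
  g <- nt_xent(z, pairs, temperature = 0.3, grad = TRUE)$grad
  eps <- 1e-6
  for (i in 1:6) for (j in 1:4) {
    z1 <- z; z1[i, j] <- z1[i, j] + eps
    z2 <- z; z2[i, j] <- z2[i, j] - eps
    num <- (nt_xent(z1, pairs, 0.3)$loss - nt_xent(z2, pairs, 0.3)$loss) /
      (2 * eps)
    expect_equal(g[i, j], num, tolerance = 1e-6)
  }
})

test_that("contrastive pretraining produces finite losses and usable weights", {
  set.seed(34)
  x <- array(runif(36 * 36 * 12), dim = c(36, 36, 12))
  cfg <- net_config(36, 2, epochs = 2L, batch_size = 6L, seed = 3)
  ssl <- simclr_pretrain(x, cfg)
  expect_s3_class(ssl, "simclr_weights")
  expect_true(all(is.finite(ssl$log$loss)))
  expect_true(all(is.finite(ssl$params)))
  # pretrained weights differ from the raw initialization
  expect_false(isTRUE(all.equal(ssl$params, init_weights(cfg))))
  # they can seed a supervised run (head re-initialized)
  cfg2 <- net_config(36, 2, epochs = 1L, seed = 3, init = ssl$params)
  y <- matrix(runif(24), 12, 2)
  m <- train_regressor(x, y, cfg2)
  expect_true(is.finite(m$log$loss[1]))
  expect_error(simclr_pretrain(x, net_config(36, 2, batch_size = 1L)),
               "batch_size")
})

test_that("two-stage predictor honors architecture contracts on a tiny fit", {
  series <- lapply(1:2, function(i)
    generate_phantom(small_spec(seed = 40 + i, n_slices = 3L)))
  model <- two_stage_landmarks(
    series,
    aligner_config = net_config(160, 14, epochs = 2L, seed = 1),
    patch_config = net_config(36, 2, epochs = 2L, seed = 1),
    seed = 1)
  expect_s3_class(model, "two_stage_model")
  expect_length(model$patches, 7)
  expect_named(model$patches, LANDMARK_NAMES)
  test_series <- generate_phantom(small_spec(seed = 50, n_slices = 3L))
  pa <- predict(model, test_series, stage = "aligner")
  pt2 <- predict(model, test_series, stage = "two_stage")
  expect_equal(nrow(pa), 3 * 7)
  expect_equal(nrow(pt2), 3 * 7)
  # the refined point lies within the 36 x 36 patch footprint of the
  # aligner point: lifted back to original space the displacement is
  # bounded by the patch diagonal over the crop scale
  for (k in unique(pa$slice_index)) {
    sl <- test_series$slices[[k + 1]]
    pp <- preprocess_slice(sl$image, model$preprocess)
    a160 <- map_coords(pp$transform,
                       as.matrix(pa[pa$slice_index == k, c("x_px", "y_px")]),
                       "forward")
    t160 <- map_coords(pp$transform,
                       as.matrix(pt2[pt2$slice_index == k, c("x_px", "y_px")]),
                       "forward")
    expect_true(all(sqrt(rowSums((a160 - t160)^2)) <= 36 * sqrt(2) + 1e-9))
  }
  # predictions are deterministic
  expect_identical(pt2, predict(model, test_series, stage = "two_stage"))
})
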