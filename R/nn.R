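#' Network and training configuration
#'
#' Configuration of the residual convolutional regression backbone. The
#' backbone is a stem convolution followed by residual stages; the terminal
#' activation of every stage is globally average-pooled and concatenated
#' into the flattened feature vector feeding the linear regression head (the
#' multi-stage supervision mechanism), so features extracted at each depth
#' contribute directly to the regression. \code{depth = "small"} is the
#' reduced-depth variant with the same supervision topology, sized for CPU
#' training; \code{"deep"} widens and adds a stage.
#'
#' @param input_size input image side length, pixels.
#' @param n_out number of regression outputs (14 for the aligner: 7
#'   landmarks x 2 normalized coordinates; 2 for each patch refiner).
#' @param depth \code{"small"} or \code{"deep"}.
#' @param learning_rate initial Adam learning rate (the training protocol
#'   uses 0.001, 0.0005 or 0.0001).
#' @param lr_decay multiplicative learning-rate decay per epoch.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and batch order.
#' @param init optional initial flat weight vector (e.g. from
#'   \code{\link{simclr_pretrain}} or a weight file); the head is
#'   re-initialized when the target dimension differs.
#' @return a list of class \code{net_config}.
#' @export
net_config <- function(input_size, n_out, depth = c("small", "deep"),
                       learning_rate = 0.001, lr_decay = 0.95, epochs = 20L,
                       batch_size = 32L, seed = 1L, init = NULL) {
  depth <- match.arg(depth)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  arch <- switch(depth,
                 small = list(stem_ch = 8L, stage_ch = c(8L, 16L, 32L, 64L)),
                 deep = list(stem_ch = 16L,
                             stage_ch = c(16L, 32L, 64L, 128L, 128L)))
  structure(list(input_size = as.integer(input_size),
                 n_out = as.integer(n_out), depth = depth,
                 stem_ch = arch$stem_ch, stage_ch = arch$stage_ch,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init = init),
            class = "net_config")
}

cpp_cfg <- function(config) {
  list(stem_ch = config$stem_ch, stage_ch = config$stage_ch,
       n_out = config$n_out)
}

#' Initialize backbone weights
#'
#' He-normal initialization for the convolutions, small-variance
#' initialization for the regression head with bias 0.5 so initial
#' predictions sit at the image center (targets are normalized
#' coordinates).
#'
#' @param config a \code{\link{net_config}}.
#' @return flat numeric parameter vector.
#' @export
init_weights <- function(config) {
  info <- cpp_param_info(cpp_cfg(config))
  with_seed(config$seed, {
    parts <- lapply(seq_along(info$name), function(i) {
      r <- info$nrow[i]; c <- info$ncol[i]
      nm <- info$name[i]
      if (grepl("_b$", nm)) {
        if (nm == "head_b") rep(0.5, r * c) else rep(0, r * c)
      } else if (nm == "head_W") {
        rnorm(r * c, 0, 0.01)
      } else {
        rnorm(r * c, 0, sqrt(2 / r))  # fan-in = 9 * C_in rows
      }
    })
    unlist(parts)
  })
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(params, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(params = params - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a convolutional coordinate regressor
#'
#' Minimizes mean squared error on normalized target coordinates with Adam;
#' the learning rate is multiplied by \code{lr_decay} after every epoch.
#' With a fixed seed the loss trajectory is reproducible on the same
#' machine.
#'
#' @param x training images, array of dim \code{(H, W, N)} with values in
#'   [0, 1].
#' @param y training targets, \code{N x n_out} matrix of normalized
#'   coordinates.
#' @param config a \code{\link{net_config}}.
#' @param verbose print per-epoch loss.
#' @return object of class \code{conv_regressor}: list with \code{params},
#'   \code{config} and a per-epoch training \code{log} (epoch, loss, lr).
#' @export
train_regressor <- function(x, y, config, verbose = FALSE) {
  stopifnot(length(dim(x)) == 3, is.matrix(y))
  N <- dim(x)[3]
  if (N == 0) stop("empty training dataset")
  if (nrow(y) != N || ncol(y) != config$n_out)
    stop("targets must be N x n_out")
  params <- if (!is.null(config$init)) {
    adapt_init(config$init, config)
  } else init_weights(config)
  st <- adam_state(length(params))
  lr <- config$learning_rate
  log_rows <- vector("list", config$epochs)
  cfgl <- cpp_cfg(config)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (b0 in seq(1, N, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, N)]
        g <- cpp_net_grad_mse(params, cfgl,
                              x[, , idx, drop = FALSE],
                              y[idx, , drop = FALSE])
        if (!is.finite(g$loss))
          stop("training aborted: non-finite loss at epoch ", ep)
        up <- adam_step(params, g$grad, st, lr)
        params <- up$params; st <- up$state
        losses <- c(losses, g$loss)
      }
      log_rows[[ep]] <- data.frame(epoch = ep, loss = mean(losses), lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.6f  lr %.6g", ep, mean(losses), lr))
      lr <- lr * config$lr_decay
    }
  })
  structure(list(params = params, config = config,
                 log = do.call(rbind, log_rows)),
            class = "conv_regressor")
}

# Reuse pretrained backbone weights; re-initialize the head if the output
# dimension (hence head size) differs from the pretraining net.
adapt_init <- function(init, config) {
  fresh <- init_weights(config)
  if (length(init) == length(fresh)) {
    info <- cpp_param_info(cpp_cfg(config))
    sizes <- info$nrow * info$ncol
    ends <- cumsum(sizes)
    head_idx <- which(info$name %in% c("head_W", "head_b"))
    out <- init
    for (i in head_idx)
      out[(ends[i] - sizes[i] + 1):ends[i]] <-
        fresh[(ends[i] - sizes[i] + 1):ends[i]]
    return(out)
  }
  # backbone portion (everything except head) must match
  n_back <- length(fresh) - tail_head_len(config)
  if (length(init) < n_back)
    stop("init weights incompatible with this architecture")
  out <- fresh
  out[seq_len(n_back)] <- init[seq_len(n_back)]
  out
}

tail_head_len <- function(config) {
  info <- cpp_param_info(cpp_cfg(config))
  sizes <- info$nrow * info$ncol
  sum(sizes[info$name %in% c("head_W", "head_b")])
}

#' Predict with a trained regressor
#'
#' @param object a \code{conv_regressor}.
#' @param x image array \code{(H, W, N)} or single matrix.
#' @param ... unused.
#' @return \code{N x n_out} matrix of normalized predictions.
#' @export
predict.conv_regressor <- function(object, x, ...) {
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  cpp_net_forward(object$params, cpp_cfg(object$config), x)$out
}

#' @export
print.conv_regressor <- function(x, ...) {
  cat(sprintf("conv_regressor (%s): %d -> %d outputs, %d params, %d epochs, final loss %.6f\n",
              x$config$depth, x$config$input_size, x$config$n_out,
              length(x$params), nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' Computes the SimCLR contrastive loss for a batch of 2B embeddings in
#' which row \code{i} and row \code{pairs[i]} are the two augmented views of
#' the same image. Embeddings are L2-normalized; pairwise cosine
#' similarities scaled by \code{1/temperature} enter a softmax over all
#' other rows, and the loss is the mean negative log-probability of the
#' positive pair. Optionally returns the analytic gradient with respect to
#' the unnormalized embeddings.
#'
#' @param z \code{2B x d} embedding matrix (unnormalized).
#' @param pairs integer vector: \code{pairs[i]} is the row of the positive
#'   partner of row \code{i}.
#' @param temperature softmax temperature.
#' @param grad also return \code{dL/dz}.
#' @return list with \code{loss} and optionally \code{grad}.
#' @export
nt_xent <- function(z, pairs, temperature = 0.1, grad = FALSE) {
  n <- nrow(z)
  if (n < 4 || n %% 2 != 0) stop("NT-Xent needs an even batch of >= 4 views")
  stopifnot(all(pairs[pairs] == seq_len(n)))
  norms <- sqrt(rowSums(z^2))
  if (any(norms == 0)) stop("zero embedding norm")
  zn <- z / norms
  s <- (zn %*% t(zn)) / temperature
  diag(s) <- -Inf
  m <- apply(s, 1, max)
  e <- exp(s - m)
  rs <- rowSums(e)
  P <- e / rs
  pos <- s[cbind(seq_len(n), pairs)]
  loss <- mean(-(pos - m) + log(rs))
  if (!grad) return(list(loss = loss))
  # dL/ds_ij = (P_ij - 1[j = pairs(i)]) / n for j != i
  G <- P
  G[cbind(seq_len(n), pairs)] <- G[cbind(seq_len(n), pairs)] - 1
  G <- G / n
  diag(G) <- 0
  # s = zn zn^T / tau: dL/dzn_i = sum_j (G_ij + G_ji) zn_j / tau
  dzn <- ((G + t(G)) %*% zn) / temperature
  # back through the row normalization: dz = (dzn - (dzn.zn) zn) / ||z||
  inner <- rowSums(dzn * zn)
  dz <- (dzn - inner * zn) / norms
  list(loss = loss, grad = dz)
}

# Stochastic augmentation for contrastive pretraining: random crop-resize
# (area scale in [0.6, 1]), random horizontal flip, brightness jitter.
augment_image <- function(img, crop_scale = c(0.6, 1), jitter = 0.2) {
  H <- nrow(img); W <- ncol(img)
  sc <- sqrt(runif(1, crop_scale[1], crop_scale[2]))
  ch <- max(8L, round(H * sc)); cw <- max(8L, round(W * sc))
  y0 <- sample.int(H - ch + 1L, 1) - 1L
  x0 <- sample.int(W - cw + 1L, 1) - 1L
  crop <- img[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), drop = FALSE]
  out <- as.matrix(EBImage::resize(crop, w = H, h = W, filter = "bilinear"))
  if (runif(1) < 0.5) out <- out[, ncol(out):1, drop = FALSE]
  out <- out + runif(1, -jitter, jitter)
  pmin(pmax(out, 0), 1)
}

#' SimCLR contrastive pretraining of the backbone
#'
#' For each batch, two stochastic augmentations per image (random
#' crop-resize, horizontal flip, brightness jitter) are embedded through the
#' backbone's pooled multi-stage features and a 2-layer projection head, and
#' the NT-Xent loss is minimized with Adam. The returned weights can be
#' passed as \code{init} to \code{\link{net_config}} for downstream
#' supervised training.
#'
#' @param x unlabeled preprocessed images, array \code{(H, W, N)}, values in
#'   [0, 1].
#' @param config a \code{\link{net_config}} (its \code{n_out} is irrelevant
#'   for pretraining; the projection head replaces the regression head).
#' @param temperature NT-Xent temperature.
#' @param proj_dim projection head output dimension.
#' @param verbose print per-epoch loss.
#' @return list of class \code{simclr_weights}: \code{params} (flat backbone
#'   vector usable as \code{init}), \code{config}, \code{log}.
#' @export
simclr_pretrain <- function(x, config, temperature = 0.1, proj_dim = 32L,
                            verbose = FALSE) {
  stopifnot(length(dim(x)) == 3)
  N <- dim(x)[3]
  if (config$batch_size < 2) stop("contrastive loss needs batch_size >= 2")
  cfgl <- cpp_cfg(config)
  info <- cpp_param_info(cfgl)
  fdim <- info$feat_dim
  params <- if (!is.null(config$init)) config$init else init_weights(config)
  log_rows <- vector("list", config$epochs)
  with_seed(config$seed + 2L, {
    W1 <- matrix(rnorm(fdim * fdim, 0, sqrt(2 / fdim)), fdim, fdim)
    b1 <- numeric(fdim)
    W2 <- matrix(rnorm(fdim * proj_dim, 0, sqrt(1 / fdim)), fdim, proj_dim)
    b2 <- numeric(proj_dim)
    nb <- length(params)
    nproj <- length(W1) + length(b1) + length(W2) + length(b2)
    st <- adam_state(nb + nproj)
    lr <- config$learning_rate
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (b0 in seq(1, N, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, N)]
        if (length(idx) < 2) next
        B <- length(idx)
        H <- dim(x)[1]; Wd <- dim(x)[2]
        xb <- array(0, dim = c(H, Wd, 2L * B))
        for (j in seq_len(B)) {
          xb[, , 2 * j - 1] <- augment_image(x[, , idx[j]])
          xb[, , 2 * j] <- augment_image(x[, , idx[j]])
        }
        pairs <- as.vector(rbind(seq(2, 2 * B, 2), seq(1, 2 * B, 2)))
        feats_raw <- cpp_net_forward(params, cfgl, xb)$feats
        # standardize features over the batch before the projection head:
        # without normalization layers the pooled features share a large
        # common offset, all cosine similarities start near 1 and the
        # contrastive gradient vanishes. The scale statistic is treated as
        # a constant in the backward pass; centering is backpropagated
        # exactly.
        mu <- colMeans(feats_raw)
        sdev <- sqrt(colMeans(sweep(feats_raw, 2, mu)^2)) + 1e-6
        feats <- sweep(sweep(feats_raw, 2, mu), 2, sdev, `/`)
        h_pre <- sweep(feats %*% W1, 2, b1, `+`)
        h <- pmax(h_pre, 0)
        zb <- sweep(h %*% W2, 2, b2, `+`)
        nt <- nt_xent(zb, pairs, temperature, grad = TRUE)
        if (!is.finite(nt$loss))
          stop("pretraining aborted: non-finite contrastive loss")
        dz <- nt$grad
        gW2 <- t(h) %*% dz
        gb2 <- colSums(dz)
        dh <- (dz %*% t(W2)) * (h_pre > 0)
        gW1 <- t(feats) %*% dh
        gb1 <- colSums(dh)
        dfeats <- dh %*% t(W1)
        dfeats <- sweep(dfeats, 2, sdev, `/`)
        dfeats <- sweep(dfeats, 2, colMeans(dfeats))  # centering backprop
        gback <- cpp_net_grad_feats(params, cfgl, xb, dfeats)
        gall <- c(gback, as.vector(gW1), gb1, as.vector(gW2), gb2)
        pall <- c(params, as.vector(W1), b1, as.vector(W2), b2)
        up <- adam_step(pall, gall, st, lr)
        st <- up$state
        params <- up$params[seq_len(nb)]
        rest <- up$params[-seq_len(nb)]
        W1 <- matrix(rest[seq_len(fdim * fdim)], fdim, fdim)
        rest <- rest[-seq_len(fdim * fdim)]
        b1 <- rest[seq_len(fdim)]; rest <- rest[-seq_len(fdim)]
        W2 <- matrix(rest[seq_len(fdim * proj_dim)], fdim, proj_dim)
        b2 <- rest[-seq_len(fdim * proj_dim)]
        losses <- c(losses, nt$loss)
      }
      log_rows[[ep]] <- data.frame(epoch = ep, loss = mean(losses), lr = lr)
      if (verbose)
        message(sprintf("ssl epoch %3d  loss %.5f", ep, mean(losses)))
      lr <- lr * config$lr_decay
    }
  })
  structure(list(params = params, config = config,
                 log = do.call(rbind, log_rows)),
            class = "simclr_weights")
}
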