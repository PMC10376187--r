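#' Fit the two-stage landmark localization model
#'
#' Fits the coarse-to-fine landmark regressor: an "aligner" network predicts
#' all 7 landmark locations simultaneously on the preprocessed 160 x 160
#' image (14 normalized outputs), then 7 per-landmark "patch" networks each
#' predict the coordinates of their landmark within a 36 x 36 patch centered
#' on the aligner's initial estimate. Both stages share the residual
#' backbone with multi-stage supervision and are trained with MSE loss and
#' Adam under an exponential learning-rate schedule. Patch training uses
#' random patch-center shifts of up to \code{max_shift} pixels as
#' augmentation; at inference patches are centered on the aligner output
#' with no shift.
#'
#' @param series_list list of annotated \code{\link{knee_series}} with
#'   images (typically phantoms from \code{\link{generate_phantom}}).
#' @param preprocess a \code{\link{preprocess_config}}.
#' @param aligner_config,patch_config \code{\link{net_config}}s for the two
#'   stages; input sizes and output counts are forced to the preprocessing
#'   geometry (160/14 and 36/2 by default).
#' @param ssl_init optional \code{simclr_weights} (or flat weight vector)
#'   used to initialize the aligner backbone.
#' @param patch_augment number of independently shifted patch samples drawn
#'   per landmark and slice for patch-model training.
#' @param seed master seed for patch augmentation and any stage seeds not
#'   set explicitly.
#' @param verbose print per-epoch losses.
#' @return an object of class \code{two_stage_model} with components
#'   \code{aligner} (a \code{conv_regressor}), \code{patches} (named list of
#'   7 \code{conv_regressor}s), \code{preprocess}, and \code{call}.
#' @seealso \code{\link{predict.two_stage_model}}
#' @export
two_stage_landmarks <- function(series_list,
                                preprocess = preprocess_config(),
                                aligner_config = NULL, patch_config = NULL,
                                ssl_init = NULL, patch_augment = 2L,
                                seed = 1L, verbose = FALSE) {
  if (inherits(series_list, "knee_series")) series_list <- list(series_list)
  if (is.null(aligner_config))
    aligner_config <- net_config(preprocess$out_size, 14L, seed = seed)
  if (is.null(patch_config))
    patch_config <- net_config(preprocess$patch_size, 2L, seed = seed)
  aligner_config$input_size <- preprocess$out_size
  aligner_config$n_out <- 14L
  patch_config$input_size <- preprocess$patch_size
  patch_config$n_out <- 2L
  if (!is.null(ssl_init)) {
    aligner_config$init <- if (inherits(ssl_init, "simclr_weights"))
      ssl_init$params else ssl_init
  }

  ad <- build_aligner_data(series_list, preprocess)
  if (verbose) message("training aligner on ", dim(ad$x)[3], " slices")
  aligner <- train_regressor(ad$x, ad$y, aligner_config, verbose = verbose)

  pd <- with_seed(seed + 17L,
                  build_patch_data(series_list, preprocess,
                                   n_aug = patch_augment))
  patches <- vector("list", 7L)
  names(patches) <- LANDMARK_NAMES
  for (nm in LANDMARK_NAMES) {
    if (verbose) message("training patch model for landmark ", nm)
    cfg <- patch_config
    cfg$seed <- patch_config$seed + match(nm, LANDMARK_NAMES)
    patches[[nm]] <- train_regressor(pd[[nm]]$x, pd[[nm]]$y, cfg,
                                     verbose = verbose)
  }
  structure(list(aligner = aligner, patches = patches,
                 preprocess = preprocess, seed = seed,
                 n_train_slices = dim(ad$x)[3], call = match.call()),
            class = "two_stage_model")
}

#' Predict landmarks on a knee series
#'
#' Per slice: the slice is preprocessed with the model's configuration
#' snapshot, the aligner predicts 7 points in model space, each point is
#' refined by its patch model on the 36 x 36 patch centered at the aligner
#' estimate, and the refined points are lifted back to original resolution
#' through the inverse crop transform. If a (clamped) patch no longer
#' contains the aligner point, refinement falls back to the aligner point
#' and the slice is flagged.
#'
#' @param object a \code{two_stage_model}.
#' @param series a \code{\link{knee_series}} with images, or a list of
#'   them.
#' @param stage \code{"two_stage"} (default) or \code{"aligner"} (coarse
#'   predictions only, for stage comparisons).
#' @param ... unused.
#' @return data.frame with columns \code{series_id}, \code{slice_index}
#'   (0-based), \code{landmark_name}, \code{x_px}, \code{y_px} (original
#'   resolution), \code{stage}, \code{fallback}.
#' @export
predict.two_stage_model <- function(object, series,
                                    stage = c("two_stage", "aligner"), ...) {
  stage <- match.arg(stage)
  if (inherits(series, "knee_series")) series <- list(series)
  cfg <- object$preprocess
  size <- cfg$out_size
  rows <- list()
  for (ser in series) {
    for (k in seq_along(ser$slices)) {
      img <- ser$slices[[k]]$image
      if (is.null(img)) next
      pp <- preprocess_slice(img, cfg)
      out <- predict(object$aligner, pp$image)
      pts160 <- matrix(out, 7, 2, byrow = TRUE) * size
      rownames(pts160) <- LANDMARK_NAMES
      fallback <- rep(FALSE, 7)
      if (stage == "two_stage") {
        for (j in seq_len(7)) {
          nm <- LANDMARK_NAMES[j]
          ctr <- pmin(pmax(pts160[j, ], 0), size - 1)
          ps <- extract_patch(pp$image, ctr, size = cfg$patch_size,
                              max_shift = 0L)
          inside <- all(pts160[j, ] >= ps$origin) &&
            all(pts160[j, ] <= ps$origin + cfg$patch_size - 1)
          if (!inside) {
            fallback[j] <- TRUE
            next
          }
          rel <- predict(object$patches[[nm]], ps$image)
          pts160[j, ] <- ps$origin + as.vector(rel) * cfg$patch_size
        }
      }
      orig <- map_coords(pp$transform, pts160, "inverse")
      rows[[length(rows) + 1]] <- data.frame(
        series_id = ser$series_id, slice_index = k - 1L,
        landmark_name = LANDMARK_NAMES, x_px = orig[, 1], y_px = orig[, 2],
        stage = stage, fallback = fallback,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Predicted landmarks as an annotated series
#'
#' Convenience wrapper: predicts on a series and returns a
#' \code{\link{knee_series}} carrying the predicted landmarks, ready for
#' \code{\link{measure_knee}}.
#'
#' @inheritParams predict.two_stage_model
#' @return a \code{knee_series} without images.
#' @export
predict_series <- function(object, series,
                           stage = c("two_stage", "aligner")) {
  pred <- predict(object, series, stage = match.arg(stage))
  pred <- pred[, c("series_id", "slice_index", "landmark_name",
                   "x_px", "y_px")]
  series_from_annotations(pred, pixel_spacing = series$pixel_spacing,
                          slice_thickness = series$slice_thickness,
                          laterality = series$laterality,
                          image_size = series$image_size)
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("Two-stage landmark model\n")
  cat(sprintf("  aligner: %dx%d -> 14 (%s), final loss %.6f\n",
              x$aligner$config$input_size, x$aligner$config$input_size,
              x$aligner$config$depth,
              x$aligner$log$loss[nrow(x$aligner$log)]))
  pl <- vapply(x$patches, function(p) p$log$loss[nrow(p$log)], numeric(1))
  cat(sprintf("  patch models: 7 x (%dx%d -> 2), final losses %s\n",
              x$patches[[1]]$config$input_size,
              x$patches[[1]]$config$input_size,
              paste(sprintf("%s=%.5f", names(pl), pl), collapse = " ")))
  cat(sprintf("  trained on %d slices, seed %d\n", x$n_train_slices, x$seed))
  invisible(x)
}

#' @export
summary.two_stage_model <- function(object, ...) {
  print(object)
  cat("\nAligner training log (last 5 epochs):\n")
  print(utils::tail(object$aligner$log, 5), row.names = FALSE)
  invisible(object)
}

#' Plot training loss curves of a two-stage model
#'
#' @param x a \code{two_stage_model}.
#' @param ... passed to \code{plot}.
#' @export
plot.two_stage_model <- function(x, ...) {
  al <- x$aligner$log
  plot(al$epoch, log10(al$loss), type = "l", lwd = 2,
       xlab = "epoch", ylab = "log10 MSE loss",
       main = "Training loss", ...)
  cols <- seq_len(7) + 1
  for (j in seq_len(7)) {
    pl <- x$patches[[j]]$log
    lines(pl$epoch, log10(pl$loss), col = cols[j])
  }
  legend("topright", legend = c("aligner", names(x$patches)),
         col = c(1, cols), lwd = c(2, rep(1, 7)), cex = 0.7, bty = "n")
  invisible(x)
}
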