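#' Landmark localization error report
#'
#' Matches predicted and ground-truth landmark tables on (series, slice,
#' landmark) keys and reports Euclidean point distances in cm (the
#' localization metric: spatial distance at original resolution scaled by
#' pixel spacing), per-landmark and pooled means, and the fraction of
#' distances at or below a precision threshold (default 0.40 cm).
#'
#' @param pred,truth annotation data.frames with columns \code{series_id},
#'   \code{slice_index}, \code{landmark_name}, \code{x_px}, \code{y_px}.
#' @param spacing_cm pixel spacing, cm per pixel.
#' @param threshold_cm precision threshold, cm.
#' @return object of class \code{landmark_error_report}: list with
#'   \code{per_landmark} (named mean distances), \code{pooled_mean_cm},
#'   \code{precision}, \code{threshold_cm}, \code{n_points},
#'   \code{distances_cm} (named by key).
#' @export
landmark_errors <- function(pred, truth, spacing_cm, threshold_cm = 0.40) {
  key <- function(d) paste(d$series_id, d$slice_index, d$landmark_name,
                           sep = "|")
  pk <- key(pred); tk <- key(truth)
  if (anyDuplicated(pk) || anyDuplicated(tk))
    stop("duplicate (series, slice, landmark) keys")
  if (!setequal(pk, tk))
    stop("prediction and truth keys do not match: ",
         length(setdiff(tk, pk)), " missing, ",
         length(setdiff(pk, tk)), " extra")
  m <- match(tk, pk)
  d_cm <- sqrt((pred$x_px[m] - truth$x_px)^2 +
               (pred$y_px[m] - truth$y_px)^2) * spacing_cm
  names(d_cm) <- tk
  per <- tapply(d_cm, truth$landmark_name, mean)
  structure(list(per_landmark = per[LANDMARK_NAMES],
                 pooled_mean_cm = mean(d_cm),
                 precision = mean(d_cm <= threshold_cm),
                 threshold_cm = threshold_cm,
                 n_points = length(d_cm),
                 distances_cm = d_cm),
            class = "landmark_error_report")
}

#' @export
print.landmark_error_report <- function(x, ...) {
  cat(sprintf("Landmark errors over %d points: mean %.3f cm, precision@%.2f cm = %.1f%%\n",
              x$n_points, x$pooled_mean_cm, x$threshold_cm,
              100 * x$precision))
  cat("  per landmark (cm):",
      paste(sprintf("%s=%.3f", names(x$per_landmark), x$per_landmark),
            collapse = " "), "\n")
  invisible(x)
}

#' Paired t-test on measurement pairs
#'
#' Two-sided paired t-test comparing, e.g., predicted against ground-truth
#' patellofemoral measurements on the same knees.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_diff},
#'   \code{degenerate} (TRUE when the difference variance is zero, in which
#'   case no p-value is produced).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  tt <- tryCatch(t.test(x, y, paired = TRUE), error = function(e) NULL)
  if (is.null(tt) || sd(d) == 0)  # zero (or numerically zero) variance
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Independent two-sample t-test
#'
#' Two-sided independent-samples t-test (Welch by default; set
#' \code{pooled = TRUE} for the equal-variance form), used e.g. to compare
#' measurements between cohorts.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (classic) form.
#' @return list with \code{t}, \code{p}, \code{df}, \code{degenerate}.
#' @export
independent_t <- function(a, b, pooled = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  tt <- tryCatch(t.test(a, b, var.equal = pooled),
                 error = function(e) NULL)
  if (is.null(tt))  # degenerate variance in both groups
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                degenerate = TRUE))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Differences \code{pred - truth} are summarized by their mean, standard
#' deviation and the limits of agreement mean +/- 1.96 sd; indices whose
#' difference lies outside the limits are flagged as outliers. A paired
#' t-test p-value on the pairs is included.
#'
#' @param pred,truth paired numeric vectors (n >= 2).
#' @return object of class \code{bland_altman}: list with
#'   \code{mean_difference}, \code{sd_difference}, \code{limits},
#'   \code{outlier_indices}, \code{paired_t_p_value}, \code{means},
#'   \code{differences}.
#' @export
bland_altman <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  d <- pred - truth
  mu <- mean(d); s <- sd(d)
  lim <- c(lower = mu - 1.96 * s, upper = mu + 1.96 * s)
  out <- which(abs(d - mu) > 1.96 * s)
  pt <- paired_t(pred, truth)
  structure(list(mean_difference = mu, sd_difference = s, limits = lim,
                 outlier_indices = out, paired_t_p_value = pt$p,
                 means = (pred + truth) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f, sd %.4f, limits [%.4f, %.4f], %d outlier(s), paired-t p = %s\n",
              x$mean_difference, x$sd_difference, x$limits[1], x$limits[2],
              length(x$outlier_indices),
              format.pval(x$paired_t_p_value, digits = 3)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x a \code{bland_altman} object.
#' @param main,xlab,ylab plot labels.
#' @param ... passed to \code{plot}.
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman",
                              xlab = "mean of pair",
                              ylab = "difference (pred - truth)", ...) {
  plot(x$means, x$differences, pch = 3, main = main, xlab = xlab,
       ylab = ylab, ...)
  abline(h = x$mean_difference, lty = 3, col = "purple", lwd = 2)
  abline(h = x$limits, lty = 3, col = "orange", lwd = 2)
  if (length(x$outlier_indices))
    points(x$means[x$outlier_indices], x$differences[x$outlier_indices],
           pch = 1, col = "red", cex = 1.5)
  invisible(x)
}

#' Compare the aligner stage against the two-stage predictor
#'
#' Computes the mean Euclidean distance and precision at the threshold for
#' each stage's predictions against ground truth, plus a paired t-test on
#' the per-point distances across stages.
#'
#' @param aligner_pred,patch_pred,truth annotation data.frames (see
#'   \code{\link{landmark_errors}}).
#' @param spacing_cm pixel spacing, cm per pixel.
#' @param threshold_cm precision threshold, cm.
#' @return data.frame with one row per stage (mean distance, precision, n)
#'   and attribute \code{p_value} for the paired test on distances.
#' @export
compare_models <- function(aligner_pred, patch_pred, truth, spacing_cm,
                           threshold_cm = 0.40) {
  ea <- landmark_errors(aligner_pred, truth, spacing_cm, threshold_cm)
  ep <- landmark_errors(patch_pred, truth, spacing_cm, threshold_cm)
  keys <- names(ea$distances_cm)
  pt <- paired_t(ea$distances_cm[keys], ep$distances_cm[keys])
  out <- data.frame(stage = c("aligner", "two_stage"),
                    mean_distance_cm = c(ea$pooled_mean_cm,
                                         ep$pooled_mean_cm),
                    precision = c(ea$precision, ep$precision),
                    n_points = c(ea$n_points, ep$n_points),
                    stringsAsFactors = FALSE)
  attr(out, "p_value") <- pt$p
  attr(out, "threshold_cm") <- threshold_cm
  out
}
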