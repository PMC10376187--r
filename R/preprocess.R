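#' Preprocessing configuration
#'
#' Parameters of the CT preprocessing chain: Hounsfield windowing (level
#' 350, width 2000, mapped to 0-255), Gaussian-filtered bone bounding-box
#' detection (threshold 105 on the windowed image), and aspect-preserving
#' resampling to a 160 x 160 model image.
#'
#' @param window_level,window_width CT window, HU.
#' @param sigma Gaussian smoothing standard deviation (pixels) used before
#'   thresholding for the bone bounding box; 0 disables smoothing.
#' @param threshold bone threshold on the windowed 0-255 image.
#' @param out_size model image side length, pixels.
#' @param patch_size refinement patch side length, pixels.
#' @param max_shift maximum patch-center shift used as training
#'   augmentation, pixels.
#' @param resize_mode \code{"pad"} pads the bone crop to a square before
#'   resizing (aspect-preserving, the default: anisotropic stretch would
#'   distort the angles downstream morphometry depends on); \code{"stretch"}
#'   reproduces a naive non-square resize.
#' @return a list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(window_level = 350, window_width = 2000,
                              sigma = 2, threshold = 105, out_size = 160L,
                              patch_size = 36L, max_shift = 10L,
                              resize_mode = c("pad", "stretch")) {
  structure(list(window_level = window_level, window_width = window_width,
                 sigma = sigma, threshold = threshold,
                 out_size = as.integer(out_size),
                 patch_size = as.integer(patch_size),
                 max_shift = as.integer(max_shift),
                 resize_mode = match.arg(resize_mode)),
            class = "preprocess_config")
}

#' Window-normalize a CT image
#'
#' Linearly maps the Hounsfield window [level - width/2, level + width/2]
#' onto [0, 255], clipping outside; the default window (level 350, width
#' 2000) maps [-650, 1350]. Values are kept as floats (no integer
#' quantization) to avoid double rounding before model input.
#'
#' @param image Hounsfield matrix.
#' @param level,width window parameters, HU; \code{width} must be positive.
#' @return matrix of the same shape with values in [0, 255].
#' @export
window_normalize <- function(image, level = 350, width = 2000) {
  stopifnot(width > 0)
  lo <- level - width / 2
  pmin(pmax((image - lo) / width, 0), 1) * 255
}

#' Detect the bone bounding box
#'
#' Gaussian-smooths the window-normalized image, thresholds it, keeps the
#' largest connected component of supra-threshold pixels, and returns its
#' tight axis-aligned bounding box.
#'
#' @param norm_image window-normalized image (0-255).
#' @param sigma Gaussian standard deviation in pixels; 0 skips smoothing.
#' @param threshold intensity threshold on the 0-255 scale.
#' @return named integer vector \code{c(x0, y0, x1, y1)}: half-open 0-based
#'   bounds (pixels with \code{x0 <= x < x1}, \code{y0 <= y < y1}).
#' @export
detect_bone_bbox <- function(norm_image, sigma = 2, threshold = 105) {
  sm <- if (sigma > 0) EBImage::gblur(norm_image, sigma = sigma)
        else norm_image
  bw <- sm > threshold
  if (!any(bw))
    stop("no bone found: no pixel above threshold ", threshold)
  lab <- EBImage::bwlabel(bw)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  idx <- which(lab == keep, arr.ind = TRUE)
  c(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
    x1 = max(idx[, 2]), y1 = max(idx[, 1]))
}

#' Crop to a bounding box and resample to model resolution
#'
#' Crops the image to the bounding box, optionally pads the shorter side
#' symmetrically with a background value to make the crop square, and
#' bilinearly resamples to \code{out_size} x \code{out_size}. The returned
#' \code{crop_transform} records the exact affine mapping between original
#' and model coordinates, so annotations can be projected into model space
#' and predictions lifted back without loss.
#'
#' @param norm_image window-normalized image.
#' @param bbox half-open bounding box from \code{\link{detect_bone_bbox}}.
#' @param out_size output side length, pixels.
#' @param mode \code{"pad"} (aspect-preserving) or \code{"stretch"}.
#' @param background padding value.
#' @return list with \code{image} (out_size x out_size matrix) and
#'   \code{transform} (a \code{crop_transform}).
#' @export
crop_resize <- function(norm_image, bbox, out_size = 160L,
                        mode = c("pad", "stretch"), background = 0) {
  mode <- match.arg(mode)
  x0 <- bbox[["x0"]]; y0 <- bbox[["y0"]]
  x1 <- bbox[["x1"]]; y1 <- bbox[["y1"]]
  w <- x1 - x0; h <- y1 - y0
  if (w <= 0 || h <= 0) stop("degenerate (zero-area) bounding box")
  crop <- norm_image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  if (mode == "pad") {
    side <- max(w, h)
    pad_left <- (side - w) %/% 2
    pad_top <- (side - h) %/% 2
    sq <- matrix(background, side, side)
    sq[(pad_top + 1):(pad_top + h), (pad_left + 1):(pad_left + w)] <- crop
    scale_x <- out_size / side
    scale_y <- out_size / side
  } else {
    sq <- crop
    pad_left <- 0L; pad_top <- 0L
    scale_x <- out_size / w
    scale_y <- out_size / h
  }
  img <- EBImage::resize(sq, w = out_size, h = out_size, filter = "bilinear")
  tr <- structure(list(bbox = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
                       out_size = as.integer(out_size),
                       scale_x = scale_x, scale_y = scale_y,
                       pad = c(left = pad_left, top = pad_top)),
                  class = "crop_transform")
  list(image = as.matrix(img), transform = tr)
}

#' Map points between original and model coordinates
#'
#' Applies the affine crop-resize mapping (or its inverse). The forward
#' direction projects original-resolution points into the
#' \code{out_size} x \code{out_size} model frame; the inverse lifts model
#' predictions back to the original resolution, where all evaluation and
#' morphometry take place. The map is the pure scaling that sends the
#' (padded) bbox corner to the origin, so a 320 x 320 bbox resampled to 160
#' maps the point at bbox offset (100, 60) to (50, 30); the round trip is
#' exact to floating point. (The bilinear resampler aligns pixel centers,
#' which differs from this corner-aligned map by under half a pixel of the
#' model frame - far below annotation precision.)
#'
#' @param transform a \code{crop_transform} from \code{\link{crop_resize}}.
#' @param points n x 2 matrix (or length-2 vector) of \code{(x, y)} points.
#' @param direction \code{"forward"} (original to model) or
#'   \code{"inverse"}.
#' @return points in the target frame, same shape as the input.
#' @export
map_coords <- function(transform, points,
                       direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  vec_in <- is.null(dim(points))
  p <- if (vec_in) matrix(points, 1) else as.matrix(points)
  x0 <- transform$bbox[["x0"]]; y0 <- transform$bbox[["y0"]]
  pl <- transform$pad[["left"]]; pt <- transform$pad[["top"]]
  sx <- transform$scale_x; sy <- transform$scale_y
  out <- p
  if (direction == "forward") {
    out[, 1] <- (p[, 1] - x0 + pl) * sx
    out[, 2] <- (p[, 2] - y0 + pt) * sy
  } else {
    out[, 1] <- p[, 1] / sx - pl + x0
    out[, 2] <- p[, 2] / sy - pt + y0
  }
  if (vec_in) drop(out) else out
}

#' @export
print.crop_transform <- function(x, ...) {
  cat(sprintf("crop_transform: bbox [%d,%d)x[%d,%d) -> %dx%d (scale %.4f/%.4f, pad %d,%d)\n",
              x$bbox[["x0"]], x$bbox[["x1"]], x$bbox[["y0"]], x$bbox[["y1"]],
              x$out_size, x$out_size, x$scale_x, x$scale_y,
              x$pad[["left"]], x$pad[["top"]]))
  invisible(x)
}

#' Extract a refinement patch
#'
#' Crops a \code{size} x \code{size} window around a center point, with an
#' optional random integer shift drawn uniformly from
#' [-\code{max_shift}, \code{max_shift}] per axis (training augmentation;
#' at inference the patch is centered on the coarse prediction with no
#' shift). The window is clamped to the image bounds; the target is the
#' center point expressed in 0-based patch coordinates.
#'
#' @param image160 model-space image matrix.
#' @param center length-2 \code{(x, y)} point inside the image.
#' @param size patch side length.
#' @param max_shift maximum absolute shift per axis (0 disables).
#' @return list with \code{image} (size x size), \code{target} (point in
#'   patch coordinates), \code{origin} (0-based window origin in the source
#'   image), \code{shift} (the drawn shift).
#' @export
extract_patch <- function(image160, center, size = 36L, max_shift = 10L) {
  H <- nrow(image160); W <- ncol(image160)
  stopifnot(size <= H, size <= W)
  shift <- if (max_shift > 0)
    c(sample(-max_shift:max_shift, 1), sample(-max_shift:max_shift, 1))
  else c(0L, 0L)
  half <- size %/% 2
  x_start <- round(center[1] + shift[1]) - half
  y_start <- round(center[2] + shift[2]) - half
  x_start <- min(max(x_start, 0), W - size)
  y_start <- min(max(y_start, 0), H - size)
  patch <- image160[(y_start + 1):(y_start + size),
                    (x_start + 1):(x_start + size), drop = FALSE]
  list(image = patch,
       target = c(center[1] - x_start, center[2] - y_start),
       origin = c(x = x_start, y = y_start),
       shift = shift)
}

#' Preprocess one slice
#'
#' Runs windowing, bone bounding-box detection and crop-resize on a raw
#' Hounsfield slice. The model image is scaled to [0, 1].
#'
#' @param image Hounsfield matrix.
#' @param config a \code{\link{preprocess_config}}.
#' @return list with \code{image} (out_size x out_size, [0, 1]) and
#'   \code{transform}.
#' @export
preprocess_slice <- function(image, config = preprocess_config()) {
  norm <- window_normalize(image, config$window_level, config$window_width)
  bbox <- detect_bone_bbox(norm, sigma = config$sigma,
                           threshold = config$threshold)
  cr <- crop_resize(norm, bbox, out_size = config$out_size,
                    mode = config$resize_mode)
  list(image = cr$image / 255, transform = cr$transform)
}

# Assemble the aligner training set: preprocessed model images plus all 7
# landmark coordinates projected into model space, normalized by out_size.
build_aligner_data <- function(series_list, config = preprocess_config()) {
  xs <- list(); ys <- list(); meta <- list()
  for (series in series_list) {
    for (k in annotated_indices(series)) {
      sl <- series$slices[[k]]
      if (is.null(sl$image)) next
      pp <- preprocess_slice(sl$image, config)
      lm160 <- map_coords(pp$transform, sl$landmarks, "forward")
      xs[[length(xs) + 1]] <- pp$image
      ys[[length(ys) + 1]] <- as.vector(t(lm160)) / config$out_size
      meta[[length(meta) + 1]] <- list(series_id = series$series_id,
                                       slice_index = k - 1L,
                                       transform = pp$transform)
    }
  }
  if (!length(xs)) stop("no annotated image slices available for training")
  x <- array(unlist(xs), dim = c(dim(xs[[1]]), length(xs)))
  list(x = x, y = do.call(rbind, ys), meta = meta)
}

# Assemble per-landmark patch training sets with random shift augmentation
# (n_aug independently shifted draws per landmark and slice); targets are
# patch coordinates normalized by patch_size.
build_patch_data <- function(series_list, config = preprocess_config(),
                             n_aug = 2L) {
  acc <- lapply(LANDMARK_NAMES, function(nm) list(x = list(), y = list()))
  names(acc) <- LANDMARK_NAMES
  for (series in series_list) {
    for (k in annotated_indices(series)) {
      sl <- series$slices[[k]]
      if (is.null(sl$image)) next
      pp <- preprocess_slice(sl$image, config)
      lm160 <- map_coords(pp$transform, sl$landmarks, "forward")
      for (nm in LANDMARK_NAMES) {
        for (a in seq_len(max(1L, n_aug))) {
          ps <- extract_patch(pp$image, lm160[nm, ],
                              size = config$patch_size,
                              max_shift = config$max_shift)
          acc[[nm]]$x[[length(acc[[nm]]$x) + 1]] <- ps$image
          acc[[nm]]$y[[length(acc[[nm]]$y) + 1]] <-
            ps$target / config$patch_size
        }
      }
    }
  }
  lapply(acc, function(a) {
    if (!length(a$x)) stop("no annotated image slices available for training")
    list(x = array(unlist(a$x), dim = c(dim(a$x[[1]]), length(a$x))),
         y = do.call(rbind, a$y))
  })
}
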