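#' @name morphometry
#' @title Patellofemoral morphometry from per-slice landmarks
#'
#' @description Geometric derivation of the four patellofemoral parameters
#' from the seven landmarks: TEA length, TEA-PFA angle, trochlear medial
#' asymmetry ratio, and sulcus angle. The same contract applies whether the
#' landmarks are human annotations, phantom ground truth, or model
#' predictions. All distances are computed in original-resolution pixel
#' space and scaled by the series pixel spacing; angles are dimensionless,
#' so every output is invariant under rigid in-plane rotation, translation
#' and mirroring of the landmark scene.
NULL

annotated_indices <- function(series) {
  idx <- which(vapply(series$slices, function(s) !is.null(s$landmarks),
                      logical(1)))
  if (!length(idx)) stop("series has no annotated slices")
  idx
}

#' Select the TEA slice and axis
#'
#' Per slice, the transepicondylar length is the Euclidean distance between
#' the most medial and most lateral of the seven landmarks (the extremes
#' along x in canonical orientation; in practice the epicondyles D and E).
#' The slice attaining the longest transepicondylar length defines the TEA.
#' Ties are broken toward the lowest slice index.
#'
#' @param series a \code{\link{knee_series}} with at least one annotated
#'   slice.
#' @return list with \code{slice_index} (1-based), \code{length_cm},
#'   \code{line} (list with point \code{p} and unit direction \code{d},
#'   directed medial to lateral), \code{extreme_landmarks} (names of the two
#'   extreme points).
#' @export
select_tea_slice <- function(series) {
  idx <- annotated_indices(series)
  best <- NULL
  for (k in idx) {
    lm <- series$slices[[k]]$landmarks
    i_med <- which.min(lm[, 1])
    i_lat <- which.max(lm[, 1])
    len_px <- sqrt(sum((lm[i_lat, ] - lm[i_med, ])^2))
    if (is.null(best) || len_px > best$len_px + 1e-12)
      best <- list(k = k, len_px = len_px, i_med = i_med, i_lat = i_lat,
                   lm = lm)
  }
  p <- best$lm[best$i_med, ]
  d <- best$lm[best$i_lat, ] - p
  if (best$len_px == 0) stop("degenerate TEA: extreme landmarks coincide")
  list(slice_index = best$k,
       length_cm = best$len_px * series$pixel_spacing,
       line = list(p = unname(p), d = unname(d / sqrt(sum(d^2)))),
       extreme_landmarks = rownames(best$lm)[c(best$i_med, best$i_lat)])
}

#' Angle between the TEA and the posterior femur axis
#'
#' The PFA is the line through the posterior condyle landmarks F and G; the
#' returned value is the acute angle in degrees between the TEA and PFA
#' direction vectors, in [0, 90].
#'
#' @param landmarks 7 x 2 landmark matrix on the TEA slice.
#' @param tea_line TEA line (list with unit direction \code{d}) from
#'   \code{\link{select_tea_slice}}.
#' @return angle in degrees.
#' @export
tea_pfa_angle <- function(landmarks, tea_line) {
  check_landmark_set(landmarks)
  v <- landmarks["G", ] - landmarks["F", ]
  if (all(v == 0)) stop("degenerate PFA: posterior condyle landmarks coincide")
  d <- tea_line$d
  # atan2(|cross|, |dot|) is well-conditioned near parallel, unlike acos
  unname(atan2(abs(v[1] * d[2] - v[2] * d[1]), abs(sum(v * d))) * 180 / pi)
}

point_line_distance <- function(p, line) {
  w <- p - line$p
  abs(w[1] * line$d[2] - w[2] * line$d[1])
}

#' Select the trough slice
#'
#' On each annotated slice the trochlear central trough (landmark A) has a
#' perpendicular distance to the TEA line; the slice whose trough is closest
#' to the TEA is selected for the asymmetry ratio and sulcus angle. Ties are
#' broken toward the lowest slice index.
#'
#' @inheritParams select_tea_slice
#' @param tea_line TEA line from \code{\link{select_tea_slice}}.
#' @return 1-based slice index.
#' @export
select_trough_slice <- function(series, tea_line) {
  idx <- annotated_indices(series)
  d <- vapply(idx, function(k)
    point_line_distance(series$slices[[k]]$landmarks["A", ], tea_line),
    numeric(1))
  idx[which.min(d)]
}

#' Trochlear medial asymmetry ratio
#'
#' The trough (A) and the medial/lateral trochlear aspects (B, C) are
#' orthogonally projected onto the TEA; the ratio of the groove-to-lateral
#' projected length (G-L, between A and C) to the medial-to-lateral length
#' (M-L, between B and C) is returned. A centered groove gives 0.5; the
#' ratio is 0 when the trough projection coincides with the lateral aspect
#' and 1 at the medial aspect.
#'
#' @param landmarks 7 x 2 landmark matrix on the trough slice.
#' @param tea_line TEA line from \code{\link{select_tea_slice}}.
#' @return dimensionless ratio.
#' @export
asymmetry_ratio <- function(landmarks, tea_line) {
  check_landmark_set(landmarks)
  proj <- function(p) sum((p - tea_line$p) * tea_line$d)
  tA <- proj(landmarks["A", ])
  tB <- proj(landmarks["B", ])
  tC <- proj(landmarks["C", ])
  ml <- abs(tC - tB)
  if (ml == 0) stop("degenerate projections: M-L length is zero")
  abs(tC - tA) / ml
}

#' Sulcus angle
#'
#' Angle at the trochlear central trough (A) between the rays toward the
#' medial (B) and lateral (C) trochlear aspects, in degrees; 180 is a flat
#' groove.
#'
#' @param landmarks 7 x 2 landmark matrix on the trough slice.
#' @return angle in degrees, in (0, 180].
#' @export
sulcus_angle <- function(landmarks) {
  check_landmark_set(landmarks)
  u <- landmarks["B", ] - landmarks["A", ]
  v <- landmarks["C", ] - landmarks["A", ]
  if (all(u == 0) || all(v == 0))
    stop("degenerate sulcus: trough coincides with an aspect")
  # atan2 form of the vertex angle: stable near flat (180) grooves
  unname(atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)) * 180 / pi)
}

#' Measure the four patellofemoral parameters of a knee
#'
#' Runs the measurement chain: TEA slice selection, TEA-PFA angle on the TEA
#' slice, trough slice selection against the TEA line, then asymmetry ratio
#' and sulcus angle on the trough slice.
#'
#' @param series a \code{\link{knee_series}} with at least one fully
#'   annotated slice (human annotations, phantom ground truth or model
#'   predictions).
#' @return an object of class \code{knee_measurements}: a list with
#'   \code{tea_length_cm}, \code{tea_pfa_angle_deg}, \code{asymmetry_ratio},
#'   \code{sulcus_angle_deg}, \code{tea_slice}, \code{trough_slice}
#'   (1-based indices) and \code{series_id}.
#' @examples
#' series <- generate_phantom(phantom_spec(sulcus_angle = 140, seed = 1))
#' measure_knee(series)
#' @export
measure_knee <- function(series) {
  tea <- select_tea_slice(series)
  ang <- tea_pfa_angle(series$slices[[tea$slice_index]]$landmarks, tea$line)
  kt <- select_trough_slice(series, tea$line)
  lm_t <- series$slices[[kt]]$landmarks
  out <- list(series_id = series$series_id,
              tea_length_cm = tea$length_cm,
              tea_pfa_angle_deg = ang,
              asymmetry_ratio = asymmetry_ratio(lm_t, tea$line),
              sulcus_angle_deg = sulcus_angle(lm_t),
              tea_slice = tea$slice_index,
              trough_slice = kt,
              tea_extremes = tea$extreme_landmarks)
  class(out) <- "knee_measurements"
  out
}

#' @export
print.knee_measurements <- function(x, ...) {
  cat(sprintf("Patellofemoral measurements for '%s':\n", x$series_id))
  cat(sprintf("  TEA length        %7.3f cm  (slice %d, extremes %s-%s)\n",
              x$tea_length_cm, x$tea_slice, x$tea_extremes[1],
              x$tea_extremes[2]))
  cat(sprintf("  TEA-PFA angle     %7.3f deg\n", x$tea_pfa_angle_deg))
  cat(sprintf("  asymmetry ratio   %7.4f     (slice %d)\n",
              x$asymmetry_ratio, x$trough_slice))
  cat(sprintf("  sulcus angle      %7.3f deg (slice %d)\n",
              x$sulcus_angle_deg, x$trough_slice))
  invisible(x)
}

#' @export
as.data.frame.knee_measurements <- function(x, ...) {
  data.frame(series_id = x$series_id, tea_length_cm = x$tea_length_cm,
             tea_pfa_angle_deg = x$tea_pfa_angle_deg,
             asymmetry_ratio = x$asymmetry_ratio,
             sulcus_angle_deg = x$sulcus_angle_deg,
             tea_slice = x$tea_slice, trough_slice = x$trough_slice,
             stringsAsFactors = FALSE)
}

#' Build an annotation-only knee series from an annotation table
#'
#' @param annotations data.frame with columns \code{series_id},
#'   \code{slice_index} (0-based), \code{landmark_name}, \code{x_px},
#'   \code{y_px} for a single series.
#' @param pixel_spacing cm per pixel.
#' @param slice_thickness cm.
#' @param laterality \code{"right"} or \code{"left"}.
#' @param image_size optional slice side length in pixels.
#' @return a \code{\link{knee_series}} without images.
#' @export
series_from_annotations <- function(annotations, pixel_spacing,
                                    slice_thickness = 0.25,
                                    laterality = "right",
                                    image_size = NULL) {
  validate_annotations(annotations)
  sid <- unique(annotations$series_id)
  if (length(sid) != 1)
    stop("annotations must describe a single series; got: ",
         paste(sid, collapse = ", "))
  ks <- sort(unique(annotations$slice_index))
  slices <- lapply(ks, function(k) {
    a <- annotations[annotations$slice_index == k, ]
    if (nrow(a) != 7)
      stop("slice ", k, " must carry exactly 7 landmarks, got ", nrow(a))
    lm <- as.matrix(a[match(LANDMARK_NAMES, a$landmark_name),
                      c("x_px", "y_px")])
    dimnames(lm) <- list(LANDMARK_NAMES, c("x", "y"))
    list(image = NULL, landmarks = lm)
  })
  knee_series(slices, pixel_spacing = pixel_spacing,
              slice_thickness = slice_thickness, laterality = laterality,
              series_id = sid, image_size = image_size)
}
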