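#' Specify a synthetic knee phantom
#'
#' Parameters of the synthetic axial knee-CT phantom. The phantom renders a
#' bicondylar distal-femur cross-section (two overlapping filled ellipses
#' with a wedge-shaped trochlear groove cut between the medial aspect, the
#' central trough and the lateral aspect) as bone-density foreground on a
#' soft-tissue background, across an ordered stack of slices in which
#' condylar width and trochlear depth follow smooth quadratic profiles. The
#' seven landmarks are placed analytically in continuous (sub-pixel)
#' coordinates, so the specification doubles as measurement ground truth:
#' exactly one slice attains the maximum epicondylar span (equal to
#' \code{tea_length}), the posterior condyle line makes \code{tea_pfa_angle}
#' with the transepicondylar line on every slice, and on the trough-selection
#' slice the sulcus angle and asymmetry ratio equal the specified values.
#'
#' @param n_slices number of axial slices in the stack.
#' @param image_size slice side length in pixels.
#' @param pixel_spacing in-plane pixel spacing, cm per pixel.
#' @param tea_length transepicondylar axis length, cm.
#' @param tea_pfa_angle angle between the transepicondylar axis and the
#'   posterior femur axis, degrees.
#' @param sulcus_angle sulcus angle at the trochlear central trough, degrees
#'   (90 to just under 180; larger is flatter).
#' @param asymmetry_ratio trochlear medial asymmetry ratio, the
#'   groove-to-lateral over medial-to-lateral projected length, in (0, 1).
#' @param laterality \code{"right"} or \code{"left"}.
#' @param bone_hu,background_hu foreground/background intensities in
#'   Hounsfield units.
#' @param noise_sd standard deviation of additive Gaussian noise, HU.
#' @param slice_thickness slice thickness, cm (metadata only).
#' @param seed integer seed; identical spec and seed give bit-identical
#'   output.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(n_slices = 9L, image_size = 512L,
                         pixel_spacing = 0.04, tea_length = 8.2,
                         tea_pfa_angle = 5, sulcus_angle = 140,
                         asymmetry_ratio = 0.5,
                         laterality = c("right", "left"),
                         bone_hu = 700, background_hu = 40, noise_sd = 50,
                         slice_thickness = 0.25, seed = 1L) {
  spec <- list(n_slices = as.integer(n_slices),
               image_size = as.integer(image_size),
               pixel_spacing = pixel_spacing, tea_length = tea_length,
               tea_pfa_angle = tea_pfa_angle, sulcus_angle = sulcus_angle,
               asymmetry_ratio = asymmetry_ratio,
               laterality = match.arg(laterality), bone_hu = bone_hu,
               background_hu = background_hu, noise_sd = noise_sd,
               slice_thickness = slice_thickness, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$n_slices >= 1, spec$image_size >= 64,
            spec$pixel_spacing > 0, spec$tea_length > 0)
  if (!(spec$asymmetry_ratio > 0 && spec$asymmetry_ratio < 1))
    stop("asymmetry_ratio must be strictly inside (0, 1)")
  if (!(spec$sulcus_angle >= 90 && spec$sulcus_angle < 180))
    stop("sulcus_angle must be in [90, 180) degrees")
  if (!(spec$tea_pfa_angle >= 0 && spec$tea_pfa_angle <= 30))
    stop("tea_pfa_angle must be in [0, 30] degrees")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Knee phantom spec:", x$n_slices, "slices of", x$image_size, "x",
      x$image_size, "px @", x$pixel_spacing, "cm/px,", x$laterality,
      "knee\n")
  cat(sprintf("  TEA %.2f cm | TEA-PFA %.2f deg | sulcus %.1f deg | asymmetry %.3f | noise %.0f HU | seed %d\n",
              x$tea_length, x$tea_pfa_angle, x$sulcus_angle,
              x$asymmetry_ratio, x$noise_sd, x$seed))
  invisible(x)
}

#' Construct a knee series container
#'
#' An ordered stack of axial slices of one knee. Each slice is a list with
#' an \code{image} (Hounsfield matrix, \code{m[y+1, x+1]}; may be
#' \code{NULL} for annotation-only series) and \code{landmarks} (7 x 2
#' matrix with rows \code{A}..\code{G} and columns \code{x}, \code{y} in
#' 0-based original-slice pixel coordinates; may be \code{NULL}).
#'
#' @param slices list of slices as described above.
#' @param pixel_spacing cm per pixel (> 0).
#' @param slice_thickness cm.
#' @param laterality \code{"right"} or \code{"left"}.
#' @param series_id identifier string.
#' @param image_size slice side length in pixels; inferred from the images
#'   when present, required for annotation-only series that will be
#'   mirrored.
#' @return an object of class \code{knee_series}.
#' @export
knee_series <- function(slices, pixel_spacing, slice_thickness = 0.25,
                        laterality = "right", series_id = "series",
                        image_size = NULL) {
  stopifnot(length(slices) >= 1, pixel_spacing > 0)
  shapes <- unique(lapply(slices, function(s)
    if (is.null(s$image)) NULL else dim(s$image)))
  shapes <- shapes[!vapply(shapes, is.null, logical(1))]
  if (length(shapes) > 1) stop("all slices must have the same shape")
  if (length(shapes) == 1 && is.null(image_size))
    image_size <- shapes[[1]][2]
  for (s in slices) {
    if (!is.null(s$landmarks)) check_landmark_set(s$landmarks, s$image)
  }
  structure(list(slices = slices, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, laterality = laterality,
                 series_id = series_id, image_size = image_size),
            class = "knee_series")
}

check_landmark_set <- function(lm, image = NULL) {
  if (!is.matrix(lm) || nrow(lm) != 7 || ncol(lm) != 2 ||
      !identical(rownames(lm), LANDMARK_NAMES))
    stop("landmarks must be a 7 x 2 matrix with rows A..G")
  if (any(!is.finite(lm))) stop("landmarks must all be finite")
  if (!is.null(image)) {
    if (any(lm[, 1] < 0 | lm[, 1] > ncol(image) - 1) ||
        any(lm[, 2] < 0 | lm[, 2] > nrow(image) - 1))
      stop("landmarks must lie inside the image bounds")
  }
  invisible(lm)
}

#' @export
print.knee_series <- function(x, ...) {
  n_ann <- sum(vapply(x$slices, function(s) !is.null(s$landmarks),
                      logical(1)))
  dims <- dim(x$slices[[1]]$image)
  cat(sprintf("Knee series '%s' (%s): %d slices%s, %d annotated, %.3f cm/px\n",
              x$series_id, x$laterality, length(x$slices),
              if (is.null(dims)) " (no images)" else
                sprintf(" of %d x %d", dims[1], dims[2]),
              n_ann, x$pixel_spacing))
  invisible(x)
}

# Solve the trough depth t > 0 below the aspect line such that the angle at
# the trough between rays to the medial and lateral aspects equals `deg`,
# with horizontal half-spans a (to medial) and b (to lateral).
solve_trough_depth <- function(a, b, deg) {
  stopifnot(a > 0, b > 0, deg > 0, deg < 180)
  f <- function(t) atan(a / t) + atan(b / t) - deg * pi / 180
  uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-12)$root
}

#' Generate a synthetic knee phantom series
#'
#' Renders the slice stack described by a \code{\link{phantom_spec}} and
#' attaches analytic landmark ground truth to every slice. Morphometry run
#' on the ground-truth landmarks recovers the spec parameters to within
#' pixel-discretization tolerance (the landmarks themselves are continuous,
#' so recovery is exact up to floating point).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a \code{\link{knee_series}} with landmarks on all slices and a
#'   \code{truth} attribute holding the spec and the constructed TEA/trough
#'   slice indices (1-based).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  N <- spec$image_size
  n <- spec$n_slices
  w_max <- spec$tea_length / spec$pixel_spacing   # px, exact TEA span
  k_tea <- (n + 1L) %/% 2L
  k_trough <- if (n >= 3) min(n - 1L, k_tea + max(1L, n %/% 4L)) else k_tea

  res <- with_seed(spec$seed, {
    cx <- (N - 1) / 2 + runif(1, -12, 12)
    cy <- (N - 1) / 2 + runif(1, -12, 12)
    ml_frac <- runif(1, 0.45, 0.60)
    h_frac <- runif(1, 0.50, 0.62)
    noise <- lapply(seq_len(n), function(k)
      if (spec$noise_sd > 0)
        matrix(rnorm(N * N, 0, spec$noise_sd), N, N) else 0)
    list(cx = cx, cy = cy, ml_frac = ml_frac, h_frac = h_frac,
         noise = noise)
  })
  cx <- res$cx; cy <- res$cy

  rel_tea <- (seq_len(n) - k_tea) / max(n - 1, 1)
  w_k <- w_max * (1 - 0.20 * rel_tea^2)
  h_k <- res$h_frac * w_k
  q_k <- h_k / 2                                  # anterior semi-axis
  s_k <- (w_k / 4) * tan(spec$tea_pfa_angle * pi / 180)

  # feasibility: the widest slice plus noise margin must fit the field of view
  if (cx - w_max / 2 < 4 || cx + w_max / 2 > N - 5 ||
      cy + max(q_k + s_k) > N - 5 || cy - max(q_k) < 4)
    stop(sprintf(paste0("phantom geometry infeasible: TEA length %.2f cm at ",
                        "%.3f cm/px (%.0f px) does not fit a %d px field of view"),
                 spec$tea_length, spec$pixel_spacing, w_max, N))

  r <- spec$asymmetry_ratio
  geom <- vector("list", n)
  for (k in seq_len(n)) {
    w <- w_k[k]; q <- q_k[k]; s <- s_k[k]
    ae <- w / 4                                   # condyle semi-width
    cxm <- cx - w / 4; cxl <- cx + w / 4          # condyle centers
    ml <- res$ml_frac * w
    xa <- cx
    xb <- cx - (1 - r) * ml
    xc <- cx + r * ml
    top_at <- function(x) {
      dm <- (x - cxm) / ae; dl <- (x - cxl) / ae
      ym <- if (abs(dm) <= 1) cy - q * sqrt(1 - dm^2) else Inf
      yl <- if (abs(dl) <= 1) cy - q * sqrt(1 - dl^2) else Inf
      min(ym, yl)
    }
    ybc <- max(top_at(xb), top_at(xc)) + 0.5      # both aspects on/in mask
    geom[[k]] <- list(w = w, q = q, s = s, ae = ae, cxm = cxm, cxl = cxl,
                      xa = xa, xb = xb, xc = xc, ybc = ybc)
  }

  # trough depth: exact spec sulcus angle on the trough slice, strictly
  # shallower (quadratic in slice index) elsewhere so the selection rule
  # picks a unique slice
  gt <- geom[[k_trough]]
  t_tr <- solve_trough_depth(gt$xa - gt$xb, gt$xc - gt$xa, spec$sulcus_angle)
  ya_tr <- gt$ybc + t_tr
  d_tr <- cy - ya_tr                              # trough-to-TEA distance
  if (d_tr <= 1) stop("phantom geometry infeasible: trough reaches the TEA line")
  rel_tr <- (seq_len(n) - k_trough) / max(n - 1, 1)
  # depth-profile amplitude: as large as possible (up to a quarter of the
  # condylar height) while keeping every groove strictly below the aspects
  D0 <- 0.25 * max(h_k)
  for (k in seq_len(n)) {
    if (rel_tr[k] == 0) next
    margin <- ya_tr - (geom[[k]]$ybc + 0.5)
    if (margin <= 0.5)
      stop("phantom geometry infeasible: groove too shallow on slice ", k)
    D0 <- min(D0, 0.8 * margin / rel_tr[k]^2)
  }
  ya_k <- cy - (d_tr + D0 * rel_tr^2)
  for (k in seq_len(n)) {
    if (ya_k[k] <= geom[[k]]$ybc + 0.5)
      stop("phantom geometry infeasible: groove too shallow on slice ", k)
  }

  xs <- matrix(rep(0:(N - 1), each = N), N, N)    # X[y+1, x+1] = x
  ys <- matrix(rep(0:(N - 1), times = N), N, N)   # Y[y+1, x+1] = y
  slices <- vector("list", n)
  for (k in seq_len(n)) {
    g <- geom[[k]]
    ya <- ya_k[k]
    bmed <- g$q + g$s * (ys > cy)
    blat <- pmax(g$q - g$s, 0.25 * g$q) * (ys > cy) + g$q * (ys <= cy)
    in_med <- ((xs - g$cxm) / g$ae)^2 + ((ys - cy) / bmed)^2 <= 1
    in_lat <- ((xs - g$cxl) / g$ae)^2 + ((ys - cy) / blat)^2 <= 1
    vline <- ifelse(xs <= g$xa,
                    g$ybc + (ya - g$ybc) * (xs - g$xb) / (g$xa - g$xb),
                    ya + (g$ybc - ya) * (xs - g$xa) / (g$xc - g$xa))
    cut <- xs >= g$xb & xs <= g$xc & ys < vline
    mask <- (in_med | in_lat) & !cut
    img <- spec$background_hu + (spec$bone_hu - spec$background_hu) * mask +
      res$noise[[k]]
    lm <- rbind(A = c(g$xa, ya),
                B = c(g$xb, g$ybc),
                C = c(g$xc, g$ybc),
                D = c(cx - g$w / 2, cy),
                E = c(cx + g$w / 2, cy),
                F = c(g$cxm, cy + g$q + g$s),
                G = c(g$cxl, cy + g$q - g$s))
    colnames(lm) <- c("x", "y")
    slices[[k]] <- list(image = img, landmarks = lm)
  }

  series <- knee_series(slices, pixel_spacing = spec$pixel_spacing,
                        slice_thickness = spec$slice_thickness,
                        laterality = "right",
                        series_id = sprintf("phantom_seed%d", spec$seed))
  series$truth <- list(spec = spec, tea_slice = k_tea,
                       trough_slice = k_trough)
  if (spec$laterality == "left") {
    series <- mirror_series(series)
    series$series_id <- sprintf("phantom_seed%d", spec$seed)
  }
  series
}

#' Mirror a knee series across the vertical midline
#'
#' Flips images and x-coordinates horizontally and toggles laterality,
#' turning a right knee into the corresponding left knee. Landmark labels
#' follow the anatomy: the medial epicondyle D stays labelled D, and after
#' mirroring it sits at larger x, which is exactly the canonical orientation
#' of a left knee (for a right knee, x(D) < x(E)). The medial/lateral roles
#' thus swap sides in the image without any relabelling - relabelling would
#' silently turn the asymmetry ratio r into 1 - r. Mirroring twice is the
#' identity, and all four derived measurements are invariant under
#' mirroring.
#'
#' @param series a \code{\link{knee_series}}.
#' @return the mirrored \code{knee_series}.
#' @export
mirror_series <- function(series) {
  stopifnot(inherits(series, "knee_series"))
  out <- series
  for (k in seq_along(series$slices)) {
    s <- series$slices[[k]]
    W <- series$image_size
    if (!is.null(s$image)) {
      W <- ncol(s$image)
      s$image <- s$image[, W:1, drop = FALSE]
    }
    if (!is.null(s$landmarks)) {
      lm <- s$landmarks
      if (is.null(W))
        stop("cannot mirror an annotation-only series without image_size")
      lm[, 1] <- (W - 1) - lm[, 1]
      s$landmarks <- lm
    }
    out$slices[[k]] <- s
  }
  out$laterality <- if (series$laterality == "right") "left" else "right"
  out
}

#' Extract the landmark annotation table of a series
#'
#' @param series a \code{\link{knee_series}} with landmarks.
#' @return a data.frame with columns \code{series_id}, \code{slice_index}
#'   (0-based), \code{landmark_name}, \code{x_px}, \code{y_px}.
#' @export
series_annotations <- function(series) {
  rows <- list()
  for (k in seq_along(series$slices)) {
    lm <- series$slices[[k]]$landmarks
    if (is.null(lm)) next
    rows[[length(rows) + 1]] <- data.frame(
      series_id = series$series_id, slice_index = k - 1L,
      landmark_name = rownames(lm), x_px = lm[, 1], y_px = lm[, 2],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("series has no annotated slices")
  do.call(rbind, rows)
}
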