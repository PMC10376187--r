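#' Write a knee series to disk
#'
#' Writes the slice stack as a NIfTI volume (Hounsfield units, in-plane
#' spacing in the header in mm), a JSON sidecar carrying
#' \code{pixel_spacing} (cm/px), \code{slice_thickness}, \code{laterality}
#' and \code{series_id}, and - when landmarks are present - an annotation
#' CSV with columns \code{series_id, slice_index, landmark_name, x_px,
#' y_px} (0-based sub-pixel coordinates).
#'
#' @param series a \code{\link{knee_series}} with images.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named list).
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "knee_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgs <- lapply(series$slices, `[[`, "image")
  if (any(vapply(imgs, is.null, logical(1))))
    stop("cannot write a series without images")
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  vol <- array(0, dim = c(W, H, length(imgs)))
  for (k in seq_along(imgs)) vol[, , k] <- t(imgs[[k]])
  nii <- RNifti::asNifti(vol)
  RNifti::pixdim(nii) <- c(series$pixel_spacing * 10,
                           series$pixel_spacing * 10,
                           series$slice_thickness * 10)
  base <- file.path(dir, series$series_id)
  nii_path <- paste0(base, ".nii.gz")
  RNifti::writeNifti(nii, nii_path)
  sidecar <- paste0(base, ".json")
  jsonlite::write_json(list(series_id = series$series_id,
                            pixel_spacing = series$pixel_spacing,
                            slice_thickness = series$slice_thickness,
                            laterality = series$laterality,
                            image_size = series$image_size),
                       sidecar, auto_unbox = TRUE, digits = NA)
  paths <- list(nifti = nii_path, sidecar = sidecar)
  if (any(vapply(series$slices, function(s) !is.null(s$landmarks),
                 logical(1)))) {
    ann_path <- paste0(base, "_annotations.csv")
    write_annotations(series_annotations(series), ann_path)
    paths$annotations <- ann_path
  }
  invisible(paths)
}

#' Read a knee series from disk
#'
#' Reads a NIfTI volume written by \code{\link{write_series}} (or any
#' axial NIfTI stack), its JSON sidecar, and an annotation CSV when present
#' alongside. Pixel spacing is taken from the sidecar, falling back to the
#' NIfTI header; a missing or non-positive spacing is an error - physical
#' units are never silently assumed.
#'
#' @param path path to a \code{.nii}/\code{.nii.gz} file, or a directory
#'   containing exactly one.
#' @return a \code{\link{knee_series}}.
#' @export
read_series <- function(path) {
  if (dir.exists(path)) {
    cand <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    if (length(cand) != 1)
      stop("expected exactly one NIfTI volume in ", path, ", found ",
           length(cand))
    path <- cand
  }
  if (!file.exists(path)) stop("no such file: ", path)
  nii <- RNifti::readNifti(path)
  vol <- as.array(nii)
  if (length(dim(vol)) == 2) vol <- array(vol, dim = c(dim(vol), 1))
  base <- sub("\\.nii(\\.gz)?$", "", path)
  sidecar_path <- paste0(base, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else list()
  spacing <- sidecar$pixel_spacing
  if (is.null(spacing)) {
    pd <- RNifti::pixdim(nii)
    if (length(pd) >= 1 && is.finite(pd[1]) && pd[1] > 0)
      spacing <- pd[1] / 10  # header mm -> cm
  }
  if (is.null(spacing) || !is.finite(spacing) || spacing <= 0)
    stop("missing pixel spacing metadata for ", path,
         " (no sidecar value and no usable header pixdim)")
  sid <- sidecar$series_id %||% basename(base)
  slices <- lapply(seq_len(dim(vol)[3]), function(k)
    list(image = t(vol[, , k]), landmarks = NULL))
  series <- knee_series(slices, pixel_spacing = spacing,
                        slice_thickness = sidecar$slice_thickness %||% 0.25,
                        laterality = sidecar$laterality %||% "right",
                        series_id = sid)
  ann_path <- paste0(base, "_annotations.csv")
  if (file.exists(ann_path)) {
    ann <- read_annotations(ann_path)
    ann <- ann[ann$series_id == sid, ]
    for (k in sort(unique(ann$slice_index))) {
      a <- ann[ann$slice_index == k, ]
      lm <- as.matrix(a[match(LANDMARK_NAMES, a$landmark_name),
                        c("x_px", "y_px")])
      dimnames(lm) <- list(LANDMARK_NAMES, c("x", "y"))
      series$slices[[k + 1]]$landmarks <- lm
    }
  }
  series
}

validate_annotations <- function(df) {
  need <- c("series_id", "slice_index", "landmark_name", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$landmark_name), LANDMARK_NAMES)
  if (length(bad))
    stop("unknown landmark names: ", paste(bad, collapse = ", "))
  key <- paste(df$series_id, df$slice_index, df$landmark_name)
  if (anyDuplicated(key))
    stop("duplicate (series_id, slice_index, landmark_name) rows")
  invisible(df)
}

#' Read or write a landmark annotation table
#'
#' CSV schema: \code{series_id, slice_index, landmark_name, x_px, y_px};
#' one row per landmark per annotated slice, coordinates 0-based sub-pixel
#' floats. Writing then reading is the identity.
#'
#' @param path CSV file path.
#' @return for \code{read_annotations}, the validated data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df)
  df
}

#' @rdname read_annotations
#' @param df annotation data.frame to write.
#' @export
write_annotations <- function(df, path) {
  validate_annotations(df)
  write.csv(df[, c("series_id", "slice_index", "landmark_name",
                   "x_px", "y_px")],
            path, row.names = FALSE)
  invisible(path)
}

#' Save or load a two-stage model checkpoint
#'
#' Checkpoints embed the full configuration and seeds, so a loaded model
#' reproduces its predictions exactly.
#'
#' @param model a \code{two_stage_model}.
#' @param path file path (RDS).
#' @return \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "two_stage_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "two_stage_model"))
    stop("file does not contain a two-stage model checkpoint")
  model
}

#' Write per-knee measurement results
#'
#' @param measurements a \code{knee_measurements} object or list of them.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
write_measurements <- function(measurements, path) {
  if (inherits(measurements, "knee_measurements"))
    measurements <- list(measurements)
  df <- do.call(rbind, lapply(measurements, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
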