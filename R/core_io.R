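# Typed containers and NIfTI/JSON/CSV I/O shared by all downstream stages.
#
# Conventions: voxel grids are base-R 3-D arrays (column-major, first index
# fastest); masks and volumes must share a grid -- no cross-modality
# resampling is performed, features are computed on each modality's native
# grid. Acquisition physics (b-values, flip angles, tracer dose) travel in a
# JSON sidecar because NIfTI headers cannot carry them.

#' Construct an image volume
#'
#' A regular 3-D voxel grid with physical spacing, the basic container for
#' parametric maps, PET volumes and single diffusion-weighted frames.
#'
#' @param voxels Numeric 3-D array of voxel values (modality-specific units).
#' @param spacing Numeric length-3 vector, voxel size in mm per axis.
#' @param origin Numeric length-3 vector, position of voxel (1,1,1) in mm.
#' @param timepoint Optional timepoint label, `"PRE"` or `"INTRA"`.
#' @return An object of class `image_volume`.
#' @export
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4))
#' voxel_volume_ml(vol)
image_volume <- function(voxels, spacing, origin = c(0, 0, 0), timepoint = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array, got ", length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite")
  if (!is.null(timepoint)) timepoint <- match.arg(timepoint, c("PRE", "INTRA"))
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         timepoint = timepoint),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, spacing %s mm%s\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              if (is.null(x$timepoint)) "" else paste0(", ", x$timepoint)))
  invisible(x)
}

#' Volume of one voxel in mL
#' @param volume An `image_volume` (or anything with a `spacing` field).
#' @return Voxel volume in mL.
#' @export
voxel_volume_ml <- function(volume) prod(volume$spacing) / 1000

#' Construct a binary ROI mask
#'
#' @param mask Logical (or 0/1) 3-D array aligned to an [image_volume()].
#' @param observer_id Observer label, 1 or 2.
#' @param lesion_id Optional lesion identifier.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, observer_id = 1L, lesion_id = "primary") {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("'mask' must be a 3-D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask may not contain NA")
  if (!observer_id %in% c(1L, 2L)) stop("'observer_id' must be 1 or 2")
  structure(list(mask = mask, observer_id = as.integer(observer_id),
                 lesion_id = lesion_id),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d voxels set, observer %d\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask), x$observer_id))
  invisible(x)
}

#' Construct a dynamic (4-D) image series
#'
#' Time-resolved volumes sharing one grid, e.g. a dynamic contrast-enhanced
#' acquisition: by default 75 frames of 4.16 s with the contrast bolus
#' administered after 3 baseline frames.
#'
#' @param frames 4-D array (x, y, z, t).
#' @param spacing Voxel spacing in mm.
#' @param frame_duration_s Seconds per dynamic frame.
#' @param n_baseline_frames Number of pre-bolus frames.
#' @param flip_angle_deg,tr_ms,te_ms Spoiled-gradient-echo acquisition settings.
#' @param origin Grid origin in mm.
#' @param timepoint Optional `"PRE"`/`"INTRA"` label.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, spacing, frame_duration_s = 4.16,
                           n_baseline_frames = 3L, flip_angle_deg = 12,
                           tr_ms = 4.8, te_ms = 2.4, origin = c(0, 0, 0),
                           timepoint = NULL) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 4L) stop("'frames' must be a 4-D array (x,y,z,t)")
  if (frame_duration_s <= 0) stop("'frame_duration_s' must be positive")
  if (n_baseline_frames < 1L) stop("'n_baseline_frames' must be >= 1")
  if (any(!is.finite(frames))) stop("frame values must be finite")
  structure(
    list(frames = frames, spacing = as.numeric(spacing),
         frame_duration_s = frame_duration_s,
         n_baseline_frames = as.integer(n_baseline_frames),
         flip_angle_deg = flip_angle_deg, tr_ms = tr_ms, te_ms = te_ms,
         origin = as.numeric(origin), timepoint = timepoint),
    class = "dynamic_series")
}

#' Frame mid-times of a dynamic series, in minutes
#' @param series A `dynamic_series`.
#' @return Numeric vector of frame start times in minutes (first frame at 0).
#' @export
frame_times_min <- function(series) {
  n <- dim(series$frames)[4]
  (seq_len(n) - 1) * series$frame_duration_s / 60
}

#' Construct acquisition metadata
#'
#' Physics parameters required by the forward models and fitters that NIfTI
#' headers cannot hold; serialized as a JSON sidecar.
#'
#' @param b_values Diffusion b-values in s/mm^2; must be nonnegative, strictly
#'   increasing and include 0. Default is the 10-value ladder
#'   0/10/25/50/75/150/300/500/750/1000.
#' @param vfa_angles_deg Variable flip angles for T1 mapping, degrees in
#'   (0, 90), default 2/5/10/15/20.
#' @param injected_dose_MBq Injected tracer activity in MBq.
#' @param body_weight_kg Patient body weight in kg.
#' @param relaxivity_r1 Contrast-agent longitudinal relaxivity in
#'   L mmol^-1 s^-1 (default 3.5, typical for Gd-DOTA at 3 T).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(b_values = c(0, 10, 25, 50, 75, 150, 300, 500, 750, 1000),
                             vfa_angles_deg = c(2, 5, 10, 15, 20),
                             injected_dose_MBq = 175,
                             body_weight_kg = 70,
                             relaxivity_r1 = 3.5) {
  b_values <- as.numeric(b_values)
  if (any(b_values < 0) || is.unsorted(b_values, strictly = TRUE))
    stop("'b_values' must be nonnegative and strictly increasing")
  if (b_values[1] != 0) stop("'b_values' must include 0")
  vfa_angles_deg <- as.numeric(vfa_angles_deg)
  if (anyDuplicated(vfa_angles_deg) || any(vfa_angles_deg <= 0) ||
      any(vfa_angles_deg >= 90))
    stop("'vfa_angles_deg' must be distinct angles in (0, 90)")
  if (injected_dose_MBq <= 0 || body_weight_kg <= 0)
    stop("dose and weight must be positive")
  structure(list(b_values = b_values, vfa_angles_deg = vfa_angles_deg,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg,
                 relaxivity_r1 = relaxivity_r1),
            class = "acquisition_meta")
}

#' Write acquisition metadata as a JSON sidecar
#' @param meta An `acquisition_meta`.
#' @param path Output path (conventionally `<image>.json`).
#' @return `path`, invisibly.
#' @export
write_meta <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acquisition-metadata JSON sidecar
#' @param path Path written by [write_meta()].
#' @return An `acquisition_meta`.
#' @export
read_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_meta(b_values = x$b_values, vfa_angles_deg = x$vfa_angles_deg,
                   injected_dose_MBq = x$injected_dose_MBq,
                   body_weight_kg = x$body_weight_kg,
                   relaxivity_r1 = x$relaxivity_r1)
}

#' Load a NIfTI volume, mask or dynamic series
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param kind One of `"volume"` (3-D scalar), `"mask"` (3-D binary) or
#'   `"dynamic"` (4-D).
#' @param ... Extra fields passed to the container constructor (e.g.
#'   `frame_duration_s` for dynamics, `observer_id` for masks).
#' @return An `image_volume`, `roi_mask` or `dynamic_series`.
#' @export
load_volume <- function(path, kind = c("volume", "mask", "dynamic"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (any(!is.finite(arr))) stop("non-finite voxel values in ", path)
  if (kind == "dynamic") {
    if (length(d) != 4L)
      stop("kind='dynamic' requires a 4-D payload, got ", length(d), "-D")
    dynamic_series(arr, spacing = pd[1:3], ...)
  } else {
    if (length(d) != 3L)
      stop("kind='", kind, "' requires a 3-D payload, got ", length(d), "-D")
    if (kind == "mask") roi_mask(arr != 0, ...)
    else image_volume(arr, spacing = pd[1:3], ...)
  }
}

#' Write a volume, mask or dynamic series as NIfTI
#' @param x An `image_volume`, `roi_mask` or `dynamic_series`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "roi_mask")) x$mask + 0 else
         if (inherits(x, "dynamic_series")) x$frames else x$voxels
  spacing <- if (inherits(x, "roi_mask")) c(1, 1, 1) else x$spacing
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L)
    c(spacing, 1) else spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract ROI voxel values
#'
#' Returns the voxel values of `volume` where the mask is set, in stable
#' lexicographic voxel-index order (first index fastest), the per-voxel input
#' to median/histogram feature extraction over delineated 3-D ROIs.
#'
#' @param volume An `image_volume`.
#' @param mask An `roi_mask` (or logical array) on the same grid.
#' @return Numeric vector of length `sum(mask)`.
#' @export
extract_roi_values <- function(volume, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(volume$voxels), dim(m)))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match volume shape ",
         paste(dim(volume$voxels), collapse = "x"))
  if (!any(m)) stop("empty mask")
  volume$voxels[m]
}

#' ROI volume in mL
#'
#' Gross tumor volume of a delineation: number of set voxels times the voxel
#' volume, in mL.
#'
#' @param mask An `roi_mask` or logical array.
#' @param spacing Voxel spacing in mm (length 3).
#' @return Volume in mL.
#' @export
roi_volume_ml <- function(mask, spacing) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  n <- sum(m)
  if (n == 0) stop("empty mask")
  n * prod(spacing) / 1000
}
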