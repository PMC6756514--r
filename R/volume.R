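#' 4D time-series volume
#'
#' The universal carrier between pipeline stages: a 4D scalar field
#' (x, y, z, t) with its frame interval (TR, seconds) and a 3D brain mask.
#' Orientation/affine metadata read from a NIfTI header is passed through
#' unmodified in `space_meta`.
#'
#' @param data 4D numeric array (x, y, z, t), at least 2 frames.
#' @param frame_interval_s seconds per frame (TR), must be positive.
#' @param mask 3D logical array matching the spatial dimensions; defaults to
#'   voxels with nonzero temporal variance.
#' @param space_meta NIfTI header (or NULL) carried through unmodified.
#' @return An object of class `ts_volume`.
#' @export
ts_volume <- function(data, frame_interval_s, mask = NULL, space_meta = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("a time-series volume needs at least 2 frames")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  if (is.null(mask)) {
    mask <- array(.voxel_variance(data) > 0, dim(data)[1:3])
  }
  if (!identical(dim(mask), dim(data)[1:3]))
    stop("`mask` shape must equal the spatial shape of `data`")
  structure(
    list(data = data, frame_interval_s = as.numeric(frame_interval_s),
         mask = array(as.logical(mask), dim(data)[1:3]),
         space_meta = space_meta),
    class = "ts_volume")
}

.voxel_variance <- function(data) {
  d <- dim(data)
  m <- matrix(data, prod(d[1:3]), d[4])
  rowSums((m - rowMeans(m))^2) / (d[4] - 1)
}

#' @export
print.ts_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_volume> %d x %d x %d voxels, %d frames @ %.4g s (%.4g s total)\n",
              d[1], d[2], d[3], d[4], x$frame_interval_s,
              d[4] * x$frame_interval_s))
  cat(sprintf("  mask: %d / %d voxels\n", sum(x$mask), prod(d[1:3])))
  invisible(x)
}

#' @export
dim.ts_volume <- function(x) dim(x$data)

n_frames <- function(vol) dim(vol$data)[4]

#' Frame acquisition times
#'
#' @param vol a `ts_volume`.
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(vol) (seq_len(n_frames(vol)) - 1) * vol$frame_interval_s

#' Extract the masked voxel matrix
#'
#' @param vol a `ts_volume`.
#' @return A frames-by-voxels numeric matrix holding the in-mask voxels, in
#'   linear (column-major) spatial order.
#' @export
vox_matrix <- function(vol) {
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m[as.vector(vol$mask), , drop = FALSE])
}

#' Replace the masked voxel matrix
#'
#' Inverse of [vox_matrix()]: writes a frames-by-voxels matrix back into the
#' in-mask voxels of `vol` and returns the updated volume.
#'
#' @param vol a `ts_volume`.
#' @param M frames-by-voxels matrix, dimensions matching `vox_matrix(vol)`.
#' @return The updated `ts_volume`.
#' @export
set_vox_matrix <- function(vol, M) {
  d <- dim(vol$data)
  stopifnot(nrow(M) == d[4], ncol(M) == sum(vol$mask))
  flat <- matrix(vol$data, prod(d[1:3]), d[4])
  flat[as.vector(vol$mask), ] <- t(M)
  vol$data <- array(flat, d)
  vol
}

#' Global (brain-mean) signal
#'
#' @param vol a `ts_volume`.
#' @return Numeric vector, one value per frame: mean over in-mask voxels.
#' @export
global_signal <- function(vol) rowMeans(vox_matrix(vol))

#' Read a 4D NIfTI image as a time-series volume
#'
#' The frame interval is taken from `pixdim[4]` of the header; the default
#' mask excludes zero-variance voxels. The full header is retained in
#' `space_meta` and written back by [write_volume()].
#'
#' @param path path to a NIfTI-1 4D image.
#' @param frame_interval_s optional override of the header frame interval.
#' @return A `ts_volume`.
#' @export
read_volume <- function(path, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D image, got ", length(dim(img)), "D: ", path)
  if (is.null(frame_interval_s)) {
    frame_interval_s <- RNifti::pixdim(img)[4]
    if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
      stop("non-positive frame interval (pixdim[4]) in header of ", path)
  }
  ts_volume(array(as.numeric(img), dim(img)), frame_interval_s,
            space_meta = RNifti::niftiHeader(img))
}

#' Write a time-series volume as NIfTI
#'
#' @param vol a `ts_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; the default `"double"` preserves values
#'   to write/read round-trip identity.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  img <- RNifti::asNifti(vol$data, reference = vol$space_meta)
  pd <- RNifti::pixdim(img)
  pd[4] <- vol$frame_interval_s
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 3D map (e.g. a lag map) as float NIfTI
#'
#' Untracked/undefined voxels are stored as NaN so that sign and units
#' survive into downstream tools.
#'
#' @param map 3D numeric array.
#' @param path output path.
#' @param reference optional NIfTI header for orientation metadata.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, reference = NULL) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  map[is.na(map)] <- NaN
  img <- RNifti::asNifti(map, reference = reference)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a motion-parameter table
#'
#' Six columns per frame: 3 translations (mm) and 3 rotations (degrees),
#' whitespace/tab separated, no header.
#'
#' @param path path to the text file.
#' @return Data frame with columns tx, ty, tz, rx, ry, rz.
#' @export
read_motion <- function(path) {
  m <- utils::read.table(path, header = FALSE)
  if (ncol(m) != 6L) stop("motion table must have 6 columns, got ", ncol(m))
  names(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' @rdname read_motion
#' @param motion data frame as returned by [read_motion()].
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a task event list
#'
#' Tab-separated with header columns `onset`, `duration` (seconds) and
#' optionally `label`. Onsets must be non-negative and strictly increasing;
#' durations non-negative.
#'
#' @param path path to the text file.
#' @return Data frame with columns onset, duration, label.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_events(ev)
}

#' @rdname read_events
#' @param events event data frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_events <- function(events) {
  stopifnot(is.data.frame(events), all(c("onset", "duration") %in% names(events)))
  if (any(events$onset < 0)) stop("event onsets must be non-negative")
  if (is.unsorted(events$onset, strictly = TRUE))
    stop("event onsets must be strictly increasing")
  if (any(events$duration < 0)) stop("event durations must be non-negative")
  if (is.null(events$label)) events$label <- rep("event", nrow(events))
  events
}
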