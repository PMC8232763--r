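# NIfTI IO and intensity preprocessing.
#
# On disk, NIfTI stores axes (x, y, z); in memory every volume is indexed
# (slice z, row y, col x) because the fine stage iterates axial slices.
# read/write permute accordingly and carry pixdim along, reversed.

#' Read a 3D volume from a NIfTI file
#'
#' Reads a \code{.nii}/\code{.nii.gz} file into a volume object, permuting
#' the on-disk (x, y, z) axes to the in-memory (slice, row, col) order and
#' taking voxel spacing from the header \code{pixdim}. The origin is taken
#' from the q-offset when present (informational only).
#'
#' @param path path to an existing NIfTI file.
#' @param kind one of \code{"image"}, \code{"label"}, \code{"probability"} —
#'   the container the payload should be validated into.
#' @return An [ImageVolume()], [LabelVolume()] or [ProbabilityVolume()].
#' @seealso [writeVolume()], [normalizeIntensity()]
#' @export
readVolume <- function(path, kind = c("image", "label", "probability")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header/payload in '",
                                           path, "': ", conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("not a 3D volume: '", path, "' has ", length(dim(img)), " dimensions")
  hdr <- RNifti::niftiHeader(img)
  spacing <- rev(RNifti::pixdim(img)[1:3])
  origin <- rev(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  arr <- aperm(unclass(img), c(3, 2, 1))
  attributes(arr) <- list(dim = dim(arr))
  switch(kind,
    image = ImageVolume(arr, spacing, origin),
    label = LabelVolume(arr, spacing, origin),
    probability = ProbabilityVolume(arr, spacing, origin))
}

#' Write a volume to a NIfTI file
#'
#' Labels are written as \code{uint8}, images and probabilities as
#' \code{float32}. Round trips are exact for labels and within float32
#' representation for images/probabilities.
#'
#' @param vol an [ImageVolume()], [LabelVolume()] or [ProbabilityVolume()].
#' @param path output path (\code{.nii} or \code{.nii.gz}); the parent
#'   directory must exist.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  arr <- aperm(vol@data, c(3, 2, 1))
  dtype <- if (is(vol, "LabelVolume")) "uint8" else "float"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol@spacing)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Clip and rescale raw intensities to [0, 1]
#'
#' Raw scanner intensities are truncated to \code{[lo, hi]} and mapped
#' linearly onto \code{[0, 1]}: \code{(clip(v, lo, hi) - lo) / (hi - lo)}.
#' The default bounds (-1000, 2000) cover air through dense bone/metal on
#' the HU scale and are applied identically to CBCT-like data whose stored
#' values are not calibrated HU. The map is monotone non-decreasing and
#' idempotent on already-normalized input with \code{lo = 0, hi = 1}.
#'
#' @param vol an [ImageVolume()] (or bare numeric array).
#' @param lo,hi clip bounds, \code{hi > lo}.
#' @return Same kind as the input, values in \code{[0, 1]}, spacing kept.
#' @export
normalizeIntensity <- function(vol, lo = -1000, hi = 2000) {
  if (hi <= lo) stop("normalization bounds require hi > lo")
  if (is(vol, "Volume")) {
    ImageVolume((pmin(pmax(vol@data, lo), hi) - lo) / (hi - lo),
                vol@spacing, vol@origin)
  } else {
    (pmin(pmax(vol, lo), hi) - lo) / (hi - lo)
  }
}
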