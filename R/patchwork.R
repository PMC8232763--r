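# Crop/UnCrop, training-patch sampling with hard negative mining, and
# sliding-window tiling + mean fusion for coarse-stage inference.

#' Crop a sub-volume
#'
#' Copies the window described by \code{spec} out of a volume; spacing and
#' origin are inherited. \code{UnCrop} (placing predictions back) is
#' performed by [fusePatches()].
#'
#' @param vol an [ImageVolume()], [LabelVolume()] or [ProbabilityVolume()].
#' @param spec a [SubVolumeSpec()] within the volume bounds.
#' @return A volume of the same kind with \code{dim == spec@size}.
#' @export
cropVolume <- function(vol, spec) {
  stopifnot(is(vol, "Volume"), is(spec, "SubVolumeSpec"))
  d <- dim(vol@data)
  e <- spec@start + spec@size - 1L
  if (any(e > d)) stop("crop window exceeds volume bounds")
  sub <- vol@data[spec@start[1]:e[1], spec@start[2]:e[2], spec@start[3]:e[3],
                  drop = FALSE]
  initialize(vol, data = sub, spacing = vol@spacing, origin = vol@origin)
}

#' Sample a training sub-volume with hard negative mining
#'
#' With probability \code{positiveFraction} the patch is guaranteed to
#' contain foreground: a foreground voxel is drawn uniformly and the window
#' position is drawn uniformly among all positions covering it. Otherwise
#' the window position is uniform over all valid starts, so patches from
#' empty background regions occur and act as hard negative mining against
#' false positives. Sampling uses the current RNG state.
#'
#' @param image an [ImageVolume()].
#' @param label the paired [LabelVolume()].
#' @param size integer(3) patch size, componentwise <= the volume shape.
#' @param positiveFraction probability in [0, 1] of forcing foreground.
#' @return \code{list(image =, label =, spec =)} — the two patches and the
#'   window they came from.
#' @export
sampleTrainingSubvolume <- function(image, label, size,
                                    positiveFraction = 0.5) {
  stopifnot(is(image, "ImageVolume"), is(label, "LabelVolume"))
  if (!sameGeometry(image, label)) stop("image/label geometry mismatch")
  size <- as.integer(size)
  d <- dim(image@data)
  if (any(d < size)) stop("volume smaller than the requested patch")
  if (positiveFraction < 0 || positiveFraction > 1)
    stop("positiveFraction must be in [0, 1]")
  maxStart <- d - size + 1L

  wantPositive <- runif(1) < positiveFraction
  if (wantPositive && !any(label@data == 1L)) {
    warning("positive patch requested but label is empty; sampling uniformly")
    wantPositive <- FALSE
  }
  if (wantPositive) {
    fg <- which(label@data == 1L, arr.ind = TRUE)
    v <- fg[sample.int(nrow(fg), 1L), ]
    lo <- pmax(1L, v - size + 1L)
    hi <- pmin(maxStart, v)
    start <- lo + vapply(hi - lo + 1L, sample.int, integer(1), size = 1L) - 1L
  } else {
    start <- vapply(maxStart, sample.int, integer(1), size = 1L)
  }
  spec <- SubVolumeSpec(start, size)
  list(image = cropVolume(image, spec), label = cropVolume(label, spec),
       spec = spec)
}

#' Tile a volume into sliding-window specs
#'
#' Produces windows of \code{patchSize} with stride
#' \code{patchSize - overlap} per axis; the last window per axis is clamped
#' to end at the volume boundary, so the union of windows covers every
#' voxel. Windows are ordered z-major (slice index varies slowest).
#'
#' @param shape integer(3) volume shape.
#' @param patchSize integer(3), componentwise <= shape.
#' @param overlap integer(3) (or scalar), componentwise < patchSize.
#' @return A list of [SubVolumeSpec()].
#' @export
tileVolume <- function(shape, patchSize, overlap = 0) {
  shape <- as.integer(shape)
  patchSize <- as.integer(rep_len(patchSize, 3))
  overlap <- as.integer(rep_len(overlap, 3))
  if (any(overlap >= patchSize)) stop("overlap must be < patchSize")
  if (any(patchSize > shape)) stop("patchSize exceeds volume shape")
  stride <- patchSize - overlap
  axisStarts <- function(n, p, s) {
    st <- seq.int(1L, max(1L, n - p + 1L), by = s)
    if (st[length(st)] + p - 1L < n) st <- c(st, n - p + 1L)
    st[length(st)] <- n - p + 1L  # clamp the final window to the boundary
    unique(st)
  }
  zs <- axisStarts(shape[1], patchSize[1], stride[1])
  ys <- axisStarts(shape[2], patchSize[2], stride[2])
  xs <- axisStarts(shape[3], patchSize[3], stride[3])
  specs <- vector("list", length(zs) * length(ys) * length(xs))
  k <- 0L
  for (z in zs) for (y in ys) for (x in xs) {
    k <- k + 1L
    specs[[k]] <- SubVolumeSpec(c(z, y, x), patchSize)
  }
  specs
}

#' Fuse overlapping patch predictions into a full volume
#'
#' Places every probability patch back at its window (UnCrop) and sets each
#' output voxel to the arithmetic mean of all patch predictions covering
#' it — a symmetric, order-independent fusion. Voxels covered by no patch
#' are an error.
#'
#' @param specs list of [SubVolumeSpec()].
#' @param patches list of probability patches (arrays or
#'   [ProbabilityVolume()]), each matching its spec's size.
#' @param shape integer(3) output shape.
#' @param spacing,origin geometry for the returned volume.
#' @return A [ProbabilityVolume()].
#' @export
fusePatches <- function(specs, patches, shape, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (length(specs) != length(patches))
    stop("specs and patches must have equal length")
  shape <- as.integer(shape)
  acc <- array(0, shape)
  cnt <- array(0L, shape)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    p <- patches[[i]]
    if (is(p, "Volume")) p <- p@data
    if (!identical(dim(p), as.integer(sp@size)))
      stop("patch ", i, " does not match its spec size")
    e <- sp@start + sp@size - 1L
    if (any(e > shape)) stop("spec ", i, " exceeds the output shape")
    zi <- sp@start[1]:e[1]; yi <- sp@start[2]:e[2]; xi <- sp@start[3]:e[3]
    acc[zi, yi, xi] <- acc[zi, yi, xi, drop = FALSE] + p
    cnt[zi, yi, xi] <- cnt[zi, yi, xi] + 1L
  }
  if (any(cnt == 0L)) stop("tiling does not cover every voxel")
  ProbabilityVolume(acc / cnt, spacing, origin)
}
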