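#' @import methods
NULL

# ---------------------------------------------------------------------------
# Volumes
# ---------------------------------------------------------------------------

#' @rdname ImageVolume
#' @export
setClass("Volume", representation("VIRTUAL",
  data = "array", spacing = "numeric", origin = "numeric"))

setValidity("Volume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array (slice, row, col)")
  if (any(d < 1L)) return("all shape components must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be 3 positive finite values (dz, dy, dx) in mm")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  TRUE
})

#' Volume containers
#'
#' S4 containers for 3D scan data indexed \code{(slice, row, col)} with
#' physical voxel spacing \code{(dz, dy, dx)} in millimetres.
#' \code{ImageVolume} holds real-valued intensities (raw CT/CBCT-like, or
#' normalized to \code{[0,1]}), \code{LabelVolume} a binary mask (ground
#' truth or a hard prediction), and \code{ProbabilityVolume} a soft
#' prediction in \code{[0,1]}.
#'
#' @param data 3D numeric array, first index the axial slice.
#' @param spacing numeric(3), voxel spacing (dz, dy, dx) in mm.
#' @param origin numeric(3), physical offset in mm (informational).
#' @return An object of the corresponding class.
#' @examples
#' v <- ImageVolume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(1, .5, .5))
#' dim(v)
#' volSpacing(v)
#' @aliases Volume-class ImageVolume-class LabelVolume-class
#'   ProbabilityVolume-class
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = as.array(data), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname ImageVolume
#' @export
setClass("ImageVolume", contains = "Volume")

setValidity("ImageVolume", function(object) {
  if (any(!is.finite(object@data))) return("all intensities must be finite")
  TRUE
})

#' @rdname ImageVolume
#' @export
setClass("LabelVolume", contains = "Volume")

setValidity("LabelVolume", function(object) {
  v <- object@data
  if (any(v != 0 & v != 1)) return("label values must be exactly 0 or 1")
  TRUE
})

#' @rdname ImageVolume
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- as.array(data)
  storage.mode(d) <- "integer"
  new("LabelVolume", data = d, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname ImageVolume
#' @export
setClass("ProbabilityVolume", contains = "Volume")

setValidity("ProbabilityVolume", function(object) {
  v <- object@data
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' @rdname ImageVolume
#' @export
ProbabilityVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ProbabilityVolume", data = as.array(data) * 1,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' @describeIn ImageVolume the voxel grid as a plain array.
#' @param x,object a volume.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname ImageVolume
#' @export
setMethod("volData", "Volume", function(x) x@data)

#' @describeIn ImageVolume voxel spacing (dz, dy, dx) in mm.
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname ImageVolume
#' @export
setMethod("volSpacing", "Volume", function(x) x@spacing)

#' @describeIn ImageVolume physical origin in mm.
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))
#' @rdname ImageVolume
#' @export
setMethod("volOrigin", "Volume", function(x) x@origin)

#' @rdname ImageVolume
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(class(object), ": ", d[1], " x ", d[2], " x ", d[3],
      " voxels (slice x row x col), spacing ",
      paste(signif(object@spacing, 4), collapse = " x "), " mm\n", sep = "")
  cat("  intensity range: [", signif(min(object@data), 6), ", ",
      signif(max(object@data), 6), "]\n", sep = "")
})

# two volumes share a grid if shapes match and spacings agree to rounding
sameGeometry <- function(a, b, tol = 1e-8) {
  identical(dim(a@data), dim(b@data)) &&
    all(abs(a@spacing - b@spacing) < tol)
}

# ---------------------------------------------------------------------------
# Sub-volume crops
# ---------------------------------------------------------------------------

#' Sub-volume crop window
#'
#' A crop window given by its 1-based start voxel indices and its size, used
#' both for training-patch extraction and for sliding-window tiling. Bound
#' to a volume, a spec must satisfy \code{start >= 1} and
#' \code{start + size - 1 <= dim(volume)} componentwise.
#'
#' @param start integer(3) 1-based (slice, row, col) start indices.
#' @param size integer(3) window size in voxels.
#' @return A \code{SubVolumeSpec}.
#' @examples
#' SubVolumeSpec(c(1, 1, 1), c(16, 32, 32))
#' @aliases SubVolumeSpec-class
#' @export
SubVolumeSpec <- function(start, size) {
  new("SubVolumeSpec", start = as.integer(start), size = as.integer(size))
}

#' @rdname SubVolumeSpec
#' @export
setClass("SubVolumeSpec", representation(start = "integer", size = "integer"))

setValidity("SubVolumeSpec", function(object) {
  if (length(object@start) != 3L || length(object@size) != 3L)
    return("start and size must each have 3 components")
  if (any(object@start < 1L)) return("start indices must be >= 1")
  if (any(object@size < 1L)) return("size components must be >= 1")
  TRUE
})

setMethod("show", "SubVolumeSpec", function(object) {
  cat("SubVolumeSpec: start (", paste(object@start, collapse = ", "),
      "), size (", paste(object@size, collapse = ", "), ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# Loss weights
# ---------------------------------------------------------------------------

#' Compound loss weights
#'
#' Weights of the compound objective
#' \eqn{L = \omega_1 L_{BCE} + \omega_2 L_{Dice}}. Both default to 0.5.
#' \code{smooth} is the Dice smoothing constant added to numerator and
#' denominator so that the loss is defined (and zero) for two empty masks.
#'
#' @param omega1 weight of the binary cross-entropy term.
#' @param omega2 weight of the Dice term.
#' @param smooth Dice smoothing constant.
#' @return A \code{LossWeights} object.
#' @aliases LossWeights-class
#' @export
LossWeights <- function(omega1 = 0.5, omega2 = 0.5, smooth = 1e-6) {
  new("LossWeights", omega1 = as.numeric(omega1), omega2 = as.numeric(omega2),
      smooth = as.numeric(smooth))
}

#' @rdname LossWeights
#' @export
setClass("LossWeights",
  representation(omega1 = "numeric", omega2 = "numeric", smooth = "numeric"))

setValidity("LossWeights", function(object) {
  if (object@omega1 < 0 || object@omega2 < 0) return("weights must be >= 0")
  if (object@omega1 + object@omega2 <= 0) return("omega1 + omega2 must be > 0")
  if (object@smooth < 0) return("smooth must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Network configuration
# ---------------------------------------------------------------------------

#' SegUnet architecture configuration
#'
#' Structural description of a SegUnet encoder-decoder: \code{depth} encoder
#' blocks (each two conv + batch-norm + ReLU layers followed by factor-2 max
#' pooling that records argmax indices) and \code{depth} mirrored decoder
#' blocks (max unpooling at the recorded indices, concatenation of the
#' same-level encoder features, then two conv + BN + ReLU layers), closed by
#' a 1x1(x1) convolution and a sigmoid. Filter widths start at
#' \code{baseFilters} and double per encoder level. The reference
#' configuration is \code{baseFilters = 32, depth = 4}; desk-scale
#' configurations (e.g. \code{baseFilters = 4, depth = 2}) are first-class.
#'
#' @param inChannels input channel count (1 for the coarse 3D net, 3 for the
#'   recurrent 2D net).
#' @param baseFilters filters in the first encoder block.
#' @param depth number of encoder (= decoder) blocks.
#' @param spatialRank 2 or 3.
#' @param kernelSize odd conv kernel extent per spatial axis (default 3).
#' @param outChannels output channels (1: foreground probability).
#' @return A \code{NetworkConfig}.
#' @aliases NetworkConfig-class
#' @export
NetworkConfig <- function(inChannels = 1, baseFilters = 32, depth = 4,
                          spatialRank = 3, kernelSize = 3, outChannels = 1) {
  new("NetworkConfig", inChannels = as.integer(inChannels),
      baseFilters = as.integer(baseFilters), depth = as.integer(depth),
      spatialRank = as.integer(spatialRank),
      kernelSize = as.integer(kernelSize),
      outChannels = as.integer(outChannels))
}

#' @rdname NetworkConfig
#' @export
setClass("NetworkConfig", representation(
  inChannels = "integer", baseFilters = "integer", depth = "integer",
  spatialRank = "integer", kernelSize = "integer", outChannels = "integer"))

setValidity("NetworkConfig", function(object) {
  if (object@baseFilters < 1L) return("baseFilters must be >= 1")
  if (object@depth < 1L) return("depth must be >= 1")
  if (!object@spatialRank %in% c(2L, 3L)) return("spatialRank must be 2 or 3")
  if (object@kernelSize < 1L || object@kernelSize %% 2L == 0L)
    return("kernelSize must be odd")
  if (object@inChannels < 1L || object@outChannels < 1L)
    return("channel counts must be >= 1")
  TRUE
})

setMethod("show", "NetworkConfig", function(object) {
  w <- object@baseFilters * 2^(seq_len(object@depth) - 1)
  cat("NetworkConfig: ", object@spatialRank, "D SegUnet, in=",
      object@inChannels, ", encoder widths ", paste(w, collapse = "-"),
      ", depth ", object@depth, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Training configuration
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Settings shared by coarse and fine training. Adam is the optimizer; the
#' reference learning rate is 1e-4. \code{patchSize} is the training
#' sub-volume (reference 64 x 128 x 128; desk-scale runs override it).
#' \code{positiveFraction} is the probability that a sampled training patch
#' is forced to contain foreground; the complementary patches are drawn
#' uniformly and act as hard negative mining. \code{bpttWindow} is the
#' number of recurrent steps unrolled with gradient during fine-stage
#' training (truncated BPTT); \code{teacherForcing = TRUE} feeds the ground
#' truth of slice t-1 instead of the model's own previous soft prediction.
#'
#' @param learningRate Adam learning rate (> 0).
#' @param epochs training epochs (>= 0).
#' @param batchSize patches accumulated per optimizer step.
#' @param patchSize integer(3) training sub-volume size.
#' @param patchesPerCase patches sampled per case per epoch (coarse stage).
#' @param positiveFraction probability in [0,1] of a foreground-covering patch.
#' @param lossWeights a [LossWeights()].
#' @param bpttWindow recurrent steps unrolled with gradient (>= 1).
#' @param teacherForcing logical; see above.
#' @param overlap integer(3) sliding-window overlap for coarse inference.
#' @param seed RNG seed controlling init, sampling and noise.
#' @return A \code{TrainConfig}.
#' @aliases TrainConfig-class
#' @export
TrainConfig <- function(learningRate = 1e-4, epochs = 10, batchSize = 1,
                        patchSize = c(64, 128, 128), patchesPerCase = 2,
                        positiveFraction = 0.5, lossWeights = LossWeights(),
                        bpttWindow = 4, teacherForcing = FALSE,
                        overlap = c(8, 16, 16), seed = 1) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      patchSize = as.integer(patchSize),
      patchesPerCase = as.integer(patchesPerCase),
      positiveFraction = as.numeric(positiveFraction),
      lossWeights = lossWeights, bpttWindow = as.integer(bpttWindow),
      teacherForcing = as.logical(teacherForcing),
      overlap = as.integer(overlap), seed = as.integer(seed))
}

#' @rdname TrainConfig
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", epochs = "integer", batchSize = "integer",
  patchSize = "integer", patchesPerCase = "integer",
  positiveFraction = "numeric", lossWeights = "LossWeights",
  bpttWindow = "integer", teacherForcing = "logical", overlap = "integer",
  seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@bpttWindow < 1L) return("bpttWindow must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@patchesPerCase < 1L) return("patchesPerCase must be >= 1")
  if (object@positiveFraction < 0 || object@positiveFraction > 1)
    return("positiveFraction must be in [0, 1]")
  if (length(object@patchSize) != 3L) return("patchSize must have 3 components")
  TRUE
})

# ---------------------------------------------------------------------------
# Cascade
# ---------------------------------------------------------------------------

#' Two-stage cascade model
#'
#' Bundles the trained coarse 3D model (stage F1) and the fine recurrent 2D
#' model (stage F2) together with the intensity preprocessing bounds and the
#' final binarization threshold, so that [predictCascade()] can run the full
#' pipeline on a raw volume. Either stage may be a plain
#' \code{function(input_array) -> output} for testing.
#'
#' @param coarse coarse-stage model (from [trainCoarse()] or a function).
#' @param fine fine-stage model (from [trainFine()] or a function).
#' @param intensityBounds numeric(2) clip bounds for normalization.
#' @param threshold binarization threshold in (0, 1); voxels with
#'   probability >= threshold map to foreground.
#' @param patchSize integer(3) sliding-window patch for the coarse stage.
#' @param overlap integer(3) sliding-window overlap.
#' @return A \code{CascadeModel}.
#' @aliases CascadeModel-class
#' @export
CascadeModel <- function(coarse, fine, intensityBounds = c(-1000, 2000),
                         threshold = 0.5, patchSize = c(64, 128, 128),
                         overlap = c(8, 16, 16)) {
  new("CascadeModel", coarse = coarse, fine = fine,
      intensityBounds = as.numeric(intensityBounds),
      threshold = as.numeric(threshold), patchSize = as.integer(patchSize),
      overlap = as.integer(overlap))
}

#' @rdname CascadeModel
#' @export
setClass("CascadeModel", representation(
  coarse = "ANY", fine = "ANY", intensityBounds = "numeric",
  threshold = "numeric", patchSize = "integer", overlap = "integer"))

setValidity("CascadeModel", function(object) {
  if (is.null(object@coarse) || is.null(object@fine))
    return("both coarse and fine models must be present")
  if (length(object@intensityBounds) != 2L ||
      object@intensityBounds[2] <= object@intensityBounds[1])
    return("intensityBounds must be (lo, hi) with hi > lo")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

# ---------------------------------------------------------------------------
# Metrics report
# ---------------------------------------------------------------------------

#' Per-case evaluation report
#'
#' Holds the four evaluation metrics for one case: Dice overlap, average
#' symmetric surface distance (mm), 95th-percentile Hausdorff distance (mm)
#' and maximum Hausdorff distance (mm). Distance slots are \code{NA} when
#' exactly one of the two masks is empty (no surface to measure against).
#'
#' @param dice Dice coefficient in [0, 1].
#' @param asdMM average symmetric surface distance, mm.
#' @param hd95MM 95th-percentile Hausdorff distance, mm.
#' @param hdMM maximum Hausdorff distance, mm.
#' @return A \code{MetricsReport}.
#' @aliases MetricsReport-class
#' @export
MetricsReport <- function(dice, asdMM, hd95MM, hdMM) {
  new("MetricsReport", dice = as.numeric(dice), asdMM = as.numeric(asdMM),
      hd95MM = as.numeric(hd95MM), hdMM = as.numeric(hdMM))
}

#' @rdname MetricsReport
#' @export
setClass("MetricsReport", representation(
  dice = "numeric", asdMM = "numeric", hd95MM = "numeric", hdMM = "numeric"))

setValidity("MetricsReport", function(object) {
  ok <- function(x) is.na(x) || x >= 0
  if (!is.na(object@dice) && (object@dice < 0 || object@dice > 1))
    return("dice must be in [0, 1]")
  if (!ok(object@asdMM) || !ok(object@hd95MM) || !ok(object@hdMM))
    return("distances must be >= 0 (or NA when undefined)")
  if (!anyNA(c(object@hd95MM, object@hdMM)) && object@hd95MM > object@hdMM + 1e-9)
    return("hd95MM cannot exceed hdMM")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: Dice %.4f | ASD %.4f mm | 95HD %.4f mm | HD %.4f mm\n",
              object@dice, object@asdMM, object@hd95MM, object@hdMM))
})

#' @rdname MetricsReport
#' @param x a \code{MetricsReport}.
#' @param row.names,optional,... passed through for the S3 generic.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(dice = x@dice, asd_mm = x@asdMM, hd95_mm = x@hd95MM,
             hd_mm = x@hdMM, row.names = row.names)
}
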