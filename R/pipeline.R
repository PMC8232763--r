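# Orchestration of the two-stage method: coarse training on randomly
# sampled sub-volumes, fine-stage recurrent training with truncated BPTT,
# cascaded inference, and largest-component post-processing.

loadManifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  need <- c("case_id", "image", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns case_id, image, label")
  manifest
}

manifestTrainRows <- function(manifest) {
  if ("split" %in% names(manifest) && any(manifest$split == "train"))
    manifest[manifest$split == "train", , drop = FALSE]
  else manifest
}

loadCases <- function(manifest, bounds) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = normalizeIntensity(readVolume(manifest$image[i]),
                                    bounds[1], bounds[2]),
         label = readVolume(manifest$label[i], "label"),
         case_id = manifest$case_id[i])
  })
}

addGrads <- function(a, b) if (is.null(a)) b else Map(`+`, a, b)

clipProbs <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Train the coarse 3D stage
#'
#' Per epoch, for every training case, \code{patchesPerCase} sub-volumes of
#' \code{patchSize} are sampled (foreground-covering with probability
#' \code{positiveFraction}, uniform otherwise — hard negative mining), and
#' each batch of \code{batchSize} patches triggers one Adam step on the
#' compound BCE + Dice loss. Deterministic given \code{trainConfig@seed} in
#' single-threaded execution.
#'
#' @param manifest a manifest \code{data.frame} or CSV path (columns
#'   \code{case_id,image,label[,split]}); rows with split \code{"train"}
#'   are used when the column is present.
#' @param netConfig a 3D [NetworkConfig()] with 1 input channel.
#' @param trainConfig a [TrainConfig()].
#' @param bounds intensity normalization bounds.
#' @param verbose print per-epoch losses.
#' @return \code{list(model =, history =)} with one mean training loss per
#'   epoch.
#' @export
trainCoarse <- function(manifest, netConfig, trainConfig,
                        bounds = c(-1000, 2000), verbose = FALSE) {
  manifest <- manifestTrainRows(loadManifest(manifest))
  if (nrow(manifest) == 0L) stop("empty training dataset")
  cases <- loadCases(manifest, bounds)
  w <- trainConfig@lossWeights
  withSeed(trainConfig@seed, {
    model <- buildSegUnet(netConfig)
    opt <- adamInit(model$params)
    history <- numeric(0)
    for (ep in seq_len(trainConfig@epochs)) {
      losses <- numeric(0)
      for (cs in cases) {
        for (r in seq_len(trainConfig@patchesPerCase)) {
          gacc <- NULL
          lsum <- 0
          for (b in seq_len(trainConfig@batchSize)) {
            s <- sampleTrainingSubvolume(cs$image, cs$label,
                                         trainConfig@patchSize,
                                         trainConfig@positiveFraction)
            x <- matrix(as.numeric(s$image@data), ncol = 1L)
            y <- matrix(as.numeric(s$label@data), ncol = 1L)
            fw <- segunetForwardCore(model, x, dim(s$image@data), train = TRUE)
            model$stats <- fw$stats
            pred <- clipProbs(fw$out)
            lsum <- lsum + combinedLoss(pred, y, w)
            bw <- segunetBackwardCore(model, fw, lossGradient(pred, y, w))
            gacc <- addGrads(gacc, bw$grads)
          }
          if (trainConfig@batchSize > 1L)
            gacc <- lapply(gacc, `/`, trainConfig@batchSize)
          upd <- adamUpdate(model$params, gacc, opt, trainConfig@learningRate)
          model$params <- upd$params
          opt <- upd$state
          losses <- c(losses, lsum / trainConfig@batchSize)
        }
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("coarse epoch %d/%d: loss %.4f", ep,
                        trainConfig@epochs, history[ep]))
    }
    list(model = model, history = history)
  })
}

#' Whole-volume coarse inference by sliding window
#'
#' Normalizes the volume (unless already normalized), pads it symmetrically
#' with zeros to at least \code{patchSize} when needed, tiles it with the
#' given overlap, evaluates the coarse model on every tile and fuses the
#' tile predictions by voxelwise mean; padding is removed afterwards.
#'
#' @param image an [ImageVolume()].
#' @param model the coarse 3D model (or a function mock, see
#'   [coarseForward()]).
#' @param patchSize integer(3) sliding-window patch size (spatial dims
#'   divisible by \code{2^depth}).
#' @param overlap integer(3) window overlap.
#' @param bounds normalization bounds.
#' @param normalized set \code{TRUE} when \code{image} is already in [0, 1].
#' @return A [ProbabilityVolume()] of the input shape.
#' @export
runCoarseInference <- function(image, model, patchSize,
                               overlap = c(8, 16, 16),
                               bounds = c(-1000, 2000), normalized = FALSE) {
  stopifnot(is(image, "ImageVolume"))
  vol <- if (normalized) image else normalizeIntensity(image, bounds[1], bounds[2])
  d <- dim(vol@data)
  patchSize <- as.integer(rep_len(patchSize, 3))
  pad <- pmax(0L, patchSize - d)
  lo <- pad %/% 2L
  arr <- vol@data
  if (any(pad > 0L)) {
    big <- array(0, d + pad)
    big[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
    arr <- big
  }
  shape <- dim(arr)
  specs <- tileVolume(shape, patchSize, overlap)
  patches <- lapply(specs, function(sp) {
    e <- sp@start + sp@size - 1L
    coarseForward(model, arr[sp@start[1]:e[1], sp@start[2]:e[2],
                             sp@start[3]:e[3], drop = FALSE])
  })
  fused <- fusePatches(specs, patches, shape, image@spacing, image@origin)
  probs <- fused@data
  if (any(pad > 0L))
    probs <- probs[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
                   lo[3] + seq_len(d[3]), drop = FALSE]
  ProbabilityVolume(probs, image@spacing, image@origin)
}

#' Train the fine recurrent 2D stage
#'
#' Precomputes the coarse probability map of every training case, then
#' iterates axial slices in ascending order. Each step feeds the 3-channel
#' stack (image slice, coarse slice, previous soft prediction) through the
#' recurrent SegUnet; per-step compound losses are summed and
#' backpropagated through time, truncated to windows of
#' \code{bpttWindow} steps (one Adam update per window). The previous-step
#' probability is passed soft so gradients can flow through the recurrence;
#' with \code{teacherForcing = TRUE} the ground truth of the previous slice
#' is fed instead (gradient detached).
#'
#' @param manifest as in [trainCoarse()].
#' @param coarseModel the trained coarse stage, used to produce the
#'   second input channel.
#' @param netConfig a 2D [NetworkConfig()] with 3 input channels.
#' @param trainConfig a [TrainConfig()]; \code{patchSize}/\code{overlap}
#'   control the coarse sliding window.
#' @param bounds intensity normalization bounds.
#' @param verbose print per-epoch losses.
#' @return \code{list(model =, history =)} with one mean per-step loss per
#'   epoch.
#' @export
trainFine <- function(manifest, coarseModel, netConfig, trainConfig,
                      bounds = c(-1000, 2000), verbose = FALSE) {
  manifest <- manifestTrainRows(loadManifest(manifest))
  if (nrow(manifest) == 0L) stop("empty training dataset")
  cases <- loadCases(manifest, bounds)
  coarseProbs <- lapply(cases, function(cs)
    runCoarseInference(cs$image, coarseModel, trainConfig@patchSize,
                       trainConfig@overlap, normalized = TRUE))
  w <- trainConfig@lossWeights
  withSeed(trainConfig@seed, {
    model <- buildSegUnet(netConfig)
    opt <- adamInit(model$params)
    history <- numeric(0)
    for (ep in seq_len(trainConfig@epochs)) {
      losses <- numeric(0)
      for (ci in seq_along(cases)) {
        img <- cases[[ci]]$image@data
        lab <- cases[[ci]]$label@data
        if (!identical(dim(coarseProbs[[ci]]@data), dim(img)))
          stop("coarse prediction geometry mismatch for case ",
               cases[[ci]]$case_id)
        cpr <- coarseProbs[[ci]]@data
        d <- dim(img)
        prev <- matrix(0, d[2], d[3])
        t0 <- 1L
        while (t0 <= d[1]) {
          win <- t0:min(d[1], t0 + trainConfig@bpttWindow - 1L)
          fws <- vector("list", length(win))
          gpreds <- vector("list", length(win))
          for (k in seq_along(win)) {
            tt <- win[k]
            xmat <- cbind(as.numeric(img[tt, , ]), as.numeric(cpr[tt, , ]),
                          as.numeric(prev))
            fw <- segunetForwardCore(model, xmat, c(d[2], d[3], 1L),
                                     train = TRUE)
            model$stats <- fw$stats
            fws[[k]] <- fw
            pred <- clipProbs(fw$out)
            y <- matrix(as.numeric(lab[tt, , ]), ncol = 1L)
            losses <- c(losses, combinedLoss(pred, y, w))
            gpreds[[k]] <- lossGradient(pred, y, w)
            prev <- if (trainConfig@teacherForcing) matrix(lab[tt, , ], d[2], d[3])
                    else matrix(fw$out, d[2], d[3])
          }
          gacc <- NULL
          gnext <- NULL  # gradient flowing into the previous-slice channel
          for (k in rev(seq_along(win))) {
            g <- gpreds[[k]]
            if (!is.null(gnext) && !trainConfig@teacherForcing)
              g <- g + gnext
            bw <- segunetBackwardCore(model, fws[[k]], g)
            gacc <- addGrads(gacc, bw$grads)
            gnext <- bw$gx[, 3L, drop = FALSE]
          }
          upd <- adamUpdate(model$params, gacc, opt, trainConfig@learningRate)
          model$params <- upd$params
          opt <- upd$state
          t0 <- t0 + length(win)
        }
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("fine epoch %d/%d: loss %.4f", ep,
                        trainConfig@epochs, history[ep]))
    }
    list(model = model, history = history)
  })
}

#' Run the full cascade on a raw volume
#'
#' Normalize, run coarse sliding-window inference, then the fine recurrence
#' over axial slices in ascending order: each slice's input is (image
#' slice, coarse slice, previous fine prediction), with the prediction
#' "before" the first slice an all-zeros map. Soft probabilities are
#' carried through the recurrence and binarized only at the end (voxels
#' \code{>= threshold} map to foreground). Optional post-processing keeps
#' only the largest 26-connected component.
#'
#' @param image a raw [ImageVolume()].
#' @param cascade a [CascadeModel()].
#' @param postprocess keep only the largest connected component.
#' @return A [LabelVolume()] prediction.
#' @export
predictCascade <- function(image, cascade, postprocess = FALSE) {
  stopifnot(is(image, "ImageVolume"), is(cascade, "CascadeModel"))
  vol <- normalizeIntensity(image, cascade@intensityBounds[1],
                            cascade@intensityBounds[2])
  coarse <- runCoarseInference(vol, cascade@coarse, cascade@patchSize,
                               cascade@overlap, normalized = TRUE)
  d <- dim(vol@data)
  probs <- array(0, d)
  prev <- matrix(0, d[2], d[3])
  for (t in seq_len(d[1])) {
    prev <- fineStep(cascade@fine, vol@data[t, , ], coarse@data[t, , ], prev)
    probs[t, , ] <- prev
  }
  mask <- LabelVolume((probs >= cascade@threshold) * 1L, image@spacing,
                      image@origin)
  if (postprocess) mask <- postprocessLargestComponent(mask)
  mask
}

#' Keep only the largest 26-connected foreground component
#'
#' Removes all but the largest 26-connected component of a binary mask;
#' ties are broken in favor of the component containing the earliest voxel
#' in the array's linear scan order. An empty mask is returned unchanged.
#' Never increases the foreground voxel count.
#'
#' @param mask a [LabelVolume()].
#' @return The filtered [LabelVolume()].
#' @export
postprocessLargestComponent <- function(mask) {
  stopifnot(is(mask, "LabelVolume"))
  m <- mask@data
  if (!any(m == 1L)) return(mask)
  labs <- cpp_label_components(as.integer(m), dim(m))
  counts <- tabulate(labs)
  keep <- which.max(counts)  # first maximum = earliest component in scan order
  LabelVolume(array(as.integer(labs == keep), dim(m)), mask@spacing,
              mask@origin)
}

#' Desk-scale end-to-end study on synthetic phantoms
#'
#' Generates an artifact-polluted phantom dataset (default 20 training + 5
#' held-out cases of shape 32 x 64 x 64), trains the coarse 3D stage (base
#' 4, depth 2, patch 16 x 32 x 32, 30 epochs) and the fine recurrent stage
#' (15 epochs, BPTT window 4), then evaluates both the thresholded
#' coarse-only prediction and the full cascade (with largest-component
#' post-processing) on the held-out cases. Every random draw derives from
#' \code{seed}, so repeated runs are bit-identical in single-threaded
#' execution.
#'
#' @param seed master seed for data generation, initialization and
#'   sampling.
#' @param outDir directory for the generated dataset (default: a fresh
#'   temporary directory).
#' @param nTrain,nTest number of training / held-out phantom cases.
#' @param phantomConfig a [PhantomConfig()]; its seed is overridden by
#'   \code{seed}.
#' @param epochsCoarse,epochsFine training epochs per stage.
#' @param verbose print progress.
#' @return A list: \code{coarseHistory}, \code{fineHistory} (per-epoch
#'   losses), \code{cascadeReport} and \code{coarseReport} (per-case metric
#'   tables from [evaluateDataset()]), \code{meanDiceCascade},
#'   \code{meanDiceCoarse}, \code{predictions} (held-out cascade masks),
#'   and \code{cascade} (the trained [CascadeModel()]).
#' @export
runCascadeStudy <- function(seed = 1, outDir = tempfile("c2fseg-study"),
                            nTrain = 20, nTest = 5,
                            phantomConfig = PhantomConfig(),
                            epochsCoarse = 30, epochsFine = 15,
                            verbose = FALSE) {
  phantomConfig@seed <- as.integer(seed)
  manifest <- makeDataset(nTrain + nTest, phantomConfig, outDir,
                          split = rep(c("train", "test"), c(nTrain, nTest)))
  coarseNet <- NetworkConfig(inChannels = 1, baseFilters = 4, depth = 2,
                             spatialRank = 3)
  fineNet <- NetworkConfig(inChannels = 3, baseFilters = 4, depth = 2,
                           spatialRank = 2)
  coarseTrain <- TrainConfig(learningRate = 1e-3, epochs = epochsCoarse,
                             patchSize = c(16, 32, 32),
                             overlap = c(8, 16, 16), patchesPerCase = 1,
                             positiveFraction = 0.5,
                             seed = as.integer(seed) + 1000L)
  fineTrain <- TrainConfig(learningRate = 1e-3, epochs = epochsFine,
                           patchSize = c(16, 32, 32), overlap = c(8, 16, 16),
                           bpttWindow = 4, seed = as.integer(seed) + 2000L)

  coarseFit <- trainCoarse(manifest, coarseNet, coarseTrain, verbose = verbose)
  fineFit <- trainFine(manifest, coarseFit$model, fineNet, fineTrain,
                       verbose = verbose)
  cascade <- CascadeModel(coarseFit$model, fineFit$model,
                          patchSize = coarseTrain@patchSize,
                          overlap = coarseTrain@overlap)

  test <- manifest[manifest$split == "test", , drop = FALSE]
  cascadeMasks <- list()
  coarseMasks <- list()
  truths <- list()
  for (i in seq_len(nrow(test))) {
    img <- readVolume(test$image[i])
    truths[[i]] <- readVolume(test$label[i], "label")
    cascadeMasks[[i]] <- predictCascade(img, cascade, postprocess = TRUE)
    cp <- runCoarseInference(img, coarseFit$model, coarseTrain@patchSize,
                             coarseTrain@overlap)
    coarseMasks[[i]] <- LabelVolume((cp@data >= 0.5) * 1L, img@spacing)
  }
  cascadeReport <- evaluateDataset(cascadeMasks, truths, test$case_id)
  coarseReport <- evaluateDataset(coarseMasks, truths, test$case_id)
  diceOf <- function(rep) rep$dice[rep$case_id == "mean"]
  list(coarseHistory = coarseFit$history, fineHistory = fineFit$history,
       cascadeReport = cascadeReport, coarseReport = coarseReport,
       meanDiceCascade = diceOf(cascadeReport),
       meanDiceCoarse = diceOf(coarseReport),
       predictions = lapply(cascadeMasks, volData),
       cascade = cascade, manifest = manifest)
}
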