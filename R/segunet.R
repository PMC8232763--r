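# SegUnet: encoder-decoder with U-Net skip concatenation AND SegNet-style
# max-pooling index transfer to unpooling. Decoder block at level i:
# unpool(indices_i) -> concat(skip_i) -> conv/BN/ReLU x2, where the second
# conv halves the width so channel counts always match the recorded
# indices of the next shallower level. Head: 1x1(x1) conv + sigmoid.
#
# Models are plain lists (config + named parameter list + named BN running
# stats); all training state transformations are functional.

encoderWidths <- function(config) {
  config@baseFilters * 2L^(seq_len(config@depth) - 1L)
}

# channel layout per layer; shared by the builder, the forward/backward
# passes and the closed-form parameter count
segunetLayout <- function(config) {
  w <- encoderWidths(config)
  dep <- config@depth
  enc <- lapply(seq_len(dep), function(i) {
    cin1 <- if (i == 1L) config@inChannels else w[i - 1L]
    list(conv1 = c(cin1, w[i]), conv2 = c(w[i], w[i]))
  })
  dec <- lapply(seq_len(dep), function(i) {
    dout <- if (i > 1L) w[i - 1L] else w[1L]
    list(conv1 = c(2L * w[i], w[i]), conv2 = c(w[i], dout))
  })
  list(widths = w, enc = enc, dec = dec,
       head = c(w[1L], config@outChannels))
}

kaimingConv <- function(ksz, cin, cout) {
  fanIn <- prod(ksz) * cin
  array(rnorm(prod(ksz) * cin * cout, sd = sqrt(2 / fanIn)),
        c(ksz, cin, cout))
}

#' Build a SegUnet model
#'
#' Allocates and initializes all parameters of the architecture described
#' by a [NetworkConfig()]: conv weights Kaiming-style (fan-in), biases 0,
#' batch-norm gamma 1 / beta 0, running stats (0, 1). With \code{seed} the
#' initialization is reproducible and the caller's RNG state is untouched.
#'
#' @param config a [NetworkConfig()].
#' @param seed optional integer seed for the weight draw.
#' @return A model list with elements \code{config}, \code{params} (named
#'   list of arrays) and \code{stats} (named BN running statistics).
#' @seealso [segUnetForward()], [countParameters()]
#' @export
buildSegUnet <- function(config, seed = NULL) {
  stopifnot(is(config, "NetworkConfig"))
  build <- function() {
    ksz <- kernelVec(config)
    lay <- segunetLayout(config)
    params <- list()
    stats <- list()
    addUnit <- function(key, cin, cout) {
      params[[paste0(key, "c_W")]] <<- kaimingConv(ksz, cin, cout)
      params[[paste0(key, "c_b")]] <<- numeric(cout)
      params[[paste0(key, "n_g")]] <<- rep(1, cout)
      params[[paste0(key, "n_b")]] <<- numeric(cout)
      stats[[paste0(key, "n_rm")]] <<- numeric(cout)
      stats[[paste0(key, "n_rv")]] <<- rep(1, cout)
    }
    for (i in seq_len(config@depth)) {
      addUnit(sprintf("e%d_1", i), lay$enc[[i]]$conv1[1], lay$enc[[i]]$conv1[2])
      addUnit(sprintf("e%d_2", i), lay$enc[[i]]$conv2[1], lay$enc[[i]]$conv2[2])
      addUnit(sprintf("d%d_1", i), lay$dec[[i]]$conv1[1], lay$dec[[i]]$conv1[2])
      addUnit(sprintf("d%d_2", i), lay$dec[[i]]$conv2[1], lay$dec[[i]]$conv2[2])
    }
    params[["head_W"]] <- kaimingConv(c(1L, 1L, 1L), lay$head[1], lay$head[2])
    params[["head_b"]] <- numeric(lay$head[2])
    structure(list(config = config, params = params, stats = stats),
              class = "segUnet")
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' @rdname buildSegUnet
#' @param model a model from \code{buildSegUnet}.
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

checkSpatialDims <- function(config, dims) {
  f <- 2L^config@depth
  pooled <- if (config@spatialRank == 3L) 1:3 else 1:2
  if (any(dims[pooled] %% f != 0L))
    stop("input spatial dims must be divisible by 2^depth = ", f)
}

# conv -> BN -> ReLU; returns activation, cache for backward, updated stats.
# Training mode normalizes by batch statistics (fused C++ kernel) and
# updates the running stats; eval mode applies the stored running stats.
unitForward <- function(key, x, dims, params, stats, ksz, train,
                        momentum = 0.1, eps = 1e-5) {
  cv <- convForward(x, dims, params[[paste0(key, "c_W")]],
                    params[[paste0(key, "c_b")]], ksz)
  if (train) {
    bn <- cpp_bn_relu_fwd(cv$out, params[[paste0(key, "n_g")]],
                          params[[paste0(key, "n_b")]], eps)
    N <- nrow(cv$out)
    stats[[paste0(key, "n_rm")]] <-
      (1 - momentum) * stats[[paste0(key, "n_rm")]] + momentum * bn$mean
    stats[[paste0(key, "n_rv")]] <-
      (1 - momentum) * stats[[paste0(key, "n_rv")]] +
      momentum * bn$var * N / max(1L, N - 1L)
    cache <- list(x = cv$x, xhat = bn$xhat, invstd = bn$invstd,
                  mask = bn$mask, cin = ncol(x), dims = dims)
    return(list(out = bn$out, cache = cache, stats = stats))
  }
  bn <- bnForward(cv$out, params[[paste0(key, "n_g")]],
                  params[[paste0(key, "n_b")]],
                  stats[[paste0(key, "n_rm")]], stats[[paste0(key, "n_rv")]],
                  train = FALSE, eps = eps)
  list(out = bn$out * (bn$out > 0), cache = NULL, stats = stats)
}

unitBackward <- function(key, gout, cache, params, ksz, grads) {
  bb <- cpp_bn_relu_bwd(gout, cache$xhat, cache$invstd,
                        params[[paste0(key, "n_g")]], cache$mask)
  grads[[paste0(key, "n_g")]] <- bb$gg
  grads[[paste0(key, "n_b")]] <- bb$gb
  cb <- convBackward(bb$gx, cache$x, params[[paste0(key, "c_W")]], ksz,
                     cache$cin, cache$dims)
  grads[[paste0(key, "c_W")]] <- cb$gW
  grads[[paste0(key, "c_b")]] <- cb$gb
  list(gx = cb$gx, grads = grads)
}

# Core forward pass on the internal (voxels x channels) representation.
# Returns the sigmoid output; in training mode also every cache needed by
# segunetBackwardCore and the updated BN running stats.
segunetForwardCore <- function(model, x, dims, train = FALSE) {
  cfg <- model$config
  checkSpatialDims(cfg, dims)
  ksz <- kernelVec(cfg)
  pv <- poolVec(cfg)
  dep <- cfg@depth
  w <- encoderWidths(cfg)
  params <- model$params
  stats <- model$stats
  caches <- list()
  skips <- vector("list", dep)
  skipdims <- vector("list", dep)
  idxs <- vector("list", dep)
  cur <- x
  curdims <- as.integer(dims)
  for (i in seq_len(dep)) {
    for (j in 1:2) {
      key <- sprintf("e%d_%d", i, j)
      u <- unitForward(key, cur, curdims, params, stats, ksz, train)
      cur <- u$out; stats <- u$stats
      if (train) caches[[key]] <- u$cache
    }
    skips[[i]] <- cur
    skipdims[[i]] <- curdims
    pl <- cpp_maxpool(cur, c(curdims, ncol(cur)), pv)
    idxs[[i]] <- pl$idx
    cur <- matrix(pl$out, ncol = ncol(cur))
    curdims <- curdims %/% pv
  }
  for (i in rev(seq_len(dep))) {
    nfull <- prod(skipdims[[i]]) * ncol(cur)
    cur <- matrix(cpp_unpool(cur, idxs[[i]], nfull), ncol = ncol(cur))
    curdims <- skipdims[[i]]
    cur <- cbind(cur, skips[[i]])
    for (j in 1:2) {
      key <- sprintf("d%d_%d", i, j)
      u <- unitForward(key, cur, curdims, params, stats, ksz, train)
      cur <- u$out; stats <- u$stats
      if (train) caches[[key]] <- u$cache
    }
  }
  z <- cur %*% matrix(params$head_W, ncol = cfg@outChannels)
  z <- z + rep(params$head_b, each = nrow(z))
  out <- 1 / (1 + exp(-z))
  if (!train) return(list(out = out))
  list(out = out, stats = stats,
       record = list(caches = caches, idxs = idxs, skipdims = skipdims,
                     headIn = cur, dims = as.integer(dims)))
}

# Backward pass: gpred is dLoss/dOutputProbability (same shape as out).
# Returns parameter gradients (named like params) and dLoss/dInput.
segunetBackwardCore <- function(model, fw, gpred) {
  cfg <- model$config
  ksz <- kernelVec(cfg)
  dep <- cfg@depth
  w <- encoderWidths(cfg)
  params <- model$params
  rec <- fw$record
  grads <- list()
  out <- fw$out
  gz <- gpred * out * (1 - out)
  grads$head_b <- colSums(gz)
  grads$head_W <- array(crossprod(rec$headIn, gz), dim(params$head_W))
  gcur <- gz %*% t(matrix(params$head_W, ncol = cfg@outChannels))
  gskips <- vector("list", dep)
  for (i in seq_len(dep)) {  # decoder blocks in reverse execution order
    for (j in 2:1) {
      key <- sprintf("d%d_%d", i, j)
      ub <- unitBackward(key, gcur, rec$caches[[key]], params, ksz, grads)
      gcur <- ub$gx; grads <- ub$grads
    }
    gskips[[i]] <- gcur[, w[i] + seq_len(w[i]), drop = FALSE]
    gup <- gcur[, seq_len(w[i]), drop = FALSE]
    gcur <- matrix(gup[rec$idxs[[i]]], ncol = w[i])  # unpool backward: gather
  }
  for (i in rev(seq_len(dep))) {  # encoder blocks in reverse
    # pool backward: scatter the pooled gradient to the argmax positions
    nfull <- prod(rec$skipdims[[i]]) * ncol(gcur)
    gskip <- matrix(cpp_unpool(gcur, rec$idxs[[i]], nfull), ncol = ncol(gcur))
    gcur <- gskip + gskips[[i]]
    for (j in 2:1) {
      key <- sprintf("e%d_%d", i, j)
      ub <- unitBackward(key, gcur, rec$caches[[key]], params, ksz, grads)
      gcur <- ub$gx; grads <- ub$grads
    }
  }
  list(grads = grads, gx = gcur)
}

#' Run a SegUnet forward pass
#'
#' @param model a model from [buildSegUnet()].
#' @param x channel-first input array: \code{(C, D, H, W)} for a 3D model,
#'   \code{(C, H, W)} for a 2D model; spatial dims must be divisible by
#'   \code{2^depth}.
#' @param train logical; training mode uses batch statistics in the BN
#'   layers and updates running statistics, evaluation mode (default) uses
#'   the stored running statistics and is deterministic.
#' @return In evaluation mode, the channel-first probability array
#'   \code{(outChannels, ...)} with values in (0, 1). In training mode a
#'   list also carrying the updated model and the backward record.
#' @export
segUnetForward <- function(model, x, train = FALSE) {
  cfg <- model$config
  d <- dim(x)
  expectRank <- if (cfg@spatialRank == 3L) 4L else 3L
  if (length(d) != expectRank)
    stop("expected a channel-first array of rank ", expectRank)
  if (d[1] != cfg@inChannels)
    stop("expected ", cfg@inChannels, " input channels, got ", d[1])
  cf <- channelFirstToMatrix(x)
  fw <- segunetForwardCore(model, cf$mat, cf$dims, train = train)
  out <- matrixToChannelFirst(fw$out, cf$dims, cfg@spatialRank == 3L)
  if (!train) return(out)
  model$stats <- fw$stats
  list(out = out, model = model, fw = fw)
}

#' Coarse-stage forward pass on one sub-volume
#'
#' Evaluates the 3D coarse model F1 on a normalized sub-volume Xc and
#' returns the same-shape soft prediction. Used per tile by
#' [runCoarseInference()].
#'
#' @param model a 3D SegUnet (or a \code{function(array) -> array} mock).
#' @param patch an [ImageVolume()] or bare 3D array with values in [0, 1].
#' @return A [ProbabilityVolume()] (or bare array when the input was bare).
#' @export
coarseForward <- function(model, patch) {
  arr <- if (is(patch, "Volume")) patch@data else patch
  d <- dim(arr)
  if (length(d) != 3L) stop("patch must be a 3D sub-volume")
  if (is.function(model)) {
    out <- model(array(arr, c(1L, d)))
    probs <- array(out, d)
  } else {
    fw <- segunetForwardCore(model, matrix(as.numeric(arr), ncol = 1L), d)
    probs <- array(fw$out, d)
  }
  if (is(patch, "Volume")) ProbabilityVolume(probs, patch@spacing, patch@origin)
  else probs
}

#' One step of the recurrent fine stage
#'
#' Applies the fine model F2 to one axial slice. The model input is the
#' 3-channel stack \code{(x_t, yhat1_t, yhat2_{t-1})} in that fixed order:
#' the normalized image slice, the coarse-stage probability slice and the
#' previous slice's fine prediction.
#'
#' @param model a 2D SegUnet with 3 input channels, or a
#'   \code{function(array_3HW) -> matrix} mock.
#' @param sliceX normalized image slice (matrix, values in [0, 1]).
#' @param coarseSlice coarse probability slice, same shape.
#' @param prevPred previous fine prediction (soft or hard), same shape.
#' @return The probability matrix for this slice.
#' @export
fineStep <- function(model, sliceX, coarseSlice, prevPred) {
  d <- dim(sliceX)
  if (!identical(d, dim(coarseSlice)) || !identical(d, dim(prevPred)))
    stop("all three input slices must share the same shape")
  if (is.function(model)) {
    stack <- array(0, c(3L, d))
    stack[1, , ] <- sliceX
    stack[2, , ] <- coarseSlice
    stack[3, , ] <- prevPred
    return(matrix(model(stack), d[1], d[2]))
  }
  xmat <- cbind(as.numeric(sliceX), as.numeric(coarseSlice),
                as.numeric(prevPred))
  fw <- segunetForwardCore(model, xmat, c(d, 1L))
  matrix(fw$out, d[1], d[2])
}

#' Save / load a model checkpoint
#'
#' Serializes a model (parameters, BN statistics and the embedded
#' [NetworkConfig()]) to a single RDS file.
#'
#' @param model a model from [buildSegUnet()] (possibly trained).
#' @param path checkpoint file path.
#' @return \code{saveCheckpoint}: invisibly, \code{path};
#'   \code{loadCheckpoint}: the model.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(inherits(model, "segUnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "segUnet")) stop("not a SegUnet checkpoint: ", path)
  model
}
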