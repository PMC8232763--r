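# Low-level layer primitives. Activations are (voxels x channels) matrices
# whose rows follow the column-major order of a (D,H,W) grid, so a matrix
# doubles as a channel-last tensor; `dims` carries (D,H,W) alongside.
# 3x3(x3) convolutions run through direct C++ kernels with "same" zero
# padding (1x1 convs are a plain GEMM); max pooling records argmax indices
# so unpooling can restore exact positions.

# rank-2 inputs use the layout (H, W, 1) so the innermost C++ loops run
# along image rows, never along a singleton axis
kernelVec <- function(config) {
  k <- config@kernelSize
  if (config@spatialRank == 3L) c(k, k, k) else c(k, k, 1L)
}

poolVec <- function(config) {
  if (config@spatialRank == 3L) c(2L, 2L, 2L) else c(2L, 2L, 1L)
}

convForward <- function(x, dims, W, b, ksz) {
  cout <- length(b)
  if (all(ksz == 1L)) {
    out <- x %*% matrix(W, ncol = cout)
    out <- out + rep(b, each = nrow(out))
  } else {
    out <- cpp_conv_fwd(x, c(dims, ncol(x)), W, b, ksz)
  }
  list(out = out, x = x)
}

convBackward <- function(gout, x, W, ksz, cin, dims) {
  cout <- ncol(gout)
  if (all(ksz == 1L)) {
    gW <- crossprod(x, gout)
    gx <- gout %*% t(matrix(W, ncol = cout))
    return(list(gx = gx, gW = array(gW, dim(W)), gb = colSums(gout)))
  }
  gW <- cpp_conv_bwd_w(x, gout, c(dims, cin), ksz)
  # input gradient = convolution of gout with the flipped kernels,
  # input/output channel roles swapped
  Wt <- aperm(array(W, dim(W))[ksz[1]:1, ksz[2]:1, ksz[3]:1, , , drop = FALSE],
              c(1, 2, 3, 5, 4))
  gx <- cpp_conv_fwd(gout, c(dims, cout), Wt, numeric(cin), ksz)
  list(gx = gx, gW = array(gW, dim(W)), gb = colSums(gout))
}

# evaluation-mode batch norm: apply the stored running statistics
# (training mode runs through the fused C++ kernel, cpp_bn_relu_fwd)
bnForward <- function(x, g, b, rm, rv, train = FALSE, eps = 1e-5) {
  N <- nrow(x)
  list(out = (x - rep(rm, each = N)) * rep(1 / sqrt(rv + eps) * g, each = N) +
         rep(b, each = N))
}

#' Max pooling with recorded argmax indices
#'
#' Factor-2 (per pooled axis) max pooling over a channel-first array,
#' returning the pooled tensor together with the 1-based argmax position of
#' every pooled value in the input. [maxUnpool()] scatters values back to
#' exactly those positions (zero elsewhere), the "cross connection" that
#' transfers coordinates from pooling to unpooling in the decoder.
#'
#' @param x array, \code{(C, D, H, W)} or \code{(C, H, W)}.
#' @param poolSize integer factor per spatial axis (default 2).
#' @return \code{list(out =, idx =)}: the pooled channel-first array and an
#'   integer vector of flat indices into the channel-last layout used
#'   internally; pass both to [maxUnpool()] unchanged.
#' @examples
#' x <- array(rnorm(1 * 4 * 4), c(1, 4, 4))
#' p <- maxPoolIndices(x)
#' u <- maxUnpool(p$out, p$idx, dim(x))
#' all(u[u != 0] %in% p$out)
#' @export
maxPoolIndices <- function(x, poolSize = 2) {
  cf <- channelFirstToMatrix(x)
  pv <- if (length(dim(x)) == 4L) rep(as.integer(poolSize), 3L) else
    c(rep(as.integer(poolSize), 2L), 1L)
  pl <- cpp_maxpool(cf$mat, c(cf$dims, ncol(cf$mat)), pv)
  outdims <- cf$dims %/% pv
  list(out = matrixToChannelFirst(matrix(pl$out, ncol = ncol(cf$mat)),
                                  outdims, length(dim(x)) == 4L),
       idx = pl$idx)
}

#' @rdname maxPoolIndices
#' @param pooled pooled channel-first array from \code{maxPoolIndices}.
#' @param idx recorded indices from \code{maxPoolIndices}.
#' @param outDim dim of the original (unpooled) channel-first array.
#' @export
maxUnpool <- function(pooled, idx, outDim) {
  cf <- channelFirstToMatrix(pooled)
  rank3 <- length(outDim) == 4L
  fulldims <- if (rank3) outDim[2:4] else c(outDim[2:3], 1L)
  C <- outDim[1]
  full <- matrix(cpp_unpool(cf$mat, idx, prod(fulldims) * C), ncol = C)
  matrixToChannelFirst(full, fulldims, rank3)
}

# (C,D,H,W) or (C,H,W) array -> list(mat = N x C, dims = c(D,H,W))
channelFirstToMatrix <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    list(mat = matrix(aperm(x, c(2, 3, 4, 1)), ncol = d[1]), dims = d[2:4])
  } else if (length(d) == 3L) {
    list(mat = matrix(aperm(x, c(2, 3, 1)), ncol = d[1]),
         dims = c(d[2], d[3], 1L))
  } else stop("expected a channel-first array of rank 3 or 4")
}

matrixToChannelFirst <- function(mat, dims, rank3) {
  C <- ncol(mat)
  if (rank3) {
    aperm(array(mat, c(dims, C)), c(4, 1, 2, 3))
  } else {
    aperm(array(mat, c(dims[1], dims[2], C)), c(3, 1, 2))
  }
}

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

adamInit <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adamUpdate <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
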