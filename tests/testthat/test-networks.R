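# closed-form trainable parameter count, derived independently from the
# block structure: encoder/decoder blocks of two (conv + BN) units plus the
# 1x1 head conv; conv = prod(k)*cin*cout + cout, BN = 2*cout
oracleParamCount <- function(inCh, base, depth, rank) {
  kvol <- 3^rank
  w <- base * 2^(seq_len(depth) - 1)
  unit <- function(cin, cout) kvol * cin * cout + cout + 2 * cout
  total <- 0
  for (i in seq_len(depth)) {
    encIn <- if (i == 1) inCh else w[i - 1]
    total <- total + unit(encIn, w[i]) + unit(w[i], w[i])
    decOut <- if (i > 1) w[i - 1] else w[1]
    total <- total + unit(2 * w[i], w[i]) + unit(w[i], decOut)
  }
  total + (w[1] * 1 + 1)  # head: 1x1 conv to one channel
}

test_that("forward pass obeys shape and range contracts", {
  m3 <- buildSegUnet(NetworkConfig(1, 4, 2, 3), seed = 1)
  x3 <- array(runif(16 * 32 * 32), c(1, 16, 32, 32))
  out3 <- segUnetForward(m3, x3)
  expect_equal(dim(out3), c(1, 16, 32, 32))
  expect_true(all(out3 > 0 & out3 < 1))

  m2 <- buildSegUnet(NetworkConfig(3, 4, 2, 2), seed = 2)
  x2 <- array(runif(3 * 64 * 64), c(3, 64, 64))
  out2 <- segUnetForward(m2, x2)
  expect_equal(dim(out2), c(1, 64, 64))
  expect_true(all(out2 > 0 & out2 < 1))

  # indivisible spatial dims are rejected
  expect_error(segUnetForward(m3, array(0.5, c(1, 10, 32, 32))),
               "divisible")
})

test_that("trainable parameter counts match the closed-form oracle", {
  for (cfg in list(list(3, 4, 2, 2), list(1, 4, 2, 3), list(1, 8, 3, 2))) {
    m <- buildSegUnet(NetworkConfig(cfg[[1]], cfg[[2]], cfg[[3]], cfg[[4]]))
    expect_equal(countParameters(m),
                 oracleParamCount(cfg[[1]], cfg[[2]], cfg[[3]], cfg[[4]]))
  }
  # doubling base filters scales the count by the closed-form ratio
  n1 <- countParameters(buildSegUnet(NetworkConfig(3, 4, 2, 2)))
  n2 <- countParameters(buildSegUnet(NetworkConfig(3, 8, 2, 2)))
  expect_equal(n2 / n1, oracleParamCount(3, 8, 2, 2) / oracleParamCount(3, 4, 2, 2))
})

test_that("encoder widths double per level from the base count", {
  cfg <- NetworkConfig(1, 32, 4, 3)
  expect_equal(c2fseg:::encoderWidths(cfg), c(32, 64, 128, 256))
  lay <- c2fseg:::segunetLayout(cfg)
  expect_equal(lay$enc[[3]]$conv1, c(64, 128))
  expect_equal(lay$dec[[3]]$conv1, c(256, 128))  # concat doubles the input
  expect_equal(lay$dec[[3]]$conv2, c(128, 64))   # halve before next unpool
})

test_that("unpooling places each value exactly at its argmax position", {
  set.seed(30)
  for (rep in 1:5) {
    x <- array(runif(2 * 4 * 6 * 8, 0.1, 1), c(2, 4, 6, 8))
    p <- maxPoolIndices(x)
    u <- maxUnpool(p$out, p$idx, dim(x))
    expect_equal(dim(u), dim(x))
    nz <- u != 0
    expect_equal(sum(nz), length(p$out))
    expect_equal(sort(u[nz]), sort(as.numeric(p$out)))
    # at every nonzero position the value agrees with the original tensor
    expect_equal(u[nz], x[nz])
    # and pooling the unpooled tensor returns the pooled values
    expect_equal(maxPoolIndices(u)$out, p$out)
  }
})

test_that("direct convolution agrees with the im2col+GEMM route", {
  set.seed(31)
  for (spec in list(list(c(6L, 8L, 10L), 2L, 3L, c(3L, 3L, 3L)),
                    list(c(12L, 10L, 1L), 3L, 4L, c(3L, 3L, 1L)))) {
    dims <- spec[[1]]; cin <- spec[[2]]; cout <- spec[[3]]; ksz <- spec[[4]]
    x <- matrix(rnorm(prod(dims) * cin), ncol = cin)
    W <- array(rnorm(prod(ksz) * cin * cout), c(ksz, cin, cout))
    b <- rnorm(cout)
    direct <- c2fseg:::cpp_conv_fwd(x, c(dims, cin), W, b, ksz)
    cols <- c2fseg:::cpp_im2col(x, c(dims, cin), ksz)
    ref <- cols %*% matrix(W, ncol = cout) + rep(b, each = prod(dims))
    expect_equal(direct, ref, tolerance = 1e-12)
  }
})

test_that("fine step feeds (image, coarse, previous) in that order", {
  h <- matrix(runif(16 * 16), 16, 16)
  coarse <- matrix(runif(16 * 16), 16, 16)
  prev <- matrix(runif(16 * 16), 16, 16)
  pickChannel <- function(k) function(stack) stack[k, , ]
  expect_equal(fineStep(pickChannel(1), h, coarse, prev), h)
  expect_equal(fineStep(pickChannel(2), h, coarse, prev), coarse)
  expect_equal(fineStep(pickChannel(3), h, coarse, prev), prev)
  expect_error(fineStep(pickChannel(1), h, coarse, prev[1:8, 1:8]), "shape")
})

test_that("evaluation-mode forward is deterministic and seeded builds repeat", {
  m <- buildSegUnet(NetworkConfig(3, 4, 2, 2), seed = 7)
  x <- matrix(runif(32 * 32), 32, 32)
  a <- fineStep(m, x, x, x)
  b <- fineStep(m, x, x, x)
  expect_identical(a, b)
  m2 <- buildSegUnet(NetworkConfig(3, 4, 2, 2), seed = 7)
  expect_identical(m$params, m2$params)
})

test_that("network gradients match central finite differences", {
  set.seed(33)
  cfg <- NetworkConfig(3, 2, 1, 2)
  m <- buildSegUnet(cfg, seed = 5)
  H <- 6L; W <- 6L
  xm <- matrix(runif(H * W * 3), ncol = 3)
  y <- matrix(rbinom(H * W, 1, 0.4), ncol = 1)
  w <- LossWeights()
  lossOf <- function(params, x = xm) {
    mm <- m
    mm$params <- params
    fw <- c2fseg:::segunetForwardCore(mm, x, c(H, W, 1L), train = TRUE)
    combinedLoss(pmin(pmax(fw$out, 1e-7), 1 - 1e-7), y, w)
  }
  fw <- c2fseg:::segunetForwardCore(m, xm, c(H, W, 1L), train = TRUE)
  g <- lossGradient(pmin(pmax(fw$out, 1e-7), 1 - 1e-7), y, w)
  bw <- c2fseg:::segunetBackwardCore(m, fw, g)
  h <- 1e-5
  for (nm in names(m$params)) {
    ks <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (k in ks) {
      pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - h
      fd <- (lossOf(pp) - lossOf(pm)) / (2 * h)
      expect_lt(abs(fd - bw$grads[[nm]][k]), 1e-5 + 1e-3 * abs(fd))
    }
  }
  # gradient w.r.t. the input (the path BPTT uses through channel 3)
  for (k in sample(length(xm), 5)) {
    xp <- xm; xp[k] <- xp[k] + h
    xq <- xm; xq[k] <- xq[k] - h
    fd <- (lossOf(m$params, xp) - lossOf(m$params, xq)) / (2 * h)
    expect_lt(abs(fd - bw$gx[k]), 1e-6 + 1e-3 * abs(fd))
  }
})

test_that("checkpoints round-trip through a single file", {
  d <- withr::local_tempdir()
  m <- buildSegUnet(NetworkConfig(1, 2, 1, 3), seed = 9)
  p <- file.path(d, "model.rds")
  saveCheckpoint(m, p)
  back <- loadCheckpoint(p)
  expect_identical(back$params, m$params)
  expect_equal(back$config@baseFilters, 2L)
  saveRDS(list(1), file.path(d, "junk.rds"))
  expect_error(loadCheckpoint(file.path(d, "junk.rds")), "checkpoint")
})
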