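test_that("crop copies exactly the requested window", {
  v <- tinyImage(c(6, 8, 10))
  whole <- cropVolume(v, SubVolumeSpec(c(1, 1, 1), dim(v)))
  expect_identical(volData(whole), volData(v))

  one <- cropVolume(v, SubVolumeSpec(c(3, 5, 7), c(1, 1, 1)))
  expect_equal(as.numeric(volData(one)), volData(v)[3, 5, 7])

  set.seed(4)
  for (i in 1:10) {
    size <- c(sample(6, 1), sample(8, 1), sample(10, 1))
    start <- 1L + c(sample(6 - size[1] + 1, 1), sample(8 - size[2] + 1, 1),
                    sample(10 - size[3] + 1, 1)) - 1L
    sp <- SubVolumeSpec(start, size)
    e <- start + size - 1L
    expect_identical(volData(cropVolume(v, sp)),
                     volData(v)[start[1]:e[1], start[2]:e[2], start[3]:e[3],
                                drop = FALSE])
  }
  expect_error(cropVolume(v, SubVolumeSpec(c(5, 1, 1), c(6, 2, 2))), "bounds")
})

test_that("positive-fraction sampling honors its contract", {
  img <- tinyImage(c(8, 12, 12))
  lab <- LabelVolume(array(0L, c(8, 12, 12)))
  lab@data[5, 6, 7] <- 1L  # a single foreground voxel

  set.seed(10)
  for (i in 1:100) {
    s <- sampleTrainingSubvolume(img, lab, c(4, 6, 6), positiveFraction = 1)
    expect_gte(sum(volData(s$label)), 1L)
  }

  set.seed(11)
  a <- sampleTrainingSubvolume(img, lab, c(4, 6, 6), 0.5)
  set.seed(11)
  b <- sampleTrainingSubvolume(img, lab, c(4, 6, 6), 0.5)
  expect_identical(volData(a$image), volData(b$image))
  expect_identical(a$spec@start, b$spec@start)

  expect_error(sampleTrainingSubvolume(img, lab, c(10, 6, 6)), "smaller")
  empty <- LabelVolume(array(0L, c(8, 12, 12)))
  expect_warning(sampleTrainingSubvolume(img, empty, c(4, 6, 6), 1),
                 "empty")
})

test_that("hard-negative (uniform) sampling is uniform over valid starts", {
  img <- tinyImage(c(8, 8, 8))
  lab <- tinyLabel(c(8, 8, 8))
  set.seed(12)
  starts <- t(vapply(1:1000, function(i)
    sampleTrainingSubvolume(img, lab, c(4, 4, 4), 0)$spec@start,
    integer(3)))
  # 5 valid start positions per axis; chi-square sanity on each margin
  for (ax in 1:3) {
    tab <- tabulate(starts[, ax], nbins = 5)
    expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
  }
})

test_that("tiling covers every voxel with clamped strides", {
  specs <- tileVolume(c(64, 128, 128), c(64, 128, 128), 0)
  expect_length(specs, 1L)
  expect_equal(specs[[1]]@start, c(1L, 1L, 1L))

  expect_length(tileVolume(c(64, 256, 128), c(64, 128, 128), 0), 2L)
  expect_error(tileVolume(c(64, 128, 128), c(64, 128, 128), c(64, 0, 0)),
               "overlap")

  # brute-force cover enumerator as the oracle
  oracleStarts <- function(n, p, s) {
    st <- 1L
    out <- integer(0)
    while (TRUE) {
      st <- min(st, n - p + 1L)
      out <- c(out, st)
      if (st + p - 1L >= n) break
      st <- st + s
    }
    unique(out)
  }
  shape <- c(70, 140, 150); patch <- c(64, 128, 128); ov <- c(8, 16, 16)
  specs <- tileVolume(shape, patch, ov)
  stride <- patch - ov
  want <- expand.grid(x = oracleStarts(shape[3], patch[3], stride[3]),
                      y = oracleStarts(shape[2], patch[2], stride[2]),
                      z = oracleStarts(shape[1], patch[1], stride[1]))
  got <- t(vapply(specs, function(s) s@start, integer(3)))
  expect_equal(nrow(got), nrow(want))  # minimal count for the scheme
  expect_equal(got[, 1], want$z)       # z-major ordering
  expect_equal(got[, 2], want$y)
  expect_equal(got[, 3], want$x)

  cover <- array(0L, shape)
  for (s in specs) {
    e <- s@start + s@size - 1L
    cover[s@start[1]:e[1], s@start[2]:e[2], s@start[3]:e[3]] <-
      cover[s@start[1]:e[1], s@start[2]:e[2], s@start[3]:e[3]] + 1L
  }
  expect_true(all(cover >= 1L))
})

test_that("mean fusion reproduces simple overlap cases", {
  sp1 <- SubVolumeSpec(c(1, 1, 1), c(2, 4, 4))
  whole <- array(runif(2 * 4 * 4), c(2, 4, 4))
  fused <- fusePatches(list(sp1), list(whole), c(2, 4, 4))
  expect_equal(volData(fused), whole)

  # two constant patches overlapping in columns 3:4 of a 2x4x6 volume
  a <- array(0, c(2, 4, 4))
  b <- array(1, c(2, 4, 4))
  f <- fusePatches(list(SubVolumeSpec(c(1, 1, 1), c(2, 4, 4)),
                        SubVolumeSpec(c(1, 1, 3), c(2, 4, 4))),
                   list(a, b), c(2, 4, 6))
  expect_true(all(volData(f)[, , 1:2] == 0))
  expect_true(all(volData(f)[, , 3:4] == 0.5))
  expect_true(all(volData(f)[, , 5:6] == 1))

  expect_error(fusePatches(list(sp1), list(whole), c(4, 4, 4)), "cover")
  expect_error(fusePatches(list(sp1), list(array(0, c(1, 4, 4))),
                           c(2, 4, 4)), "size")
})

test_that("tile -> crop -> fuse reconstructs any volume exactly", {
  set.seed(20)
  prob <- ProbabilityVolume(array(runif(24 * 40 * 40), c(24, 40, 40)))
  for (ov in list(c(0, 0, 0), c(8, 16, 16))) {
    specs <- tileVolume(dim(prob), c(16, 32, 32), ov)
    patches <- lapply(specs, function(s) cropVolume(prob, s))
    fused <- fusePatches(specs, patches, dim(prob))
    expect_equal(volData(fused), volData(prob), tolerance = 1e-15)
  }
})

test_that("fused values stay within the contributing patch range", {
  set.seed(21)
  shape <- c(8, 12, 12)
  specs <- tileVolume(shape, c(4, 8, 8), c(2, 4, 4))
  patches <- lapply(specs, function(s) array(runif(prod(s@size)), s@size))
  fused <- fusePatches(specs, patches, shape)
  expect_true(all(volData(fused) >= 0 & volData(fused) <= 1))
  # oracle: accumulate sums and counts independently
  acc <- array(0, shape); cnt <- array(0, shape)
  for (i in seq_along(specs)) {
    s <- specs[[i]]; e <- s@start + s@size - 1L
    acc[s@start[1]:e[1], s@start[2]:e[2], s@start[3]:e[3]] <-
      acc[s@start[1]:e[1], s@start[2]:e[2], s@start[3]:e[3]] + patches[[i]]
    cnt[s@start[1]:e[1], s@start[2]:e[2], s@start[3]:e[3]] <-
      cnt[s@start[1]:e[1], s@start[2]:e[2], s@start[3]:e[3]] + 1
  }
  expect_equal(volData(fused), acc / cnt, tolerance = 1e-15)
})
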