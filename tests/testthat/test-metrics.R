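# Brute-force oracles: exhaustive neighbor scan for the surface and
# O(|A||B|) pairwise distance loops for ASD / Hausdorff.

oracleSurface <- function(mask) {
  m <- volData(mask)
  d <- dim(m)
  sp <- volSpacing(mask)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] != 1L) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else 0L, if (i < d[1]) m[i + 1, j, k] else 0L,
      if (j > 1) m[i, j - 1, k] else 0L, if (j < d[2]) m[i, j + 1, k] else 0L,
      if (k > 1) m[i, j, k - 1] else 0L, if (k < d[3]) m[i, j, k + 1] else 0L)
    if (any(nb == 0L)) pts <- rbind(pts, (c(i, j, k) - 1) * sp)
  }
  pts
}

pairwiseMins <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min(colSums((t(B) - A[i, ])^2))), numeric(1))
}

oracleAsd <- function(A, B) (mean(pairwiseMins(A, B)) +
                               mean(pairwiseMins(B, A))) / 2

oracleHd <- function(A, B, p = 1) {
  dir <- function(X, Y) {
    dd <- sort(pairwiseMins(X, Y))
    dd[ceiling(p * length(dd))]
  }
  max(dir(A, B), dir(B, A))
}

randomMask <- function(dims, p, spacing = c(1, 1, 1)) {
  m <- array(rbinom(prod(dims), 1, p), dims)
  if (!any(m == 1L)) m[1, 1, 1] <- 1L
  LabelVolume(m, spacing)
}

test_that("Dice handles the canonical overlap cases", {
  a <- cubeMask(c(4, 4, 4), 1:2, 1:2, 1:2)
  expect_equal(diceCoefficient(a, a), 1)
  b <- cubeMask(c(4, 4, 4), 3:4, 3:4, 3:4)
  expect_equal(diceCoefficient(a, b), 0)
  # |A| = 2, |B| = 2, one shared voxel
  x <- cubeMask(c(3, 3, 3), 1, 1, 1:2)
  y <- cubeMask(c(3, 3, 3), 1, 1, 2:3)
  expect_equal(diceCoefficient(x, y), 0.5)
  empty <- LabelVolume(array(0L, c(3, 3, 3)))
  expect_equal(diceCoefficient(empty, empty), 1)
})

test_that("surface extraction matches the exhaustive neighbor scan", {
  single <- cubeMask(c(5, 5, 5), 3, 3, 3, spacing = c(2, 1, 1))
  s <- extractSurface(single)
  expect_equal(nrow(s), 1L)
  expect_equal(as.numeric(s), c(2 * 2, 2 * 1, 2 * 1))

  solid <- cubeMask(c(5, 5, 5), 2:4, 2:4, 2:4)
  shell <- extractSurface(solid)
  expect_equal(nrow(shell), 26L)  # 27-voxel cube minus its center
  expect_false(any(shell[, 1] == 2 & shell[, 2] == 2 & shell[, 3] == 2))

  set.seed(50)
  for (i in 1:5) {
    m <- randomMask(c(6, 7, 5), 0.4, spacing = c(0.5, 0.7, 1.1))
    got <- extractSurface(m)
    want <- oracleSurface(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2], want[, 3]), ,
                             drop = FALSE]),
                 ignore_attr = TRUE)
  }
  expect_error(extractSurface(LabelVolume(array(0L, c(3, 3, 3)))), "empty")
})

test_that("ASD reproduces hand-computed and brute-force values", {
  A <- matrix(c(0, 0, 0), 1)
  B <- matrix(c(0, 0, 1.5), 1)  # voxel (0,0,3) at 0.5 mm isotropic
  expect_equal(asd(A, B), 1.5)
  expect_equal(asd(A, A), 0)

  set.seed(51)
  for (i in 1:5) {
    ma <- randomMask(c(12, 12, 12), 0.2, spacing = c(0.8, 0.5, 0.5))
    mb <- randomMask(c(12, 12, 12), 0.2, spacing = c(0.8, 0.5, 0.5))
    A <- extractSurface(ma); B <- extractSurface(mb)
    expect_equal(asd(A, B), oracleAsd(A, B), tolerance = 1e-9)
    expect_equal(asd(A, B), asd(B, A))  # symmetric by construction
  }
})

test_that("Hausdorff distances follow the nearest-rank percentile rule", {
  A <- matrix(c(0, 0, 0), 1)
  B <- matrix(c(0, 0, 4), 1)
  expect_equal(hausdorffDistance(A, B, 0.95), 4)  # singleton: rank 1
  expect_equal(hausdorffDistance(A, A, 0.95), 0)
  expect_error(hausdorffDistance(A, B, 0), "percentile")

  set.seed(52)
  for (i in 1:5) {
    ma <- randomMask(c(10, 14, 9), 0.15, spacing = c(1.2, 0.6, 0.6))
    mb <- randomMask(c(10, 14, 9), 0.15, spacing = c(1.2, 0.6, 0.6))
    A <- extractSurface(ma); B <- extractSurface(mb)
    expect_equal(hausdorffDistance(A, B, 0.95), oracleHd(A, B, 0.95),
                 tolerance = 1e-9)
    expect_equal(hausdorffDistance(A, B, 1), oracleHd(A, B, 1),
                 tolerance = 1e-9)
  }
})

test_that("per-case evaluation composes the metrics and handles empties", {
  truth <- cubeMask(c(8, 8, 8), 2:5, 2:5, 2:5)
  perfect <- evaluateCase(truth, truth)
  expect_equal(perfect@dice, 1)
  expect_equal(c(perfect@asdMM, perfect@hd95MM, perfect@hdMM), c(0, 0, 0))

  shifted <- cubeMask(c(8, 8, 8), 3:6, 2:5, 2:5)
  rep <- evaluateCase(shifted, truth)
  A <- extractSurface(shifted); B <- extractSurface(truth)
  expect_equal(rep@dice, diceCoefficient(shifted, truth))
  expect_equal(rep@asdMM, oracleAsd(A, B), tolerance = 1e-9)
  expect_equal(rep@hd95MM, oracleHd(A, B, 0.95), tolerance = 1e-9)
  expect_equal(rep@hdMM, oracleHd(A, B, 1), tolerance = 1e-9)

  empty <- LabelVolume(array(0L, c(8, 8, 8)))
  both <- evaluateCase(empty, empty)
  expect_equal(both@dice, 1)
  expect_equal(both@hdMM, 0)
  expect_warning(one <- evaluateCase(empty, truth), "undefined")
  expect_equal(one@dice, 0)
  expect_true(is.na(one@asdMM))
})

test_that("rank ordering keeps hd95 below hd on random pairs", {
  set.seed(53)
  for (i in 1:50) {
    a <- randomMask(c(8, 8, 8), runif(1, 0.05, 0.5))
    b <- randomMask(c(8, 8, 8), runif(1, 0.05, 0.5))
    r <- evaluateCase(a, b)
    expect_lte(r@hd95MM, r@hdMM + 1e-12)
    expect_lte(r@asdMM, r@hdMM + 1e-12)
  }
})

test_that("scaling the voxel spacing scales distances, not Dice", {
  set.seed(54)
  a <- randomMask(c(9, 9, 9), 0.2, spacing = c(1, 0.5, 0.5))
  b <- randomMask(c(9, 9, 9), 0.2, spacing = c(1, 0.5, 0.5))
  r1 <- evaluateCase(a, b)
  k <- 3.5
  a2 <- LabelVolume(volData(a), volSpacing(a) * k)
  b2 <- LabelVolume(volData(b), volSpacing(b) * k)
  r2 <- evaluateCase(a2, b2)
  expect_equal(r2@dice, r1@dice)
  expect_equal(r2@asdMM, k * r1@asdMM, tolerance = 1e-12)
  expect_equal(r2@hd95MM, k * r1@hd95MM, tolerance = 1e-12)
  expect_equal(r2@hdMM, k * r1@hdMM, tolerance = 1e-12)
})

test_that("dataset evaluation writes a per-case table with summary rows", {
  d <- withr::local_tempdir()
  truth <- cubeMask(c(6, 6, 6), 2:4, 2:4, 2:4)
  pred <- cubeMask(c(6, 6, 6), 2:4, 2:4, 3:5)
  tab <- evaluateDataset(list(pred, truth), list(truth, truth),
                         file = file.path(d, "report.csv"))
  expect_equal(tab$case_id, c("case001", "case002", "mean", "sd"))
  expect_equal(tab$dice[2], 1)
  expect_equal(tab$dice[3], mean(tab$dice[1:2]))
  back <- read.csv(file.path(d, "report.csv"))
  expect_equal(back$dice, tab$dice, tolerance = 1e-12)
  evaluateDataset(list(pred), list(truth), file = file.path(d, "report.json"))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(length(js), 3L)
})
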