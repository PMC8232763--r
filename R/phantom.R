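# Synthetic mandible-like phantoms: a bright horseshoe arch (body) with two
# rami and condylar knobs, metallic "tooth" voxels far above the clip
# ceiling, in-plane streak artifacts radiating from each metal voxel, and
# additive Gaussian noise. Labels are the clean anatomy; artifacts corrupt
# only the image.

#' Phantom generator configuration
#'
#' Describes a synthetic scan: geometry of the mandible-like structure,
#' material intensities on a CT-like scale, metal/streak artifact settings
#' and the noise level. \code{metalIntensity} (default 3000) deliberately
#' exceeds the standard clip ceiling of 2000 so metallic voxels saturate
#' after [normalizeIntensity()], as real fillings and braces do.
#'
#' \code{archParams} controls the anatomy, as fractions of the in-plane
#' extent: \code{center} (row, col) of the dental arch; \code{outerRadius}
#' (of the smaller in-plane dimension); \code{thickness} (of the outer
#' radius); \code{openingDeg}, the posterior opening angle of the horseshoe
#' in degrees; \code{bodyZ} and \code{ramusZ}, fractional slice ranges of
#' the arch body and the rami; \code{condyleRadius} (of the smaller in-plane
#' dimension).
#'
#' @param shape integer(3) volume shape (slices, rows, cols), each >= 8.
#' @param spacing numeric(3) voxel spacing (dz, dy, dx) in mm.
#' @param boneIntensity mean intensity of the arch.
#' @param tissueIntensity background mean intensity.
#' @param metalIntensity intensity of metallic voxels
#'   (> boneIntensity > tissueIntensity required).
#' @param nMetalSeeds number of metallic tooth voxels.
#' @param streakCount streak rays per metal voxel.
#' @param streakAmplitude absolute intensity offset of streaks at the source.
#' @param noiseSD Gaussian noise standard deviation (>= 0).
#' @param archParams list of geometry fractions, see Details.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A \code{PhantomConfig}.
#' @aliases PhantomConfig-class
#' @export
PhantomConfig <- function(shape = c(32, 64, 64), spacing = c(1, 0.5, 0.5),
                          boneIntensity = 1200, tissueIntensity = 0,
                          metalIntensity = 3000, nMetalSeeds = 4,
                          streakCount = 6, streakAmplitude = 400,
                          noiseSD = 50,
                          archParams = list(), seed = 1) {
  ap <- utils::modifyList(list(
    center = c(0.58, 0.50), outerRadius = 0.34, thickness = 0.36,
    openingDeg = 100, bodyZ = c(0.15, 0.50), ramusZ = c(0.50, 0.88),
    condyleRadius = 0.06), archParams)
  new("PhantomConfig", shape = as.integer(shape),
      spacing = as.numeric(spacing), boneIntensity = as.numeric(boneIntensity),
      tissueIntensity = as.numeric(tissueIntensity),
      metalIntensity = as.numeric(metalIntensity),
      nMetalSeeds = as.integer(nMetalSeeds),
      streakCount = as.integer(streakCount),
      streakAmplitude = as.numeric(streakAmplitude),
      noiseSD = as.numeric(noiseSD), archParams = ap, seed = as.integer(seed))
}

#' @rdname PhantomConfig
#' @export
setClass("PhantomConfig", representation(
  shape = "integer", spacing = "numeric", boneIntensity = "numeric",
  tissueIntensity = "numeric", metalIntensity = "numeric",
  nMetalSeeds = "integer", streakCount = "integer",
  streakAmplitude = "numeric", noiseSD = "numeric", archParams = "list",
  seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (any(object@shape < 8L)) return("all shape components must be >= 8")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (!(object@metalIntensity > object@boneIntensity &&
        object@boneIntensity > object@tissueIntensity))
    return("need metalIntensity > boneIntensity > tissueIntensity")
  if (object@archParams$thickness <= 0)
    return("degenerate arch: thickness must be > 0")
  if (object@archParams$outerRadius <= 0)
    return("degenerate arch: outerRadius must be > 0")
  TRUE
})

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# binary mask of the mandible-like structure; returns also per-part masks
phantomAnatomy <- function(shape, ap) {
  nz <- shape[1]; nr <- shape[2]; nc <- shape[3]
  yc <- ap$center[1] * nr; xc <- ap$center[2] * nc
  rOut <- ap$outerRadius * min(nr, nc)
  thick <- ap$thickness * rOut
  rIn <- rOut - thick
  halfOpen <- ap$openingDeg / 2 * pi / 180

  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- sqrt((yy - yc)^2 + (xx - xc)^2)
  ang <- atan2(yy - yc, xx - xc)
  # opening faces posterior (+row direction, angle pi/2)
  inWedge <- abs(atan2(sin(ang - pi / 2), cos(ang - pi / 2))) < halfOpen
  arch2d <- rr >= rIn & rr <= rOut & !inWedge

  # rami rise from the two arch ends; condyles cap them
  endAng <- pi / 2 + c(-1, 1) * halfOpen
  rMid <- (rIn + rOut) / 2
  ry <- yc + rMid * sin(endAng)
  rx <- xc + rMid * cos(endAng)
  rRad <- thick / 2
  ramus2d <- ((yy - ry[1])^2 + (xx - rx[1])^2 <= rRad^2) |
             ((yy - ry[2])^2 + (xx - rx[2])^2 <= rRad^2)

  zBody <- max(1L, round(ap$bodyZ[1] * nz)):min(nz, round(ap$bodyZ[2] * nz))
  zRamus <- max(1L, round(ap$ramusZ[1] * nz)):min(nz, round(ap$ramusZ[2] * nz))
  cRad <- ap$condyleRadius * min(nr, nc)
  zCond <- max(zRamus)

  lab <- array(0L, shape)
  for (z in zBody) lab[z, , ][arch2d] <- 1L
  for (z in zRamus) lab[z, , ][ramus2d] <- 1L
  for (z in seq_len(nz)) {
    dz2 <- cRad^2 - (z - zCond)^2
    if (dz2 <= 0) next
    cond2d <- ((yy - ry[1])^2 + (xx - rx[1])^2 <= dz2) |
              ((yy - ry[2])^2 + (xx - rx[2])^2 <= dz2)
    lab[z, , ][cond2d] <- 1L
  }
  # anterior teeth region of the body band, candidate sites for metal seeds
  anterior2d <- arch2d & abs(atan2(sin(ang + pi / 2), cos(ang + pi / 2))) < 0.7
  list(label = lab, anterior2d = anterior2d, zBody = zBody)
}

# in-plane ray through `center` at `angle`; returns a data.frame of cells
# (row, col) with a linear falloff factor, ordered from the source outwards
streakRayCells <- function(nr, nc, center, angle, falloffLen) {
  tt <- seq(-falloffLen, falloffLen, by = 0.5)
  ry <- round(center[1] + tt * sin(angle))
  rx <- round(center[2] + tt * cos(angle))
  keep <- ry >= 1 & ry <= nr & rx >= 1 & rx <= nc
  tt <- tt[keep]; ry <- ry[keep]; rx <- rx[keep]
  o <- order(abs(tt))
  tt <- tt[o]; ry <- ry[o]; rx <- rx[o]
  dup <- duplicated(ry + nr * rx)
  data.frame(row = ry[!dup], col = rx[!dup],
             factor = pmax(0, 1 - abs(tt[!dup]) / falloffLen))
}

#' Add in-plane streak artifacts around metallic voxels
#'
#' For every metal voxel, \code{streakCount} rays at random in-plane angles
#' are rasterized through that voxel across its axial slice; voxels on the
#' s-th ray receive an intensity offset of alternating sign
#' \eqn{(-1)^{s+1}} amplitude, with linear falloff away from the source.
#' Voxels on no ray are unchanged. This is a visual model of the bright/dark
#' streaks that metal objects create, not a cone-beam physics simulation.
#' Angles are drawn from the current RNG state; seed the RNG (or use
#' [generatePhantom()]) for reproducibility.
#'
#' @param image an [ImageVolume()].
#' @param metalMask a [LabelVolume()] marking metal voxels, same geometry.
#' @param streakCount rays per metal voxel.
#' @param streakAmplitude intensity offset at the source (0 = no-op).
#' @return The corrupted [ImageVolume()].
#' @export
addStreakArtifacts <- function(image, metalMask, streakCount, streakAmplitude) {
  stopifnot(is(image, "ImageVolume"), is(metalMask, "LabelVolume"))
  if (!sameGeometry(image, metalMask))
    stop("metal mask geometry does not match the image")
  arr <- image@data
  seeds <- which(metalMask@data == 1L, arr.ind = TRUE)
  if (nrow(seeds) == 0L || streakCount < 1L)
    return(ImageVolume(arr, image@spacing, image@origin))
  nr <- dim(arr)[2]; nc <- dim(arr)[3]
  falloffLen <- max(nr, nc)
  for (i in seq_len(nrow(seeds))) {
    z <- seeds[i, 1]
    angles <- runif(streakCount, 0, 2 * pi)
    for (s in seq_len(streakCount)) {
      sgn <- if (s %% 2 == 1) 1 else -1
      cells <- streakRayCells(nr, nc, seeds[i, 2:3], angles[s], falloffLen)
      ii <- cbind(z, cells$row, cells$col)
      arr[ii] <- arr[ii] + sgn * streakAmplitude * cells$factor
    }
  }
  ImageVolume(arr, image@spacing, image@origin)
}

#' Generate a synthetic mandible-like scan with paired ground truth
#'
#' Builds the label (arch body, rami, condyles; metallic tooth voxels are
#' inside the arch and labeled foreground, as teeth belong to the jaw in
#' the gold standard), then the image: tissue background + bone + metal
#' voxels + streak artifacts + Gaussian noise. Generation is deterministic
#' given \code{config@seed}; the label depends only on the geometry, never
#' on artifact or noise settings.
#'
#' @param config a [PhantomConfig()].
#' @return \code{list(image = ImageVolume, label = LabelVolume)}.
#' @examples
#' ph <- generatePhantom(PhantomConfig(shape = c(16, 32, 32), seed = 7))
#' mean(volData(ph$label))
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  withSeed(config@seed, {
    an <- phantomAnatomy(config@shape, config@archParams)
    lab <- an$label
    img <- array(config@tissueIntensity, config@shape)
    img[lab == 1L] <- config@boneIntensity

    metal <- array(0L, config@shape)
    if (config@nMetalSeeds > 0L) {
      sites2d <- which(an$anterior2d)
      if (length(sites2d) > 0L) {
        zTop <- max(an$zBody)  # teeth sit at the top slices of the body
        zPick <- sample(max(1L, zTop - 2L):zTop, config@nMetalSeeds,
                        replace = TRUE)
        pick <- sample(sites2d, config@nMetalSeeds,
                       replace = length(sites2d) < config@nMetalSeeds)
        nr <- config@shape[2]
        for (k in seq_len(config@nMetalSeeds)) {
          r <- ((pick[k] - 1) %% nr) + 1
          cc <- ((pick[k] - 1) %/% nr) + 1
          img[zPick[k], r, cc] <- config@metalIntensity
          metal[zPick[k], r, cc] <- 1L
          lab[zPick[k], r, cc] <- 1L  # inside the arch already, kept explicit
        }
      }
    }

    image <- ImageVolume(img, config@spacing)
    if (config@streakCount > 0L && config@streakAmplitude != 0) {
      image <- addStreakArtifacts(image, LabelVolume(metal, config@spacing),
                                  config@streakCount, config@streakAmplitude)
    }
    if (config@noiseSD > 0) {
      image <- ImageVolume(image@data + rnorm(length(img), 0, config@noiseSD),
                           config@spacing)
    }
    list(image = image, label = LabelVolume(lab, config@spacing))
  })
}

#' Write a dataset of phantom cases with a manifest
#'
#' Generates \code{nCases} phantoms (case i uses seed
#' \code{config@seed + i - 1}, so a dataset can be extended without
#' reshuffling earlier cases), writes paired image/label NIfTI files to
#' \code{outDir} and a \code{manifest.csv} with columns
#' \code{case_id,image,label,split}.
#'
#' @param nCases number of cases (>= 1).
#' @param config a [PhantomConfig()]; per-case seeds derive from its seed.
#' @param outDir output directory (created if missing).
#' @param split character vector of split tags, recycled to \code{nCases};
#'   default all \code{"train"}.
#' @return The manifest \code{data.frame}, invisibly; its \code{"path"}
#'   attribute holds the manifest file path.
#' @export
makeDataset <- function(nCases, config, outDir, split = "train") {
  stopifnot(nCases >= 1, is(config, "PhantomConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  split <- rep_len(split, nCases)
  rows <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    cfg <- config
    cfg@seed <- config@seed + i - 1L
    ph <- generatePhantom(cfg)
    ip <- file.path(outDir, sprintf("case%03d_image.nii.gz", i))
    lp <- file.path(outDir, sprintf("case%03d_label.nii.gz", i))
    writeVolume(ph$image, ip)
    writeVolume(ph$label, lp)
    rows[[i]] <- data.frame(case_id = sprintf("case%03d", i), image = ip,
                            label = lp, split = split[i])
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(outDir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  attr(manifest, "path") <- mp
  invisible(manifest)
}
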