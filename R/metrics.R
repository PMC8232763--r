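# Evaluation metrics on binary volumes with anisotropic voxel spacing:
# Dice overlap, average symmetric surface distance, and (95%) Hausdorff
# distance between boundary point sets measured in millimetres.

#' Dice coefficient between two binary volumes
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param pred,truth [LabelVolume()]s (or bare binary arrays) with matching
#'   geometry.
#' @return Overlap fraction in [0, 1].
#' @export
diceCoefficient <- function(pred, truth) {
  if (is(pred, "Volume") && is(truth, "Volume")) {
    if (!sameGeometry(pred, truth)) stop("pred/truth geometry mismatch")
    pred <- pred@data; truth <- truth@data
  }
  if (!identical(dim(pred), dim(truth))) stop("pred/truth shape mismatch")
  sa <- sum(pred); sb <- sum(truth)
  if (sa + sb == 0) return(1)
  2 * sum(pred * truth) / (sa + sb)
}

#' Extract the boundary point set of a mask
#'
#' The surface of a binary mask: all foreground voxels having at least one
#' background 6-neighbor, where out-of-volume counts as background. Points
#' are voxel centers in physical millimetres, \code{(index - 1) * spacing}
#' per axis.
#'
#' @param mask a nonempty [LabelVolume()].
#' @return A numeric matrix with columns \code{(z, y, x)} in mm, one row per
#'   surface voxel.
#' @export
extractSurface <- function(mask) {
  stopifnot(is(mask, "LabelVolume"))
  m <- mask@data
  if (!any(m == 1L)) stop("cannot extract a surface from an empty mask")
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  ci <- 2:(d[1] + 1); cj <- 2:(d[2] + 1); ck <- 2:(d[3] + 1)
  interior <- pad[ci - 1, cj, ck] & pad[ci + 1, cj, ck] &
    pad[ci, cj - 1, ck] & pad[ci, cj + 1, ck] &
    pad[ci, cj, ck - 1] & pad[ci, cj, ck + 1]
  idx <- which(m == 1L & !interior, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, mask@spacing, "*")
  colnames(pts) <- c("z", "y", "x")
  pts
}

#' Average symmetric surface distance
#'
#' \eqn{ASD(A, B) = [d(A,B) + d(B,A)]/2} with
#' \eqn{d(A,B) = |A|^{-1} \sum_{a} \min_b \|a - b\|} (Euclidean, mm).
#'
#' @param predSurface,truthSurface nonempty point matrices from
#'   [extractSurface()] (mm).
#' @return Distance in mm (>= 0), symmetric in its arguments.
#' @export
asd <- function(predSurface, truthSurface) {
  if (nrow(predSurface) == 0L || nrow(truthSurface) == 0L)
    stop("surface point sets must be nonempty")
  dab <- mean(cpp_nn_dists(predSurface, truthSurface))
  dba <- mean(cpp_nn_dists(truthSurface, predSurface))
  (dab + dba) / 2
}

#' (Percentile) Hausdorff distance
#'
#' Directed distance: the nearest-rank \code{percentile} (rank
#' \eqn{\lceil p \cdot |A| \rceil} of the ascending nearest-neighbor
#' distances from A to B); the symmetric value is the maximum of the two
#' directed values. \code{percentile = 1} gives the classical maximum
#' Hausdorff distance; \code{percentile = 0.95} the outlier-robust 95HD.
#'
#' @inheritParams asd
#' @param percentile fraction in (0, 1].
#' @return Distance in mm.
#' @export
hausdorffDistance <- function(predSurface, truthSurface, percentile = 1) {
  if (nrow(predSurface) == 0L || nrow(truthSurface) == 0L)
    stop("surface point sets must be nonempty")
  if (percentile <= 0 || percentile > 1)
    stop("percentile must be in (0, 1]")
  directed <- function(A, B) {
    dd <- sort(cpp_nn_dists(A, B))
    dd[ceiling(percentile * length(dd))]
  }
  max(directed(predSurface, truthSurface),
      directed(truthSurface, predSurface))
}

#' Evaluate one predicted segmentation against the ground truth
#'
#' Computes Dice, ASD, 95HD and maximum HD for one case. When both masks
#' are empty the case is perfect (Dice 1, all distances 0); when exactly
#' one mask is empty the surface distances are undefined and reported as
#' \code{NA} with a warning, keeping report tables finite.
#'
#' @param pred predicted [LabelVolume()].
#' @param truth ground-truth [LabelVolume()], same geometry.
#' @return A [MetricsReport()].
#' @export
evaluateCase <- function(pred, truth) {
  stopifnot(is(pred, "LabelVolume"), is(truth, "LabelVolume"))
  if (!sameGeometry(pred, truth)) stop("pred/truth geometry mismatch")
  dice <- diceCoefficient(pred, truth)
  ep <- !any(pred@data == 1L)
  et <- !any(truth@data == 1L)
  if (ep && et) return(MetricsReport(1, 0, 0, 0))
  if (ep || et) {
    warning("one mask is empty; surface distances are undefined (NA)")
    return(MetricsReport(dice, NA_real_, NA_real_, NA_real_))
  }
  sp <- extractSurface(pred)
  st <- extractSurface(truth)
  MetricsReport(dice, asd(sp, st), hausdorffDistance(sp, st, 0.95),
                hausdorffDistance(sp, st, 1))
}

#' Evaluate a set of cases and write a report table
#'
#' Runs [evaluateCase()] per case and assembles the per-case rows plus a
#' mean and standard-deviation summary. With \code{file} ending in
#' \code{.json} the table is written as JSON, otherwise as CSV.
#'
#' @param preds,truths lists of [LabelVolume()]s (or of NIfTI paths), in
#'   matching order.
#' @param caseIds optional character ids; defaults to \code{case001, ...}.
#' @param file optional output path for the report.
#' @return A \code{data.frame} with columns \code{case_id, dice, asd_mm,
#'   hd95_mm, hd_mm}; the summary rows carry ids \code{mean} and \code{sd}.
#' @export
evaluateDataset <- function(preds, truths, caseIds = NULL, file = NULL) {
  if (length(preds) != length(truths))
    stop("preds and truths must have equal length")
  loadIf <- function(x) if (is.character(x)) readVolume(x, "label") else x
  if (is.null(caseIds)) caseIds <- sprintf("case%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    as.data.frame(evaluateCase(loadIf(preds[[i]]), loadIf(truths[[i]])))
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(case_id = caseIds, tab)
  num <- tab[, -1, drop = FALSE]
  summary <- data.frame(
    case_id = c("mean", "sd"),
    rbind(colMeans(num, na.rm = TRUE),
          apply(num, 2, stats::sd, na.rm = TRUE)))
  out <- rbind(tab, summary)
  rownames(out) <- NULL
  if (!is.null(file)) {
    if (grepl("\\.json$", file)) {
      jsonlite::write_json(out, file, dataframe = "rows", digits = NA)
    } else {
      write.csv(out, file, row.names = FALSE)
    }
  }
  out
}
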