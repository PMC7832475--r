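#' ROI extraction settings
#'
#' @param metal_threshold_hu HU cutoff above which voxels are treated as
#'   metal and removed from the ROI. Default 1400 HU; applied inclusively
#'   (a voxel at exactly the threshold is removed) so partial-volume metal
#'   never enters the density ROI.
#' @param erosion_depth_mm metric erosion depth in mm applied to the body
#'   mask to exclude cortical bone and partial-volume effects. Default 10.
#' @param min_roi_voxels QC floor: an eroded ROI with fewer voxels is
#'   excluded. Default 50.
#' @param manual_exclusions character vector of levels (`"L1".."L4"`) to drop
#'   regardless of mask content — the analogue of excluding fractured or
#'   severely degenerated vertebrae on visual inspection.
#' @return A `RoiConfig` (validated list).
#' @export
roiConfig <- function(metal_threshold_hu = 1400, erosion_depth_mm = 10,
                      min_roi_voxels = 50, manual_exclusions = character()) {
  stopifnot(metal_threshold_hu > 0, erosion_depth_mm >= 0, min_roi_voxels >= 1,
            all(manual_exclusions %in% .LEVELS))
  structure(list(metal_threshold_hu = metal_threshold_hu,
                 erosion_depth_mm = erosion_depth_mm,
                 min_roi_voxels = as.integer(min_roi_voxels),
                 manual_exclusions = manual_exclusions),
            class = "RoiConfig")
}

#' Select the vertebral body mask for one level
#'
#' Returns the binary mask of voxels carrying the level's body label only;
#' posterior elements (codes 101-104) and hardware (200) are excluded by
#' construction of the label dialect.
#'
#' @param labels a [LabelMap-class].
#' @param level `"L1".."L4"`.
#' @return Logical array on the label-map grid.
#' @export
selectVertebralBody <- function(labels, level) {
  stopifnot(is(labels, "LabelMap"))
  level <- match.arg(level, .LEVELS)
  code <- .BODY_CODES[[level]]
  mask <- labels@labels == code
  if (!any(mask))
    stop(sprintf("no vertebral body label for level %s in the label map",
                 level))
  mask
}

#' Remove metal voxels from a mask
#'
#' Drops every masked voxel with attenuation at or above the metal
#' threshold. Pedicle screws (and their densest partial-volume voxels) are
#' far above any bone HU, so this cleanly delineates screw contours.
#'
#' @param vol a [CTVolume-class] co-registered with `mask`.
#' @param mask logical array.
#' @param cfg a [roiConfig()].
#' @return Logical array, a subset of `mask`, with no retained voxel at
#'   HU >= `metal_threshold_hu`.
#' @export
excludeMetal <- function(vol, mask, cfg = roiConfig()) {
  stopifnot(is(vol, "CTVolume"), inherits(cfg, "RoiConfig"))
  .checkMask(vol, mask)
  mask & vol@values < cfg$metal_threshold_hu
}

## 1-D squared distance transform (Felzenszwalb-Huttenlocher lower
## envelope) with sampling step s; f holds squared distances, BIG = +inf.
.dt1d <- function(f, s, BIG) {
  n <- length(f)
  if (n == 1L || all(f >= BIG)) return(f)
  s2 <- s * s
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      inter <- ((f[q] + q * q * s2) - (f[p] + p * p * s2)) /
        (2 * s2 * (q - p))
      if (inter <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- inter
    z[k + 1L] <- Inf
  }
  out <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    out[q] <- (q - p)^2 * s2 + f[p]
  }
  out
}

## apply the 1-D transform along axis `ax` of 3-D array a
.dtAxis <- function(a, ax, s, BIG) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = d[ax])
  for (j in seq_len(ncol(m))) m[, j] <- .dt1d(m[, j], s, BIG)
  aperm(array(m, d[perm]), order(perm))
}

#' Squared Euclidean distance to the mask complement, in world mm
#'
#' Separable exact distance transform honouring anisotropic voxel spacing.
#' Voxels outside the mask get distance 0. If the mask has no complement in
#' the grid, distances are infinite.
#'
#' @param mask logical array.
#' @param spacing numeric(3), mm per voxel along each axis.
#' @return Numeric array of squared distances (mm^2).
#' @export
distanceToComplement <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, all(spacing > 0))
  d <- dim(mask)
  BIG <- sum((d * spacing)^2) * 4 + 1
  f <- array(ifelse(mask, BIG, 0), dim = d)
  for (ax in 1:3) f <- .dtAxis(f, ax, spacing[ax], BIG)
  f[f >= BIG] <- Inf
  f
}

#' Metric erosion of a binary mask
#'
#' Keeps exactly the voxels whose Euclidean distance to the mask complement
#' exceeds `depth_mm`, computed in world millimetres so that anisotropic
#' voxels (e.g. 2-3 mm slices) erode by the same physical depth along every
#' axis. This is a metric operation, not iterated structuring-element
#' erosion. Depth 0 returns the mask unchanged; an empty result is legal
#' and left to QC.
#'
#' For speed the transform runs on the mask's bounding box padded by one
#' voxel: every voxel outside the bounding box is complement, so the padded
#' shell carries a complement voxel at least as close as any farther one —
#' the crop is exact.
#'
#' @param mask logical array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param depth_mm erosion depth in mm, >= 0.
#' @return Logical array, subset of `mask`.
#' @examples
#' m <- array(TRUE, c(30, 30, 30))  # 30 mm cube at 1 mm spacing
#' sum(erodeMask(m, c(1, 1, 1), 5)) # interior 20 mm core, minus boundary
#' @export
erodeMask <- function(mask, spacing, depth_mm) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, all(spacing > 0),
            depth_mm >= 0)
  if (depth_mm == 0 || !any(mask)) return(mask)
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  dist2 <- distanceToComplement(sub, spacing)
  out <- array(FALSE, dim = d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dist2 > depth_mm^2
  out & mask
}

#' Per-vertebra quality control
#'
#' Rule-based replacement for visual QC: a vertebra is excluded when it is
#' on the manual exclusion list (fracture or severe degeneration flagged by
#' the reader), when erosion emptied its mask, or when the eroded ROI is
#' smaller than `min_roi_voxels`. A vertebra is included iff no reason
#' applies.
#'
#' @param mask_eroded logical array, the final eroded ROI.
#' @param level `"L1".."L4"`.
#' @param cfg a [roiConfig()].
#' @return `QCResult`: list with `level`, `included`, `reasons`, `n_voxels`.
#' @export
qcVertebra <- function(mask_eroded, level, cfg = roiConfig()) {
  level <- match.arg(level, .LEVELS)
  stopifnot(inherits(cfg, "RoiConfig"))
  n <- sum(mask_eroded)
  reasons <- character()
  if (level %in% cfg$manual_exclusions) reasons <- c(reasons, "manual_exclusion")
  if (n == 0) reasons <- c(reasons, "empty_after_erosion")
  else if (n < cfg$min_roi_voxels) reasons <- c(reasons, "below_min_voxels")
  structure(list(level = level, included = length(reasons) == 0L,
                 reasons = reasons, n_voxels = as.integer(n)),
            class = "QCResult")
}
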