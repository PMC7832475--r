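#' ACR density bands
#'
#' American College of Radiology practice-parameter thresholds for
#' volumetric lumbar BMD: osteoporosis below 80 mg/cm^3, low bone mass from
#' 80 to 120 mg/cm^3 (both boundaries inclusive to low bone mass), normal
#' above 120 mg/cm^3.
#'
#' @param osteoporosis_below lower band boundary, mg/cm^3 (default 80).
#' @param low_mass_upper upper band boundary, mg/cm^3 (default 120).
#' @return An `AcrThresholds` (validated list).
#' @export
acrThresholds <- function(osteoporosis_below = 80, low_mass_upper = 120) {
  stopifnot(osteoporosis_below > 0, osteoporosis_below < low_mass_upper)
  structure(list(osteoporosis_below = osteoporosis_below,
                 low_mass_upper = low_mass_upper),
            class = "AcrThresholds")
}

#' ROI attenuation statistics
#'
#' Arithmetic mean and sample SD (n-1 denominator) of HU over exactly the
#' ROI voxels.
#'
#' @param vol a [CTVolume-class].
#' @param roi logical array co-registered with `vol`, nonempty.
#' @return `list(mean_hu, sd_hu, n_voxels)`; `sd_hu` is 0 for a single-voxel
#'   ROI.
#' @export
meanHu <- function(vol, roi) {
  stopifnot(is(vol, "CTVolume"))
  .checkMask(vol, roi)
  v <- vol@values[roi]
  if (length(v) == 0)
    stop("empty ROI: vertebra should have been excluded by QC")
  list(mean_hu = mean(v),
       sd_hu = if (length(v) > 1) stats::sd(v) else 0,
       n_voxels = length(v))
}

#' Convert attenuation to volumetric BMD
#'
#' Applies the asynchronous linear calibration `bmd = slope * hu +
#' intercept`. Strictly increasing in HU; by linearity, calibrating a mean
#' HU equals the mean of per-voxel calibrated values.
#'
#' @param hu attenuation (scalar or vector), HU.
#' @param eq a [CalibrationEquation-class].
#' @return BMD in mg/cm^3.
#' @export
calibrate <- function(hu, eq) {
  stopifnot(is(eq, "CalibrationEquation"))
  eq@slope * hu + eq@intercept
}

#' Classify BMD into ACR bands
#'
#' `bmd < 80` is osteoporosis; `80 <= bmd <= 120` low bone mass (both
#' boundaries inclusive); `bmd > 120` normal. Every finite BMD maps to
#' exactly one category.
#'
#' @param bmd density in mg/cm^3 (vectorised).
#' @param thr an [acrThresholds()].
#' @return Factor with levels `osteoporosis`, `low_bone_mass`, `normal`.
#' @examples
#' classifyAcr(c(79.9, 80, 120, 120.1))
#' @export
classifyAcr <- function(bmd, thr = acrThresholds()) {
  stopifnot(inherits(thr, "AcrThresholds"), all(is.finite(bmd)))
  out <- ifelse(bmd < thr$osteoporosis_below, "osteoporosis",
                ifelse(bmd <= thr$low_mass_upper, "low_bone_mass", "normal"))
  factor(out, levels = c("osteoporosis", "low_bone_mass", "normal"))
}

#' Aggregate per-level measurements into a patient value
#'
#' Patient BMD is the unweighted mean of the BMD of QC-included levels
#' (level-wise averaging, not voxel-weighted), and the patient category is
#' the ACR band of that aggregate.
#'
#' @param measurements list of per-level measurement lists as produced by
#'   [runScreening()] (each with `bmd` and `qc`).
#' @param thr an [acrThresholds()].
#' @return `list(patient_bmd, patient_category, levels_used)`.
#' @export
aggregateLevels <- function(measurements, thr = acrThresholds()) {
  inc <- Filter(function(m) isTRUE(m$qc$included), measurements)
  if (length(inc) == 0)
    stop("no included vertebral level: BMD requires at least one vertebra")
  bmd <- mean(vapply(inc, `[[`, numeric(1), "bmd"))
  list(patient_bmd = bmd,
       patient_category = as.character(classifyAcr(bmd, thr)),
       levels_used = vapply(inc, function(m) m$qc$level, ""))
}

#' Opportunistic BMD screening on one CT volume
#'
#' Runs the full per-patient pipeline for every level L1-L4 present in the
#' label map: body selection (posterior elements excluded by label), metal
#' exclusion at the HU threshold, metric erosion, QC, mean-HU extraction,
#' calibration to BMD and ACR classification, then aggregation of included
#' levels into the patient BMD.
#'
#' @param vol a [CTVolume-class].
#' @param labels the co-registered [LabelMap-class].
#' @param roi_cfg a [roiConfig()].
#' @param eq a [CalibrationEquation-class]; its kVp must match the volume's.
#' @param thr an [acrThresholds()].
#' @param id patient identifier recorded in the report.
#' @return A `PatientReport`: list with `id`, `measurements` (per level),
#'   `patient_bmd`, `patient_category`, `levels_used`.
#' @examples
#' eq <- CalibrationEquation(120, 1, 0)
#' ph <- generateVolume(
#'   list(vertebraSpec("L1", center = c(24, 24, 20), trabecular_sd_hu = 0)),
#'   grid = list(dim = c(48, 64, 40), spacing = c(1, 1, 1)), seed = 1)
#' rep <- runScreening(ph$volume, ph$labels, eq = eq)
#' rep$patient_bmd  # 100: the painted trabecular HU under identity calibration
#' @export
runScreening <- function(vol, labels, roi_cfg = roiConfig(), eq,
                         thr = acrThresholds(), id = "patient") {
  stopifnot(is(vol, "CTVolume"), is(labels, "LabelMap"),
            is(eq, "CalibrationEquation"))
  .checkCoregistered(vol, labels)
  if (!isTRUE(all.equal(vol@kvp, eq@kvp)))
    stop(sprintf("calibration equation is for %g kVp but volume was acquired at %g kVp",
                 eq@kvp, vol@kvp))
  present <- .LEVELS[.BODY_CODES %in% unique(as.vector(labels@labels))]
  if (length(present) == 0) stop("label map contains no vertebral body")
  measurements <- lapply(present, function(level) {
    body <- selectVertebralBody(labels, level)
    nometal <- excludeMetal(vol, body, roi_cfg)
    roi <- erodeMask(nometal, vol@spacing, roi_cfg$erosion_depth_mm)
    qc <- qcVertebra(roi, level, roi_cfg)
    m <- list(level = level, qc = qc,
              n_body = sum(body), n_after_metal = sum(nometal))
    if (qc$included) {
      hu <- meanHu(vol, roi)
      m$mean_hu <- hu$mean_hu
      m$sd_hu <- hu$sd_hu
      m$n_voxels <- hu$n_voxels
      m$bmd <- calibrate(hu$mean_hu, eq)
      m$category <- as.character(classifyAcr(m$bmd, thr))
    }
    m
  })
  agg <- aggregateLevels(measurements, thr)
  structure(c(list(id = id, measurements = measurements), agg),
            class = "PatientReport")
}
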