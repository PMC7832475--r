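#' @import methods
NULL

## Label dialect shared by the package: 0 background, 1-4 vertebral bodies
## L1-L4, 101-104 posterior elements of L1-L4, 200 hardware.
.LEVELS <- c("L1", "L2", "L3", "L4")
.BODY_CODES <- stats::setNames(1:4, .LEVELS)
.POSTERIOR_CODES <- stats::setNames(101:104, .LEVELS)
.HARDWARE_CODE <- 200L
.VALID_KVP <- c(120, 140)
.CONSTRUCTS <- c("L1-5", "L2-5", "L2-S1", "L3-S1", "L4-S1")

#' CTVolume: a 3-D CT attenuation grid
#'
#' Holds a 3-D array of attenuation values in Hounsfield units (HU) together
#' with the anisotropic voxel spacing in millimetres and the acquisition peak
#' tube voltage (kVp). The kVp selects the HU-to-BMD calibration equation at
#' screening time (120 kVp for standard studies, 140 kVp for postmyelography).
#'
#' @slot values 3-D numeric array of attenuation in HU. Air is at about
#'   -1000 HU, water at 0 HU.
#' @slot spacing numeric(3), per-axis voxel size in mm; all positive.
#' @slot kvp scalar tube voltage, one of 120 or 140.
#' @aliases CTVolume
#' @exportClass CTVolume
setClass("CTVolume",
  representation(values = "array", spacing = "numeric", kvp = "numeric"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3-D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite HU")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive voxel sizes in mm")
  if (length(object@kvp) != 1L || !(object@kvp %in% .VALID_KVP))
    msg <- c(msg, "'kvp' must be 120 or 140")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param values 3-D numeric array of HU.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param kvp tube voltage, 120 (default) or 140.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(-1000, c(4, 4, 4)), spacing = c(1, 1, 2))
#' voxelSpacing(vol)
#' @export
CTVolume <- function(values, spacing, kvp = 120) {
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      kvp = as.numeric(kvp))
}

#' LabelMap: integer-labelled anatomy on a CT grid
#'
#' An integer label array co-registered with a [CTVolume-class]. Label codes
#' follow the package dialect: 0 background, 1-4 vertebral bodies L1-L4,
#' 101-104 the corresponding posterior elements, 200 hardware (screws).
#'
#' @slot labels 3-D integer array of label codes.
#' @slot spacing numeric(3), voxel spacing in mm (must equal the volume's).
#' @aliases LabelMap
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "array", spacing = "numeric"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "'labels' must be a 3-D array")
  codes <- unique(as.vector(object@labels))
  allowed <- c(0L, .BODY_CODES, .POSTERIOR_CODES, .HARDWARE_CODE)
  if (!all(codes %in% allowed))
    msg <- c(msg, sprintf("unknown label codes: %s",
                          paste(setdiff(codes, allowed), collapse = ", ")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive voxel sizes in mm")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#'
#' @param labels 3-D integer array in the package label dialect.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(labels, spacing) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, spacing = as.numeric(spacing))
}

#' CalibrationEquation: per-kVp linear HU to BMD mapping
#'
#' Asynchronous calibration converts mean trabecular attenuation (HU) to
#' volumetric bone mineral density (mg/cm^3) with a scanner- and
#' kVp-specific linear equation `bmd = slope * hu + intercept`. The
#' coefficients are site-specific configuration; there is no scientific
#' default.
#'
#' @slot kvp tube voltage the equation applies to (120 or 140).
#' @slot slope mg/cm^3 per HU; strictly positive (attenuation increases
#'   with mineral density).
#' @slot intercept mg/cm^3.
#' @aliases CalibrationEquation
#' @exportClass CalibrationEquation
setClass("CalibrationEquation",
  representation(kvp = "numeric", slope = "numeric", intercept = "numeric"))

setValidity("CalibrationEquation", function(object) {
  msg <- character()
  if (!(object@kvp %in% .VALID_KVP)) msg <- c(msg, "'kvp' must be 120 or 140")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "'slope' must be a positive finite scalar")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "'intercept' must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a CalibrationEquation
#'
#' @param kvp tube voltage (120 or 140).
#' @param slope mg/cm^3 per HU, positive.
#' @param intercept mg/cm^3.
#' @return A [CalibrationEquation-class] object.
#' @examples
#' eq <- CalibrationEquation(120, slope = 0.8, intercept = -5)
#' calibrate(150, eq)  # 115 mg/cm^3
#' @export
CalibrationEquation <- function(kvp, slope, intercept) {
  new("CalibrationEquation", kvp = as.numeric(kvp), slope = as.numeric(slope),
      intercept = as.numeric(intercept))
}

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %s mm, %g kVp\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "), object@kvp))
  cat(sprintf("  HU range [%g, %g]\n", min(object@values), max(object@values)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  codes <- sort(unique(as.vector(object@labels)))
  cat(sprintf("LabelMap: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x ")))
  cat("  label codes:", paste(codes, collapse = ", "), "\n")
})

setMethod("show", "CalibrationEquation", function(object) {
  cat(sprintf("CalibrationEquation (%g kVp): BMD = %g * HU + %g mg/cm^3\n",
              object@kvp, object@slope, object@intercept))
})
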