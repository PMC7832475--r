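## sidecar path: volume.nii.gz -> volume.json
.sidecarPath <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read and write CT volumes as NIfTI
#'
#' Volumes are stored as NIfTI (`.nii` / `.nii.gz`) with the voxel spacing
#' in the header; the acquisition kVp lives in a JSON sidecar next to the
#' image (same stem, `.json`), since NIfTI has no standard field for it.
#' The roundtrip preserves values, spacing and kVp exactly.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param vol a [CTVolume-class].
#' @return `readVolume` returns a [CTVolume-class]; `writeVolume` returns
#'   `path` invisibly.
#' @name volume-io
NULL

#' @rdname volume-io
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  img <- RNifti::asNifti(vol@values, pixdim = vol@spacing)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(kvp = vol@kvp), .sidecarPath(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("not a NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3 || any(!is.finite(spacing[1:3])) ||
      any(spacing[1:3] <= 0))
    stop("NIfTI header has missing or non-positive voxel spacing")
  side <- .sidecarPath(path)
  if (!file.exists(side))
    stop("kVp sidecar not found: ", side,
         " (required to select the calibration equation)")
  kvp <- jsonlite::read_json(side)$kvp
  CTVolume(array(as.numeric(img), dim = dim(img)), spacing[1:3], kvp)
}

#' Read and write label maps as NIfTI
#'
#' Label maps use the package dialect (0 background, 1-4 bodies L1-L4,
#' 101-104 posterior elements, 200 hardware), enforced on read.
#'
#' @param path NIfTI file path.
#' @param labels a [LabelMap-class].
#' @return `readLabelMap` returns a [LabelMap-class]; `writeLabelMap`
#'   returns `path` invisibly.
#' @name labelmap-io
NULL

#' @rdname labelmap-io
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  img <- RNifti::asNifti(labels@labels, pixdim = labels@spacing,
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname labelmap-io
#' @export
readLabelMap <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("not a NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  LabelMap(array(as.integer(img), dim = dim(img)), spacing[1:3])
}

#' Read a cohort CSV
#'
#' Expects the header `id,group,sex,age,construct,bmd`. Enumerated columns
#' are validated (`group` in case/control, `sex` in F/M, `construct` one of
#' the five lumbar constructs) and offending rows are reported by number;
#' duplicate ids are rejected.
#'
#' @param path CSV file path.
#' @return Data frame of typed patient records.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "sex", "age", "construct", "bmd")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ","),
         " (missing: ", paste(setdiff(need, names(df)), collapse = ","), ")")
  if (anyDuplicated(df$id))
    stop("duplicate patient ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  .checkEnum <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("invalid %s %s in row(s) %s (allowed: %s)", col,
                   paste(unique(df[[col]][bad]), collapse = ","),
                   paste(bad, collapse = ","),
                   paste(allowed, collapse = ", ")))
  }
  .checkEnum("group", c("case", "control"))
  .checkEnum("sex", c("F", "M"))
  .checkEnum("construct", .CONSTRUCTS)
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("ages must be positive numbers")
  df
}

#' Write a cohort CSV
#'
#' @param records cohort data frame (`id,group,sex,age,construct,bmd`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calibration equations (and optional thresholds) from YAML
#'
#' Expected layout: a top-level `equations:` list of `{kvp, slope,
#' intercept}` entries, optionally a `thresholds: {osteoporosis_below,
#' low_mass_upper}` block. There is no scientific default for the
#' coefficients — they are scanner-specific and must be supplied.
#'
#' @param path YAML file path.
#' @param kvp if given, return the single [CalibrationEquation-class] for
#'   that tube voltage (error if absent); otherwise a list of all equations.
#' @return A [CalibrationEquation-class], or
#'   `list(equations = ..., thresholds = ...)` when `kvp` is `NULL`.
#' @export
readCalibration <- function(path, kvp = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$equations)) stop("calibration YAML lacks an 'equations' list")
  eqs <- lapply(cfg$equations, function(e)
    CalibrationEquation(e$kvp, e$slope, e$intercept))
  thr <- if (!is.null(cfg$thresholds))
    acrThresholds(cfg$thresholds$osteoporosis_below,
                  cfg$thresholds$low_mass_upper)
  else acrThresholds()
  if (!is.null(kvp)) {
    hit <- Filter(function(e) e@kvp == kvp, eqs)
    if (length(hit) == 0)
      stop(sprintf("no calibration equation for %g kVp in %s", kvp, path))
    return(hit[[1]])
  }
  list(equations = eqs, thresholds = thr)
}

## strip classes/factors so a report serialises to plain JSON
.plainify <- function(x) {
  if (is.factor(x)) return(as.character(x))
  if (inherits(x, "table") || inherits(x, "matrix"))
    return(apply(x, 1, as.list, simplify = FALSE))
  if (is.data.frame(x)) return(lapply(unclass(x)[names(x)], .plainify))
  if (is.list(x)) return(lapply(unclass(x), .plainify))
  x
}

#' Write and read analysis reports as JSON
#'
#' Reports (a `StatsReport` from [buildTable2()] or a `PatientReport` from
#' [runScreening()]) are serialised to JSON together with a provenance
#' block (seed and package version). The JSON roundtrip is lossless for
#' every reported number at full double precision.
#'
#' @param report a report list.
#' @param path output `.json` path.
#' @param seed the RNG seed that produced the inputs, recorded in
#'   provenance.
#' @return `writeReport` returns `path` invisibly; `readReport` the parsed
#'   list.
#' @name report-io
NULL

#' @rdname report-io
#' @export
writeReport <- function(report, path, seed = NA) {
  out <- .plainify(report)
  out$provenance <- list(
    seed = seed,
    package = "QCTscreen",
    version = as.character(utils::packageVersion("QCTscreen")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname report-io
#' @export
readReport <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
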