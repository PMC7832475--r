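#' Accessors for imaging objects
#'
#' `ctValues()` returns the HU array of a [CTVolume-class]; `labelArray()`
#' the integer array of a [LabelMap-class]; `voxelSpacing()` the per-axis
#' voxel size in mm; `kvp()` the acquisition tube voltage.
#'
#' @param x a CTVolume or LabelMap.
#' @return The slot contents (array, numeric(3) or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("kvp", function(x) standardGeneric("kvp"))

#' @rdname accessors
setMethod("ctValues", "CTVolume", function(x) x@values)

#' @rdname accessors
setMethod("labelArray", "LabelMap", function(x) x@labels)

#' @rdname accessors
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname accessors
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @rdname accessors
setMethod("kvp", "CTVolume", function(x) x@kvp)

#' @rdname accessors
setMethod("kvp", "CalibrationEquation", function(x) x@kvp)

## internal: grid + spacing agreement between a volume and its label map
.checkCoregistered <- function(vol, labels) {
  if (!identical(dim(vol@values), dim(labels@labels)))
    stop("volume and label map grids differ: ",
         paste(dim(vol@values), collapse = "x"), " vs ",
         paste(dim(labels@labels), collapse = "x"))
  if (!isTRUE(all.equal(vol@spacing, labels@spacing)))
    stop("volume and label map voxel spacing differ")
  invisible(TRUE)
}

.checkMask <- function(vol, mask) {
  if (!is.logical(mask) || !identical(dim(vol@values), dim(mask)))
    stop("mask must be a logical array on the volume grid (shape mismatch)")
  invisible(TRUE)
}

## internal: run expr with a private RNG stream seeded from (seed, tag),
## restoring the caller's RNG state afterwards. One stream per operation so
## e.g. adding hardware does not perturb trabecular noise.
.withStream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + tag) %% .Machine$integer.max)
  expr
}
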