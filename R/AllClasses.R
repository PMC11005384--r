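#' @import methods
NULL

#' Volumetric data classes
#'
#' `potholeFA` represents co-registered 3D volumes with lightweight S4
#' classes. Every volume carries its voxel grid: the array dimensions, the
#' physical voxel size in mm per axis, and an opaque orientation tag
#' identifying the spatial frame. Two grids are compatible when all three
#' match (voxel sizes within 1e-6 mm); the pipeline refuses to mix volumes
#' from different grids, since registration is assumed to have happened
#' upstream.
#'
#' @slot values The voxel array (3D).
#' @slot voxelSize Numeric length-3, mm per axis.
#' @slot orientation Single string tagging the spatial frame.
#'
#' @section Subclasses:
#' \describe{
#'   \item{`FAVolume`}{Scalar fractional anisotropy in \[0, 1\] inside the
#'     brain; voxels outside the subject's mask are `NA`.}
#'   \item{`MaskVolume`}{Logical white-matter (or brain) mask; must contain
#'     at least one `TRUE` voxel.}
#'   \item{`AtlasVolume`}{Non-negative integer region labels (0 =
#'     background) plus a label -> region-name map.}
#' }
#'
#' @name BrainVolume-class
#' @aliases FAVolume-class MaskVolume-class AtlasVolume-class
#' @exportClass BrainVolume
#' @exportClass FAVolume
#' @exportClass MaskVolume
#' @exportClass AtlasVolume
setClass("BrainVolume",
  representation("VIRTUAL",
    values = "array",
    voxelSize = "numeric",
    orientation = "character"
  )
)

.validBrainVolume <- function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite numbers (mm)")
  if (length(object@orientation) != 1L || is.na(object@orientation))
    msg <- c(msg, "orientation must be a single string")
  if (length(msg)) msg else TRUE
}

setValidity("BrainVolume", .validBrainVolume)

setClass("FAVolume", contains = "BrainVolume")

setValidity("FAVolume", function(object) {
  v <- object@values
  inmask <- v[!is.na(v)]
  if (any(!is.finite(inmask)))
    return("non-finite FA values inside the mask (use NA outside)")
  if (length(inmask) && (min(inmask) < 0 || max(inmask) > 1))
    return("in-mask FA values must lie in [0, 1]")
  TRUE
})

setClass("MaskVolume", contains = "BrainVolume")

setValidity("MaskVolume", function(object) {
  if (!is.logical(object@values))
    return("mask values must be logical")
  if (anyNA(object@values))
    return("mask values must not contain NA")
  if (!any(object@values))
    return("mask must contain at least one TRUE voxel")
  TRUE
})

setClass("AtlasVolume",
  contains = "BrainVolume",
  representation(labelNames = "character")
)

setValidity("AtlasVolume", function(object) {
  v <- object@values
  if (anyNA(v) || any(v != round(v)) || any(v < 0))
    return("atlas labels must be non-negative integers")
  labs <- sort(unique(as.integer(v[v > 0])))
  missing <- setdiff(as.character(labs), names(object@labelNames))
  if (length(missing))
    return(paste0("labels without a name: ", paste(missing, collapse = ", ")))
  TRUE
})

#' @rdname BrainVolume-class
#' @param values 3D array of voxel values (logical for masks, integer-valued
#'   for atlases).
#' @param voxelSize Numeric length-3 voxel dimensions in mm.
#' @param orientation Orientation tag string.
#' @param labelNames Named character vector mapping label (as character) to
#'   region name; required for `AtlasVolume`.
#' @return A validated volume object of the corresponding class.
#' @examples
#' fa <- FAVolume(array(0.4, c(4, 4, 4)), voxelSize = c(2, 2, 3))
#' gridShape(fa)
#' voxelVolume(fa)
#' @export
FAVolume <- function(values, voxelSize = c(1, 1, 1), orientation = "LAS") {
  new("FAVolume", values = values, voxelSize = as.numeric(voxelSize),
      orientation = orientation)
}

#' @rdname BrainVolume-class
#' @export
MaskVolume <- function(values, voxelSize = c(1, 1, 1), orientation = "LAS") {
  storage.mode(values) <- "logical"
  new("MaskVolume", values = values, voxelSize = as.numeric(voxelSize),
      orientation = orientation)
}

#' @rdname BrainVolume-class
#' @export
AtlasVolume <- function(values, labelNames, voxelSize = c(1, 1, 1),
                        orientation = "LAS") {
  storage.mode(values) <- "integer"
  new("AtlasVolume", values = values, voxelSize = as.numeric(voxelSize),
      orientation = orientation, labelNames = labelNames)
}

#' Normative FA template
#'
#' Per-voxel mean and standard deviation of FA over a control cohort,
#' restricted to white matter common to all controls. Voxels whose sample SD
#' falls below the SD floor are excluded from the valid mask so that z-maps
#' never divide by (near-)zero.
#'
#' @slot mean,sd 3D arrays of the per-voxel sample mean and sample SD
#'   (denominator n - 1).
#' @slot validMask Logical 3D array of voxels where the template is defined.
#' @slot nControls Number of control subjects the template was built from.
#' @slot voxelSize,orientation Grid metadata, as for [BrainVolume-class].
#' @seealso [buildTemplate()], [computeZMap()]
#' @exportClass NormativeTemplate
setClass("NormativeTemplate",
  representation(
    mean = "array",
    sd = "array",
    validMask = "array",
    nControls = "integer",
    voxelSize = "numeric",
    orientation = "character"
  )
)

setValidity("NormativeTemplate", function(object) {
  d <- dim(object@mean)
  if (length(d) != 3L) return("mean must be a 3D array")
  if (!identical(dim(object@sd), d) || !identical(dim(object@validMask), d))
    return("mean, sd and validMask must share dimensions")
  if (!is.logical(object@validMask)) return("validMask must be logical")
  if (object@nControls < 2L) return("a template needs at least 2 controls")
  s <- object@sd[object@validMask]
  if (any(!is.finite(s)) || any(s < 0))
    return("sd must be finite and non-negative on valid voxels")
  TRUE
})

#' Per-subject FA z-map
#'
#' Voxel-wise z = (subject FA - control mean) / control SD, defined on the
#' intersection of the template's valid mask with the subject's own
#' white-matter mask and `NA` elsewhere. Voxels flagged `NA` can never join
#' a pothole cluster.
#'
#' @slot z 3D array of z-scores, `NA` off the valid set.
#' @slot validMask Logical 3D array marking where z is defined.
#' @slot voxelSize,orientation Grid metadata.
#' @seealso [computeZMap()], [detectPotholes()]
#' @exportClass ZMap
setClass("ZMap",
  representation(
    z = "array",
    validMask = "array",
    voxelSize = "numeric",
    orientation = "character"
  )
)

setValidity("ZMap", function(object) {
  if (!identical(dim(object@z), dim(object@validMask)))
    return("z and validMask must share dimensions")
  if (any(!is.finite(object@z[object@validMask])))
    return("z must be finite on valid voxels")
  TRUE
})

#' Statistical test result
#'
#' A uniform container for the package's group statistics: the test name,
#' statistic, degrees of freedom (one or two), p-value, a named effect size
#' (Cohen's d, eta-squared, rho, ...) and an optional multiplicity-adjusted
#' p-value.
#'
#' @slot test Test name.
#' @slot statistic Test statistic.
#' @slot df One or two degrees of freedom (may be `NA` for rank tests).
#' @slot p p-value in \[0, 1\].
#' @slot effectName,effectSize Name and value of the effect size (`NA` when
#'   the test does not define one).
#' @slot adjustedP Adjusted p-value, or `NA` when no correction was applied.
#' @exportClass StatResult
setClass("StatResult",
  representation(
    test = "character",
    statistic = "numeric",
    df = "numeric",
    p = "numeric",
    effectName = "character",
    effectSize = "numeric",
    adjustedP = "numeric"
  ),
  prototype(effectName = NA_character_, effectSize = NA_real_,
            adjustedP = NA_real_)
)

setValidity("StatResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must be in [0, 1]")
  if (!is.na(object@adjustedP) &&
      (object@adjustedP < 0 || object@adjustedP > 1))
    return("adjustedP must be in [0, 1]")
  TRUE
})

StatResult <- function(test, statistic, df, p, effectName = NA_character_,
                       effectSize = NA_real_, adjustedP = NA_real_) {
  new("StatResult", test = test, statistic = as.numeric(statistic),
      df = as.numeric(df), p = as.numeric(p),
      effectName = effectName, effectSize = as.numeric(effectSize),
      adjustedP = as.numeric(adjustedP))
}
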