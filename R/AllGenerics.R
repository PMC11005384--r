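#' Grid accessors
#'
#' Accessors for the voxel grid shared by all volumetric objects: the array
#' shape (voxels per axis), the physical voxel size (mm per axis), the voxel
#' volume (mm^3) and the orientation tag.
#'
#' @param x A [BrainVolume-class], [NormativeTemplate-class] or
#'   [ZMap-class] object.
#' @return `gridShape` an integer length-3 vector; `voxelSize` a numeric
#'   length-3 vector (mm); `voxelVolume` a single number (mm^3);
#'   `orientationTag` a string; `voxelValues` the underlying 3D array.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname grid-accessors
#' @export
setGeneric("orientationTag", function(x) standardGeneric("orientationTag"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

.defGridMethods <- function(cls, arraySlot) {
  setMethod("gridShape", cls, function(x) dim(slot(x, arraySlot)))
  setMethod("voxelSize", cls, function(x) x@voxelSize)
  setMethod("voxelVolume", cls, function(x) prod(x@voxelSize))
  setMethod("orientationTag", cls, function(x) x@orientation)
  setMethod("voxelValues", cls, function(x) slot(x, arraySlot))
  invisible(NULL)
}

.defGridMethods("BrainVolume", "values")
.defGridMethods("NormativeTemplate", "mean")
.defGridMethods("ZMap", "z")

#' @rdname BrainVolume-class
#' @param x An `AtlasVolume`.
#' @export
labelNames <- function(x) {
  stopifnot(is(x, "AtlasVolume"))
  x@labelNames
}

#' Number of controls behind a normative template
#' @param x A [NormativeTemplate-class].
#' @return Integer count of control subjects.
#' @export
nControls <- function(x) {
  stopifnot(is(x, "NormativeTemplate"))
  x@nControls
}

#' Valid-voxel mask of a template or z-map
#' @param x A [NormativeTemplate-class] or [ZMap-class].
#' @return Logical 3D array.
#' @export
validMask <- function(x) {
  stopifnot(is(x, "NormativeTemplate") || is(x, "ZMap"))
  x@validMask
}

setMethod("show", "BrainVolume", function(object) {
  d <- gridShape(object)
  cat(sprintf("%s: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm [%s]\n",
              class(object), d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@orientation))
  if (is(object, "MaskVolume"))
    cat(sprintf("  %d voxels in mask\n", sum(object@values)))
  if (is(object, "AtlasVolume"))
    cat(sprintf("  %d labelled regions\n", length(object@labelNames)))
  invisible(NULL)
})

setMethod("show", "NormativeTemplate", function(object) {
  d <- gridShape(object)
  cat(sprintf(
    "NormativeTemplate: %d x %d x %d voxels, %d controls, %d valid voxels\n",
    d[1], d[2], d[3], object@nControls, sum(object@validMask)))
  invisible(NULL)
})

setMethod("show", "ZMap", function(object) {
  d <- gridShape(object)
  zz <- object@z[object@validMask]
  cat(sprintf("ZMap: %d x %d x %d voxels, %d valid; z range [%.2f, %.2f]\n",
              d[1], d[2], d[3], sum(object@validMask),
              if (length(zz)) min(zz) else NA, if (length(zz)) max(zz) else NA))
  invisible(NULL)
})

setMethod("show", "StatResult", function(object) {
  dfs <- paste(format(object@df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = (%s), p = %.4g", object@test,
              object@statistic, dfs, object@p))
  if (!is.na(object@effectSize))
    cat(sprintf(", %s = %.3f", object@effectName, object@effectSize))
  if (!is.na(object@adjustedP))
    cat(sprintf(", adjusted p = %.4g", object@adjustedP))
  cat("\n")
  invisible(NULL)
})
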