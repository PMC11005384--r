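#' Read a 3D NIfTI volume as a typed object
#'
#' Reads a (optionally gzip-compressed) NIfTI-1 file and returns the typed
#' volume the pipeline expects. Scalar volumes keep their stored values;
#' masks coerce any nonzero stored value to `TRUE` (the common dialect of
#' mask files); label volumes must be integer-valued. The voxel grid (shape,
#' voxel size, orientation tag) is populated from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param kind One of `"scalar"`, `"mask"`, `"labels"`.
#' @param labelNames Optional named character vector (label -> region name)
#'   for `kind = "labels"`; defaults to `"region_<label>"`.
#' @return An [FAVolume-class], [MaskVolume-class] or [AtlasVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(FAVolume(array(0.3, c(4, 4, 4)), c(2, 2, 3)), f)
#' readVolume(f, "scalar")
#' @export
readVolume <- function(path, kind = c("scalar", "mask", "labels"),
                       labelNames = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  vs <- RNifti::pixdim(img)[seq_len(3L)]
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "unknown")
  vals <- array(as.vector(img), dim = d)
  switch(kind,
    scalar = FAVolume(vals, voxelSize = vs, orientation = orient),
    mask = MaskVolume(vals != 0, voxelSize = vs, orientation = orient),
    labels = {
      if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
        stop("label volume must contain non-negative integers: ", path)
      labs <- sort(unique(as.integer(vals[vals > 0])))
      if (is.null(labelNames))
        labelNames <- stats::setNames(paste0("region_", labs),
                                      as.character(labs))
      AtlasVolume(vals, labelNames = labelNames, voxelSize = vs,
                  orientation = orient)
    })
}

#' Write a typed volume to NIfTI
#'
#' Scalar volumes are stored as float64 so that `readVolume(writeVolume(v))`
#' reproduces values bit for bit; masks as uint8 0/1; atlases as int32.
#' `NA` voxels of scalar volumes are stored as NaN and read back as `NA`.
#'
#' @param volume A [BrainVolume-class] object.
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "BrainVolume"))
  validObject(volume)
  vals <- volume@values
  dtype <- "double"
  if (is(volume, "MaskVolume")) {
    vals <- array(as.integer(vals), dim = dim(vals))
    dtype <- "uint8"
  } else if (is(volume, "AtlasVolume")) {
    dtype <- "int32"
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume@voxelSize
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

.gridOf <- function(x) {
  list(shape = gridShape(x), voxelSize = voxelSize(x),
       orientation = orientationTag(x))
}

.gridsCompatible <- function(a, b, tol = 1e-6) {
  identical(as.integer(a$shape), as.integer(b$shape)) &&
    all(abs(a$voxelSize - b$voxelSize) <= tol) &&
    identical(a$orientation, b$orientation)
}

#' Enforce grid compatibility across volumes
#'
#' All volumes entering a pipeline stage must live on the same grid: equal
#' shape, voxel size (within 1e-6 mm, tolerating float header jitter) and
#' orientation tag. Affine equality beyond this is deliberately not checked;
#' registration to a common frame is upstream of this package.
#'
#' @param ... A list of volumes / templates / z-maps, or several such
#'   objects passed individually.
#' @return `TRUE` invisibly if compatible; otherwise an error naming the
#'   first offending pair (1-based positions in the input order).
#' @export
checkGridCompatible <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !isS4(args[[1]]) && is.list(args[[1]]))
    args <- args[[1]]
  if (!length(args)) stop("no volumes supplied")
  grids <- lapply(args, .gridOf)
  for (i in seq_along(grids)[-1]) {
    if (!.gridsCompatible(grids[[1]], grids[[i]]))
      stop(sprintf(
        "grid mismatch between volume 1 and volume %d (shape %s vs %s, voxel %s vs %s mm, frame '%s' vs '%s')",
        i,
        paste(grids[[1]]$shape, collapse = "x"),
        paste(grids[[i]]$shape, collapse = "x"),
        paste(signif(grids[[1]]$voxelSize, 6), collapse = "x"),
        paste(signif(grids[[i]]$voxelSize, 6), collapse = "x"),
        grids[[1]]$orientation, grids[[i]]$orientation))
  }
  invisible(TRUE)
}
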