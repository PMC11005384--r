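#' Build a normative FA template from control subjects
#'
#' Computes per-voxel sample mean and sample SD (denominator n - 1) of FA
#' over the control cohort, restricted to white matter common to all
#' controls (the intersection of their masks). Voxels whose sample SD falls
#' below `sdFloor` are removed from the valid mask so that downstream
#' z-maps never divide by a vanishing SD.
#'
#' @param controls List of [FAVolume-class] control volumes.
#' @param masks Either a single shared [MaskVolume-class] or a list of
#'   per-subject masks (one per control).
#' @param sdFloor Minimum admissible per-voxel SD (default 1e-6, excludes
#'   exactly-constant voxels only).
#' @return A [NormativeTemplate-class].
#' @examples
#' toy <- toyAtlas(c(12, 12, 12))
#' cohort <- generateControlCohort(cohortSpec(nControl = 5, shape = c(12, 12, 12)))
#' tpl <- buildTemplate(cohort$fa, cohort$mask)
#' tpl
#' @export
buildTemplate <- function(controls, masks, sdFloor = 1e-6) {
  if (length(controls) < 2L)
    stop("a normative template needs at least 2 controls")
  if (is(masks, "MaskVolume")) masks <- rep(list(masks), length(controls))
  if (length(masks) != length(controls))
    stop("need one mask per control (or a single shared mask)")
  checkGridCompatible(c(controls, masks))
  stopifnot(sdFloor > 0)

  shape <- gridShape(controls[[1]])
  common <- Reduce(`&`, lapply(masks, voxelValues))
  n <- length(controls)
  X <- vapply(controls, function(v) as.vector(voxelValues(v)),
              numeric(prod(shape)))
  mu <- rowMeans(X)
  ss <- rowSums((X - mu)^2)
  sdv <- sqrt(ss / (n - 1))

  meanArr <- array(mu, shape)
  sdArr <- array(sdv, shape)
  valid <- common & !is.na(sdArr) & sdArr >= sdFloor
  meanArr[!valid] <- NA_real_
  sdArr[!valid] <- NA_real_
  if (!any(valid))
    stop("empty valid mask: all common voxels fall below the SD floor")
  new("NormativeTemplate", mean = meanArr, sd = sdArr, validMask = valid,
      nControls = as.integer(n), voxelSize = voxelSize(controls[[1]]),
      orientation = orientationTag(controls[[1]]))
}

#' Leave-one-out normative template
#'
#' Builds the template from all controls except the held-out subject. Used
#' when scoring a control against its own reference population, so that a
#' subject's own data do not deflate its z-scores.
#'
#' @param controls,masks,sdFloor As in [buildTemplate()].
#' @param heldOut 1-based index of the control to exclude.
#' @return A [NormativeTemplate-class] built from the remaining controls.
#' @export
buildTemplateLoo <- function(controls, masks, heldOut, sdFloor = 1e-6) {
  if (length(controls) < 3L)
    stop("leave-one-out needs at least 3 controls")
  if (heldOut < 1L || heldOut > length(controls))
    stop("held-out index out of range: ", heldOut)
  if (is(masks, "MaskVolume")) masks <- rep(list(masks), length(controls))
  buildTemplate(controls[-heldOut], masks[-heldOut], sdFloor = sdFloor)
}
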