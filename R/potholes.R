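#' Compute a subject's FA z-map against a normative template
#'
#' z = (subject FA - control mean) / control SD, evaluated on the
#' intersection of the template's valid mask with the subject's own
#' white-matter mask; `NA` elsewhere.
#'
#' @param subject [FAVolume-class] for one subject.
#' @param subjectMask The subject's own [MaskVolume-class].
#' @param template A [NormativeTemplate-class].
#' @return A [ZMap-class].
#' @export
computeZMap <- function(subject, subjectMask, template) {
  checkGridCompatible(subject, subjectMask, template)
  valid <- validMask(template) & voxelValues(subjectMask)
  if (!any(valid))
    stop("empty valid intersection of template and subject mask")
  z <- array(NA_real_, gridShape(subject))
  z[valid] <- (voxelValues(subject)[valid] - template@mean[valid]) /
    template@sd[valid]
  new("ZMap", z = z, validMask = valid, voxelSize = voxelSize(subject),
      orientation = orientationTag(subject))
}

.neighborOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("unknown connectivity: ", connectivity, " (use 6, 18 or 26)"))
  g[keep, , drop = FALSE]
}

# Label connected components of the TRUE voxels of a logical 3D array.
# Returns an integer vector of component memberships parallel to which(flag),
# computed by building the voxel adjacency graph and taking its components.
.labelComponents <- function(flag, connectivity = 26) {
  shape <- dim(flag)
  lin <- which(flag)
  if (!length(lin)) return(list(lin = integer(0), membership = integer(0)))
  ijk <- arrayInd(lin, shape)
  offs <- .neighborOffsets(connectivity)
  # each undirected edge once: keep offsets lexicographically positive
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (!any(ok)) next
    nlin <- .linIndex(nb[ok, , drop = FALSE], shape)
    hit <- match(nlin, lin)
    has <- !is.na(hit)
    if (any(has)) {
      from <- c(from, which(ok)[has])
      to <- c(to, hit[has])
    }
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  list(lin = lin, membership = as.integer(memb))
}

#' Detect potholes in a z-map
#'
#' Potholes are contiguous clusters of voxels with z strictly below the
#' threshold (default z < -3), labeled by 3D connected components under the
#' chosen connectivity (default 26: faces, edges and corners) and kept when
#' they meet the minimum extent (default 10 voxels; alternatively a minimum
#' volume in mm^3). Clusters are ordered by descending voxel count, ties
#' broken by ascending peak index, and numbered from 1.
#'
#' @param zmap A [ZMap-class].
#' @param zThreshold Threshold; voxels with `z < zThreshold` are candidate
#'   pothole voxels (strict inequality). Default -3.
#' @param minSize Minimum cluster extent. Default 10.
#' @param sizeUnits `"voxels"` (default) or `"mm3"`; with `"mm3"` clusters
#'   are kept when `n_voxels * voxelVolume >= minSize`.
#' @param connectivity 6, 18 or 26 (default).
#' @param atlas Optional [AtlasVolume-class]; when given, each cluster's
#'   overlap with atlas regions is recorded.
#' @return A data.frame with one row per cluster: `cluster_id`, `n_voxels`,
#'   `volume_mm3`, `min_z`, `peak_i/j/k`, plus list-columns `voxels`
#'   (ijk index matrix) and, when an atlas is given, `roi_overlap` (named
#'   voxel counts per region).
#' @examples
#' z <- array(0, c(8, 8, 8)); z[2:4, 2:4, 2:4] <- -5
#' zm <- new("ZMap", z = z, validMask = array(TRUE, c(8, 8, 8)),
#'           voxelSize = c(2, 2, 3), orientation = "synthetic")
#' detectPotholes(zm, minSize = 10)
#' @export
detectPotholes <- function(zmap, zThreshold = -3, minSize = 10,
                           sizeUnits = c("voxels", "mm3"),
                           connectivity = 26, atlas = NULL) {
  sizeUnits <- match.arg(sizeUnits)
  if (minSize < 1) stop("minSize must be >= 1")
  if (!connectivity %in% c(6, 18, 26))
    stop("unknown connectivity: ", connectivity, " (use 6, 18 or 26)")
  if (!is.null(atlas)) checkGridCompatible(zmap, atlas)

  vv <- voxelVolume(zmap)
  flag <- zmap@validMask & !is.na(zmap@z) & zmap@z < zThreshold
  lab <- .labelComponents(flag, connectivity)
  empty <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), min_z = numeric(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0))
  empty$voxels <- list()
  if (!is.null(atlas)) empty$roi_overlap <- list()
  if (!length(lab$lin)) return(empty)

  shape <- gridShape(zmap)
  comp <- split(lab$lin, lab$membership)
  sizes <- lengths(comp)
  keep <- if (sizeUnits == "voxels") sizes >= minSize else sizes * vv >= minSize
  comp <- comp[keep]
  if (!length(comp)) return(empty)

  info <- lapply(comp, function(lin) {
    z <- zmap@z[lin]
    ijk <- arrayInd(lin, shape)
    minz <- min(z)
    att <- which(z == minz)
    # peak = lexicographically smallest index attaining min z
    pijk <- ijk[att, , drop = FALSE]
    ord <- order(pijk[, 1], pijk[, 2], pijk[, 3])
    list(n = length(lin), minz = minz, peak = pijk[ord[1], ], ijk = ijk,
         lin = lin)
  })
  n <- vapply(info, `[[`, integer(1), "n")
  pk <- t(vapply(info, `[[`, numeric(3), "peak"))
  ord <- order(-n, pk[, 1], pk[, 2], pk[, 3])
  info <- info[ord]

  out <- data.frame(
    cluster_id = seq_along(info),
    n_voxels = vapply(info, `[[`, integer(1), "n"),
    volume_mm3 = vapply(info, `[[`, integer(1), "n") * vv,
    min_z = vapply(info, `[[`, numeric(1), "minz"),
    peak_i = vapply(info, function(x) x$peak[1], numeric(1)),
    peak_j = vapply(info, function(x) x$peak[2], numeric(1)),
    peak_k = vapply(info, function(x) x$peak[3], numeric(1))
  )
  out$voxels <- lapply(info, `[[`, "ijk")
  if (!is.null(atlas)) {
    labsArr <- voxelValues(atlas)
    nm <- labelNames(atlas)
    out$roi_overlap <- lapply(info, function(x) {
      l <- labsArr[x$lin]
      l <- l[l > 0]
      if (!length(l)) return(stats::setNames(integer(0), character(0)))
      tb <- table(l)
      stats::setNames(as.integer(tb), nm[names(tb)])
    })
  }
  out
}

#' Summarize a subject's potholes
#'
#' @param subjectId Subject identifier.
#' @param clusters Cluster data.frame from [detectPotholes()] for this
#'   subject.
#' @param voxelVolume Voxel volume in mm^3 (used only for the invariant
#'   check; volumes are taken from the cluster table).
#' @return A one-row data.frame: `subject_id`, `n_potholes`,
#'   `total_pothole_volume_mm3`, `mean_cluster_volume_mm3` (0 when there are
#'   no clusters).
#' @export
summarizePotholes <- function(subjectId, clusters, voxelVolume = NULL) {
  n <- nrow(clusters)
  tot <- if (n) sum(clusters$volume_mm3) else 0
  data.frame(subject_id = subjectId, n_potholes = n,
             total_pothole_volume_mm3 = tot,
             mean_cluster_volume_mm3 = if (n) tot / n else 0,
             stringsAsFactors = FALSE)
}

#' Group pothole prevalence over atlas regions
#'
#' For one group, computes per atlas region the percentage of subjects with
#' at least one pothole voxel inside that region, and a voxel-wise map of
#' the percentage of subjects whose pothole set contains each voxel — the
#' standard way pothole distributions are displayed across a cohort.
#'
#' @param clusterSets List (one element per subject) of cluster data.frames
#'   from [detectPotholes()].
#' @param atlas An [AtlasVolume-class] on the subjects' grid.
#' @return A list with `perLabel` (data.frame: `label`, `region`,
#'   `percent`) and `voxelPercent` (3D array of percentages).
#' @export
prevalenceMap <- function(clusterSets, atlas) {
  stopifnot(is(atlas, "AtlasVolume"))
  shape <- gridShape(atlas)
  labsArr <- voxelValues(atlas)
  nm <- labelNames(atlas)
  labs <- as.integer(names(nm))
  nsub <- length(clusterSets)
  if (!nsub) stop("no subjects supplied")
  counts <- array(0L, shape)
  hitLabel <- matrix(FALSE, nsub, length(labs),
                     dimnames = list(NULL, as.character(labs)))
  for (s in seq_len(nsub)) {
    cl <- clusterSets[[s]]
    if (!nrow(cl)) next
    lin <- unlist(lapply(cl$voxels, function(m) .linIndex(m, shape)))
    lin <- unique(lin)
    counts[lin] <- counts[lin] + 1L
    l <- unique(labsArr[lin])
    l <- l[l > 0]
    hitLabel[s, as.character(l)] <- TRUE
  }
  list(
    perLabel = data.frame(label = labs, region = unname(nm),
                          percent = 100 * colMeans(hitLabel)),
    voxelPercent = counts / nsub * 100
  )
}
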