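# Shared fixtures and independent oracles used across the suite.

# Independent flood-fill connected-component oracle: iterative stack-based
# labeling over a logical 3D array. Returns an integer array of component
# labels (0 = background). Deliberately naive and separate from the
# package's graph-based labeling.
floodFillLabel <- function(flag, connectivity = 26) {
  shape <- dim(flag)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
    "6"  = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
    "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
    "26" = offs)
  labels <- array(0L, shape)
  nextLab <- 0L
  todo <- which(flag)
  for (start in todo) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    stack <- start
    labels[start] <- nextLab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cc <- arrayInd(cur, shape)
      nb <- sweep(offs, 2, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 3] - 1) * shape[1] * shape[2] +
             (nb[, 2] - 1) * shape[1] + nb[, 1]
      new <- lin[flag[lin] & labels[lin] == 0L]
      labels[new] <- nextLab
      stack <- c(stack, new)
    }
  }
  labels
}

# Partition of which(flag) induced by a label array, as a canonical sorted
# list of sorted voxel-index vectors (for comparing two labelings).
canonicalPartition <- function(labelArr) {
  lin <- which(labelArr != 0L)
  parts <- split(lin, labelArr[lin])
  parts <- lapply(parts, function(p) sort(as.integer(p)))
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

canonicalClusters <- function(clusters, shape) {
  parts <- lapply(clusters$voxels, function(m)
    sort(as.integer((m[, 3] - 1) * shape[1] * shape[2] +
                    (m[, 2] - 1) * shape[1] + m[, 1])))
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# Wrap a z array defined everywhere into a ZMap.
asZMap <- function(z, voxelSize = c(1, 1, 1), validMask = NULL) {
  if (is.null(validMask)) validMask <- array(TRUE, dim(z))
  z[!validMask] <- NA_real_
  new("ZMap", z = z, validMask = validMask, voxelSize = voxelSize,
      orientation = "synthetic")
}

# Small shared cohort, built once per test run.
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateControlCohort(
        cohortSpec(nControl = 10, shape = c(14, 14, 14), seed = 99))
    cache
  }
})
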