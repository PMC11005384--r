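#' Toy white-matter atlas and mask
#'
#' Builds the desk-scale stand-in for a registered white-matter parcellation:
#' an ellipsoidal white-matter mask centred in the grid, divided into eight
#' octant regions. Real ICBM-style atlases have 48 regions; eight is enough
#' to exercise region bookkeeping while keeping each region populous on a
#' 32-voxel grid.
#'
#' @param shape Grid shape (voxels per axis), default `c(32, 32, 32)`.
#' @param voxelSize Voxel size in mm, default `c(2, 2, 3)` (typical DTI
#'   in-plane resolution and slice thickness).
#' @param orientation Orientation tag for the synthetic frame.
#' @return A list with `atlas` ([AtlasVolume-class]) and `mask`
#'   ([MaskVolume-class]).
#' @export
toyAtlas <- function(shape = c(32, 32, 32), voxelSize = c(2, 2, 3),
                     orientation = "synthetic") {
  if (any(shape < 4)) stop("degenerate grid: need at least 4 voxels per axis")
  ctr <- (shape + 1) / 2
  semi <- pmax(shape / 2 - 3, 1.5)
  i <- slice.index(array(0, shape), 1)
  j <- slice.index(array(0, shape), 2)
  k <- slice.index(array(0, shape), 3)
  inside <- ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
    ((k - ctr[3]) / semi[3])^2 <= 1
  oct <- 1L + (i > ctr[1]) + 2L * (j > ctr[2]) + 4L * (k > ctr[3])
  labs <- array(ifelse(inside, oct, 0L), shape)
  sides <- c("left", "right")
  ap <- c("anterior", "posterior")
  si <- c("inferior", "superior")
  nm <- character(8)
  for (b in 0:7) {
    nm[b + 1] <- paste(sides[b %% 2 + 1], ap[(b %/% 2) %% 2 + 1],
                       si[(b %/% 4) %% 2 + 1], sep = "_")
  }
  names(nm) <- as.character(1:8)
  list(
    atlas = AtlasVolume(labs, labelNames = nm, voxelSize = voxelSize,
                        orientation = orientation),
    mask = MaskVolume(inside, voxelSize = voxelSize, orientation = orientation)
  )
}

#' Cohort simulation specification
#'
#' Defines the synthetic study conditions: group sizes matching the
#' reference cohort (21 controls, 52 mild TBI, 17 moderate-severe TBI), the
#' toy grid, the smooth mean FA field (constant per toy-atlas region, values
#' in \[0.2, 0.6\]) and the voxel-wise Gaussian noise SD.
#'
#' @param nControl,nMtbi,nMstbi Group sizes.
#' @param shape,voxelSize Grid, passed to [toyAtlas()].
#' @param noiseSd Voxel-wise Gaussian SD of FA, default 0.05.
#' @param faRange Range of per-region base FA values.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including the seed.
#' @return A `cohortSpec` list.
#' @export
cohortSpec <- function(nControl = 21, nMtbi = 52, nMstbi = 17,
                       shape = c(32, 32, 32), voxelSize = c(2, 2, 3),
                       noiseSd = 0.05, faRange = c(0.25, 0.55), seed = 1L) {
  stopifnot(nControl >= 1, nMtbi >= 0, nMstbi >= 0, noiseSd > 0,
            length(faRange) == 2, faRange[1] >= 0.2, faRange[2] <= 0.6)
  if (max(faRange) + 4 * noiseSd > 1)
    stop("base FA + 4*noiseSd must stay <= 1")
  structure(list(nControl = as.integer(nControl), nMtbi = as.integer(nMtbi),
                 nMstbi = as.integer(nMstbi), shape = shape,
                 voxelSize = voxelSize, noiseSd = noiseSd,
                 faRange = faRange, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Lesion simulation specification
#'
#' Planted lesions are contiguous sets of white-matter voxels whose FA is
#' set to (true mean - depth * true SD), clipped at 0 — i.e. depth is in
#' units of the generating noise SD, so a depth-6 lesion sits 6 SDs below
#' the control mean before template-estimation noise.
#'
#' @param nLesions Lesions per subject.
#' @param sizeRange Inclusive voxel-count range `c(min, max)` per lesion.
#' @param depth Lesion depth in SD units (default 6).
#' @param shape `"blob"` (random connected growth, default) or `"cuboid"`.
#' @param minGap Minimum Chebyshev gap (voxels) enforced between lesions so
#'   that planted lesions stay disjoint under 26-connectivity.
#' @return A `lesionSpec` list.
#' @export
lesionSpec <- function(nLesions = 5, sizeRange = c(20, 40), depth = 6,
                       shape = c("blob", "cuboid"), minGap = 2L) {
  shape <- match.arg(shape)
  stopifnot(nLesions >= 0, length(sizeRange) == 2, sizeRange[1] >= 1,
            sizeRange[1] <= sizeRange[2], depth > 0, minGap >= 1)
  structure(list(nLesions = as.integer(nLesions),
                 sizeRange = as.integer(sizeRange), depth = depth,
                 shape = shape, minGap = as.integer(minGap)),
            class = "lesionSpec")
}

.baseFAField <- function(atlas, mask, faRange) {
  labs <- voxelValues(atlas)
  nlab <- length(labelNames(atlas))
  levels <- seq(faRange[1], faRange[2], length.out = nlab)
  base <- array(NA_real_, dim(labs))
  m <- voxelValues(mask)
  base[m] <- levels[labs[m]]
  base
}

.drawControl <- function(base, maskArr, noiseSd, voxelSize, orientation) {
  vals <- base
  n <- sum(maskArr)
  vals[maskArr] <- pmin(1, pmax(0, base[maskArr] + stats::rnorm(n, 0, noiseSd)))
  FAVolume(vals, voxelSize = voxelSize, orientation = orientation)
}

#' Generate the synthetic control cohort
#'
#' Draws `nControl` FA volumes: inside the shared white-matter mask each
#' voxel is base FA + Normal(0, noiseSd), truncated to \[0, 1\] by clipping;
#' outside the mask voxels are `NA`. The mask, atlas and base field are
#' shared across subjects. Fully determined by `spec$seed`.
#'
#' @param spec A [cohortSpec()].
#' @return A list with `fa` (list of [FAVolume-class]), `mask`, `atlas`,
#'   `baseFA` (3D array, `NA` outside mask) and `noiseSd`.
#' @examples
#' cohort <- generateControlCohort(cohortSpec(nControl = 3, shape = c(12, 12, 12)))
#' length(cohort$fa)
#' @export
generateControlCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  if (any(spec$shape < 4)) stop("degenerate grid: need >= 4 voxels per axis")
  set.seed(spec$seed)
  toy <- toyAtlas(spec$shape, spec$voxelSize)
  maskArr <- voxelValues(toy$mask)
  base <- .baseFAField(toy$atlas, toy$mask, spec$faRange)
  fa <- lapply(seq_len(spec$nControl), function(i)
    .drawControl(base, maskArr, spec$noiseSd, spec$voxelSize,
                 orientationTag(toy$mask)))
  list(fa = fa, mask = toy$mask, atlas = toy$atlas, baseFA = base,
       noiseSd = spec$noiseSd)
}

.chebyshevNeighborhood <- function(ijk, r, shape) {
  # all voxels within Chebyshev distance r of the given voxel rows
  rng <- -r:r
  off <- as.matrix(expand.grid(di = rng, dj = rng, dk = rng))
  out <- do.call(rbind, lapply(seq_len(nrow(ijk)), function(v)
    sweep(off, 2, ijk[v, ], "+")))
  ok <- out[, 1] >= 1 & out[, 1] <= shape[1] &
        out[, 2] >= 1 & out[, 2] <= shape[2] &
        out[, 3] >= 1 & out[, 3] <= shape[3]
  unique(out[ok, , drop = FALSE])
}

.linIndex <- function(ijk, shape) {
  (ijk[, 3] - 1) * shape[1] * shape[2] + (ijk[, 2] - 1) * shape[1] + ijk[, 1]
}

.growBlob <- function(seedLin, allowed, size, shape) {
  # random connected growth under 6-connectivity restricted to `allowed`;
  # linear-offset stepping can wrap across axis boundaries, so candidates
  # are re-checked as true 6-neighbors in ijk space
  members <- seedLin
  while (length(members) < size) {
    cand <- unique(as.vector(outer(members, .linOffsets6(shape), "+")))
    cand <- cand[cand >= 1 & cand <= prod(shape)]
    cand <- setdiff(cand, members)
    cand <- cand[allowed[cand]]
    if (length(cand)) {
      cijk <- arrayInd(cand, shape)
      mijk <- arrayInd(members, shape)
      good <- vapply(seq_along(cand), function(q) {
        d <- abs(sweep(mijk, 2, cijk[q, ], "-"))
        any(rowSums(d) == 1L & apply(d, 1, max) == 1L)
      }, logical(1))
      cand <- cand[good]
    }
    if (!length(cand)) return(NULL)
    members <- c(members, cand[sample.int(length(cand), 1L)])
  }
  members
}

.linOffsets6 <- function(shape) {
  nxy <- shape[1] * shape[2]
  c(-1L, 1L, -shape[1], shape[1], -nxy, nxy)
}

.placeLesions <- function(maskArr, lspec, shape, maxRetries = 200L) {
  if (lspec$nLesions == 0L) return(list())
  allowed <- as.vector(maskArr)
  forbidden <- rep(FALSE, length(allowed))
  lesions <- vector("list", lspec$nLesions)
  for (l in seq_len(lspec$nLesions)) {
    placed <- FALSE
    for (try in seq_len(maxRetries)) {
      size <- sample(seq(lspec$sizeRange[1], lspec$sizeRange[2]), 1L)
      if (lspec$shape == "cuboid") {
        dims <- .cuboidDims(size)
        ori <- .randomInMask(allowed & !forbidden, shape)
        if (is.null(ori)) next
        vox <- .cuboidVoxels(ori, dims, shape)
        if (is.null(vox)) next
        lin <- .linIndex(vox, shape)
        if (!all(allowed[lin]) || any(forbidden[lin])) next
      } else {
        seedLin <- .randomInMask(allowed & !forbidden, shape)
        if (is.null(seedLin)) next
        lin <- .growBlob(seedLin, allowed & !forbidden, size, shape)
        if (is.null(lin)) next
      }
      lesions[[l]] <- arrayInd(lin, shape)
      nb <- .chebyshevNeighborhood(lesions[[l]], lspec$minGap, shape)
      forbidden[.linIndex(nb, shape)] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place lesion ", l, " without overlap after ",
           maxRetries, " retries")
  }
  lesions
}

.randomInMask <- function(allowed, shape) {
  idx <- which(allowed)
  if (!length(idx)) return(NULL)
  idx[sample.int(length(idx), 1L)]
}

.cuboidDims <- function(size) {
  # near-cubic factorization of the requested voxel count
  a <- max(1L, round(size^(1 / 3)))
  b <- max(1L, round(sqrt(size / a)))
  cc <- max(1L, round(size / (a * b)))
  c(a, b, cc)
}

.cuboidVoxels <- function(originLin, dims, shape) {
  o <- arrayInd(originLin, shape)
  if (any(o + dims - 1L > shape)) return(NULL)
  as.matrix(expand.grid(i = o[1]:(o[1] + dims[1] - 1L),
                        j = o[2]:(o[2] + dims[2] - 1L),
                        k = o[3]:(o[3] + dims[3] - 1L)))
}

#' Generate a TBI subject with planted hypo-FA lesions
#'
#' The subject is a fresh control draw except at lesion voxels, where FA is
#' set to (true mean - depth * true SD), clipped at 0. Lesion FA is defined
#' against the true generating mean/SD — not the estimated template — so
#' that detection error isolates the pipeline's estimation noise. Ground
#' truth records the exact voxel sets.
#'
#' @param baseFA 3D array of the true mean field (from
#'   [generateControlCohort()]).
#' @param mask The shared [MaskVolume-class].
#' @param lesions A [lesionSpec()].
#' @param noiseSd True voxel-wise noise SD.
#' @param voxelSize,orientation Grid metadata (default taken from `mask`).
#' @return A list with `fa` ([FAVolume-class]) and `truth` — a list with
#'   `lesionVoxels` (list of ijk index matrices), `nLesions`, and
#'   `totalVoxels`.
#' @export
generateTbiSubject <- function(baseFA, mask, lesions = lesionSpec(),
                               noiseSd = 0.05,
                               voxelSize = NULL, orientation = NULL) {
  stopifnot(inherits(lesions, "lesionSpec"), is(mask, "MaskVolume"))
  if (is.null(voxelSize)) voxelSize <- voxelSize(mask)
  if (is.null(orientation)) orientation <- orientationTag(mask)
  maskArr <- voxelValues(mask)
  shape <- dim(maskArr)
  vol <- .drawControl(baseFA, maskArr, noiseSd, voxelSize, orientation)
  sets <- .placeLesions(maskArr, lesions, shape)
  vals <- voxelValues(vol)
  for (s in sets) {
    lin <- .linIndex(s, shape)
    vals[lin] <- pmax(0, baseFA[lin] - lesions$depth * noiseSd)
  }
  list(
    fa = FAVolume(vals, voxelSize = voxelSize, orientation = orientation),
    truth = list(lesionVoxels = sets, nLesions = length(sets),
                 totalVoxels = sum(vapply(sets, nrow, integer(1))))
  )
}

#' Metadata simulation specification
#'
#' Group-level summary statistics (n, mean, SD) for the demographic and
#' self-report variables of the reference military TBI cohort: age, years of
#' education, NSI-22, PCL-5 and HIT-6 scores for all three groups, plus
#' lifetime TBI count, months since last injury and cause-of-injury category
#' probabilities for the two TBI groups.
#'
#' @return A `metadataSpec` list with one element per group; each group has
#'   `n` and a `vars` matrix (rows mean/sd), TBI groups additionally have
#'   `causeProbs`.
#' @export
referenceMetadataSpec <- function() {
  v <- function(...) {
    m <- matrix(c(...), nrow = 2,
                dimnames = list(c("mean", "sd"), NULL))
    colnames(m) <- c("age", "education", "nsi", "pcl5", "hit6")[seq_len(ncol(m))]
    m
  }
  causes <- c("motor_vehicle", "military", "fall_accident", "sports",
              "assault_abuse")
  spec <- list(
    noTBI = list(n = 21L, vars = v(29.62, 7.28, 14.83, 2.79, 8.52, 12.46,
                                   9.33, 15.13, 4.81, 4.39)),
    mTBI = list(n = 52L, vars = v(35.00, 7.81, 14.75, 2.23, 33.10, 18.53,
                                  30.36, 20.91, 35.64, 26.50),
                injury = c(lifetimeTbiMean = 3.92, lifetimeTbiSd = 2.46,
                           monthsSinceMean = 48.04, monthsSinceSd = 44.19),
                causeProbs = stats::setNames(c(13, 17, 13, 7, 2) / 52, causes)),
    msTBI = list(n = 17L, vars = v(26.41, 7.88, 13.00, 1.54, 18.06, 15.98,
                                   21.24, 19.74, 6.24, 7.41),
                 injury = c(lifetimeTbiMean = 1.94, lifetimeTbiSd = 2.19,
                            monthsSinceMean = 10.29, monthsSinceSd = 18.30),
                 causeProbs = stats::setNames(c(5, 1, 9, 0, 2) / 17, causes))
  )
  structure(spec, class = "metadataSpec")
}

#' Simulate a subject metadata table
#'
#' One row per subject with group membership and simulated demographics and
#' symptom scores drawn Normal(mean, SD), truncated by clipping to plausible
#' ranges (age >= 18, scores >= 0); cause of injury drawn from the group's
#' category probabilities. Deterministic given `seed`.
#'
#' @param spec A metadata spec, default [referenceMetadataSpec()]. Group
#'   sizes may be overridden via `nOverride` (named vector).
#' @param seed Integer seed.
#' @param nOverride Optional named integer vector (e.g.
#'   `c(noTBI = 5, mTBI = 5, msTBI = 5)`) replacing group sizes.
#' @return A data.frame with columns `subject_id`, `group`, `age`,
#'   `education`, `nsi`, `pcl5`, `hit6`, `lifetime_tbis`,
#'   `months_since_injury`, `cause` (the last three `NA` for controls).
#' @export
generateMetadata <- function(spec = referenceMetadataSpec(), seed = 1L,
                             nOverride = NULL) {
  stopifnot(inherits(spec, "metadataSpec"))
  set.seed(seed)
  rows <- list()
  sid <- 0L
  for (g in names(spec)) {
    gs <- spec[[g]]
    n <- if (!is.null(nOverride) && g %in% names(nOverride))
      as.integer(nOverride[[g]]) else gs$n
    if (n == 0L) next
    draw <- function(mean, sd, lower) pmax(lower, stats::rnorm(n, mean, sd))
    vars <- gs$vars
    df <- data.frame(
      subject_id = sprintf("S%03d", sid + seq_len(n)),
      group = g,
      age = draw(vars["mean", "age"], vars["sd", "age"], 18),
      education = draw(vars["mean", "education"], vars["sd", "education"], 0),
      nsi = draw(vars["mean", "nsi"], vars["sd", "nsi"], 0),
      pcl5 = draw(vars["mean", "pcl5"], vars["sd", "pcl5"], 0),
      hit6 = draw(vars["mean", "hit6"], vars["sd", "hit6"], 0),
      stringsAsFactors = FALSE
    )
    if (!is.null(gs$injury)) {
      df$lifetime_tbis <- pmax(1, round(stats::rnorm(
        n, gs$injury[["lifetimeTbiMean"]], gs$injury[["lifetimeTbiSd"]])))
      df$months_since_injury <- pmax(0, stats::rnorm(
        n, gs$injury[["monthsSinceMean"]], gs$injury[["monthsSinceSd"]]))
      df$cause <- sample(names(gs$causeProbs), n, replace = TRUE,
                         prob = gs$causeProbs)
    } else {
      df$lifetime_tbis <- NA_real_
      df$months_since_injury <- NA_real_
      df$cause <- NA_character_
    }
    sid <- sid + n
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
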