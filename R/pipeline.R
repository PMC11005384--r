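#' Pipeline run configuration
#'
#' Collects every knob of the simulate -> template -> z-map -> pothole ->
#' statistics pipeline in one validated list. Defaults reproduce the
#' package's reference study conditions (21/52/17 group sizes on a 32^3
#' toy grid); `demoRunConfig()` gives a lighter 40-subject configuration
#' for quick end-to-end runs.
#'
#' @param outDir Output directory (created if absent).
#' @param nControl,nMtbi,nMstbi Group sizes.
#' @param shape,voxelSize,noiseSd Cohort grid and noise, see [cohortSpec()].
#' @param lesions A [lesionSpec()] applied to every TBI subject.
#' @param zThreshold,minSize,sizeUnits,connectivity Pothole parameters, see
#'   [detectPotholes()].
#' @param looControls Score each control against a template excluding
#'   itself (default `TRUE`); TBI subjects always use the full control
#'   template.
#' @param sdFloor Template SD floor, see [buildTemplate()].
#' @param alpha Significance level for reported tests.
#' @param writeVolumes Also write FA/mask/atlas/template NIfTI volumes
#'   under `outDir/volumes` (default `FALSE`; tables and the JSON report
#'   are always written).
#' @param seed Integer master seed; all randomness in the run derives from
#'   it.
#' @return A `runConfig` list.
#' @export
runConfig <- function(outDir, nControl = 21, nMtbi = 52, nMstbi = 17,
                      shape = c(32, 32, 32), voxelSize = c(2, 2, 3),
                      noiseSd = 0.05, lesions = lesionSpec(),
                      zThreshold = -3, minSize = 10,
                      sizeUnits = "voxels", connectivity = 26,
                      looControls = TRUE, sdFloor = 1e-6, alpha = 0.05,
                      writeVolumes = FALSE, seed = 1L) {
  stopifnot(nControl >= 3, nMtbi >= 0, nMstbi >= 0,
            connectivity %in% c(6, 18, 26), minSize >= 1,
            sizeUnits %in% c("voxels", "mm3"), alpha > 0, alpha < 1)
  structure(list(outDir = outDir, nControl = as.integer(nControl),
                 nMtbi = as.integer(nMtbi), nMstbi = as.integer(nMstbi),
                 shape = shape, voxelSize = voxelSize, noiseSd = noiseSd,
                 lesions = lesions, zThreshold = zThreshold,
                 minSize = minSize, sizeUnits = sizeUnits,
                 connectivity = connectivity, looControls = looControls,
                 sdFloor = sdFloor, alpha = alpha,
                 writeVolumes = writeVolumes, seed = as.integer(seed)),
            class = "runConfig")
}

#' @rdname runConfig
#' @export
demoRunConfig <- function(outDir, seed = 1L) {
  runConfig(outDir, nControl = 20, nMtbi = 10, nMstbi = 10, seed = seed)
}

#' Run the full pothole pipeline on a synthetic cohort
#'
#' Executes simulate -> normative template -> per-subject z-maps -> pothole
#' detection -> per-subject summaries -> group statistics -> ground-truth
#' recovery, writes `tables/` (TSV) and `report.json` under the configured
#' output directory, and returns the report. The run is a deterministic
#' function of the configuration (including the seed): repeated runs write
#' byte-identical reports.
#'
#' Controls are scored leave-one-out by default so that a control's own
#' data do not deflate its z-scores; TBI subjects are scored against the
#' full control template.
#'
#' @param config A [runConfig()].
#' @return The report, invisibly: a list with `parameters`, `groups`
#'   (per-group n, mean/SD of pothole counts and total volumes), `stats`
#'   (group comparison and symptom correlation), `recovery` (voxel
#'   recall/precision and count errors vs planted ground truth) and
#'   `files`.
#' @examples
#' \donttest{
#' cfg <- demoRunConfig(file.path(tempdir(), "demo"), seed = 7)
#' rep <- runPipeline(cfg)
#' rep$groups
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  tabDir <- file.path(config$outDir, "tables")
  dir.create(tabDir, showWarnings = FALSE)

  # --- simulate -------------------------------------------------------------
  cspec <- cohortSpec(nControl = config$nControl, nMtbi = config$nMtbi,
                      nMstbi = config$nMstbi, shape = config$shape,
                      voxelSize = config$voxelSize, noiseSd = config$noiseSd,
                      seed = config$seed)
  cohort <- generateControlCohort(cspec)
  nTbi <- config$nMtbi + config$nMstbi
  tbi <- vector("list", nTbi)
  for (i in seq_len(nTbi)) {
    tbi[[i]] <- generateTbiSubject(cohort$baseFA, cohort$mask,
                                   lesions = config$lesions,
                                   noiseSd = config$noiseSd)
  }
  meta <- generateMetadata(seed = config$seed + 1L,
                           nOverride = c(noTBI = config$nControl,
                                         mTBI = config$nMtbi,
                                         msTBI = config$nMstbi))

  # --- template + z-maps + potholes ----------------------------------------
  template <- buildTemplate(cohort$fa, cohort$mask, sdFloor = config$sdFloor)
  detect <- function(zmap) detectPotholes(
    zmap, zThreshold = config$zThreshold, minSize = config$minSize,
    sizeUnits = config$sizeUnits, connectivity = config$connectivity,
    atlas = cohort$atlas)

  clusterSets <- vector("list", config$nControl + nTbi)
  for (i in seq_len(config$nControl)) {
    tpl <- if (config$looControls)
      buildTemplateLoo(cohort$fa, cohort$mask, i, sdFloor = config$sdFloor)
    else template
    clusterSets[[i]] <- detect(computeZMap(cohort$fa[[i]], cohort$mask, tpl))
  }
  for (i in seq_len(nTbi)) {
    clusterSets[[config$nControl + i]] <-
      detect(computeZMap(tbi[[i]]$fa, cohort$mask, template))
  }

  groups <- meta$group
  ids <- meta$subject_id
  summaries <- do.call(rbind, lapply(seq_along(clusterSets), function(i)
    summarizePotholes(ids[i], clusterSets[[i]])))
  summaries$group <- groups

  clusterTab <- do.call(rbind, lapply(seq_along(clusterSets), function(i) {
    cl <- clusterSets[[i]]
    if (!nrow(cl)) return(NULL)
    topRoi <- vapply(cl$roi_overlap, function(o)
      if (length(o)) names(o)[which.max(o)] else NA_character_, character(1))
    data.frame(subject_id = ids[i], cl[, c("cluster_id", "n_voxels",
               "volume_mm3", "min_z", "peak_i", "peak_j", "peak_k")],
               top_region = topRoi, stringsAsFactors = FALSE)
  }))

  # --- statistics -----------------------------------------------------------
  counts <- split(summaries$n_potholes, factor(groups,
                                               levels = unique(groups)))
  anova <- if (sum(lengths(counts) >= 2) >= 2)
    suppressWarnings(anovaOneway(counts[lengths(counts) >= 2],
                                 posthoc = TRUE)) else NULL
  rhoNsi <- tryCatch(spearmanCor(summaries$n_potholes, meta$nsi),
                     error = function(e) NULL)

  grpStats <- lapply(counts, function(x) c(n = length(x), mean = mean(x),
                                           sd = stats::sd(x)))
  volByGrp <- split(summaries$total_pothole_volume_mm3,
                    factor(groups, levels = unique(groups)))

  # --- recovery vs planted ground truth ------------------------------------
  truth <- lapply(tbi, `[[`, "truth")
  tbiSets <- clusterSets[config$nControl + seq_len(nTbi)]
  recovery <- recoveryMetrics(tbiSets, truth, shape = config$shape)

  # --- outputs --------------------------------------------------------------
  sumPath <- file.path(tabDir, "pothole_summaries.tsv")
  utils::write.table(summaries, sumPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cluPath <- file.path(tabDir, "pothole_clusters.tsv")
  utils::write.table(
    if (is.null(clusterTab)) data.frame() else clusterTab,
    cluPath, sep = "\t", quote = FALSE, row.names = FALSE)
  metaPath <- file.path(tabDir, "metadata.tsv")
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # report paths are relative to outDir so reports from identical
  # configurations are byte-identical wherever they are written
  files <- c(summaries = "tables/pothole_summaries.tsv",
             clusters = "tables/pothole_clusters.tsv",
             metadata = "tables/metadata.tsv")
  if (isTRUE(config$writeVolumes)) {
    volDir <- file.path(config$outDir, "volumes")
    dir.create(volDir, showWarnings = FALSE)
    writeVolume(cohort$mask, file.path(volDir, "wm_mask.nii.gz"))
    writeVolume(cohort$atlas, file.path(volDir, "atlas.nii.gz"))
    tplMean <- FAVolume(template@mean, voxelSize = config$voxelSize,
                        orientation = orientationTag(cohort$mask))
    writeVolume(tplMean, file.path(volDir, "template_mean.nii.gz"))
    files <- c(files, volumes = "volumes")
  }

  statBlock <- function(s) {
    if (is.null(s)) return(NULL)
    list(test = s@test, statistic = s@statistic, df = s@df, p = s@p,
         effect_name = s@effectName, effect_size = s@effectSize)
  }
  params <- unclass(config)[setdiff(names(config), "outDir")]
  params$lesions <- unclass(params$lesions)
  report <- list(
    parameters = params,
    groups = lapply(names(grpStats), function(g) list(
      group = g, n = unname(grpStats[[g]]["n"]),
      potholes_mean = unname(grpStats[[g]]["mean"]),
      potholes_sd = unname(grpStats[[g]]["sd"]),
      volume_mean = mean(volByGrp[[g]]),
      volume_sd = stats::sd(volByGrp[[g]]))),
    stats = list(
      pothole_count_anova = if (is.null(anova)) NULL else
        c(statBlock(anova), list(posthoc = attr(anova, "posthoc"))),
      pothole_count_vs_nsi_spearman = statBlock(rhoNsi)),
    recovery = recovery,
    files = as.list(files)
  )
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(report)
}

#' Ground-truth recovery metrics
#'
#' Compares detected pothole voxels with planted lesion voxels across
#' subjects: pooled voxel-level recall and precision, per-subject count
#' error (detected minus planted), and the fraction of subjects with exact
#' count recovery. By convention precision is 1 when nothing was detected
#' (no false positives were produced).
#'
#' @param detected List (per subject) of cluster data.frames from
#'   [detectPotholes()].
#' @param truth List (per subject) of ground-truth lists from
#'   [generateTbiSubject()].
#' @param shape Grid shape used to linearize voxel indices.
#' @return A list: `voxel_recall`, `voxel_precision`, `count_errors`,
#'   `exact_count_fraction`, `n_subjects`.
#' @export
recoveryMetrics <- function(detected, truth, shape) {
  if (length(detected) != length(truth))
    stop("detected and truth must cover the same subjects")
  nInter <- 0; nTruth <- 0; nDet <- 0
  countErr <- integer(length(truth))
  for (s in seq_along(truth)) {
    tLin <- unlist(lapply(truth[[s]]$lesionVoxels, function(m)
      .linIndex(m, shape)))
    dLin <- if (nrow(detected[[s]]))
      unique(unlist(lapply(detected[[s]]$voxels, function(m)
        .linIndex(m, shape)))) else integer(0)
    nInter <- nInter + length(intersect(tLin, dLin))
    nTruth <- nTruth + length(tLin)
    nDet <- nDet + length(dLin)
    countErr[s] <- nrow(detected[[s]]) - truth[[s]]$nLesions
  }
  list(
    voxel_recall = if (nTruth) nInter / nTruth else 1,
    voxel_precision = if (nDet) nInter / nDet else 1,
    count_errors = countErr,
    exact_count_fraction = mean(countErr == 0),
    n_subjects = length(truth)
  )
}
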