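#' Per-region mean FA
#'
#' Mean FA over the voxels of each atlas region intersected with the
#' subject's own white-matter mask. Regions with no overlapping voxels are
#' reported as `NA` (missing), never as 0.
#'
#' @param subject [FAVolume-class].
#' @param subjectMask [MaskVolume-class].
#' @param atlas [AtlasVolume-class].
#' @return A data.frame with `label`, `region`, `n_voxels`, `mean_fa`.
#' @export
roiMeanFA <- function(subject, subjectMask, atlas) {
  checkGridCompatible(subject, subjectMask, atlas)
  fa <- voxelValues(subject)
  m <- voxelValues(subjectMask)
  labsArr <- voxelValues(atlas)
  nm <- labelNames(atlas)
  labs <- as.integer(names(nm))
  sel <- m & labsArr > 0
  vals <- fa[sel]
  l <- labsArr[sel]
  sums <- tapply(vals, factor(l, levels = labs), sum)
  counts <- tapply(rep(1L, length(l)), factor(l, levels = labs), sum)
  counts[is.na(counts)] <- 0L
  data.frame(
    label = labs,
    region = unname(nm),
    n_voxels = as.integer(counts),
    mean_fa = ifelse(counts > 0, as.numeric(sums) / as.numeric(counts),
                     NA_real_)
  )
}

#' Proportional scaling by total intracranial volume
#'
#' Unit-preserving normalization of a regional measure by head size:
#' `scaled = value * (cohortMeanTiv / tiv)`. A subject with the cohort-mean
#' TIV is unchanged; a subject with twice the cohort-mean TIV has its value
#' halved.
#'
#' @param value Regional measure(s).
#' @param tiv Subject total intracranial volume(s), > 0.
#' @param cohortMeanTiv Cohort mean TIV, > 0.
#' @return Scaled value(s).
#' @export
tivScale <- function(value, tiv, cohortMeanTiv) {
  if (any(tiv <= 0) || any(cohortMeanTiv <= 0))
    stop("TIV must be positive")
  value * (cohortMeanTiv / tiv)
}

#' Region-wise group comparison
#'
#' One-way ANOVA per region over a long-format region table, with per-region
#' eta^2, Bonferroni adjustment across the number of regions actually tested
#' (not the atlas's nominal count, so the family size stays correct when
#' regions are missing), and Bonferroni pairwise post hocs for regions
#' significant after correction. Missing values are dropped listwise within
#' a region; regions left with fewer than 2 groups of >= 2 subjects are
#' skipped.
#'
#' @param table Data.frame with columns `subject_id`, `group`, `region`,
#'   `value` (e.g. stacked [roiMeanFA()] output).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param alpha Significance level applied to adjusted p-values.
#' @return A data.frame with one row per tested region: `region`, `F`,
#'   `df1`, `df2`, `p`, `eta2`, `adjusted_p`, `significant`; post hoc
#'   tables for significant regions are attached as attribute
#'   `"posthoc"` (a named list).
#' @export
regionwiseGroupTest <- function(table, correction = c("bonferroni", "none"),
                                alpha = 0.05) {
  correction <- match.arg(correction)
  stopifnot(all(c("group", "region", "value") %in% names(table)))
  table <- table[is.finite(table$value), , drop = FALSE]
  regions <- unique(table$region)
  rows <- list(); ph <- list()
  for (r in regions) {
    sub <- table[table$region == r, ]
    samples <- split(sub$value, sub$group)
    samples <- samples[lengths(samples) >= 2]
    if (length(samples) < 2) next
    res <- anovaOneway(samples, posthoc = TRUE)
    rows[[as.character(r)]] <- data.frame(
      region = r, F = res@statistic, df1 = res@df[1], df2 = res@df[2],
      p = res@p, eta2 = res@effectSize)
    ph[[as.character(r)]] <- attr(res, "posthoc")
  }
  if (!length(rows)) stop("no testable regions (need >= 2 groups with n >= 2)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adjusted_p <- if (correction == "bonferroni")
    bonferroniAdjust(out$p, m = nrow(out)) else out$p
  out$significant <- out$adjusted_p < alpha
  attr(out, "posthoc") <- ph[as.character(out$region[out$significant])]
  out
}
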