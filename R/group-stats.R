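#' One-way ANOVA with eta-squared
#'
#' Classical between/within decomposition over k groups:
#' F = MSB/MSW on (k - 1, N - k) degrees of freedom, with effect size
#' eta^2 = SSB/SST. When the total sum of squares is zero (all observations
#' identical) the result is defined as F = 0, eta^2 = 0, p = 1.
#'
#' @param samples Named list of numeric vectors, one per group (each of
#'   length >= 2).
#' @param posthoc If `TRUE`, attach Bonferroni-adjusted pairwise
#'   comparisons (pooled within-group variance, df = N - k) as attribute
#'   `"posthoc"`.
#' @return A [StatResult-class] (`test = "anova"`, effect `eta2`).
#' @examples
#' anovaOneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
anovaOneway <- function(samples, posthoc = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(lengths(samples) < 2))
    stop("every group needs at least 2 observations")
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (stats::var(y) == 0) {
    res <- StatResult("anova", 0, c(nlevels(g) - 1, length(y) - nlevels(g)),
                      1, "eta2", 0)
    return(res)
  }
  a <- stats::anova(stats::lm(y ~ g))
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  res <- StatResult("anova", a$`F value`[1], a$Df, a$`Pr(>F)`[1],
                    "eta2", ssb / (ssb + ssw))
  if (posthoc) {
    nm <- names(samples)
    if (is.null(nm)) nm <- paste0("group", seq_along(samples))
    attr(res, "posthoc") <- .posthocPairwise(
      vapply(samples, length, integer(1)),
      vapply(samples, mean, numeric(1)),
      msw = ssw / a$Df[2], dfw = a$Df[2], labels = nm)
  }
  res
}

.posthocPairwise <- function(n, m, msw, dfw, labels) {
  k <- length(n)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
    diff = m[pairs[1, ]] - m[pairs[2, ]])
  se <- sqrt(msw * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  out$t <- out$diff / se
  out$p <- 2 * stats::pt(-abs(out$t), dfw)
  out$adjusted_p <- bonferroniAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA from published group summaries
#'
#' Reconstructs the one-way ANOVA exactly from per-group (n, mean, SD):
#' SSB = sum n_i (mean_i - grand mean)^2 and SSW = sum (n_i - 1) sd_i^2,
#' which equal the raw-data sums of squares for any data with those
#' summaries. This lets published tables of means and SDs be re-analyzed
#' without the raw data; agreement with published statistics is expected to
#' about 0.5% relative, limited by rounding of the printed summaries.
#'
#' @param n,mean,sd Numeric vectors (one entry per group); all `n >= 2`.
#' @param labels Optional group labels for the post hoc table.
#' @param posthoc As in [anovaOneway()].
#' @return A [StatResult-class] (`test = "anova"`, effect `eta2`).
#' @examples
#' # age comparison across three groups reconstructed from printed summaries
#' anovaFromSummary(n = c(21, 52, 17), mean = c(29.62, 35.00, 26.41),
#'                  sd = c(7.28, 7.81, 7.88))
#' @export
anovaFromSummary <- function(n, mean, sd, labels = NULL, posthoc = FALSE) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            length(n) >= 2, all(sd >= 0))
  if (any(n < 2)) stop("every group needs n >= 2")
  k <- length(n); N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  dfb <- k - 1; dfw <- N - k
  if (ssb + ssw == 0)
    return(StatResult("anova", 0, c(dfb, dfw), 1, "eta2", 0))
  Fv <- if (ssw == 0) Inf else (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  res <- StatResult("anova", Fv, c(dfb, dfw), p, "eta2", ssb / (ssb + ssw))
  if (posthoc) {
    if (is.null(labels)) labels <- paste0("group", seq_len(k))
    attr(res, "posthoc") <- .posthocPairwise(n, mean, msw = ssw / dfw,
                                             dfw = dfw, labels = labels)
  }
  res
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Either from two raw samples (`x`, `y`) or from group summaries
#' (`n`, `mean`, `sd`, each of length 2). The pooled SD uses denominator
#' n1 + n2 - 2; Cohen's d is the mean difference divided by the pooled SD.
#'
#' @param x,y Raw numeric samples (alternative to summaries).
#' @param n,mean,sd Length-2 numeric vectors of group summaries.
#' @return A [StatResult-class] (`test = "t"`, effect `d`).
#' @examples
#' ttestPooled(n = c(52, 17), mean = c(3.92, 1.94), sd = c(2.46, 2.19))
#' @export
ttestPooled <- function(x = NULL, y = NULL, n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    stopifnot(!is.null(y), length(x) >= 2, length(y) >= 2)
    n <- c(length(x), length(y))
    mean <- c(base::mean(x), base::mean(y))
    sd <- c(stats::sd(x), stats::sd(y))
  }
  stopifnot(length(n) == 2, length(mean) == 2, length(sd) == 2, all(n >= 2))
  df <- sum(n) - 2
  sp2 <- ((n[1] - 1) * sd[1]^2 + (n[2] - 1) * sd[2]^2) / df
  diff <- mean[1] - mean[2]
  if (sp2 == 0) {
    if (diff == 0)
      return(StatResult("t", 0, df, 1, "d", 0))
    stop("zero pooled variance with nonzero mean difference")
  }
  sp <- sqrt(sp2)
  tv <- diff / (sp * sqrt(1 / n[1] + 1 / n[2]))
  StatResult("t", tv, df, 2 * stats::pt(-abs(tv), df), "d", diff / sp)
}

#' Pearson chi-square test of independence
#'
#' Pearson chi^2 = sum (O - E)^2 / E with expected counts from the row and
#' column margins; df = (r - 1)(c - 1). No continuity correction is
#' applied.
#'
#' @param table A matrix of non-negative integer counts, at least 2x2.
#' @return A [StatResult-class] (`test = "chisq"`).
#' @examples
#' chiSquare(rbind(c(13, 17, 13, 7, 2), c(5, 1, 9, 0, 2)))
#' @export
chiSquare <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  rs <- rowSums(table); cs <- colSums(table); tot <- sum(table)
  if (tot == 0 || any(rs == 0) || any(cs == 0))
    stop("zero row or column margin")
  E <- outer(rs, cs) / tot
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  StatResult("chisq", stat, df, stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' U computed from rank sums with average ranks for ties; p-value by the
#' normal approximation with tie-corrected variance (no continuity
#' correction). The reported U is for the first sample:
#' U = R1 - n1(n1+1)/2.
#'
#' @param x,y Non-empty numeric samples.
#' @return A [StatResult-class] (`test = "mann-whitney"`; `statistic` = U).
#' @export
mannWhitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (sig2 <= 0) 1 else 2 * stats::pnorm(-abs((U - mu) / sqrt(sig2)))
  StatResult("mann-whitney", U, NA_real_, min(1, p))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data; p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return A [StatResult-class] (`test = "spearman"`, effect `rho`;
#'   `statistic` is the t value).
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance: correlation undefined")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    tv <- sign(rho) * Inf
    p <- 0
  } else {
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tv), n - 2)
  }
  StatResult("spearman", tv, n - 2, p, "rho", rho)
}

#' Bonferroni adjustment
#'
#' `adjusted_p = min(1, p * m)`, with `m` defaulting to the number of tests
#' in the list.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  if (m < 1) stop("family size m must be >= 1")
  pmin(1, p * m)
}
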