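test_that("summary-statistics ANOVA equals the raw-data ANOVA", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    samples <- lapply(seq_len(k), function(i)
      rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2)))
    raw <- anovaOneway(samples)
    summ <- anovaFromSummary(
      n = vapply(samples, length, integer(1)),
      mean = vapply(samples, mean, numeric(1)),
      sd = vapply(samples, sd, numeric(1)))
    expect_equal(summ@statistic, raw@statistic, tolerance = 1e-10)
    expect_equal(summ@p, raw@p, tolerance = 1e-10)
    expect_equal(summ@effectSize, raw@effectSize, tolerance = 1e-10)
    expect_equal(summ@df, raw@df)
    # eta2 stays in [0, 1] and equals SSB/(SSB+SSW) by construction
    expect_gte(raw@effectSize, 0)
    expect_lte(raw@effectSize, 1)
  }
})

test_that("ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(7)
  samples <- lapply(1:3, function(i) rnorm(6, i * 0.3, 1))
  res <- anovaOneway(samples)
  y <- unlist(samples)
  gm <- mean(y)
  ssb <- sum(vapply(samples, function(s) length(s) * (mean(s) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(samples, function(s) sum((s - mean(s))^2), numeric(1)))
  Fo <- (ssb / 2) / (ssw / (length(y) - 3))
  expect_equal(res@statistic, Fo, tolerance = 1e-10)
  expect_equal(res@effectSize, ssb / (ssb + ssw), tolerance = 1e-10)
})

test_that("degenerate ANOVAs are well defined", {
  allEq <- anovaOneway(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(allEq@statistic, 0)
  expect_equal(allEq@effectSize, 0)
  expect_equal(allEq@p, 1)

  sameMeans <- anovaFromSummary(n = c(5, 5), mean = c(2, 2), sd = c(1, 2))
  expect_equal(sameMeans@statistic, 0)
  expect_error(anovaFromSummary(n = c(1, 5), mean = c(1, 2), sd = c(0, 1)),
               "n >= 2")
})

test_that("t-squared equals the two-group ANOVA F", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(sample(4:10, 1), 0.4)
    y <- rnorm(sample(4:10, 1))
    tt <- ttestPooled(x = x, y = y)
    ff <- anovaOneway(list(x, y))
    expect_equal(tt@statistic^2, ff@statistic, tolerance = 1e-10)
    expect_equal(tt@p, ff@p, tolerance = 1e-10)
    expect_equal(tt@df, sum(length(x), length(y)) - 2)
  }
})

test_that("pooled t-test handles summaries, raw data and degeneracies alike", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5, 6)
  raw <- ttestPooled(x = x, y = y)
  summ <- ttestPooled(n = c(4, 5), mean = c(mean(x), mean(y)),
                      sd = c(sd(x), sd(y)))
  expect_equal(raw@statistic, summ@statistic, tolerance = 1e-12)
  expect_equal(raw@effectSize, summ@effectSize, tolerance = 1e-12)
  # cross-check against the standard implementation
  tref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw@statistic, unname(tref$statistic), tolerance = 1e-12)
  expect_equal(raw@p, tref$p.value, tolerance = 1e-12)

  eq <- ttestPooled(x = c(1, 1), y = c(1, 1))
  expect_equal(eq@statistic, 0)
  expect_equal(eq@effectSize, 0)
  expect_error(ttestPooled(x = c(1, 1), y = c(2, 2)), "zero pooled variance")
})

test_that("chi-square matches the term-by-term oracle and the standard implementation", {
  set.seed(13)
  for (rep in 1:10) {
    tab <- matrix(rpois(9, 8) + 1, 3, 3)
    res <- chiSquare(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res@statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res@p, ref$p.value, tolerance = 1e-10)
    expect_equal(res@df, 4)
  }
  # proportional table has zero association
  prop <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(chiSquare(prop)@statistic, 0)
  expect_error(chiSquare(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(chiSquare(matrix(1, 1, 3)), "2x2")
})

test_that("Mann-Whitney U equals the exhaustive pair-count oracle", {
  bruteU <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  set.seed(17)
  for (rep in 1:30) {
    x <- sample(1:5, sample(2:6, 1), replace = TRUE)   # ties likely
    y <- sample(1:5, sample(2:6, 1), replace = TRUE)
    res <- mannWhitney(x, y)
    expect_equal(res@statistic, bruteU(x, y))
  }
  # complete separation and identity
  expect_equal(mannWhitney(1:3, 4:6)@statistic, 0)
  expect_equal(mannWhitney(c(1, 2), c(1, 2))@statistic, 2)  # n1*n2/2
  # agreement with the standard implementation (exact U, its W)
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.4, 2.8, 3.9)
  expect_equal(mannWhitney(x, y)@statistic,
               unname(suppressWarnings(wilcox.test(x, y)$statistic)))
})

test_that("Spearman equals rank-then-Pearson and is monotone-invariant", {
  set.seed(19)
  for (rep in 1:10) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 8, replace = TRUE)
    if (var(rank(x)) == 0 || var(rank(y)) == 0) next
    res <- spearmanCor(x, y)
    expect_equal(res@effectSize, cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(res@effectSize, unname(ref$estimate), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(spearmanCor(exp(x), y^3 + y)@effectSize, res@effectSize,
                 tolerance = 1e-12)
  }
  expect_equal(spearmanCor(1:5, c(2, 4, 5, 7, 10))@effectSize, 1)
  expect_equal(spearmanCor(1:5, -(1:5)^2)@effectSize, -1)
  expect_equal(spearmanCor(1:5, c(2, 4, 5, 7, 10))@p, 0)
  expect_error(spearmanCor(rep(1, 5), 1:5), "zero rank variance")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.01, m = 5), 0.05)
  expect_equal(bonferroniAdjust(0.5, m = 10), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.3), m = 1), c(0.2, 0.3))
  expect_equal(bonferroniAdjust(c(0.01, 0.02)),
               p.adjust(c(0.01, 0.02), "bonferroni"))
  expect_error(bonferroniAdjust(0.5, m = 0), "m must be")
  expect_error(bonferroniAdjust(1.2), "p >= 0")
})

test_that("post hoc pairwise comparisons identify the shifted group", {
  set.seed(23)
  samples <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 3))
  res <- anovaOneway(samples, posthoc = TRUE)
  ph <- attr(res, "posthoc")
  expect_equal(nrow(ph), 3)
  sig <- ph$adjusted_p < 0.05
  involved <- (ph$group1 == "c") | (ph$group2 == "c")
  expect_true(all(sig[involved]))
  expect_false(any(sig[!involved]))
})
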