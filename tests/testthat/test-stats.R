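test_that("Friedman statistic matches hand and reference computations", {
  m <- matrix(rep(c(5, 9, 12), 3), 3, 3, byrow = TRUE)   # ranks 1,2,3 each row
  f <- friedmanTest(m)
  expect_equal(f@chiSquare, 6.0)
  identical_m <- matrix(rep(c(4, 4, 4, 4), 5), 5, 4, byrow = TRUE)
  f0 <- friedmanTest(identical_m)
  expect_equal(f0@chiSquare, 0)
  expect_equal(f0@p, 1)
  set.seed(71)
  r <- matrix(rnorm(48), 12, 4)
  expect_equal(friedmanTest(r)@chiSquare,
               unname(stats::friedman.test(r)$statistic))
  expect_error(friedmanTest(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
  expect_error(friedmanTest(matrix(1:4, 2, 2)), "3 conditions")
})

test_that("Friedman detects a monotone effect and is rank-invariant", {
  set.seed(72)
  base <- matrix(rep(1:4, each = 16), 16, 4) + matrix(rnorm(64, 0, 0.3), 16, 4)
  f <- friedmanTest(base)
  expect_lt(f@p, 0.05)
  expect_equal(nrow(f@posthoc), 6)                       # k(k-1)/2 pairs
  expect_true(all(f@posthoc$pCorrected >= f@posthoc$pRaw))
  fExp <- friedmanTest(exp(base))                        # monotone transform
  expect_equal(fExp@chiSquare, f@chiSquare)
})

test_that("signed-rank p-values are exact, even under ties", {
  w <- wilcoxonSignedRank((1:8) + 0.5, rep(0.5, 8))
  expect_equal(w$p.value, 2 / 2^8)
  expect_warning(wz <- wilcoxonSignedRank(1:6, 1:6), "zero")
  expect_equal(wz$p.value, 1)
  # oracle: brute force over all 2^n sign assignments, including ties
  brute <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9))
  }
  cases <- list(c(3, -1, 2, 2, -2, 5, 4),            # tied magnitudes
                c(1.5, -1.5, 2, -3, 3, 4),
                c(-1, 2, 3, 4, 5, -6, 7, 8, 9))
  for (d in cases)
    expect_equal(wilcoxonSignedRank(d)$p.value, min(1, brute(d)))
  # agreement with the reference implementation on tie-free data
  set.seed(73)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(wilcoxonSignedRank(x, y)$p.value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("signed-rank test holds its nominal level", {
  set.seed(74)
  nSim <- 4000
  rej <- 0L
  for (i in seq_len(nSim)) {
    d <- rnorm(16)
    rej <- rej + (wilcoxonSignedRank(d)$p.value < 0.05)
  }
  # the exact test's attainable level at n = 16 sits just below 0.05
  expect_lt(abs(rej / nSim - 0.05), 0.012)
})

test_that("repeated-measures correlation recovers within-subject structure", {
  s <- rep(1:5, each = 6)
  x <- rep(1:6, 5)
  up <- suppressWarnings(rmcorr(x, 2 * x + 10 * s, s))
  expect_equal(up@r, 1)
  down <- suppressWarnings(rmcorr(x, -x + 10 * s, s))
  expect_equal(down@r, -1)
  expect_equal(up@dof, length(x) - 5L - 1L)
  set.seed(75)
  n <- 2000
  sN <- rep(1:10, each = n / 10)
  r0 <- rmcorr(rnorm(n), rnorm(n), sN)
  expect_lt(abs(r0@r), 0.05)
  expect_warning(rmcorr(c(1, 2, 3, 1, 2, 3, 1), c(2, 1, 4, 3, 5, 4, 2),
                        c(1, 1, 1, 2, 2, 2, 3)), "dropped")
  expect_error(suppressWarnings(rmcorr(1:3, 3:1, c(1, 2, 3))), "2 usable")
})

test_that("reports follow the analysis sequence and round-trip as JSON", {
  tl <- generateTimeline(720)
  tabs <- lapply(1:6, function(s) simulateFeatureTable(tl, paste0("S", s),
                                                      seed = 700 + s))
  scr <- screenFeatures(tabs)
  fr <- friedmanTest(matrix(rnorm(32) + rep(1:4, each = 8), 8, 4))
  rc <- suppressWarnings(rmcorr(rep(1:5, 4), rep(5:1, 4) + rnorm(20, 0, 0.1),
                                rep(1:4, each = 5)))
  rep1 <- buildReport(screening = scr,
                      singleIndexes = list(gsr = fr),
                      fusionIndex = fr,
                      classification = list(averaged = data.frame(
                        pair = "none_vs_high", auc = 0.9, acc = 0.85)),
                      subjective = list(atco_sme = rc))
  expect_named(rep1, c("screening", "single_parameter_indexes",
                       "fusion_index", "classification",
                       "subjective_correlations"))
  path <- tempfile(fileext = ".json")
  writeReportJson(rep1, path)
  back <- readReportJson(path)
  expect_equal(back$fusion_index$chi_square, fr@chiSquare)
  expect_equal(back$classification$averaged$auc, 0.9)
  expect_equal(nrow(back$screening), nrow(scr))

  emptyScr <- scr; emptyScr$selected <- FALSE
  rep2 <- buildReport(screening = emptyScr, fusionIndex = fr)
  expect_true(isTRUE(rep2$fusion_index$skipped))
  expect_error(buildReport(), "at least one")
})
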