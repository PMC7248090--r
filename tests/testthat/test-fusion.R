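test_that("merged tables carry the documented shape and labels", {
  s1 <- singleSubject720()
  X <- featureMatrix(s1$table)
  expect_equal(ncol(X), 58)
  expect_lte(nrow(X), 1380)                      # (720 - 30)/0.5 windows
  expect_gte(nrow(X), 1300)                      # few windows lost at most
  expect_true(all(c("lf_hf", "scl") %in% colnames(X)))
  expect_equal(sum(grepl("^psd_", colnames(X))), 56)
  lab <- windowLabels(s1$table)
  map <- c("none", "medium", "high", "none")
  expect_equal(lab$stress, map[lab$slot])        # label integrity
  expect_lt(max(lab$windowStart), 720 - 30)      # no window past session end
  relab <- timelineLabels(s1$timeline, lab$windowStart)
  expect_equal(lab$phase, relab$phase)           # labels taken at window start
})

test_that("EEG window means agree with a direct epoch average", {
  s1 <- singleSubject720()
  sp <- s1$spectral
  lab <- windowLabels(s1$table)
  X <- featureMatrix(s1$table)
  w0 <- lab$windowStart[200]
  inWin <- sp@epochStart >= w0 & sp@epochStart + 2 <= w0 + 30
  direct <- mean(bandPowerArray(sp)[inWin, "Fz", "alpha"])
  expect_equal(unname(X[200, "psd_Fz_alpha"]), direct, tolerance = 1e-9)
})

test_that("screening selects responsive features and honours the null", {
  co <- cohort720()
  tabs <- lapply(co$subjects, `[[`, "tableExt")   # + hr and scr columns
  scr <- screenFeatures(tabs, alpha = 0.05)
  stressFeats <- c(featureNames(setdiff(featureChannels(), "Cz")),
                   "lf_hf", "scl")
  expect_true(all(scr$selected[scr$feature %in% stressFeats]))
  nullFeats <- c("hr", "scr", featureNames("Cz"))
  expect_lte(sum(scr$selected[scr$feature %in% nullFeats]), 2)
  expect_error(screenFeatures(tabs[1:4]), "6 subjects")
})

test_that("screening p-values match the exact signed-rank cases", {
  tl <- generateTimeline(720)
  tabs <- lapply(1:8, function(s) simulateFeatureTable(tl, paste0("S", s),
                                                      seed = 500 + s))
  scr <- screenFeatures(tabs)
  # a feature identical across slots for all subjects -> p = 1
  flat <- lapply(tabs, function(tb) {
    SummarizedExperiment::assay(tb, "features")["psd_Cz_theta", ] <- 5
    tb
  })
  scrF <- screenFeatures(flat)
  expect_equal(scrF$p[scrF$feature == "psd_Cz_theta"], 1)
  expect_false(scrF$selected[scrF$feature == "psd_Cz_theta"])
  # 8 subjects, all differences positive -> exact two-sided p = 2/256
  up <- scr$p[scr$feature == "psd_Fz_alpha"]
  expect_equal(up, 2 / 256)
})

test_that("z-scoring is fitted on training rows only", {
  set.seed(30)
  tr <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  te <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  z <- zscoreFitApply(tr, te)
  expect_equal(unname(colMeans(z$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z$train, 2, sd)), rep(1, 4), tolerance = 1e-9)
  shift <- 3
  z2 <- zscoreFitApply(tr, sweep(te, 2, -shift))
  expect_equal(colMeans(z2$others[[1]]) - colMeans(z$others[[1]]),
               shift / z$scale, tolerance = 1e-9)
  trBad <- tr; trBad[, 2] <- 7
  expect_error(zscoreFitApply(trBad), "constant.*b")
})

test_that("SMOTE balances classes with convex synthetic samples", {
  set.seed(31)
  X <- matrix(rnorm(360), 120, 3)
  X[, 3] <- 2 * X[, 2]               # minority rows live on a plane
  y <- rep(c("maj", "min"), c(100, 20))
  out <- smoteOversample(X, y, seed = 5)
  expect_equal(as.integer(table(out$y)), c(100L, 100L))
  expect_equal(sum(out$synthetic), 80)
  synth <- out$X[out$synthetic, ]
  # segments between minority points stay on the plane x3 = 2 x2
  expect_equal(synth[, 3], 2 * synth[, 2], tolerance = 1e-12)
  rng <- apply(X[y == "min", ], 2, range)
  expect_true(all(synth >= rep(rng[1, ], each = nrow(synth)) - 1e-12))
  expect_true(all(synth <= rep(rng[2, ], each = nrow(synth)) + 1e-12))
  expect_identical(out, smoteOversample(X, y, seed = 5))
  expect_error(smoteOversample(X[c(1:10, 101:104), ], rep(c("a", "b"),
                                                          c(10, 4))),
               "exceed k")
  balanced <- smoteOversample(X[1:40, ], rep(c("a", "b"), each = 20))
  expect_false(any(balanced$synthetic))
})

test_that("screening specificity matches the attainable exact level", {
  tl <- generateTimeline(720)
  nBatch <- 10
  hits <- 0L; total <- 0L
  for (b in seq_len(nBatch)) {
    tabs <- lapply(1:8, function(s)
      simulateFeatureTable(tl, paste0("S", s), effect = 0,
                           seed = 1000 + 10 * b + s))
    scr <- screenFeatures(tabs)
    hits <- hits + sum(scr$selected)
    total <- total + nrow(scr)
  }
  # attainable two-sided level of the exact n = 8 signed-rank test at 0.05
  ex <- stressfusion:::signedRankExact(1:8)
  lvl <- 0
  for (w in ex$support) {
    p <- 2 * min(sum(ex$prob[ex$support <= w]), sum(ex$prob[ex$support >= w]))
    if (p < 0.05) lvl <- lvl + ex$prob[match(w, ex$support)]
  }
  rate <- hits / total
  tolBand <- 3 * sqrt(lvl * (1 - lvl) / total)
  expect_lt(abs(rate - lvl), tolBand + 0.01)
})
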