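test_that("the informative feature is found first and models stay small", {
  firstHit <- 0L
  sizes <- integer(50)
  for (s in 1:50) {
    set.seed(s)
    X <- matrix(rnorm(400 * 10), 400, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(c("lo", "hi"), each = 200)
    X[y == "hi", 1] <- X[y == "hi", 1] + 2
    m <- swldaFit(X, factor(y, levels = c("lo", "hi")))
    if (selectedFeatures(m)[1] == "f1") firstHit <- firstHit + 1L
    sizes[s] <- length(selectedFeatures(m))
  }
  expect_gte(firstHit / 50, 0.9)
  expect_lte(median(sizes), 2)
})

test_that("null features give an empty model on most seeds", {
  errs <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(c("a", "b"), each = 100)
    errs <- errs + inherits(tryCatch(swldaFit(X, y), error = identity),
                            "swldaEmptyModel")
  }
  expect_gte(errs, 4)
})

test_that("stepwise configuration invariants are enforced", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("x", "z"), 10)
  expect_error(swldaFit(X, y, pEnter = 0.2, pRemove = 0.1), "smaller")
  expect_error(swldaFit(X, c(y[-1], "w")), "two classes")
})

test_that("scores are linear, sparse in unselected features, and directed", {
  set.seed(41)
  X <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("lo", "hi"), each = 150)
  X[y == "hi", 2] <- X[y == "hi", 2] + 3
  m <- swldaFit(X, factor(y, levels = c("lo", "hi")))
  expect_true("f2" %in% selectedFeatures(m))
  muLo <- colMeans(X[y == "lo", , drop = FALSE])
  muHi <- colMeans(X[y == "hi", , drop = FALSE])
  sc <- swldaScore(m, rbind(muLo, muHi))
  expect_lt(sc[1], sc[2])                       # fitted direction
  unsel <- setdiff(colnames(X), selectedFeatures(m))[1]
  X2 <- X; X2[, unsel] <- X2[, unsel] + 100
  expect_equal(swldaScore(m, X2), swldaScore(m, X))
  lam <- 0.3
  combo <- lam * X[1, , drop = FALSE] + (1 - lam) * X[2, , drop = FALSE]
  expect_equal(swldaScore(m, combo),
               lam * swldaScore(m, X[1, , drop = FALSE]) +
                 (1 - lam) * swldaScore(m, X[2, , drop = FALSE]))
  expect_error(swldaScore(m, X[, setdiff(colnames(X), "f2")]), "missing")
})

test_that("cross-validation folds train only on their workload-matched phases", {
  tl <- generateTimeline(720)
  st <- simulateFeatureTable(tl, seed = 21)
  cv <- runCrossValidation(st, tl, seed = 2)
  lab <- windowLabels(st)
  expect_length(cv$audit, 3)
  for (f in 1:3) {
    a <- cv$audit[[f]]
    w <- c(L = "LWL", M = "MWL", H = "HWL")[[a$workload]]
    expect_setequal(a$trainPhases, paste0(w, c(1, 3)))
    expect_true(all(lab$phase[a$trainRows] %in% a$trainPhases))
  }
  # steps outside the six training phases get 3 predictions, inside get 2
  trainPhases <- as.vector(outer(c("LWL", "MWL", "HWL"), c(1, 3), paste0))
  nf <- foldCounts(cv$index)
  expect_true(all(nf[!lab$phase %in% trainPhases] == 3L))
  expect_true(all(nf[lab$phase %in% trainPhases] == 2L))
  st2 <- st[, windowLabels(st)$phase != "MWL2"]
  expect_error(runCrossValidation(st2, tl), "missing")
})

test_that("the fused index reproduces the injected stress ordering", {
  co <- cohort720()
  sm <- t(vapply(co$subjects, function(s) {
    lab <- windowLabels(s$table)
    vapply(1:4, function(k) mean(indexValues(s$cv$index)[lab$slot == k]),
           numeric(1))
  }, numeric(4)))
  colnames(sm) <- paste0("SLOT", 1:4)
  avg <- colMeans(sm)
  expect_lt(avg[1], avg[2])
  expect_lt(avg[2], avg[3])
  expect_gt(avg[4], avg[1])                    # residual elevation in slot 4
  fr <- friedmanTest(sm)
  expect_lt(fr@p, 0.05)
})

test_that("the index anti-correlates with declining efficiency ratings", {
  co <- cohort720()
  xs <- list(); ys <- list(); ids <- list()
  for (i in seq_along(co$subjects)) {
    s <- co$subjects[[i]]
    lab <- windowLabels(s$table)
    rt <- ratingTimes(co$timeline)
    atInstant <- vapply(rt, function(tm)
      mean(indexValues(s$cv$index)[lab$windowStart >= tm - 60 &
                                     lab$windowStart < tm]), numeric(1))
    xs[[i]] <- atInstant
    ys[[i]] <- as.numeric(s$ratings@smeEfficiency)
    ids[[i]] <- rep(i, length(rt))
  }
  r <- rmcorr(unlist(xs), unlist(ys), unlist(ids))
  expect_lt(r@r, 0)
})

test_that("pairwise evaluation matches the brute-force AUC oracle", {
  # brute force over all positive-negative pairs
  bf <- function(sc, y) {
    pos <- sc[y == 1]; neg <- sc[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(aucRank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(bf(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(51)
  for (rep in 1:5) {
    sc <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)   # with ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(aucRank(sc, y), bf(sc, y))
  }
  expect_equal(aucRank(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(52)
  nullAuc <- aucRank(rnorm(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(nullAuc - 0.5), 0.02)
  expect_error(aucRank(1:4, rep(1, 4)), "both classes")
})

test_that("the permutation null is centred, reproducible and exceeded", {
  tl <- generateTimeline(720)
  st <- simulateFeatureTable(tl, seed = 61)
  nul <- permutationNull(st, tl, nPerm = 200, seed = 8)
  nulB <- permutationNull(st, tl, nPerm = 200, seed = 8)
  expect_identical(nul, nulB)
  nh <- nul$auc[nul$pair == "none_vs_high"]
  se <- sd(nh) / sqrt(length(nh))
  expect_lt(abs(mean(nh) - 0.5), 3 * se + 0.05)
  cv <- runCrossValidation(st, tl, seed = 3)
  obs <- evaluateStress(cv, st)$averaged
  measured <- obs$auc[obs$pair == "none_vs_high"]
  expect_gt(measured, quantile(nh, 0.95))
  expect_warning(permutationNull(st, tl, nPerm = 10, seed = 1), "coarse")
})
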