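# Nonparametric statistics used throughout: Friedman test with Bonferroni-
# corrected signed-rank post-hocs, exact Wilcoxon signed-rank (exact
# distribution by convolution, valid with mid-ranks), and repeated-measures
# correlation via the shared-slope analysis of covariance.

# Exact null distribution of the signed-rank statistic W+ for given
# (possibly tied, mid-) ranks: probability generating function over the
# 2^n equiprobable sign assignments, on a grid of half-integers.
signedRankExact <- function(ranks) {
  g <- round(ranks * 2)                  # mid-ranks live on the half-grid
  total <- sum(g)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in g) {
    shifted <- c(rep(0, r), f[seq_len(total + 1 - r)])
    f <- (f + shifted) / 2
  }
  list(support = (0:total) / 2, prob = f)
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test. Zero differences are dropped (with a
#' warning when all are zero, in which case p = 1). For up to `exactMax`
#' non-zero differences the p-value uses the exact distribution of the
#' statistic computed by convolution, which stays exact in the presence of
#' tied (mid-) ranks; larger samples use the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y paired samples (`y` omitted for a one-sample test against 0).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exactMax largest n handled exactly under `"auto"`.
#' @return an object of class `htest` with `statistic` (V = sum of positive
#'   ranks), `p.value` and the effective `n`.
#' @export
wilcoxonSignedRank <- function(x, y = NULL, mode = c("auto", "exact", "approx"),
                               exactMax = 25) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  dn <- paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  if (n == 0) {
    warning("all differences are zero")
    return(structure(list(statistic = c(V = 0), p.value = 1, n = 0L,
                          method = "Wilcoxon signed rank test (degenerate)",
                          data.name = dn), class = "htest"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  useExact <- mode == "exact" || (mode == "auto" && n <= exactMax)
  if (useExact) {
    ex <- signedRankExact(r)
    pLo <- sum(ex$prob[ex$support <= W + 1e-9])
    pHi <- sum(ex$prob[ex$support >= W - 1e-9])
    p <- min(1, 2 * min(pLo, pHi))
    method <- "Wilcoxon signed rank test (exact by convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sg2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sg2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon signed rank test (normal approximation)"
  }
  structure(list(statistic = c(V = W), p.value = p, n = as.integer(n),
                 method = method, data.name = dn), class = "htest")
}

#' Friedman rank test with Bonferroni post-hoc comparisons
#'
#' Within-subject ranks (mid-ranks for ties) give the statistic
#' `chi^2 = 12 n / (k (k + 1)) * sum_j (Rbar_j - (k + 1)/2)^2`, referred to
#' the chi-square distribution with `k - 1` degrees of freedom. When the
#' omnibus p-value falls below `alpha`, all pairwise conditions are compared
#' by [wilcoxonSignedRank()] with Bonferroni correction over the
#' `k (k - 1) / 2` pairs.
#'
#' @param m numeric matrix, subjects x conditions, no missing cells.
#' @param alpha omnibus level gating the post-hoc comparisons.
#' @return a [FriedmanResult-class].
#' @export
friedmanTest <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 3) stop("need at least 2 subjects and 3 conditions")
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  chi <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  p <- pchisq(chi, df = k - 1, lower.tail = FALSE)
  posthoc <- data.frame(pair = character(), pRaw = numeric(),
                        pCorrected = numeric())
  if (p < alpha) {
    pairs <- utils::combn(k, 2)
    mCmp <- ncol(pairs)
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("C", seq_len(k))
    rows <- lapply(seq_len(mCmp), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      w <- suppressWarnings(wilcoxonSignedRank(m[, a], m[, b]))
      data.frame(pair = paste(cn[a], cn[b], sep = " vs "),
                 pRaw = w$p.value, pCorrected = min(1, w$p.value * mCmp))
    })
    posthoc <- do.call(rbind, rows)
  }
  new("FriedmanResult", chiSquare = chi, p = p, n = as.integer(n),
      k = as.integer(k), posthoc = posthoc)
}

#' Repeated-measures correlation
#'
#' The common within-subject correlation from the analysis-of-covariance
#' formulation: subject enters as a factor, the slope is shared, and
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `dof = N - subjects - 1`. Subjects with fewer than two complete
#' observations are dropped with a warning.
#'
#' @param x,y paired observations.
#' @param subjects subject identifier per observation.
#' @return an [RmcorrResult-class].
#' @export
rmcorr <- function(x, y, subjects) {
  ok <- complete.cases(x, y, subjects)
  x <- x[ok]; y <- y[ok]; subjects <- as.character(subjects[ok])
  cnt <- table(subjects)
  keepSubj <- names(cnt)[cnt >= 2]
  if (length(keepSubj) < length(cnt))
    warning(length(cnt) - length(keepSubj),
            " subject(s) with fewer than 2 observations dropped")
  keep <- subjects %in% keepSubj
  x <- x[keep]; y <- y[keep]; subjects <- factor(subjects[keep])
  if (nlevels(subjects) < 2) stop("need at least 2 usable subjects")
  fit <- lm(y ~ subjects + x)
  an <- stats::anova(fit)
  ssX <- an["x", "Sum Sq"]
  ssE <- an["Residuals", "Sum Sq"]
  dof <- an["Residuals", "Df"]
  slope <- unname(coef(fit)["x"])
  denom <- ssX + ssE
  r <- if (denom > 0) sign(slope) * sqrt(ssX / denom) else 0
  p <- pf(an["x", "F value"], 1, dof, lower.tail = FALSE)
  new("RmcorrResult", r = r, p = p, dof = as.integer(dof), slope = slope)
}

asReportList <- function(x) {
  if (is(x, "FriedmanResult"))
    list(chi_square = x@chiSquare, p = x@p, n = x@n, k = x@k,
         posthoc = x@posthoc)
  else if (is(x, "RmcorrResult"))
    list(r = x@r, p = x@p, dof = x@dof, slope = x@slope)
  else if (inherits(x, "htest"))
    list(statistic = unname(x$statistic), p = x$p.value, method = x$method)
  else x
}

#' Assemble the analysis report
#'
#' Collects the pipeline's results into one structured list following the
#' analysis sequence: feature screening, single-parameter stress indexes,
#' fusion-based stress index, classification against the permutation null,
#' and subjective correlations. Sections whose inputs are absent are marked
#' skipped; an empty screening additionally marks the downstream sections
#' skipped. The list serialises losslessly to JSON via [writeReportJson()].
#'
#' @param screening result of [screenFeatures()] (or `NULL`).
#' @param singleIndexes named list of [FriedmanResult-class] per modality.
#' @param fusionIndex [FriedmanResult-class] for the fused index.
#' @param classification list with elements such as `averaged` (AUC/ACC per
#'   pair) and `null` summaries.
#' @param subjective named list of [RmcorrResult-class] objects.
#' @return a nested list with one element per section.
#' @export
buildReport <- function(screening = NULL, singleIndexes = NULL,
                        fusionIndex = NULL, classification = NULL,
                        subjective = NULL) {
  if (is.null(screening) && is.null(singleIndexes) && is.null(fusionIndex) &&
      is.null(classification) && is.null(subjective))
    stop("at least one analysis result is required")
  emptyScreen <- !is.null(screening) && !any(screening$selected)
  section <- function(x, downstream = FALSE) {
    if (is.null(x) || (downstream && emptyScreen))
      list(skipped = TRUE)
    else if (is.data.frame(x)) x
    else if (is.list(x) && !isS4(x)) lapply(x, asReportList)
    else asReportList(x)
  }
  list(
    screening = section(screening),
    single_parameter_indexes = section(singleIndexes, downstream = TRUE),
    fusion_index = section(fusionIndex, downstream = TRUE),
    classification = section(classification, downstream = TRUE),
    subjective_correlations = section(subjective)
  )
}

#' Write / read a report as JSON
#' @param report list from [buildReport()].
#' @param path output file.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReportJson
#' @export
readReportJson <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
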