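# Stepwise linear discriminant analysis: features enter by minimal partial
# F-test p-value below pEnter and leave when their p-value rises above
# pRemove; the discriminant weights are the least-squares regression of the
# +/-1 class codes on the selected features.

#' Fit a stepwise linear discriminant model
#'
#' Forward steps add the unselected feature with the smallest partial F-test
#' p-value when it is below `pEnter`; backward steps remove any selected
#' feature whose p-value exceeds `pRemove`; the procedure iterates to a
#' fixed point or until `maxFeatures` features are selected. Class codes are
#' -1 for the first level of `y` and +1 for the second, so higher
#' discriminant scores mean the second (by convention higher-stress) class.
#'
#' @param X numeric matrix (rows = observations) with column names.
#' @param y class labels with exactly two levels; a factor's level order
#'   fixes the score direction, otherwise sorted unique order is used.
#' @param pEnter,pRemove entry and removal p-value thresholds
#'   (`pEnter < pRemove`).
#' @param maxFeatures cap on selected features.
#' @return an [SWLDAModel-class].
#' @export
swldaFit <- function(X, y, pEnter = 0.05, pRemove = 0.10, maxFeatures = 60) {
  if (pEnter >= pRemove) stop("pEnter must be smaller than pRemove")
  lev <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  y <- as.character(y)
  if (length(lev) != 2 || !all(y %in% lev))
    stop("exactly two classes required")
  z <- ifelse(y == lev[2], 1, -1)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))

  selected <- integer()
  forwardP <- function(sel) {
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    ry <- z - Q %*% crossprod(Q, z)
    rss0 <- sum(ry^2)
    cand <- setdiff(seq_len(p), sel)
    Xc <- X[, cand, drop = FALSE]
    Rc <- Xc - Q %*% crossprod(Q, Xc)
    den <- colSums(Rc^2)
    num <- drop(crossprod(Rc, ry))^2 / pmax(den, .Machine$double.eps)
    df2 <- n - length(sel) - 2
    Fv <- num / pmax((rss0 - num) / df2, .Machine$double.eps)
    pv <- pf(Fv, 1, df2, lower.tail = FALSE)
    pv[den < 1e-10 * n] <- 1               # numerically collinear candidates
    list(cand = cand, p = pv)
  }
  backwardP <- function(sel) {
    Xs <- cbind(1, X[, sel, drop = FALSE])
    fit <- stats::lm.fit(Xs, z)
    df2 <- n - length(sel) - 1
    rss <- sum(fit$residuals^2)
    R <- qr.R(fit$qr)
    xtxInv <- chol2inv(R)
    se <- sqrt(pmax(diag(xtxInv), 0) * rss / df2)
    tv <- fit$coefficients / pmax(se, .Machine$double.eps)
    pf(tv[-1]^2, 1, df2, lower.tail = FALSE)
  }

  for (iter in seq_len(10 * min(p, maxFeatures) + 10)) {
    moved <- FALSE
    if (length(selected) < maxFeatures && length(selected) < p) {
      fp <- forwardP(selected)
      j <- which.min(fp$p)
      if (fp$p[j] < pEnter) {
        selected <- c(selected, fp$cand[j])
        moved <- TRUE
      }
    }
    while (length(selected) > 1) {
      bp <- backwardP(selected)
      worst <- which.max(bp)
      if (bp[worst] > pRemove) {
        selected <- selected[-worst]
        moved <- TRUE
      } else break
    }
    if (!moved) break
  }
  if (!length(selected))
    stop(structure(class = c("swldaEmptyModel", "error", "condition"),
                   list(message = "empty model: no feature passes pEnter",
                        call = sys.call(-1))))
  fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), z)
  b <- fit$coefficients
  scores <- drop(cbind(1, X[, selected, drop = FALSE]) %*% b)
  mu1 <- mean(scores[z < 0]); mu2 <- mean(scores[z > 0])
  s2 <- (sum((scores[z < 0] - mu1)^2) + sum((scores[z > 0] - mu2)^2)) /
    max(1, n - 2)
  new("SWLDAModel",
      selected = colnames(X)[selected], weights = unname(b[-1]),
      intercept = unname(b[1]), pEnter = pEnter, pRemove = pRemove,
      maxFeatures = maxFeatures, classes = lev,
      calibration = c(location = (mu1 + mu2) / 2,
                      scale = max(sqrt(s2), .Machine$double.eps)))
}

#' Score observations with an SWLDA model
#'
#' The linear discriminant `y = X[, selected] %*% b + c`; features the model
#' did not select are ignored, so the score is sparse in the inputs.
#'
#' @param model an [SWLDAModel-class].
#' @param X matrix containing (at least) the selected feature columns.
#' @return numeric discriminant scores; higher means the second class.
#' @export
swldaScore <- function(model, X) {
  miss <- setdiff(model@selected, colnames(X))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  drop(X[, model@selected, drop = FALSE] %*% model@weights) + model@intercept
}

#' Class probability of the higher-stress class
#'
#' Logistic mapping of the discriminant score using the location/scale
#' calibration fitted on the training scores; thresholding the probability
#' at 0.5 is equivalent to thresholding the score at the calibrated
#' location.
#'
#' @param model an [SWLDAModel-class].
#' @param scores discriminant scores from [swldaScore()].
#' @return probabilities in `(0, 1)`.
#' @export
swldaProbability <- function(model, scores) {
  1 / (1 + exp(-(scores - model@calibration[["location"]]) /
                 model@calibration[["scale"]]))
}
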