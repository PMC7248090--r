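# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1/f ("pink") noise of length n with standard deviation sd, built by
# spectral shaping of white Gaussian noise.
pinkNoise <- function(n, sd = 1) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))            # guard the DC bin
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

# Biexponential (Bateman) impulse response on a sampling grid, peak-normalised.
batemanKernel <- function(fs, tauRise = 1, tauDecay = 3.75, length_s = 30) {
  if (tauDecay <= tauRise || tauRise <= 0)
    stop("need tauDecay > tauRise > 0")
  t <- seq(0, length_s, by = 1 / fs)
  b <- exp(-t / tauDecay) - exp(-t / tauRise)
  b / max(b)
}

#' Area under the ROC curve
#'
#' Rank formulation (equivalent to the probability that a random positive
#' outranks a random negative); ties count one half.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1; `TRUE`/1 marks the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucRank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
aucRank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Moving sums of x over windows of length L starting at the given 1-based
# offsets; O(n) via cumulative sums.
windowSums <- function(x, starts, L) {
  cs <- c(0, cumsum(x))
  cs[starts + L] - cs[starts]
}
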