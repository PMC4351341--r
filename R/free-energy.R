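#' Umbrella-integration window
#'
#' One biased-sampling window: restraint center, force constant, and the CV
#' time series sampled under the bias `U = (k/2)(x - x0)^2`.
#'
#' @param x0 Restraint center (CV units).
#' @param k Force constant (kcal/mol per CV unit^2), > 0.
#' @param samples Numeric CV time series.
#' @param equilibrationDrop Initial fraction (if < 1) or count (if >= 1) of
#'   samples discarded as equilibration. Default 0.18 (e.g. 1 ps of a 5.5 ps
#'   window).
#' @param blockSize Block length for block-averaged variance (default: 1/20
#'   of the post-drop samples, at least 1).
#' @return A `uiWindow` list.
#' @export
uiWindow <- function(x0, k, samples, equilibrationDrop = 0.18,
                     blockSize = NULL) {
  if (k <= 0) stop("k must be > 0")
  drop <- if (equilibrationDrop < 1) floor(equilibrationDrop * length(samples))
          else as.integer(equilibrationDrop)
  kept <- samples[seq_along(samples) > drop]
  if (length(kept) < 2L) stop("need at least 2 post-equilibration samples")
  if (is.null(blockSize)) blockSize <- max(1L, length(kept) %/% 20L)
  structure(list(x0 = x0, k = k, samples = kept,
                 blockSize = as.integer(blockSize)),
            class = "uiWindow")
}

## block means of a series (trailing partial block dropped)
.blockMeans <- function(x, blockSize) {
  nb <- length(x) %/% blockSize
  if (nb < 1L) stop("fewer samples than one block")
  colMeans(matrix(x[seq_len(nb * blockSize)], nrow = blockSize))
}

#' Local free-energy gradient of one window
#'
#' In a biased simulation the mean gradient of the bias potential equals
#' (approximately) the negative of the PMF gradient at the mean CV value:
#' `dF/dx (xbar) = -k (xbar - x0)`. The variance of the gradient estimate is
#' propagated from the block-averaged variance of the sample mean,
#' `k^2 var(xbar)`.
#'
#' @param w A [uiWindow()].
#' @return List with `xbar`, `dFdx`, `var` (variance of `dFdx`), `n`.
#' @export
windowGradient <- function(w) {
  bm <- .blockMeans(w$samples, w$blockSize)
  if (length(bm) < 2L) stop("need at least 2 blocks for the variance")
  xbar <- mean(w$samples)
  varXbar <- var(bm) / length(bm)
  list(xbar = xbar, dFdx = -w$k * (xbar - w$x0), var = w$k^2 * varXbar,
       n = length(w$samples))
}

#' Assemble a PMF profile from umbrella-integration windows
#'
#' Sorts windows by their mean CV value, integrates the window gradients by
#' the trapezoid rule, and shifts the profile so that F(anchor) = 0 (linear
#' interpolation at the anchor). 95% confidence half-widths are propagated
#' from the window gradient variances under an independent-window assumption
#' and are reported relative to the anchored profile's arbitrary origin.
#'
#' @param windows List of [uiWindow()].
#' @param anchor CV value at which F is set to zero (default: first grid
#'   point).
#' @param varianceCorrection Logical; use the Gaussian-kernel refinement in
#'   which each grid point's gradient combines all windows,
#'   `A'(x) = sum_i w_i(x) [ (x - xbar_i) kB T / s_i^2 - k (x - x0_i) ]` with
#'   normal weights `w_i(x)` built from each window's sample mean and
#'   variance. The default (FALSE) is the plain first-order estimator
#'   evaluated at each window mean, which is the documented protocol; the
#'   refinement matters only when window variances differ appreciably from
#'   `kB T / k`.
#' @param temperature Temperature (K), required when
#'   `varianceCorrection = TRUE`.
#' @export
assemblePMF <- function(windows, anchor = NULL, varianceCorrection = FALSE,
                        temperature = NULL) {
  if (length(windows) < 2L) stop("need at least 2 windows")
  g <- lapply(windows, windowGradient)
  x <- vapply(g, `[[`, numeric(1), "xbar")
  if (anyDuplicated(signif(x, 12)))
    stop("windows with identical mean CV values; merge them")
  o <- order(x)
  x <- x[o]
  dF <- vapply(g, `[[`, numeric(1), "dFdx")[o]
  vr <- vapply(g, `[[`, numeric(1), "var")[o]
  if (varianceCorrection) {
    if (is.null(temperature)) stop("temperature required for the correction")
    kBT <- .kB * temperature
    wo <- windows[o]
    xb <- x
    s2 <- vapply(wo, function(w) var(w$samples), numeric(1))
    ns <- vapply(wo, function(w) length(w$samples), numeric(1))
    k0 <- vapply(wo, function(w) w$k, numeric(1))
    x0 <- vapply(wo, function(w) w$x0, numeric(1))
    dF <- vapply(x, function(xx) {
      wgt <- ns * exp(-0.5 * (xx - xb)^2 / s2) / sqrt(s2)
      wgt <- wgt / sum(wgt)
      sum(wgt * ((xx - xb) * kBT / s2 - k0 * (xx - x0)))
    }, numeric(1))
  }
  nw <- length(x)
  dx <- diff(x)
  Fcum <- c(0, cumsum(dx * (head(dF, -1) + tail(dF, -1)) / 2))
  ## variance: each gradient enters cumulative F_j with trapezoid weight
  varF <- numeric(nw)
  for (j in 2:nw) {
    wgt <- numeric(nw)
    wgt[1] <- dx[1] / 2
    if (j > 2) wgt[2:(j - 1)] <- (dx[1:(j - 2)] + dx[2:(j - 1)]) / 2
    wgt[j] <- dx[j - 1] / 2
    varF[j] <- sum(wgt[1:j]^2 * vr[1:j])
  }
  if (is.null(anchor)) anchor <- x[1]
  if (anchor < min(x) || anchor > max(x))
    stop("anchor outside the sampled CV range")
  shift <- approx(x, Fcum, xout = anchor)$y
  data.frame(x = x, F = Fcum - shift, ci95 = 1.96 * sqrt(varF))
}

#' Block-bootstrap confidence intervals for a PMF profile
#'
#' Resamples each window's sample blocks with replacement, re-assembles the
#' profile `nBoot` times, and returns pointwise 2.5/97.5 percentile bands on
#' the original grid (profiles are interpolated onto the original mean-CV
#' grid before taking percentiles).
#'
#' @param windows List of [uiWindow()].
#' @param nBoot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed (reproducible output).
#' @param anchor As in [assemblePMF()].
#' @return data.frame with `x`, `F`, `lo`, `hi`, `ci95` (half-width).
#' @export
uiConfidenceIntervals <- function(windows, nBoot = 200L, seed = 1L,
                                  anchor = NULL) {
  if (nBoot < 100L) stop("nBoot must be >= 100")
  set.seed(seed)
  base <- assemblePMF(windows, anchor)
  boot <- matrix(NA_real_, nBoot, nrow(base))
  for (b in seq_len(nBoot)) {
    wb <- lapply(windows, function(w) {
      bm <- matrix(w$samples[seq_len((length(w$samples) %/% w$blockSize) *
                                       w$blockSize)],
                   nrow = w$blockSize)
      if (ncol(bm) < 2L) stop("block count < 2; shrink blockSize")
      res <- bm[, sample.int(ncol(bm), replace = TRUE), drop = FALSE]
      w2 <- w
      w2$samples <- as.vector(res)
      w2
    })
    prof <- assemblePMF(wb, anchor)
    boot[b, ] <- approx(prof$x, prof$F, xout = base$x, rule = 2)$y
  }
  lo <- apply(boot, 2L, quantile, probs = 0.025)
  hi <- apply(boot, 2L, quantile, probs = 0.975)
  data.frame(x = base$x, F = base$F, lo = lo, hi = hi, ci95 = (hi - lo) / 2)
}
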