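kB <- kBoltzmann()

## direct Metropolis sampler from the biased density exp(-beta (U + bias)),
## used as an independent route to window samples
mcWindowSamples <- function(U, x0, k, n, beta, x = x0, step = 0.05) {
  out <- numeric(n)
  e <- function(x) U(x) + k / 2 * (x - x0)^2
  ecur <- e(x)
  for (i in seq_len(n)) {
    prop <- x + runif(1, -step, step)
    eprop <- e(prop)
    if (log(runif(1)) < -beta * (eprop - ecur)) {
      x <- prop; ecur <- eprop
    }
    out[i] <- x
  }
  out
}

test_that("window gradient: symmetric samples, arithmetic, and recovery of a
           known linear PMF slope", {
  ## samples symmetric about x0: flat local PMF
  w <- uiWindow(1.0, 400, rep(c(0.98, 1.02), 200), equilibrationDrop = 0)
  expect_equal(windowGradient(w)$dFdx, 0)
  ## xbar - x0 = -0.01 at k = 400: dF/dx = +4
  w2 <- uiWindow(1.0, 400, rep(0.99, 100), equilibrationDrop = 0)
  expect_equal(windowGradient(w2)$dFdx, 4.0)
  ## biased Gaussian oracle: U = s x (linear), biased density is Gaussian
  ## with mean x0 - s/(k + 0) and the UI estimate recovers slope s
  s <- 3.5; k <- 400; beta <- 1 / (kB * 300)
  sd <- sqrt(1 / (beta * k))
  set.seed(91)
  est <- replicate(200, {
    x <- rnorm(500, mean = 0.7 - s / k, sd = sd)
    g <- windowGradient(uiWindow(0.7, k, x, equilibrationDrop = 0))
    (g$dFdx - s) / sqrt(g$var)
  })
  ## standardized errors ~ t-distribution: about 95% within +/- 2 CI
  expect_gt(mean(abs(est) < 2), 0.85)
  expect_lt(abs(mean(est)), 0.2)
  expect_error(windowGradient(uiWindow(0, 1, c(1, 2), blockSize = 2)),
               "blocks")
})

test_that("two opposite-gradient windows give a symmetric two-point profile", {
  w1 <- uiWindow(-1, 100, rnorm(100, -1.02, 1e-6), equilibrationDrop = 0)
  w2 <- uiWindow(1, 100, rnorm(100, 1.02, 1e-6), equilibrationDrop = 0)
  prof <- assemblePMF(list(w1, w2))
  expect_identical(nrow(prof), 2L)
  expect_equal(prof$F[1], 0)
  ## gradients +2 then -2 integrate to ~0 net change over the interval mean
  expect_equal(prof$F[2], 0, tolerance = 1e-3)
})

test_that("umbrella integration recovers the double-well barrier sampled by
           Monte Carlo, against the exact-quadrature oracle", {
  a <- 5; k <- 400; Temp <- 300; beta <- 1 / (kB * Temp)
  U <- function(x) a * (x^2 - 1)^2
  centers <- seq(-1.5, 1.5, by = 0.25)
  ## exact quadrature of window means
  xg <- seq(-3, 3, length.out = 10001)
  xbarExact <- vapply(centers, function(x0) {
    wgt <- exp(-beta * (U(xg) + k / 2 * (xg - x0)^2))
    sum(xg * wgt) / sum(wgt)
  }, numeric(1))
  gradExact <- -k * (xbarExact - centers)
  Fex <- c(0, cumsum(diff(xbarExact) *
                       (head(gradExact, -1) + tail(gradExact, -1)) / 2))
  barrierOracle <- approx(xbarExact, Fex, 0)$y - approx(xbarExact, Fex, -1)$y
  set.seed(92)
  windows <- lapply(centers, function(x0) {
    uiWindow(x0, k, mcWindowSamples(U, x0, k, 20000, beta),
             equilibrationDrop = 0.18)
  })
  prof <- assemblePMF(windows, anchor = -1)
  barrier <- approx(prof$x, prof$F, 0)$y - approx(prof$x, prof$F, -1)$y
  expect_lt(abs(barrier - barrierOracle), 0.25)
  ## and the quadrature UI barrier itself is close to the true U barrier
  expect_lt(abs(barrierOracle - a), 0.5)
})

test_that("the variance-corrected gradient agrees with the first-order
           estimator on well-behaved windows", {
  a <- 5; k <- 400; Temp <- 300; beta <- 1 / (kB * Temp)
  U <- function(x) a * (x^2 - 1)^2
  set.seed(97)
  windows <- lapply(seq(-1.5, 1.5, by = 0.25), function(x0) {
    uiWindow(x0, k, mcWindowSamples(U, x0, k, 8000, beta),
             equilibrationDrop = 0.18)
  })
  plain <- assemblePMF(windows, anchor = -1)
  corr <- assemblePMF(windows, anchor = -1, varianceCorrection = TRUE,
                      temperature = Temp)
  ## stiff bias: the refinement is a small perturbation of the same profile
  expect_lt(max(abs(plain$F - corr$F)), 0.5)
  expect_error(assemblePMF(windows, varianceCorrection = TRUE),
               "temperature")
})

test_that("anchor choice rigidly shifts the profile", {
  set.seed(93)
  windows <- lapply(seq(-1, 1, by = 0.25), function(x0) {
    uiWindow(x0, 50, rnorm(400, x0 + rnorm(1, 0, 0.02), 0.05),
             equilibrationDrop = 0)
  })
  p1 <- assemblePMF(windows, anchor = -0.5)
  p2 <- assemblePMF(windows, anchor = 0.5)
  d1 <- diff(p1$F); d2 <- diff(p2$F)
  expect_lt(max(abs(d1 - d2)), 1e-12)
  expect_error(assemblePMF(windows, anchor = 9), "anchor")
})

test_that("bootstrap confidence intervals: zero-variance, CLT scaling,
           reproducibility", {
  mkwin <- function(nsamp, sd, seed) {
    set.seed(seed)
    lapply(seq(-1, 1, by = 0.5), function(x0) {
      uiWindow(x0, 100, rnorm(nsamp, x0, sd), equilibrationDrop = 0,
               blockSize = 10)
    })
  }
  ## (near) zero-variance samples give (near) zero-width CIs
  wz <- lapply(seq(-1, 1, by = 0.5), function(x0) {
    uiWindow(x0, 100, rep(x0, 200), equilibrationDrop = 0, blockSize = 10)
  })
  ciz <- uiConfidenceIntervals(wz, nBoot = 120, seed = 1)
  expect_lt(max(ciz$ci95), 1e-10)
  ## doubling samples shrinks the mean CI width by about 1/sqrt(2)
  ci1 <- uiConfidenceIntervals(mkwin(400, 0.1, 94), nBoot = 300, seed = 2)
  ci2 <- uiConfidenceIntervals(mkwin(800, 0.1, 94), nBoot = 300, seed = 2)
  ratio <- mean(ci2$ci95[-1]) / mean(ci1$ci95[-1])
  expect_gt(ratio, 1 / sqrt(2) * 0.8)
  expect_lt(ratio, 1 / sqrt(2) * 1.2)
  ## fixed seed reproduces identical intervals
  ciA <- uiConfidenceIntervals(mkwin(400, 0.1, 95), nBoot = 150, seed = 7)
  ciB <- uiConfidenceIntervals(mkwin(400, 0.1, 95), nBoot = 150, seed = 7)
  expect_identical(ciA, ciB)
  expect_error(uiConfidenceIntervals(mkwin(400, 0.1, 96), nBoot = 10),
               "nBoot")
})
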