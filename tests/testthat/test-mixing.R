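test_that("abrupt mixing selects per atom by region", {
  set.seed(51)
  n <- 30
  fE <- matrix(rnorm(3 * n), n)
  fR <- matrix(rnorm(3 * n), n)
  codes <- sample(1:4, n, replace = TRUE)
  lab <- regionLabels(codes)
  mixed <- mixForces(fE, fR, lab)
  ## index-wise oracle
  for (i in 1:n) {
    want <- if (codes[i] <= 2) fE[i, ] else fR[i, ]
    expect_identical(mixed$forces[i, ], want)
  }
  expect_identical(mixed$source, ifelse(codes <= 2, "extended", "reduced"))
  ## identical inputs pass through unchanged; all-MM gives the reduced forces
  expect_identical(mixForces(fE, fE, lab)$forces, fE)
  expect_identical(mixForces(fE, fR, regionLabels(rep(4L, n)))$forces, fR)
  expect_error(mixForces(fE, fR[-1, ], lab), "shape")
})

test_that("momentum correction removes the net force as specified", {
  ## zero net force is a fixed point
  f0 <- rbind(c(1, 0, 0), c(-1, 0, 0))
  out <- correctMomentum(f0, c(2, 2), momentumCorrectionSpec("uniform"))
  expect_identical(out$forces, f0)
  ## 2 equal masses, F_net = (2,0,0), uniform: each corrected by (-1,0,0)
  f1 <- rbind(c(2, 0, 0), c(0, 0, 0))
  out1 <- correctMomentum(f1, c(3, 3), momentumCorrectionSpec("uniform"))
  expect_equal(out1$forces, rbind(c(1, 0, 0), c(-1, 0, 0)))
  ## mass-weighted: per-atom delta proportional to m_i, direct formula
  set.seed(52)
  n <- 12
  f <- matrix(rnorm(3 * n), n)
  m <- runif(n, 1, 20)
  out2 <- correctMomentum(f, m, momentumCorrectionSpec("mass_weighted"))
  expect_lt(max(abs(colSums(out2$forces))), 1e-12)
  fnet <- colSums(f)
  expect_equal(out2$forces, f - outer(m / sum(m), fnet), tolerance = 1e-10)
  ## region-restricted: atoms outside the region untouched
  lab <- regionLabels(c(rep(1L, 4), rep(4L, n - 4)))
  out3 <- correctMomentum(f, m, momentumCorrectionSpec("uniform",
                                                       "dynamical_qm"), lab)
  expect_identical(out3$forces[5:n, ], f[5:n, ])
  expect_lt(max(abs(colSums(out3$forces))), 1e-12)
  ## empty region errors
  labMM <- regionLabels(rep(4L, n))
  expect_error(correctMomentum(f, m, momentumCorrectionSpec(
    "uniform", "dynamical_qm"), labMM), "empty")
})

test_that("variant degeneracies: AdBF with no buffer equals AdUF, etc.", {
  mp <- makeModelPair(0.5)
  st <- randomBox(10, edge = 11, seed = 53)
  specNoBuf <- regionSpec(fixedCore = 1:3, rQm = c(3.5, 4))
  fUF <- runVariantStep(st, specNoBuf, "AdUF", mp$A, mp$B)
  fBF <- runVariantStep(st, specNoBuf, "AdBF", mp$A, mp$B)
  expect_identical(fBF$forces, fUF$forces)
  expect_identical(fUF$nEvals, 2L)
  ## AdUF with DYN_QM = CORE gives AdConv forces on the dynamical QM atoms
  specCoreOnly <- regionSpec(fixedCore = 1:3, rCore = c(3.5, 4))
  fUF2 <- runVariantStep(st, specCoreOnly, "AdUF", mp$A, mp$B,
                         momentum = momentumCorrectionSpec("none"))
  fConv2 <- runVariantStep(st, specCoreOnly, "AdConv", mp$A, mp$B,
                           momentum = momentumCorrectionSpec("none"))
  dyn <- dynamicalQMAtoms(fConv2$labels)
  expect_equal(fUF2$forces[dyn, ], fConv2$forces[dyn, ], tolerance = 1e-12)
  expect_identical(fConv2$nEvals, 1L)
})

test_that("AdBF forces on the center of a 3-molecule line come from the
           evaluation where its neighbor is QM (buffer)", {
  mp <- makeModelPair(0.5)
  st <- makeMoleculeLine(rbind(c(5, 5, 5), c(8.2, 5, 5), c(16, 5, 5)),
                         cell = c(30, 30, 30))
  ## molecule 1 is the dynamical QM seed; molecule 2 within buffer range
  spec <- regionSpec(fixedQm = 1:3, rBuffer = c(4, 4.5),
                     selectionSpeciesFilter = "O")
  res <- runVariantStep(st, spec, "AdBF", mp$A, mp$B,
                        momentum = momentumCorrectionSpec("none"))
  expect_identical(regionOf(res$labels)[1:3], rep("DYN_QM", 3))
  expect_identical(regionOf(res$labels)[4:6], rep("BUFFER", 3))
  ## hand assembly: extended evaluation has molecules 1+2 QM
  comp <- compositeForceField(mp$A, mp$B)
  fExt <- evaluateForces(comp, st, 1:6)$forces
  expect_equal(res$forces[1:3, ], fExt[1:3, ], tolerance = 1e-12)
  ## the buffer molecule itself takes reduced (pure B) forces
  fB <- evaluateForces(mp$B, st)$forces
  expect_equal(res$forces[4:6, ], fB[4:6, ], tolerance = 1e-12)
})

test_that("variant/spec inconsistencies are rejected, not silently fixed", {
  mp <- makeModelPair(0.1)
  st <- randomBox(5, edge = 10, seed = 54)
  specBuf <- regionSpec(fixedCore = 1:3, rBuffer = c(3, 3.5))
  expect_error(runVariantStep(st, specBuf, "AdUF", mp$A, mp$B), "buffer")
  expect_error(runVariantStep(st, specBuf, "Conv", mp$A, mp$B), "radii")
  specQm <- regionSpec(fixedCore = 1:3, rQm = c(3, 3.5))
  expect_error(runVariantStep(st, specQm, "AdConv", mp$A, mp$B), "rQm")
})

test_that("reduced evaluation with empty core is a pure model-B call", {
  mp <- makeModelPair(0.5)
  st <- randomBox(8, edge = 11, seed = 55)
  spec <- regionSpec(fixedQm = 1:3, rQm = c(3, 3.5))
  res <- runVariantStep(st, spec, "AdUF", mp$A, mp$B,
                        momentum = momentumCorrectionSpec("none"))
  fB <- evaluateForces(mp$B, st)$forces
  mm <- which(regionOf(res$labels) == "MM")
  expect_equal(res$forces[mm, ], fB[mm, ], tolerance = 1e-12)
})
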