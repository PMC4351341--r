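test_that("minimum-image distance handles identity, wrap and general cases", {
  expect_equal(minimumImageDistance(c(0, 0, 0), c(0, 0, 0), c(10, 10, 10)), 0)
  expect_equal(minimumImageDistance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10)), 1)
  ## brute-force image enumeration oracle on random pairs
  set.seed(4)
  for (i in 1:50) {
    a <- runif(3, -5, 15); b <- runif(3, -5, 15)
    cell <- runif(3, 6, 12)
    pbc <- runif(3) > 0.3
    expect_equal(minimumImageDistance(a, b, cell, pbc),
                 bruteMinImage(a, b, cell, pbc), tolerance = 1e-12)
    expect_equal(minimumImageDistance(a, b, cell, pbc),
                 minimumImageDistance(b, a, cell, pbc))
  }
  expect_equal(minimumImageDistance(c(1, 1, 1), c(6, 6, 6), c(10, 10, 10)),
               bruteMinImage(c(1, 1, 1), c(6, 6, 6), c(10, 10, 10)))
  expect_error(minimumImageDistance(c(NA, 0, 0), c(0, 0, 0), c(10, 10, 10)),
               "non-finite")
})

test_that("cross-distance matrix matches the scalar routine", {
  set.seed(5)
  X <- matrix(runif(15, 0, 10), 5)
  Y <- matrix(runif(9, 0, 10), 3)
  cell <- c(8, 9, 10); pbc <- c(TRUE, TRUE, FALSE)
  D <- minimumImageCrossDist(X, Y, cell, pbc)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(D[i, j], minimumImageDistance(X[i, ], Y[j, ], cell, pbc))
  }
})

test_that("SystemState validity catches bad inputs", {
  expect_error(systemState(matrix(0, 1, 3), masses = -1, species = "O",
                           moleculeId = 1L, cell = c(10, 10, 10)),
               "positive")
  expect_error(systemState(matrix(0, 1, 3), masses = 16, species = "O",
                           moleculeId = 1L, cell = c(0, 10, 10)),
               "periodic")
  st <- systemState(matrix(0, 1, 3), masses = 16, species = "O",
                    moleculeId = 1L, cell = c(10, 10, 10))
  expect_equal(nAtoms(st), 1L)
})

test_that("forces are the negative energy gradient (finite differences)", {
  st <- randomBox(4, edge = 9, seed = 11)
  model <- defaultWaterLikeModel()
  err <- fdForceError(st, function(s) evaluateForces(model, s))
  expect_lt(err, 1e-5)
  ## composite with a fixed QM set is conservative too
  mp <- makeModelPair(0.3)
  comp <- compositeForceField(mp$A, mp$B)
  qm <- which(moleculeId(st) <= 2)
  err2 <- fdForceError(st, function(s) evaluateForces(comp, s, qm))
  expect_lt(err2, 1e-5)
})

test_that("rigid translation (with PBC) leaves forces unchanged", {
  st <- randomBox(5, edge = 10, seed = 12)
  model <- defaultWaterLikeModel()
  f0 <- evaluateForces(model, st)$forces
  st2 <- st
  st2@positions <- st@positions +
    matrix(c(3.123, -7.5, 14.2), nAtoms(st), 3, byrow = TRUE)
  f1 <- evaluateForces(model, st2)$forces
  expect_lt(max(abs(f1 - f0)), 1e-10)
})

test_that("Newton's third law holds before any correction", {
  st <- randomBox(6, edge = 10, seed = 13)
  f <- evaluateForces(defaultWaterLikeModel(), st)$forces
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("two atoms at the pair minimum feel (almost) no force", {
  model <- defaultWaterLikeModel()
  ## heavy-heavy dimer: locate the shifted-force minimum by a fine scan,
  ## then check the force vanishes there
  mkDimer <- function(d) {
    systemState(rbind(c(0, 0, 0), c(d, 0, 0)), masses = c(16, 16),
                species = c("O", "O"), moleculeId = 1:2,
                cell = c(40, 40, 40))
  }
  ds <- seq(2.8, 4.0, by = 1e-4)
  es <- vapply(ds, function(d) evaluateForces(model, mkDimer(d))$energy,
               numeric(1))
  dmin <- ds[which.min(es)]
  f <- evaluateForces(model, mkDimer(dmin))$forces
  expect_lt(max(abs(f)), 5e-3)
})

test_that("degenerate QM sets and bad inputs behave per contract", {
  st <- randomBox(3, edge = 9, seed = 14)
  mp <- makeModelPair(0.4)
  comp <- compositeForceField(mp$A, mp$B)
  fAll <- evaluateForces(comp, st, seq_len(nAtoms(st)))$forces
  fA <- evaluateForces(mp$A, st)$forces
  expect_identical(fAll, fA)
  fNone <- evaluateForces(comp, st, integer(0))$forces
  fB <- evaluateForces(mp$B, st)$forces
  expect_identical(fNone, fB)
  expect_error(evaluateForces(comp, st, c(1L, 99L)), "out of range")
  stBad <- st
  stBad@species[1] <- "Zn"
  expect_error(evaluateForces(comp, stBad), "unknown species")
})

test_that("kinetic temperature is exact for hand-set velocities", {
  st <- systemState(matrix(0, 2, 3), masses = c(16, 1), species = c("O", "H"),
                    moleculeId = c(1L, 1L), cell = c(10, 10, 10))
  expect_equal(kineticTemperature(st), 0)
  ## one DOF with m v^2 = kB * 300 (internal units)
  v <- sqrt(kBoltzmann() * 300 * accelUnit() / 16)
  st@velocities[1, 1] <- v
  perDof <- kineticTemperature(st, perDof = TRUE)
  expect_equal(perDof[1, 1], 300)
  expect_equal(sum(perDof), 300)
  ## Maxwell-Boltzmann draw at 300 K
  set.seed(20)
  m <- rep(c(16, 1, 1), 3000)
  vmb <- maxwellBoltzmannVelocities(m, 300)
  Tkin <- kineticTemperature(vmb, m = m)
  ndof <- length(m) * 3
  expect_lt(abs(Tkin - 300), 2 * 300 * sqrt(2 / ndof))
})
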