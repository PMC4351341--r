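test_that("restraint forces: one-sided activation and harmonic CV gradient", {
  st <- makeMoleculeLine(rbind(c(5, 5, 5), c(7.5, 5, 5)), cell = c(30, 30, 30))
  ## one-sided O-O restraint beyond 3.0 A, k = 25: inactive at 2.5 A
  spec <- list(kind = "one_sided_distance", atoms = c(1L, 4L),
               threshold = 3.0, k = 25.0, side = "upper")
  r <- restraintForces(st, spec)
  expect_equal(max(abs(r$forces)), 0)
  expect_equal(r$energy, 0)
  ## active beyond the threshold, continuous at it
  st2 <- st
  st2@positions[4:6, 1] <- st2@positions[4:6, 1] + 1.0   # O-O now 3.5 A
  r2 <- restraintForces(st2, spec)
  expect_equal(r2$energy, 0.5 * 25 * 0.5^2)
  stEdge <- st
  stEdge@positions[4:6, 1] <- stEdge@positions[4:6, 1] + 0.5 + 1e-9
  expect_lt(max(abs(restraintForces(stEdge, spec)$forces)), 1e-6)
  ## harmonic CV bias on DRCN with k = 400: force is -k (x - x0) grad x
  cv <- list(type = "drcn", donorO = 1, acceptorO = 4, hydrogens = c(2, 3, 5, 6))
  bias <- list(kind = "harmonic_cv", cv = cv, x0 = 0.5, k = 400)
  rb <- restraintForces(st, bias)
  cvr <- cvValue(cv, st)
  expect_equal(rb$forces, -400 * (cvr$value - 0.5) * cvr$gradient)
  ## and matches finite differences of the bias energy
  h <- 1e-6
  for (a in c(1, 2, 5)) for (k in 1:3) {
    sp <- st; sm <- st
    sp@positions[a, k] <- sp@positions[a, k] + h
    sm@positions[a, k] <- sm@positions[a, k] - h
    num <- -(restraintForces(sp, bias)$energy -
               restraintForces(sm, bias)$energy) / (2 * h)
    expect_equal(rb$forces[a, k], num, tolerance = 1e-4)
  }
})

test_that("zero-step run returns only the initial frame", {
  st <- randomBox(3, edge = 9, seed = 81)
  cfg <- simulationConfig(nSteps = 0, variant = "MD",
                          provider = defaultWaterLikeModel())
  tr <- runMD(st, cfg)
  expect_length(tr$frames, 1L)
  expect_identical(tr$frameSteps, 0L)
  expect_identical(positions(tr$finalState), positions(st))
})

test_that("identical config and seed give identical trajectories", {
  st <- buildWaterBox(8, seed = 82)
  mp <- makeModelPair(0.3)
  spec <- regionSpec(fixedQm = 1:3, rQm = c(4, 4.5), rBuffer = c(4, 4.5),
                     selectionSpeciesFilter = "O")
  cfg <- simulationConfig(nSteps = 60, variant = "AdBF", regionSpec = spec,
                          modelA = mp$A, modelB = mp$B,
                          thermostat = adLangevinThermostat(nAtoms(st)),
                          seed = 5)
  t1 <- runMD(st, cfg)
  t2 <- runMD(st, cfg)
  expect_identical(positions(t1$finalState), positions(t2$finalState))
  expect_identical(t1$temperature, t2$temperature)
})

test_that("with identical models every variant reproduces single-model MD", {
  st <- buildWaterBox(8, seed = 83)
  mp <- makeModelPair(0)
  th <- function() adLangevinThermostat(nAtoms(st))
  base <- simulationConfig(nSteps = 80, variant = "MD", provider = mp$B,
                           thermostat = th(), seed = 9)
  ref <- runMD(st, base)
  specs <- list(
    AdBF = regionSpec(fixedQm = 1:3, rQm = c(4, 4.5), rBuffer = c(4, 4.5),
                      selectionSpeciesFilter = "O"),
    AdUF = regionSpec(fixedQm = 1:3, rQm = c(4, 4.5),
                      selectionSpeciesFilter = "O"),
    AdConv = regionSpec(fixedCore = 1:3, rCore = c(4, 4.5),
                        selectionSpeciesFilter = "O"),
    Conv = regionSpec(fixedQm = 1:3))
  for (v in names(specs)) {
    cfg <- simulationConfig(nSteps = 80, variant = v, regionSpec = specs[[v]],
                            modelA = mp$A, modelB = mp$B, thermostat = th(),
                            seed = 9)
    tr <- runMD(st, cfg)
    expect_lt(max(abs(positions(tr$finalState) - positions(ref$finalState))),
              1e-8)
  }
})

test_that("unthermostatted velocity-Verlet limit conserves energy", {
  st <- buildWaterBox(8, seed = 84, temperature = 150)
  model <- defaultWaterLikeModel()
  cfg <- simulationConfig(dt = 0.1, nSteps = 5000, variant = "MD",
                          provider = model, thermostat = NULL,
                          momentum = momentumCorrectionSpec("none"),
                          outputEvery = 500)
  tr <- runMD(st, cfg)
  etot <- vapply(tr$frames, function(s) {
    evaluateForces(model, s)$energy +
      sum(masses(s) * velocities(s)^2) / (2 * accelUnit())
  }, numeric(1))
  drift <- max(abs(etot - etot[1]))
  expect_lt(drift / nAtoms(st), 1e-4)
})

test_that("region-size series matches post-hoc re-partitioning of frames", {
  st <- buildWaterBox(10, seed = 85)
  mp <- makeModelPair(0.2)
  spec <- regionSpec(fixedQm = 1:3, rQm = c(4, 4.5), rBuffer = c(4, 4.5),
                     selectionSpeciesFilter = "O")
  cfg <- simulationConfig(nSteps = 40, variant = "AdBF", regionSpec = spec,
                          modelA = mp$A, modelB = mp$B,
                          thermostat = adLangevinThermostat(nAtoms(st)),
                          seed = 11, outputEvery = 1)
  tr <- runMD(st, cfg)
  post <- qmCountTrace(c(list(tr$frames[[1]]), tr$frames[-1]), spec)
  ## frame 1 is the initial state; live log rows correspond to frames 2..41
  expect_identical(tr$regionLog$extended_qm, post$counts$extended_qm[-1])
})

test_that("blow-up aborts with the failing step index", {
  ## a single molecule in a non-periodic cell with a time step far beyond
  ## the bond-oscillation stability limit grows until positions overflow
  tpl <- makeMolecule(c(6, 6, 6))
  st <- systemState(tpl$positions, masses = tpl$masses, species = tpl$species,
                    moleculeId = rep(1L, 3), cell = c(12, 12, 12),
                    pbc = rep(FALSE, 3), bonds = tpl$bonds,
                    angles = tpl$angles)
  st@positions[2, 1] <- st@positions[2, 1] + 0.05   # seed the instability
  cfg <- simulationConfig(dt = 10, nSteps = 500, variant = "MD",
                          provider = defaultWaterLikeModel(),
                          momentum = momentumCorrectionSpec("none"))
  expect_error(runMD(st, cfg), "step [0-9]+")
})

test_that("steered schedule: window bookkeeping and hold sampling", {
  st <- systemState(matrix(c(-1, 0, 0), 1, 3), masses = 16, species = "X",
                    moleculeId = 1L, cell = c(50, 50, 50),
                    pbc = rep(FALSE, 3))
  cfg <- simulationConfig(dt = 1, variant = "MD",
                          provider = externalDoubleWell(1, 1),
                          thermostat = adLangevinThermostat(1, 300, 10, 10),
                          momentum = momentumCorrectionSpec("none"),
                          bias = list(cv = list(type = "coordinate", atom = 1,
                                                axis = 1), k = 400, x0 = -1))
  ## the proton-transfer window ladder: -0.2 to 2.2 in steps of 0.1 is 25
  ## windows (here applied to a plain coordinate CV)
  centers <- seq(-0.2, 2.2, by = 0.1)
  expect_length(centers, 25L)
  set.seed(86)
  ss <- steeredSchedule(st, cfg, centers[1:3], moveSteps = 10,
                        holdSteps = 50, sampleEvery = 5,
                        equilibrationDrop = 0.2)
  expect_length(ss$windows, 3L)
  expect_identical(nrow(ss$schedule), 3L)
  ## each window keeps 10 samples minus 20% equilibration drop
  expect_length(ss$windows[[1]]$samples, 8L)
  expect_equal(ss$windows[[2]]$x0, centers[2])
  ## moving 0.1 A per 1 ps at dt = 0.5 fs is 2000 steps per move
  expect_equal(1000 / 0.5, 2000)
})

test_that("config round trip through YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "dt: 0.5", "n_steps: 10", "variant: AdBF", "seed: 3",
    "model:", "  delta: 0.2",
    "regions:",
    "  fixed_qm: [1, 2, 3]",
    "  r_qm: [4.0, 4.5]",
    "  r_buffer: [4.0, 4.5]",
    "  species_filter: O",
    "thermostat:",
    "  type: ad_langevin", "  temperature: 300",
    "  tau_langevin: 200", "  tau_nh: 200",
    "momentum:", "  mode: mass_weighted", "  region: all"), yml)
  cfg <- readSimulationConfig(yml, nAtoms = 24)
  expect_equal(cfg$dt, 0.5)
  expect_identical(cfg$variant, "AdBF")
  expect_equal(cfg$regionSpec@rQm, c(4.0, 4.5))
  expect_s4_class(cfg$thermostat, "AdLangevinThermostat")
  expect_equal(cfg$modelA@eps["O", "O"] / cfg$modelB@eps["O", "O"], 1.2)
  st <- buildWaterBox(8, seed = 87)
  tr <- runMD(st, cfg)
  expect_length(tr$temperature, 10L)
})
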