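test_that("hysteretic selection reduces to plain cutoff when rIn = rOut", {
  st <- randomBox(15, edge = 12, seed = 41)
  all_atoms <- seq_len(nAtoms(st))
  ref <- 1:3
  set.seed(42)
  for (i in 1:5) {
    prev <- sample(all_atoms, 10)
    r <- runif(1, 2, 6)
    sel <- hystereticSelect(all_atoms, ref, prev, r, r, st)
    selNoPrev <- hystereticSelect(all_atoms, ref, integer(0), r, r, st)
    expect_identical(sel, selNoPrev)
  }
})

test_that("an atom between the radii is kept iff previously a member", {
  ## bulk-water-style hysteretic radii 4.0-4.5 A: an atom at 4.2 A is inside
  ## the outer but outside the inner radius
  st <- systemState(rbind(c(0, 0, 0), c(4.2, 0, 0)), masses = c(16, 16),
                    species = c("O", "O"), moleculeId = 1:2,
                    cell = c(30, 30, 30))
  inSet <- hystereticSelect(2L, 1L, prevMembers = 2L, 4.0, 4.5, st)
  outSet <- hystereticSelect(2L, 1L, prevMembers = integer(0), 4.0, 4.5, st)
  expect_identical(inSet, 2L)
  expect_identical(outSet, integer(0))
  expect_error(hystereticSelect(2L, 1L, integer(0), 4.5, 4.0, st), "exceeds")
  expect_error(hystereticSelect(2L, integer(0), integer(0), 4, 4.5, st),
               "empty")
})

test_that("hysteretic selection matches the set-comprehension oracle", {
  set.seed(43)
  for (i in 1:20) {
    st <- randomBox(17, edge = 11)
    n <- nAtoms(st)
    cand <- sample(n, 40)
    ref <- sample(n, 4)
    prev <- sample(n, 12)
    rIn <- runif(1, 1, 5)
    rOut <- rIn + runif(1, 0, 2)
    filt <- if (runif(1) < 0.5) "O" else character(0)
    expect_identical(
      hystereticSelect(cand, ref, prev, rIn, rOut, st, filt),
      oracleSelect(cand, ref, prev, rIn, rOut, st, filt))
  }
})

test_that("degenerate radii give the conventional QM/MM configuration", {
  st <- randomBox(10, edge = 11, seed = 44)
  ## all radii zero: CORE = fixed core, DYN_QM = CORE, BUFFER empty
  spec <- regionSpec(fixedCore = 1:3)
  lab <- partitionRegions(st, spec)
  expect_identical(coreAtoms(lab), 1:3)
  expect_identical(dynamicalQMAtoms(lab), 1:3)
  expect_identical(extendedQMAtoms(lab), 1:3)
  ## AdConv-style: adaptive core, no dynamical-QM or buffer extension
  spec2 <- regionSpec(fixedCore = 1:3, rCore = c(2.5, 3.0))
  lab2 <- partitionRegions(st, spec2)
  expect_identical(coreAtoms(lab2), dynamicalQMAtoms(lab2))
  expect_identical(sum(regionOf(lab2) == "BUFFER"), 0L)
  expect_true(all(1:3 %in% coreAtoms(lab2)))
})

test_that("partition matches the brute-force oracle with molecule promotion", {
  set.seed(45)
  for (i in 1:15) {
    st <- randomBox(20, edge = 13)
    spec <- regionSpec(fixedCore = 1:3,
                       rCore = sort(runif(2, 0, 3)),
                       rQm = sort(runif(2, 2, 4)),
                       rBuffer = sort(runif(2, 2, 4)),
                       selectionSpeciesFilter =
                         if (runif(1) < 0.5) "O" else character(0),
                       wholeMolecules = TRUE)
    prevCodes <- sample(1:4, nAtoms(st), replace = TRUE)
    ## make prev molecule-consistent (post-promotion labels)
    for (m in unique(moleculeId(st))) {
      idx <- which(moleculeId(st) == m)
      prevCodes[idx] <- min(prevCodes[idx])
    }
    lab <- partitionRegions(st, spec, regionLabels(prevCodes))
    expect_identical(lab@codes, oraclePartition(st, spec, prevCodes))
  }
})

test_that("region algebra: nesting, idempotence, monotonicity", {
  set.seed(46)
  for (i in 1:10) {
    st <- randomBox(15, edge = 12)
    spec <- regionSpec(fixedCore = 1:3, rCore = c(2, 2.5), rQm = c(3, 3.5),
                       rBuffer = c(3, 3.5))
    lab <- partitionRegions(st, spec)
    ## nesting
    expect_true(all(coreAtoms(lab) %in% dynamicalQMAtoms(lab)))
    expect_length(intersect(dynamicalQMAtoms(lab),
                            which(regionOf(lab) == "BUFFER")), 0)
    ## idempotence
    lab2 <- partitionRegions(st, spec)
    expect_identical(lab@codes, lab2@codes)
    ## monotonicity: larger inner radius never shrinks the region
    spec3 <- spec
    spec3@rQm <- c(3.4, 3.5)
    lab3 <- partitionRegions(st, spec3)
    expect_true(all(dynamicalQMAtoms(lab) %in% dynamicalQMAtoms(lab3)))
  }
})

test_that("fixed-list atoms promote inward and the size cap errors", {
  st <- randomBox(8, edge = 10, seed = 47)
  ## a fixed buffer atom that geometrically falls in the core selection is
  ## promoted to CORE
  spec <- regionSpec(fixedCore = 1L, fixedBuffer = 2L, rCore = c(5, 5))
  lab <- partitionRegions(st, spec)
  d12 <- minimumImageDistance(positions(st)[1, ], positions(st)[2, ],
                              st@cell, st@pbc)
  if (d12 <= 5) expect_identical(regionOf(lab)[2], "CORE")
  specCap <- regionSpec(fixedCore = 1L, rCore = c(5, 5), maxExtendedAtoms = 2L)
  expect_error(partitionRegions(st, specCap), "maxExtendedAtoms")
  expect_error(regionSpec(fixedCore = 1:2, fixedQm = 2:3), "disjoint")
})

test_that("species filter restricts selection but molecule promotion fills in", {
  st <- makeMoleculeLine(rbind(c(5, 5, 5), c(8.5, 5, 5)), cell = c(20, 20, 20))
  spec <- regionSpec(fixedQm = 1:3, rQm = c(4, 4.5),
                     selectionSpeciesFilter = "O", wholeMolecules = TRUE)
  lab <- partitionRegions(st, spec)
  ## second molecule's O is at 3.5 A from the first O: whole molecule joins
  expect_true(all(regionOf(lab)[4:6] == "DYN_QM"))
  ## without promotion, only the O atom joins
  spec2 <- spec
  spec2@wholeMolecules <- FALSE
  lab2 <- partitionRegions(st, spec2)
  expect_identical(regionOf(lab2)[4], "DYN_QM")
  expect_true(all(regionOf(lab2)[5:6] == "MM"))
})
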