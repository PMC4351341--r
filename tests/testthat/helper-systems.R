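## Shared fixtures and independent oracles for the test suite. All fixtures
## are generated in code; no data files.

## a single water-like molecule at a given heavy-atom position
makeMolecule <- function(center, molId = 1L, b0 = 1.0,
                         theta0 = 104.52 * pi / 180) {
  h <- theta0 / 2
  pos <- rbind(c(0, 0, 0),
               b0 * c(sin(h), cos(h), 0),
               b0 * c(-sin(h), cos(h), 0))
  pos <- pos + matrix(center, 3, 3, byrow = TRUE)
  list(positions = pos, species = c("O", "H", "H"), masses = c(16, 1, 1),
       moleculeId = rep(molId, 3L),
       bonds = rbind(c(1L, 2L), c(1L, 3L)) + (molId - 1L) * 3L,
       angles = matrix(c(2L, 1L, 3L), 1) + (molId - 1L) * 3L)
}

## n molecules with heavy atoms at given centers (n x 3 matrix)
makeMoleculeLine <- function(centers, cell = c(30, 30, 30),
                             pbc = c(TRUE, TRUE, TRUE)) {
  centers <- rbind(centers)
  parts <- lapply(seq_len(nrow(centers)), function(i) {
    makeMolecule(centers[i, ], molId = i)
  })
  systemState(
    positions = do.call(rbind, lapply(parts, `[[`, "positions")),
    masses = unlist(lapply(parts, `[[`, "masses")),
    species = unlist(lapply(parts, `[[`, "species")),
    moleculeId = unlist(lapply(parts, `[[`, "moleculeId")),
    cell = cell, pbc = pbc,
    bonds = do.call(rbind, lapply(parts, `[[`, "bonds")),
    angles = do.call(rbind, lapply(parts, `[[`, "angles")))
}

## central finite-difference force check for a conservative evaluation
fdForceError <- function(state, evalFun, atoms = NULL, h = 1e-5) {
  f <- evalFun(state)$forces
  if (is.null(atoms)) atoms <- seq_len(nAtoms(state))
  errs <- c()
  for (i in atoms) {
    for (k in 1:3) {
      sp <- state; sm <- state
      sp@positions[i, k] <- sp@positions[i, k] + h
      sm@positions[i, k] <- sm@positions[i, k] - h
      num <- -(evalFun(sp)$energy - evalFun(sm)$energy) / (2 * h)
      errs <- c(errs, abs(num - f[i, k]))
    }
  }
  max(errs)
}

## brute-force minimum-image distance by enumerating periodic images
bruteMinImage <- function(a, b, cell, pbc = c(TRUE, TRUE, TRUE)) {
  best <- Inf
  for (ix in -3:3) for (iy in -3:3) for (iz in -3:3) {
    shift <- c(ix, iy, iz) * ifelse(pbc, cell, 0)
    if (any(c(ix, iy, iz) != 0 & !pbc)) next
    best <- min(best, sqrt(sum((a - b - shift)^2)))
  }
  best
}

## independent set-comprehension re-implementation of hysteretic selection
oracleSelect <- function(candidates, reference, prevMembers, rIn, rOut,
                         state, filter = character(0)) {
  sp <- species(state)
  if (length(filter)) {
    candidates <- candidates[sp[candidates] %in% filter]
    reference <- reference[sp[reference] %in% filter]
    if (!length(reference)) return(integer(0))
  }
  keep <- vapply(candidates, function(a) {
    d <- min(vapply(reference, function(r) {
      minimumImageDistance(positions(state)[a, ], positions(state)[r, ],
                           state@cell, state@pbc)
    }, numeric(1)))
    d <= rIn || (a %in% prevMembers && d <= rOut)
  }, logical(1))
  sort(candidates[keep])
}

## independent re-implementation of the three-stage partition + promotion
oraclePartition <- function(state, spec, prevCodes = NULL) {
  n <- nAtoms(state)
  allA <- seq_len(n)
  prevIn <- function(code) {
    if (is.null(prevCodes)) integer(0) else which(prevCodes <= code)
  }
  sel <- function(ref, code, r) {
    if (!length(ref) || r[2] <= 0) return(integer(0))
    oracleSelect(allA, ref, prevIn(code), r[1], r[2], state,
                 spec@selectionSpeciesFilter)
  }
  core <- sort(unique(c(spec@fixedCore, sel(spec@fixedCore, 1L, spec@rCore))))
  seed <- if (spec@seedIsOnlyFixedCore) spec@fixedCore
          else sort(unique(c(core, spec@fixedQm)))
  dynqm <- sort(unique(c(core, spec@fixedQm, sel(seed, 2L, spec@rQm))))
  buffer <- setdiff(sort(unique(c(spec@fixedBuffer,
                                  sel(dynqm, 3L, spec@rBuffer)))), dynqm)
  codes <- rep(4L, n)
  codes[buffer] <- 3L
  codes[dynqm] <- 2L
  codes[core] <- 1L
  if (spec@wholeMolecules) {
    for (m in unique(moleculeId(state))) {
      idx <- which(moleculeId(state) == m)
      codes[idx] <- min(codes[idx])
    }
  }
  codes
}

## random small box of molecules for property tests
randomBox <- function(nMol, edge = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(runif(3 * nMol, 0, edge), ncol = 3)
  makeMoleculeLine(centers, cell = rep(edge, 3))
}
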