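#' ForceProvider: contract mapping (state, QM atom set) to forces
#'
#' Virtual parent of all force providers. Implementations supply an
#' [evaluateForces()] method returning per-atom forces (kcal mol^-1 A^-1)
#' and, where defined, a potential energy.
#'
#' @export
setClass("ForceProvider", representation("VIRTUAL"))

#' PairForceField: water-like classical force model
#'
#' A cheap classical model of a molecular liquid: shifted-force Lennard-Jones
#' between heavy atoms, an optional short-range shifted-force Gaussian
#' attraction between heavy and light atoms of different molecules (to give a
#' structured first neighbor shell), and harmonic bonds and angles inside
#' molecules. Both the potential and the force go continuously to zero at the
#' cutoff (shifted-force form). Two such models with deliberately mismatched
#' intermolecular parameters play the roles of the "QM" and "MM" engines in
#' the adaptive force-mixing machinery.
#'
#' @slot speciesTable Character vector of known element symbols; row/column
#'   order of the parameter matrices.
#' @slot eps,rmin,rcut S x S matrices: LJ well depth (kcal/mol), position of
#'   the LJ minimum (A), and cutoff (A). `eps = 0` disables the LJ term for
#'   that pair; where enabled `rcut > rmin` is required.
#' @slot geps,gr0,gw,grcut S x S matrices for the Gaussian attraction: depth
#'   (kcal/mol), center (A), width (A), cutoff (A). `geps = 0` disables it.
#' @slot kBond,b0 Harmonic bond constant (kcal mol^-1 A^-2) and rest length (A).
#' @slot kAngle,theta0 Harmonic angle constant (kcal mol^-1 rad^-2) and rest
#'   angle (rad).
#' @export
setClass("PairForceField",
  contains = "ForceProvider",
  representation(
    speciesTable = "character",
    eps = "matrix", rmin = "matrix", rcut = "matrix",
    geps = "matrix", gr0 = "matrix", gw = "matrix", grcut = "matrix",
    kBond = "numeric", b0 = "numeric",
    kAngle = "numeric", theta0 = "numeric"
  )
)

setValidity("PairForceField", function(object) {
  s <- length(object@speciesTable)
  mats <- list(object@eps, object@rmin, object@rcut, object@geps,
               object@gr0, object@gw, object@grcut)
  if (any(vapply(mats, function(m) !all(dim(m) == c(s, s)), logical(1))))
    return("all parameter matrices must be S x S")
  if (any(object@eps < 0)) return("LJ well depths must be >= 0")
  act <- object@eps > 0
  if (any(object@rmin[act] <= 0)) return("rmin must be > 0 where LJ is active")
  if (any(object@rcut[act] <= object@rmin[act]))
    return("rcut must exceed rmin where LJ is active")
  TRUE
})

#' Construct a pair force field
#'
#' @param speciesTable Character vector of element symbols.
#' @param eps,rmin,rcut,geps,gr0,gw,grcut Parameter matrices, see
#'   [PairForceField-class]. Scalars are recycled to S x S.
#' @param kBond,b0,kAngle,theta0 Bonded parameters.
#' @return A [PairForceField-class] object.
#' @export
pairForceField <- function(speciesTable, eps, rmin, rcut,
                           geps = 0, gr0 = 1, gw = 1, grcut = 1,
                           kBond = 0, b0 = 1, kAngle = 0, theta0 = pi / 2) {
  s <- length(speciesTable)
  expand <- function(x) {
    if (is.matrix(x)) x else matrix(x, s, s)
  }
  new("PairForceField", speciesTable = speciesTable,
      eps = expand(eps), rmin = expand(rmin), rcut = expand(rcut),
      geps = expand(geps), gr0 = expand(gr0), gw = expand(gw),
      grcut = expand(grcut),
      kBond = kBond, b0 = b0, kAngle = kAngle, theta0 = theta0)
}

setMethod("show", "PairForceField", function(object) {
  cat(sprintf("PairForceField over {%s}\n",
              paste(object@speciesTable, collapse = ", ")))
  cat(sprintf("  LJ: eps[1,1]=%.4g kcal/mol rmin[1,1]=%.4g A rcut[1,1]=%.4g A\n",
              object@eps[1, 1], object@rmin[1, 1], object@rcut[1, 1]))
  cat(sprintf("  bonds: k=%.4g b0=%.4g; angles: k=%.4g theta0=%.4g rad\n",
              object@kBond, object@b0, object@kAngle, object@theta0))
  invisible(object)
})

#' CompositeForceField: two-model QM/MM evaluator
#'
#' Holds a "QM" model A and an "MM" model B over the same species set. In a
#' composite evaluation with a QM atom set, every intermolecular pair with
#' both atoms in the set interacts with A's parameters; every other pair with
#' B's. Intramolecular terms use A iff all of the molecule's atoms are in the
#' set (whole molecules switch description; no bond cutting). For a fixed QM
#' set the evaluation is conservative.
#'
#' @slot modelA,modelB [PairForceField-class] objects.
#' @export
setClass("CompositeForceField",
  contains = "ForceProvider",
  representation(modelA = "PairForceField", modelB = "PairForceField")
)

setValidity("CompositeForceField", function(object) {
  if (!identical(object@modelA@speciesTable, object@modelB@speciesTable))
    return("models A and B must share the same species table")
  TRUE
})

#' @rdname CompositeForceField-class
#' @param modelA,modelB [PairForceField-class] objects over the same species.
#' @export
compositeForceField <- function(modelA, modelB) {
  new("CompositeForceField", modelA = modelA, modelB = modelB)
}

#' Default water-like model parameters
#'
#' Named preset for the toy liquid used throughout: molecules of one heavy
#' ("O", 16 amu) and two light ("H", 1 amu) atoms with harmonic bonds
#' (k = 450 kcal mol^-1 A^-2, b0 = 1.0 A) and angle (k = 55 kcal mol^-1
#' rad^-2, theta0 = 104.52 deg); intermolecular shifted-force LJ between
#' heavy atoms (eps = 0.20 kcal/mol, rmin = 3.2 A, rcut = 7.0 A) plus a
#' short-range Gaussian O-H attraction (0.25 kcal/mol at 2.0 A, width 0.3 A,
#' cutoff 4.0 A) with an r^-12 core, giving a structured first neighbor
#' shell. No fidelity to real water thermodynamics is intended.
#'
#' @return A [PairForceField-class].
#' @export
defaultWaterLikeModel <- function() {
  sp <- c("O", "H")
  eps <- matrix(0, 2, 2, dimnames = list(sp, sp))
  rmin <- matrix(1, 2, 2, dimnames = list(sp, sp))
  rcut <- matrix(2, 2, 2, dimnames = list(sp, sp))
  eps["O", "O"] <- 0.20
  rmin["O", "O"] <- 3.2
  rcut["O", "O"] <- 7.0
  ## weak O-H core repulsion realized as tiny LJ with small rmin
  eps["O", "H"] <- eps["H", "O"] <- 0.01
  rmin["O", "H"] <- rmin["H", "O"] <- 1.4
  rcut["O", "H"] <- rcut["H", "O"] <- 3.5
  dn <- list(sp, sp)
  geps <- matrix(0, 2, 2, dimnames = dn)
  gr0 <- matrix(1, 2, 2, dimnames = dn)
  gw <- matrix(1, 2, 2, dimnames = dn)
  grcut <- matrix(2, 2, 2, dimnames = dn)
  geps["O", "H"] <- geps["H", "O"] <- 0.25
  gr0["O", "H"] <- gr0["H", "O"] <- 2.0
  gw["O", "H"] <- gw["H", "O"] <- 0.3
  grcut["O", "H"] <- grcut["H", "O"] <- 4.0
  pairForceField(sp, eps, rmin, rcut, geps, gr0, gw, grcut,
                 kBond = 450, b0 = 1.0, kAngle = 55,
                 theta0 = 104.52 * pi / 180)
}

#' Build a mismatched QM/MM model pair
#'
#' Returns two water-like models over the same species set in which model A's
#' intermolecular well depths, equilibrium distances and cutoffs are scaled by
#' `(1 + delta)` relative to model B. `delta = 0` gives bitwise-identical
#' parameters. The scale factor is the controlled analogue of the chemical
#' potential mismatch between a QM and an MM description of the same species;
#' the boundary force error it induces is exactly what the buffered
#' force-mixing method is designed to bury inside the buffer. Intramolecular
#' (bond/angle) terms are identical in A and B.
#'
#' @param delta Dimensionless mismatch scale (finite; `1 + delta > 0`).
#' @param base Model B template, default [defaultWaterLikeModel()].
#' @return List with elements `A` and `B` ([PairForceField-class]).
#' @examples
#' mp <- makeModelPair(0.2)
#' mp$A@eps["O", "O"] / mp$B@eps["O", "O"]
#' @export
makeModelPair <- function(delta, base = defaultWaterLikeModel()) {
  if (!is.finite(delta)) stop("delta must be finite")
  s <- 1 + delta
  if (s <= 0) stop("resulting well depth would be negative: 1 + delta <= 0")
  A <- base
  A@eps <- base@eps * s
  A@rmin <- base@rmin * s
  A@rcut <- base@rcut * s
  A@geps <- base@geps * s
  A@gr0 <- base@gr0 * s
  A@gw <- base@gw * s
  A@grcut <- base@grcut * s
  list(A = A, B = base)
}

.paramList <- function(ff) {
  list(eps = ff@eps, rmin = ff@rmin, rcut = ff@rcut,
       geps = ff@geps, gr0 = ff@gr0, gw = ff@gw, grcut = ff@grcut)
}

.speciesIndex <- function(state, ff) {
  idx <- match(species(state), ff@speciesTable)
  if (anyNA(idx)) {
    stop("unknown species for this force field: ",
         paste(unique(species(state)[is.na(idx)]), collapse = ", "))
  }
  idx
}

.checkQmAtoms <- function(state, qmAtoms) {
  qmAtoms <- as.integer(qmAtoms)
  n <- nAtoms(state)
  if (length(qmAtoms) && (min(qmAtoms) < 1L || max(qmAtoms) > n))
    stop("qmAtoms indices out of range")
  qmAtoms
}

.compositeEval <- function(A, B, state, qmAtoms) {
  qmAtoms <- .checkQmAtoms(state, qmAtoms)
  n <- nAtoms(state)
  qmAtom <- logical(n)
  qmAtom[qmAtoms] <- TRUE
  ## whole-molecule flag: TRUE iff every atom of the molecule is in the set
  molAll <- tapply(qmAtom, moleculeId(state), all)
  qmMolAtom <- as.logical(molAll[as.character(moleculeId(state))])
  nb <- nrow(state@bonds)
  na <- nrow(state@angles)
  res <- cpp_pair_forces(
    positions(state), state@cell, state@pbc,
    as.integer(.speciesIndex(state, B)), moleculeId(state),
    qmAtom, qmMolAtom, .paramList(A), .paramList(B),
    state@bonds, rep(A@kBond, nb), rep(A@b0, nb),
    rep(B@kBond, nb), rep(B@b0, nb),
    state@angles, rep(A@kAngle, na), rep(A@theta0, na),
    rep(B@kAngle, na), rep(B@theta0, na))
  if (any(!is.finite(res$forces))) stop("non-finite forces")
  res
}

#' @describeIn evaluateForces Single-model evaluation; `qmAtoms` is validated
#'   but does not affect the result (every interaction uses this model).
#' @export
setMethod("evaluateForces", "PairForceField",
  function(provider, state, qmAtoms = integer(0), label = "extended") {
    .compositeEval(provider, provider, state, qmAtoms)
  })

#' @describeIn evaluateForces Composite two-model evaluation: pairs with both
#'   atoms in `qmAtoms` use model A, all others model B; intramolecular terms
#'   use A iff the whole molecule is inside `qmAtoms`.
#' @export
setMethod("evaluateForces", "CompositeForceField",
  function(provider, state, qmAtoms = integer(0), label = "extended") {
    .compositeEval(provider@modelA, provider@modelB, state, qmAtoms)
  })

#' ExternalDoubleWell: one-dimensional quartic double-well potential
#'
#' External potential `U(x) = a ((x - center)^2 - w^2)^2` acting on one
#' Cartesian coordinate of one atom; all other degrees of freedom are free.
#' Used for end-to-end validation of the umbrella-integration machinery
#' against exact quadrature.
#'
#' @slot atom Atom index the potential acts on.
#' @slot axis Cartesian axis (1-3).
#' @slot a Quartic amplitude (kcal/mol); the barrier between the wells equals `a * w^4`.
#' @slot center Position of the barrier top (A).
#' @slot width Half-separation `w` of the two minima (A).
#' @export
setClass("ExternalDoubleWell",
  contains = "ForceProvider",
  representation(atom = "integer", axis = "integer", a = "numeric",
                 center = "numeric", width = "numeric")
)

#' @rdname ExternalDoubleWell-class
#' @param atom,axis,a,center,width See slots.
#' @export
externalDoubleWell <- function(atom = 1L, axis = 1L, a = 5, center = 0,
                               width = 1) {
  new("ExternalDoubleWell", atom = as.integer(atom), axis = as.integer(axis),
      a = a, center = center, width = width)
}

#' @describeIn evaluateForces Double-well external potential on a single
#'   coordinate.
#' @export
setMethod("evaluateForces", "ExternalDoubleWell",
  function(provider, state, qmAtoms = integer(0), label = "extended") {
    .checkQmAtoms(state, qmAtoms)
    f <- matrix(0, nAtoms(state), 3L)
    x <- positions(state)[provider@atom, provider@axis] - provider@center
    u <- provider@a * (x^2 - provider@width^2)^2
    f[provider@atom, provider@axis] <-
      -4 * provider@a * x * (x^2 - provider@width^2)
    list(forces = f, energy = u)
  })
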