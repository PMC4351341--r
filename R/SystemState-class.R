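#' SystemState: atoms in a periodic orthorhombic cell
#'
#' Central container for the simulation state: positions (Angstrom),
#' velocities (Angstrom/fs), masses (amu), element symbols, per-atom molecule
#' identifiers, orthorhombic cell edge lengths (Angstrom) and periodicity
#' flags. Optional bond and angle index tables carry the intramolecular
#' topology used by the pair force fields; molecules are the only topology
#' concept beyond that.
#'
#' @slot positions n x 3 numeric matrix (Angstrom).
#' @slot velocities n x 3 numeric matrix (Angstrom/fs).
#' @slot masses Numeric vector of length n, all > 0 (amu).
#' @slot species Character vector of element symbols, length n.
#' @slot moleculeId Integer vector, length n; partitions atoms into molecules.
#' @slot cell Numeric length-3 vector of edge lengths (Angstrom).
#' @slot pbc Logical length-3 vector; edge must be > 0 where TRUE.
#' @slot bonds Integer matrix (m x 2) of bonded atom index pairs (may have 0 rows).
#' @slot angles Integer matrix (m x 3) of angle triplets i-j-k with j the apex.
#'
#' @export
setClass("SystemState",
  representation(
    positions = "matrix",
    velocities = "matrix",
    masses = "numeric",
    species = "character",
    moleculeId = "integer",
    cell = "numeric",
    pbc = "logical",
    bonds = "matrix",
    angles = "matrix"
  )
)

setValidity("SystemState", function(object) {
  n <- nrow(object@positions)
  msgs <- character(0)
  if (ncol(object@positions) != 3L) msgs <- c(msgs, "positions must have 3 columns")
  if (!all(dim(object@velocities) == c(n, 3L)))
    msgs <- c(msgs, "velocities must match positions dimensions")
  if (length(object@masses) != n) msgs <- c(msgs, "masses length mismatch")
  if (any(!is.finite(object@masses)) || any(object@masses <= 0))
    msgs <- c(msgs, "all masses must be positive and finite")
  if (length(object@species) != n) msgs <- c(msgs, "species length mismatch")
  if (length(object@moleculeId) != n) msgs <- c(msgs, "moleculeId length mismatch")
  if (length(object@cell) != 3L || length(object@pbc) != 3L)
    msgs <- c(msgs, "cell and pbc must have length 3")
  if (any(object@pbc & !(object@cell > 0)))
    msgs <- c(msgs, "cell edges must be > 0 on periodic axes")
  if (any(!is.finite(object@positions)))
    msgs <- c(msgs, "positions must be finite")
  if (nrow(object@bonds) > 0 &&
      (max(object@bonds) > n || min(object@bonds) < 1))
    msgs <- c(msgs, "bond indices out of range")
  if (nrow(object@angles) > 0 &&
      (max(object@angles) > n || min(object@angles) < 1))
    msgs <- c(msgs, "angle indices out of range")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SystemState
#'
#' @param positions n x 3 matrix (Angstrom).
#' @param velocities n x 3 matrix (Angstrom/fs); defaults to zeros.
#' @param masses Numeric vector (amu).
#' @param species Character vector of element symbols.
#' @param moleculeId Integer vector of molecule identifiers.
#' @param cell Length-3 numeric cell edges (Angstrom).
#' @param pbc Length-3 logical periodicity flags.
#' @param bonds Integer matrix (m x 2) of intramolecular bonds.
#' @param angles Integer matrix (m x 3) of intramolecular angles (apex second).
#' @return A [SystemState].
#' @examples
#' st <- systemState(matrix(0, 1, 3), masses = 16, species = "O",
#'                   moleculeId = 1L, cell = c(10, 10, 10))
#' nAtoms(st)
#' @export
systemState <- function(positions, velocities = NULL, masses, species,
                        moleculeId, cell, pbc = c(TRUE, TRUE, TRUE),
                        bonds = NULL, angles = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3L)
  velocities <- as.matrix(velocities)
  storage.mode(velocities) <- "double"
  if (is.null(bonds)) bonds <- matrix(integer(0), 0L, 2L)
  if (is.null(angles)) angles <- matrix(integer(0), 0L, 3L)
  bonds <- as.matrix(bonds); storage.mode(bonds) <- "integer"
  angles <- as.matrix(angles); storage.mode(angles) <- "integer"
  new("SystemState",
      positions = positions, velocities = velocities,
      masses = as.numeric(masses), species = as.character(species),
      moleculeId = as.integer(moleculeId), cell = as.numeric(cell),
      pbc = as.logical(pbc), bonds = bonds, angles = angles)
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SystemState", function(x) nrow(x@positions))

#' @rdname positions
#' @export
setMethod("positions", "SystemState", function(x) x@positions)

#' @rdname positions
#' @export
setMethod("positions<-", "SystemState", function(x, value) {
  x@positions <- value
  validObject(x)
  x
})

#' @rdname velocities
#' @export
setMethod("velocities", "SystemState", function(x) x@velocities)

#' @rdname velocities
#' @export
setMethod("velocities<-", "SystemState", function(x, value) {
  x@velocities <- value
  validObject(x)
  x
})

#' @rdname masses
#' @export
setMethod("masses", "SystemState", function(x) x@masses)

#' @rdname species
#' @export
setMethod("species", "SystemState", function(x) x@species)

#' @rdname moleculeId
#' @export
setMethod("moleculeId", "SystemState", function(x) x@moleculeId)

setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d atoms, %d molecules\n",
              nAtoms(object), length(unique(object@moleculeId))))
  cat(sprintf("  cell: %.3f x %.3f x %.3f A  pbc: %s\n",
              object@cell[1], object@cell[2], object@cell[3],
              paste(ifelse(object@pbc, "T", "F"), collapse = "")))
  cat(sprintf("  species: %s\n",
              paste(sprintf("%s:%d", names(table(object@species)),
                            table(object@species)), collapse = " ")))
  invisible(object)
})

#' Minimum-image distance between two points
#'
#' Shortest distance between `a` and `b` over all periodic images of an
#' orthorhombic cell. Non-periodic axes use the plain coordinate difference.
#'
#' @param a,b Length-3 numeric positions (Angstrom).
#' @param cell Length-3 cell edges (Angstrom).
#' @param pbc Length-3 logical flags.
#' @return Scalar distance (Angstrom).
#' @examples
#' minimumImageDistance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10))
#' @export
minimumImageDistance <- function(a, b, cell, pbc = c(TRUE, TRUE, TRUE)) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite coordinates")
  if (any(pbc & !(cell > 0))) stop("cell edges must be > 0 on periodic axes")
  d <- a - b
  w <- pbc & cell > 0
  d[w] <- d[w] - cell[w] * round(d[w] / cell[w])
  sqrt(sum(d * d))
}

#' Minimum-image distances between two sets of points
#'
#' @param X n x 3 matrix of positions.
#' @param Y m x 3 matrix of positions.
#' @param cell,pbc As in [minimumImageDistance()].
#' @return n x m matrix of distances.
#' @export
minimumImageCrossDist <- function(X, Y, cell, pbc = c(TRUE, TRUE, TRUE)) {
  X <- rbind(X); Y <- rbind(Y)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite coordinates")
  cpp_cross_dist(X, Y, as.numeric(cell), as.logical(pbc))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each Cartesian component is drawn from N(0, kB T / m) in internal units.
#'
#' @param masses Per-atom masses (amu).
#' @param temperature Target temperature (K).
#' @return n x 3 velocity matrix (A/fs).
#' @export
maxwellBoltzmannVelocities <- function(masses, temperature) {
  n <- length(masses)
  sdv <- sqrt(.kB * temperature * .acc / masses)
  matrix(rnorm(3L * n), n, 3L) * sdv
}

#' Instantaneous kinetic temperature
#'
#' Returns `sum(m v^2) / (N_dof kB)` in Kelvin, or the per-DOF array
#' `m v^2 / kB` when `perDof = TRUE`.
#'
#' @param state A [SystemState], or an n x 3 velocity matrix if `m` is given.
#' @param perDof Logical; return one temperature per Cartesian DOF.
#' @param m Masses, required when `state` is a velocity matrix.
#' @return Scalar temperature (K) or n x 3 matrix.
#' @export
kineticTemperature <- function(state, perDof = FALSE, m = NULL) {
  if (is(state, "SystemState")) {
    v <- state@velocities
    m <- state@masses
  } else {
    v <- state
    if (is.null(m)) stop("masses required")
  }
  if (any(m <= 0)) stop("masses must be positive")
  tdof <- (m * v * v) / (.kB * .acc)
  if (perDof) tdof else sum(tdof) / length(tdof)
}

## wrap positions into the primary cell (used for output only; dynamics keep
## unwrapped coordinates)
wrapPositions <- function(pos, cell, pbc) {
  for (k in 1:3) {
    if (pbc[k] && cell[k] > 0) pos[, k] <- pos[, k] %% cell[k]
  }
  pos
}
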