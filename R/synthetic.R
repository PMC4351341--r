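## Default number density of the water-like liquid (molecules / A^3).
## A 93-molecule cubic box of edge 13.8 A at the real water O-O peak (~2.8 A)
## rescaled to the toy model's rmin = 3.2 A gives edge 15.8 A, i.e. 0.0237.
.DEFAULT_DENSITY <- 0.0237

## water-like molecule template in its rest geometry (O at origin)
.waterTemplate <- function(b0 = 1.0, theta0 = 104.52 * pi / 180) {
  h <- theta0 / 2
  list(species = c("O", "H", "H"),
       positions = rbind(c(0, 0, 0),
                         b0 * c(sin(h), cos(h), 0),
                         b0 * c(-sin(h), cos(h), 0)),
       masses = c(16, 1, 1),
       bonds = rbind(c(1L, 2L), c(1L, 3L)),
       angles = rbind(c(2L, 1L, 3L)))
}

## random rotation matrix (uniform over SO(3) via QR of a Gaussian matrix)
.randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q * sign(diag(qr.R(qr_)))[col(Q)]
}

#' Build a water-like box
#'
#' Places `nMolecules` water-like molecules (1 heavy + 2 light atoms, rest
#' geometry) on a jittered cubic lattice with random orientations, draws
#' Maxwell-Boltzmann velocities at the target temperature, and runs a short
#' capped steepest-descent overlap-removal relaxation under the given model.
#' Reproducible for a fixed seed. Errors if, after bounded retries, any
#' intermolecular heavy-atom pair remains closer than 0.8 x the model's
#' heavy-heavy equilibrium distance.
#'
#' @param nMolecules Number of molecules.
#' @param edge Cubic box edge (A); default from `density`.
#' @param density Number density (molecules / A^3) used when `edge` is NULL;
#'   default 0.0237 (a 93-molecule box of edge 15.8 A).
#' @param temperature Velocity-draw temperature (K).
#' @param seed Integer seed (set at entry).
#' @param model [PairForceField-class] used for the relaxation (default the
#'   water-like MM model).
#' @param relaxSteps Steepest-descent iterations (0 disables).
#' @return A [SystemState] with bonds/angles topology.
#' @examples
#' st <- buildWaterBox(8, seed = 1)
#' nAtoms(st)
#' @export
buildWaterBox <- function(nMolecules, edge = NULL, density = .DEFAULT_DENSITY,
                          temperature = 300, seed = NULL,
                          model = defaultWaterLikeModel(), relaxSteps = 200L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(edge)) edge <- (nMolecules / density)^(1 / 3)
  tpl <- .waterTemplate(model@b0, model@theta0)
  ## lattice sites
  nside <- ceiling(nMolecules^(1 / 3))
  spacing <- edge / nside
  rminOO <- model@rmin[match("O", model@speciesTable),
                       match("O", model@speciesTable)]
  if (spacing < 0.8 * rminOO * 0.9)
    stop("infeasible packing: density above the hard-sphere limit")
  grid <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                                z = seq_len(nside)))
  sites <- (grid - 0.5) * spacing
  sites <- sites[sample.int(nrow(sites), nMolecules), , drop = FALSE]
  sites <- sites + matrix(rnorm(3 * nMolecules, sd = 0.05 * spacing),
                          ncol = 3)
  natm <- 3L * nMolecules
  pos <- matrix(0, natm, 3L)
  bonds <- matrix(0L, 2L * nMolecules, 2L)
  angles <- matrix(0L, nMolecules, 3L)
  for (i in seq_len(nMolecules)) {
    R <- .randomRotation()
    rows <- (i - 1L) * 3L + 1:3
    pos[rows, ] <- tpl$positions %*% t(R) +
      matrix(sites[i, ], 3L, 3L, byrow = TRUE)
    bonds[(i - 1L) * 2L + 1:2, ] <- tpl$bonds + (i - 1L) * 3L
    angles[i, ] <- tpl$angles + (i - 1L) * 3L
  }
  state <- systemState(
    positions = pos,
    masses = rep(tpl$masses, nMolecules),
    species = rep(tpl$species, nMolecules),
    moleculeId = rep(seq_len(nMolecules), each = 3L),
    cell = rep(edge, 3L), bonds = bonds, angles = angles)
  if (relaxSteps > 0L) state <- .relax(state, model, relaxSteps)
  state@velocities <- maxwellBoltzmannVelocities(masses(state), temperature)
  .checkPacking(state, 0.8 * rminOO)
  state
}

## capped steepest descent under a single model
.relax <- function(state, model, nSteps, cap = 0.1, alpha = 5e-4) {
  for (i in seq_len(nSteps)) {
    f <- evaluateForces(model, state)$forces
    d <- f * alpha
    nd <- sqrt(rowSums(d * d))
    over <- nd > cap
    if (any(over)) d[over, ] <- d[over, ] * (cap / nd[over])
    state@positions <- state@positions + d
  }
  state
}

.checkPacking <- function(state, dmin, retriesDone = TRUE) {
  heavy <- which(species(state) == "O")
  if (length(heavy) < 2L) return(invisible(TRUE))
  D <- minimumImageCrossDist(positions(state)[heavy, , drop = FALSE],
                             positions(state)[heavy, , drop = FALSE],
                             state@cell, state@pbc)
  diag(D) <- Inf
  if (min(D) < dmin)
    stop(sprintf("packing failure: closest heavy-atom pair at %.2f A < %.2f A",
                 min(D), dmin))
  invisible(TRUE)
}

#' Embed a solute into a solvent box
#'
#' Removes every solvent molecule with any atom closer than `rExclude` to any
#' solute atom, then inserts the solute atoms with a fresh molecule id. The
#' returned state carries the solute atom indices in attribute `fixedCore`
#' (the natural fixed core list).
#'
#' @param box A [SystemState] solvent box.
#' @param template Solute template: list with `species`, `positions` (n x 3,
#'   relative), `masses`, optional `bonds`, `angles`.
#' @param position Length-3 insertion point (inside the cell).
#' @param rExclude Overlap removal radius (A), default 2.6.
#' @return A [SystemState] with attribute `fixedCore`.
#' @export
embedSolute <- function(box, template, position, rExclude = 2.6) {
  if (any(position < 0) || any(position > box@cell))
    stop("position must lie inside the cell")
  solPos <- template$positions +
    matrix(position, nrow(template$positions), 3L, byrow = TRUE)
  if (any(apply(template$positions, 2L, function(x) diff(range(x))) >
          box@cell))
    stop("solute larger than the cell")
  keepAtoms <- rep(TRUE, nAtoms(box))
  if (nAtoms(box) > 0L) {
    D <- minimumImageCrossDist(positions(box), solPos, box@cell, box@pbc)
    tooClose <- apply(D, 1L, min) < rExclude
    dropMol <- unique(moleculeId(box)[tooClose])
    keepAtoms <- !(moleculeId(box) %in% dropMol)
  }
  oldPos <- positions(box)[keepAtoms, , drop = FALSE]
  oldMol <- moleculeId(box)[keepAtoms]
  ## re-index kept molecules compactly
  oldMol <- as.integer(factor(oldMol))
  keepIdx <- which(keepAtoms)
  remap <- match(seq_len(nAtoms(box)), keepIdx)
  oldBonds <- box@bonds[keepAtoms[box@bonds[, 1L]] &
                        keepAtoms[box@bonds[, 2L]], , drop = FALSE]
  oldBonds <- matrix(remap[oldBonds], ncol = 2L)
  oldAngles <- box@angles[keepAtoms[box@angles[, 1L]] &
                          keepAtoms[box@angles[, 2L]] &
                          keepAtoms[box@angles[, 3L]], , drop = FALSE]
  oldAngles <- matrix(remap[oldAngles], ncol = 3L)
  nOld <- nrow(oldPos)
  nSol <- nrow(solPos)
  solBonds <- if (is.null(template$bonds)) matrix(integer(0), 0L, 2L)
              else template$bonds + nOld
  solAngles <- if (is.null(template$angles)) matrix(integer(0), 0L, 3L)
               else template$angles + nOld
  st <- systemState(
    positions = rbind(oldPos, solPos),
    velocities = rbind(velocities(box)[keepAtoms, , drop = FALSE],
                       matrix(0, nSol, 3L)),
    masses = c(masses(box)[keepAtoms], template$masses),
    species = c(species(box)[keepAtoms], template$species),
    moleculeId = c(oldMol, rep(max(oldMol, 0L) + 1L, nSol)),
    cell = box@cell, pbc = box@pbc,
    bonds = rbind(oldBonds, solBonds),
    angles = rbind(oldAngles, solAngles))
  attr(st, "fixedCore") <- nOld + seq_len(nSol)
  st
}
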