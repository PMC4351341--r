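## frames argument: a trajectory list from runMD() or a bare list of states
.asFrames <- function(trajectory) {
  if (is.list(trajectory) && !is.null(trajectory$frames)) trajectory$frames
  else trajectory
}

#' Radial distribution function around a designated center
#'
#' Computes the RDF g(r) of partner atoms around one center atom (typically
#' the heavy atom of the central molecule of the dynamical QM region, the
#' quantity under test in buffered force-mixing validation), averaged over
#' frames. Normalization uses the ideal-gas shell density of the partner
#' species; the cumulative neighbor count `N_cum` is computed by direct
#' counting per frame and then averaged, not by integrating g (which is noisy
#' in sparse bins).
#'
#' @param trajectory A [runMD()] trajectory or list of [SystemState] frames.
#' @param centerAtom Atom index of the center.
#' @param partnerSpecies Element symbol of partner atoms (e.g. "O").
#' @param rMax Maximum radius (A); must not exceed half the smallest periodic
#'   cell edge.
#' @param dr Bin width (A), > 0.
#' @return data.frame (`RDFResult`) with `r` (bin centers), `g`, `ncum`;
#'   attribute `framesUsed`.
#' @export
rdf <- function(trajectory, centerAtom, partnerSpecies = "O", rMax = NULL,
                dr = 0.1) {
  frames <- .asFrames(trajectory)
  if (!length(frames)) stop("no frames")
  st1 <- frames[[1L]]
  halfmin <- min(st1@cell[st1@pbc]) / 2
  if (is.null(rMax)) rMax <- halfmin
  if (rMax > halfmin + 1e-9) stop("rMax exceeds half the smallest cell edge")
  if (dr <= 0) stop("dr must be > 0")
  breaks <- seq(0, rMax, by = dr)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  ncum <- numeric(nb)
  vol <- prod(st1@cell)
  partners <- setdiff(which(species(st1) == partnerSpecies), centerAtom)
  rho <- length(partners) / vol
  for (st in frames) {
    D <- minimumImageCrossDist(positions(st)[centerAtom, , drop = FALSE],
                               positions(st)[partners, , drop = FALSE],
                               st@cell, st@pbc)
    d <- D[1L, ]
    h <- hist(d[d < rMax], breaks = breaks, plot = FALSE)$counts
    counts <- counts + h
    ncum <- ncum + cumsum(h)
  }
  nf <- length(frames)
  shellVol <- 4 / 3 * pi * diff(breaks^3)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  out <- data.frame(r = centers,
                    g = counts / nf / (shellVol * rho),
                    ncum = ncum / nf)
  attr(out, "framesUsed") <- nf
  out
}

#' QM-atom-count trace and membership-switch statistics
#'
#' Re-labels a stored trajectory sequentially under a [RegionSpec-class]
#' (hysteresis memory carried frame to frame), returning the extended-QM atom
#' count per frame and the total number of per-molecule (or per-atom, if the
#' spec does not use whole molecules) region-membership changes between
#' consecutive frames. Re-labelling a trajectory under modified radii (e.g.
#' the averaged inner/outer radius) quantifies how much hysteresis suppresses
#' region flicker.
#'
#' @param trajectory A [runMD()] trajectory or list of [SystemState] frames.
#' @param spec A [RegionSpec-class].
#' @return List with `counts` (data.frame: frame, core, dyn_qm, buffer,
#'   extended_qm, mm), `switchEvents` (integer), `labels` (list of
#'   [RegionLabels-class]).
#' @export
qmCountTrace <- function(trajectory, spec) {
  frames <- .asFrames(trajectory)
  if (!length(frames)) stop("empty trajectory")
  labels <- vector("list", length(frames))
  prev <- NULL
  cnt <- matrix(0L, length(frames), 5L)
  switches <- 0L
  prevUnitCodes <- NULL
  for (i in seq_along(frames)) {
    lab <- partitionRegions(frames[[i]], spec, prev)
    labels[[i]] <- lab
    cnt[i, ] <- regionCounts(lab)
    unitCodes <- if (spec@wholeMolecules) {
      as.integer(tapply(lab@codes, moleculeId(frames[[i]]), min))
    } else {
      lab@codes
    }
    if (!is.null(prevUnitCodes)) {
      switches <- switches + sum(unitCodes != prevUnitCodes)
    }
    prevUnitCodes <- unitCodes
    prev <- lab
  }
  counts <- as.data.frame(cnt)
  names(counts) <- c("core", "dyn_qm", "buffer", "extended_qm", "mm")
  counts <- cbind(frame = seq_along(frames), counts)
  list(counts = counts, switchEvents = switches, labels = labels)
}

#' Buffer-size force-convergence scan
#'
#' For each configuration and each buffer radius, computes composite forces
#' with the extended QM set equal to the dynamical QM region plus a
#' (non-hysteretic) buffer of that radius, and reports per-tagged-atom force
#' errors against the evaluation at a large reference radius. This is the
#' protocol used to choose the production buffer size: the buffer radius at
#' which the mean error falls below an acceptable threshold.
#'
#' @param states List of [SystemState] configurations.
#' @param taggedAtoms Atom indices whose forces are compared; must lie in the
#'   dynamical QM region of every configuration.
#' @param rBufferGrid Numeric vector of buffer radii (A).
#' @param rReference Reference radius (A), > max(rBufferGrid).
#' @param A,B [PairForceField-class] models.
#' @param spec [RegionSpec-class] defining the dynamical QM construction
#'   (its `rBuffer` is overridden by the scan).
#' @return data.frame (`ForceScanResult`) with `rBuffer`, `meanError`,
#'   `maxError` (kcal mol^-1 A^-1); attribute `rReference`.
#' @export
bufferConvergenceScan <- function(states, taggedAtoms, rBufferGrid,
                                  rReference, A, B, spec) {
  if (rReference < max(rBufferGrid))
    stop("rReference must be at least max(rBufferGrid)")
  comp <- compositeForceField(A, B)
  extSet <- function(state, rb) {
    sp <- spec
    sp@rBuffer <- c(rb, rb)
    extendedQMAtoms(partitionRegions(state, sp, NULL))
  }
  errs <- array(NA_real_, c(length(states), length(rBufferGrid),
                            length(taggedAtoms)))
  for (s in seq_along(states)) {
    st <- states[[s]]
    dyn <- dynamicalQMAtoms(partitionRegions(st, spec, NULL))
    if (!all(taggedAtoms %in% dyn))
      stop("tagged atom outside the dynamical QM region")
    fRef <- evaluateForces(comp, st, extSet(st, rReference))$forces
    for (b in seq_along(rBufferGrid)) {
      f <- evaluateForces(comp, st, extSet(st, rBufferGrid[b]))$forces
      dfr <- f[taggedAtoms, , drop = FALSE] -
        fRef[taggedAtoms, , drop = FALSE]
      errs[s, b, ] <- sqrt(rowSums(dfr * dfr))
    }
  }
  out <- data.frame(rBuffer = rBufferGrid,
                    meanError = apply(errs, 2L, mean),
                    maxError = apply(errs, 2L, max))
  attr(out, "rReference") <- rReference
  out
}
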