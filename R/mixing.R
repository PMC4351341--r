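#' Momentum correction specification
#'
#' Force mixing breaks Newton's third law across the mixing boundary, leaving
#' a (typically small) net force on the system. The correction removes it
#' exactly by subtracting the net force from the atoms of a chosen region:
#' uniformly (`F_net / N`) or mass-weighted (`(m_i / M) F_net`, which leaves
#' the center-of-mass acceleration correction unbiased toward light atoms).
#'
#' @param mode One of "none", "uniform", "mass_weighted".
#' @param region One of "all", "extended_qm", "dynamical_qm".
#' @return A named list spec.
#' @export
momentumCorrectionSpec <- function(mode = c("mass_weighted", "uniform", "none"),
                                   region = c("all", "extended_qm",
                                              "dynamical_qm")) {
  list(mode = match.arg(mode), region = match.arg(region))
}

#' Abrupt per-atom force mixing
#'
#' Atom i takes the extended-evaluation force if it is in the dynamical QM
#' region (CORE or DYN_QM), and the reduced-evaluation force otherwise
#' (BUFFER or MM). There is no transition region: forces switch from one
#' description to the other abruptly.
#'
#' @param fExtended,fReduced n x 3 force matrices (kcal mol^-1 A^-1) from the
#'   extended and reduced evaluations.
#' @param labels A [RegionLabels-class].
#' @return A list (`MixedForces`) with `forces` (n x 3), `source` (character,
#'   "extended"/"reduced" per atom) and `netForceBeforeCorrection` (3-vector).
#' @export
mixForces <- function(fExtended, fReduced, labels) {
  if (!all(dim(fExtended) == dim(fReduced)))
    stop("extended and reduced force arrays differ in shape")
  if (nrow(fExtended) != length(labels@codes))
    stop("force array length does not match labels")
  ext <- labels@codes <= .R_DYNQM
  f <- fReduced
  f[ext, ] <- fExtended[ext, ]
  list(forces = f,
       source = ifelse(ext, "extended", "reduced"),
       netForceBeforeCorrection = colSums(f))
}

#' Remove the net force from mixed forces
#'
#' @param mixed A `MixedForces` list (from [mixForces()]) or a bare n x 3
#'   force matrix.
#' @param masses Per-atom masses (amu).
#' @param spec A [momentumCorrectionSpec()].
#' @param labels [RegionLabels-class]; required when `spec$region != "all"`.
#' @return The input with `forces` corrected so that `colSums(forces) = 0`
#'   (to machine precision) and the correction applied only inside the chosen
#'   region; `netForceBeforeCorrection` records the pre-correction net force.
#' @export
correctMomentum <- function(mixed, masses, spec = momentumCorrectionSpec(),
                            labels = NULL) {
  bare <- is.matrix(mixed)
  f <- if (bare) mixed else mixed$forces
  if (spec$mode == "none") {
    out <- list(forces = f, netForceBeforeCorrection = colSums(f))
    return(if (bare) out else modifyList(mixed, out))
  }
  idx <- switch(spec$region,
    all = seq_len(nrow(f)),
    extended_qm = {
      if (is.null(labels)) stop("labels required for region-restricted correction")
      extendedQMAtoms(labels)
    },
    dynamical_qm = {
      if (is.null(labels)) stop("labels required for region-restricted correction")
      dynamicalQMAtoms(labels)
    })
  if (length(idx) == 0L) stop("momentum correction region is empty")
  fnet <- colSums(f)
  w <- switch(spec$mode,
    uniform = rep(1 / length(idx), length(idx)),
    mass_weighted = masses[idx] / sum(masses[idx]))
  f[idx, ] <- f[idx, ] - outer(w, fnet)
  ## compensate residual rounding so |sum F| stays at machine precision
  res <- colSums(f)
  f[idx[1L], ] <- f[idx[1L], ] - res
  out <- list(forces = f, netForceBeforeCorrection = fnet)
  if (bare) out else modifyList(mixed, out)
}

.VARIANTS <- c("Conv", "AdConv", "AdUF", "AdBF")

.validateVariantSpec <- function(variant, spec) {
  adaptiveBuffer <- spec@rBuffer[2] > 0 || length(spec@fixedBuffer) > 0
  if (variant == "Conv") {
    if (any(c(spec@rCore[2], spec@rQm[2], spec@rBuffer[2]) > 0))
      stop("Conv variant requires all adaptive radii to be zero")
    if (adaptiveBuffer) stop("Conv variant requires an empty buffer region")
  } else if (variant == "AdConv") {
    if (spec@rQm[2] > 0)
      stop("AdConv variant requires rQm = 0 (core and dynamical QM coincide)")
    if (adaptiveBuffer) stop("AdConv variant requires an empty buffer region")
  } else if (variant == "AdUF") {
    if (adaptiveBuffer) stop("AdUF variant requires an empty buffer region")
  }
  invisible(TRUE)
}

#' One force-assembly step of a method variant
#'
#' Runs the per-step force machinery of the chosen QM/MM method variant:
#' \describe{
#'   \item{Conv}{fixed QM set (the fixed core + fixed QM lists), one
#'     composite evaluation, no mixing.}
#'   \item{AdConv}{adaptive dynamical QM region equal to the core; one
#'     evaluation with that QM set; all atoms take its forces.}
#'   \item{AdUF}{extended QM set = dynamical QM region, reduced QM set =
#'     core (possibly empty, i.e. a pure model-B evaluation); abrupt mixing.}
#'   \item{AdBF}{extended QM set = dynamical QM + buffer, reduced QM set =
#'     core; abrupt mixing.}
#' }
#' Conv and AdConv perform one force evaluation per step, AdUF and AdBF two.
#'
#' @param state A [SystemState].
#' @param spec A [RegionSpec-class] consistent with the variant (validated,
#'   not silently fixed).
#' @param variant One of "Conv", "AdConv", "AdUF", "AdBF".
#' @param A,B [PairForceField-class] models (QM-role and MM-role).
#' @param prev Previous [RegionLabels-class] or NULL.
#' @param momentum A [momentumCorrectionSpec()].
#' @return List with `forces` (n x 3, corrected), `labels`
#'   ([RegionLabels-class]), `source`, `netForceBeforeCorrection`, `nEvals`.
#' @export
runVariantStep <- function(state, spec, variant = .VARIANTS, A, B,
                           prev = NULL,
                           momentum = momentumCorrectionSpec()) {
  variant <- match.arg(variant, .VARIANTS)
  .validateVariantSpec(variant, spec)
  comp <- compositeForceField(A, B)
  labels <- partitionRegions(state, spec, prev)
  if (variant %in% c("Conv", "AdConv")) {
    qm <- if (variant == "Conv") sort(unique(c(spec@fixedCore, spec@fixedQm)))
          else dynamicalQMAtoms(labels)
    ev <- evaluateForces(comp, state, qm, label = "extended")
    mixed <- list(forces = ev$forces,
                  source = rep("extended", nAtoms(state)),
                  netForceBeforeCorrection = colSums(ev$forces))
    nEvals <- 1L
  } else {
    qmExt <- if (variant == "AdBF") extendedQMAtoms(labels)
             else dynamicalQMAtoms(labels)
    fExt <- evaluateForces(comp, state, qmExt, label = "extended")$forces
    fRed <- evaluateForces(comp, state, coreAtoms(labels),
                           label = "reduced")$forces
    mixed <- mixForces(fExt, fRed, labels)
    nEvals <- 2L
  }
  mixed <- correctMomentum(mixed, masses(state), momentum, labels)
  mixed$labels <- labels
  mixed$nEvals <- nEvals
  mixed
}
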