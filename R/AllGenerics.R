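#' Evaluate forces for a system under a force provider
#'
#' Dispatches on the force provider. A provider maps a [SystemState] and a set
#' of "QM" atom indices to per-atom forces (kcal mol^-1 A^-1) and, for
#' conservative providers with a fixed QM set, a potential energy
#' (kcal mol^-1).
#'
#' @param provider A [ForceProvider-class] object.
#' @param state A [SystemState].
#' @param qmAtoms Integer vector of atom indices treated with the "QM" model
#'   (model A). May be empty for a pure model-B (MM) evaluation. Providers
#'   that are not composite validate but ignore it.
#' @param label Free-text tag for the evaluation ("extended" or "reduced").
#' @return A list with elements `forces` (n x 3 matrix) and `energy` (scalar).
#' @export
setGeneric("evaluateForces", function(provider, state, qmAtoms = integer(0),
                                      label = "extended") {
  standardGeneric("evaluateForces")
})

#' Number of atoms in an object
#' @param x Object with atoms.
#' @return Integer count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atomic positions accessor
#' @param x A [SystemState].
#' @return n x 3 numeric matrix (Angstrom).
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname positions
#' @param value Replacement n x 3 matrix.
#' @export
setGeneric("positions<-", function(x, value) standardGeneric("positions<-"))

#' Atomic velocities accessor
#' @param x A [SystemState].
#' @return n x 3 numeric matrix (Angstrom/fs).
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))

#' @rdname velocities
#' @param value Replacement n x 3 matrix.
#' @export
setGeneric("velocities<-", function(x, value) standardGeneric("velocities<-"))

#' Per-atom masses accessor
#' @param x A [SystemState].
#' @return Numeric vector (amu).
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' Per-atom element symbols accessor
#' @param x A [SystemState].
#' @return Character vector.
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' Per-atom molecule identifiers accessor
#' @param x A [SystemState].
#' @return Integer vector.
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))

#' Region label codes accessor
#' @param x A [RegionLabels-class] object.
#' @return Character vector with values CORE, DYN_QM, BUFFER, MM.
#' @export
setGeneric("regionOf", function(x) standardGeneric("regionOf"))

#' Advance thermostat internal variables and velocities by one coupling phase
#'
#' Applied once per MD step between the two half force kicks of the symmetric
#' splitting; integrates the thermostat variables and the
#' friction/noise action on the velocities over a full `dt`.
#'
#' @param th Thermostat object.
#' @param v n x 3 velocity matrix (A/fs).
#' @param m Per-atom masses (amu).
#' @param dt Time step (fs).
#' @return List with updated `v` and `th`.
#' @export
setGeneric("thermostatPhase", function(th, v, m, dt) {
  standardGeneric("thermostatPhase")
})
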