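#' Adaptive Langevin thermostat (massive coupling)
#'
#' A Langevin thermostat (for ergodicity) in parallel with a Nose-Hoover
#' thermostat (to absorb the net heat produced by nonconservative mixed
#' forces), coupled independently to each Cartesian degree of freedom.
#' Per DOF the dynamics are
#' \deqn{dq = (p/m) dt, \quad
#'       dp = F dt - (\chi + \gamma) p dt + \sqrt{2 \gamma m k_B T} dW, \quad
#'       d\chi = (p^2/m - k_B T)/Q \, dt}
#' with friction `gamma = 1/tauLangevin` and fictitious mass
#' `Q = kB T tauNH^2` (one DOF per thermostat). With `gamma = 0` this reduces
#' to a pure (per-DOF) Nose-Hoover thermostat; with the chi coupling removed
#' it is a plain Langevin thermostat. The discretization is a symmetric
#' splitting with the Ornstein-Uhlenbeck part integrated exactly and the chi
#' coupling by midpoint halves, so there is no dt-dependent temperature bias
#' from the noise integration.
#'
#' @slot temperature Target temperature (K).
#' @slot tauLangevin Langevin time constant (fs); `Inf` disables the noise.
#' @slot tauNH Nose-Hoover time constant (fs), > 0.
#' @slot chi Per-DOF Nose-Hoover variables (n x 3 matrix, fs^-1).
#' @slot freezeChi Diagnostic switch: hold chi at its current value.
#' @export
setClass("AdLangevinThermostat",
  representation(temperature = "numeric", tauLangevin = "numeric",
                 tauNH = "numeric", chi = "matrix", freezeChi = "logical"))

setValidity("AdLangevinThermostat", function(object) {
  if (object@tauNH <= 0) return("tauNH must be > 0")
  if (object@tauLangevin <= 0) return("tauLangevin must be > 0 (use Inf for no noise)")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

#' Construct an adaptive Langevin thermostat
#'
#' The default time constants `tauLangevin = tauNH = 200 fs` are the named
#' preset used for the proton-transfer simulations; a second preset
#' (`tauLangevin = 300`, `tauNH = 74` fs) matches the phosphate-hydrolysis
#' protocol and is available via `preset = "hydrolysis"`.
#'
#' @param nAtoms Number of atoms (one chi per Cartesian DOF).
#' @param temperature Target temperature (K).
#' @param tauLangevin,tauNH Time constants (fs).
#' @param preset Optional preset name: "autoprotolysis" (200/200) or
#'   "hydrolysis" (300/74); overrides the tau arguments.
#' @param freezeChi Diagnostic: disable the adaptive (NH) response.
#' @return An [AdLangevinThermostat-class].
#' @export
adLangevinThermostat <- function(nAtoms, temperature = 300,
                                 tauLangevin = 200, tauNH = 200,
                                 preset = NULL, freezeChi = FALSE) {
  if (!is.null(preset)) {
    p <- match.arg(preset, c("autoprotolysis", "hydrolysis"))
    if (p == "autoprotolysis") { tauLangevin <- 200; tauNH <- 200 }
    else { tauLangevin <- 300; tauNH <- 74 }
  }
  new("AdLangevinThermostat", temperature = temperature,
      tauLangevin = tauLangevin, tauNH = tauNH,
      chi = matrix(0, nAtoms, 3L), freezeChi = freezeChi)
}

setMethod("show", "AdLangevinThermostat", function(object) {
  cat(sprintf(
    "AdLangevinThermostat: T=%g K tauL=%g fs tauNH=%g fs (%d DOFs, massive)\n",
    object@temperature, object@tauLangevin, object@tauNH,
    length(object@chi)))
  invisible(object)
})

#' @rdname thermostatPhase
#' @export
setMethod("thermostatPhase", "AdLangevinThermostat", function(th, v, m, dt) {
  gamma <- if (is.finite(th@tauLangevin)) 1 / th@tauLangevin else 0
  kBT <- .kB * th@temperature
  Q <- kBT * th@tauNH^2
  res <- cpp_adl_phase(as.vector(v), as.vector(th@chi), rep(m, 3L),
                       dt, gamma, Q, kBT, th@freezeChi)
  th@chi <- matrix(res$chi, nrow(v), 3L)
  list(v = matrix(res$v, nrow(v), 3L), th = th)
})

#' Adaptive Nose-Hoover-chains-Langevin thermostat (massive coupling)
#'
#' The Langevin part of the adaptive Langevin thermostat is replaced by a
#' Nose-Hoover chain of length `r`, with optional Langevin thermalization
#' (friction `gammaL`) of the last chain variable. `r = 1` gives the adaptive
#' Nose-Hoover-Langevin thermostat; `gammaL = 0` with `r > 1` the adaptive
#' Nose-Hoover chain. Chain masses are `Q_i = kB T tauNH^2`. Coupling is per
#' Cartesian DOF.
#'
#' @slot temperature Target temperature (K).
#' @slot tauNH Chain time constant (fs).
#' @slot gammaL Terminal Langevin friction (fs^-1), >= 0.
#' @slot r Chain length, >= 1.
#' @slot xi (3 n) x r matrix of chain variables (fs^-1).
#' @export
setClass("AdNHCLThermostat",
  representation(temperature = "numeric", tauNH = "numeric",
                 gammaL = "numeric", r = "integer", xi = "matrix"))

setValidity("AdNHCLThermostat", function(object) {
  if (object@r < 1L) return("chain length r must be >= 1")
  if (object@gammaL < 0) return("gammaL must be >= 0")
  if (object@tauNH <= 0) return("tauNH must be > 0")
  if (ncol(object@xi) != object@r) return("xi must have r columns")
  TRUE
})

#' Construct an adaptive NHC-Langevin thermostat
#'
#' @param nAtoms Number of atoms.
#' @param temperature Target temperature (K).
#' @param tauNH Chain time constant (fs).
#' @param chainLength Chain length r >= 1.
#' @param gammaL Terminal Langevin friction (fs^-1).
#' @return An [AdNHCLThermostat-class].
#' @export
adNHCLThermostat <- function(nAtoms, temperature = 300, tauNH = 200,
                             chainLength = 3L, gammaL = 1 / 200) {
  new("AdNHCLThermostat", temperature = temperature, tauNH = tauNH,
      gammaL = gammaL, r = as.integer(chainLength),
      xi = matrix(0, 3L * nAtoms, as.integer(chainLength)))
}

setMethod("show", "AdNHCLThermostat", function(object) {
  cat(sprintf(
    "AdNHCLThermostat: T=%g K tauNH=%g fs r=%d gammaL=%g fs^-1 (%d DOFs)\n",
    object@temperature, object@tauNH, object@r, object@gammaL,
    nrow(object@xi)))
  invisible(object)
})

#' @rdname thermostatPhase
#' @export
setMethod("thermostatPhase", "AdNHCLThermostat", function(th, v, m, dt) {
  kBT <- .kB * th@temperature
  Q <- kBT * th@tauNH^2
  res <- cpp_nhcl_phase(as.vector(v), th@xi, rep(m, 3L), dt, th@gammaL, Q,
                        kBT)
  th@xi <- res$xi
  list(v = matrix(res$v, nrow(v), 3L), th = th)
})

## NULL thermostat: plain velocity Verlet (used for conservation checks)
setClassUnion("ThermostatOrNULL", c("AdLangevinThermostat", "AdNHCLThermostat",
                                    "NULL"))

#' Long-run adaptive-Langevin sampling of independent harmonic oscillators
#'
#' C-level driver using the same per-step splitting as the MD loop, for
#' stationary-statistics checks (canonical sampling, heat compensation) at
#' millions of steps. An optional per-step stochastic stirring kick of known
#' standard deviation injects heat at a constant rate; `freezeChi` disables
#' the adaptive compensation for comparison.
#'
#' @param nSteps Number of steps.
#' @param dt Time step (fs).
#' @param m,omega Per-oscillator mass (amu) and angular frequency (fs^-1).
#' @param temperature Target temperature (K).
#' @param tauLangevin,tauNH Thermostat time constants (fs).
#' @param q0,v0 Initial positions/velocities (defaults: 0).
#' @param stirSd Stirring kick sd per step (A/fs), 0 for none.
#' @param freezeChi Hold chi at zero.
#' @param sampleEvery Record q of the first oscillator every so many steps.
#' @return List with per-DOF `meanQ2`, `meanV2`, `meanChi`, the recorded
#'   `qSamples`, and final state.
#' @export
harmonicAdLangevinRun <- function(nSteps, dt, m, omega, temperature = 300,
                                  tauLangevin = 200, tauNH = 200,
                                  q0 = NULL, v0 = NULL, stirSd = 0,
                                  freezeChi = FALSE, sampleEvery = 0) {
  nd <- max(length(m), length(omega))
  m <- rep_len(m, nd); omega <- rep_len(omega, nd)
  if (is.null(q0)) q0 <- numeric(nd)
  if (is.null(v0)) v0 <- numeric(nd)
  gamma <- if (is.finite(tauLangevin)) 1 / tauLangevin else 0
  cpp_harmonic_adl_run(as.integer(nSteps), dt, m, omega, gamma, tauNH,
                       temperature, q0, v0, stirSd, freezeChi,
                       as.integer(sampleEvery))
}

#' Long-run NHC-Langevin sampling of independent harmonic oscillators
#'
#' @inheritParams harmonicAdLangevinRun
#' @param chainLength Chain length r.
#' @param gammaL Terminal Langevin friction (fs^-1).
#' @return List with per-DOF `meanQ2`, `meanV2`, the extended-system
#'   `invariant` series (meaningful for `gammaL = 0`), and final state.
#' @export
harmonicNHCLRun <- function(nSteps, dt, m, omega, temperature = 300,
                            chainLength = 3L, gammaL = 1 / 200, tauNH = 200,
                            q0 = NULL, v0 = NULL, sampleEvery = 0) {
  nd <- max(length(m), length(omega))
  m <- rep_len(m, nd); omega <- rep_len(omega, nd)
  if (is.null(q0)) q0 <- numeric(nd)
  ## a zero-velocity state is invariant under pure chain scaling (the noise
  ## enters only through the terminal chain variable), so default initial
  ## velocities are Maxwell-Boltzmann
  if (is.null(v0)) v0 <- rnorm(nd, sd = sqrt(.kB * temperature * .acc / m))
  if (chainLength < 1L) stop("chain length r must be >= 1")
  cpp_harmonic_nhcl_run(as.integer(nSteps), dt, m, omega,
                        as.integer(chainLength), gammaL, tauNH, temperature,
                        q0, v0, as.integer(sampleEvery))
}
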