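#' Read a simulation configuration from a YAML file
#'
#' Maps a plain-text config onto [simulationConfig()]. Recognized keys (all
#' optional unless noted): `dt`, `n_steps`, `variant` (Conv | AdConv | AdUF |
#' AdBF | MD), `seed`, `output_every`, `region_update_every`;
#' `model: {preset: default_water_like, delta: <mismatch>}`;
#' `regions: {fixed_core, fixed_qm, fixed_buffer, r_core: [in, out], r_qm,
#' r_buffer, species_filter, whole_molecules, seed_is_only_fixed_core,
#' max_extended_atoms}`;
#' `thermostat: {type: ad_langevin | ad_nhl | ad_nhc | ad_nhcl, temperature,
#' tau_langevin, tau_nh, chain_length}`;
#' `momentum: {mode, region}`;
#' `restraints:` a list of restraint specs (kind, atoms, threshold, k, side).
#'
#' @param file Path to the YAML file.
#' @param nAtoms Atom count of the system the config will run (needed to size
#'   the per-DOF thermostat state).
#' @return A [simulationConfig()] list.
#' @export
readSimulationConfig <- function(file, nAtoms) {
  y <- yaml::read_yaml(file)
  delta <- if (!is.null(y$model$delta)) y$model$delta else 0
  mp <- makeModelPair(delta)
  rs <- y$regions
  spec <- regionSpec(
    fixedCore = if (is.null(rs$fixed_core)) integer(0) else rs$fixed_core,
    fixedQm = if (is.null(rs$fixed_qm)) integer(0) else rs$fixed_qm,
    fixedBuffer = if (is.null(rs$fixed_buffer)) integer(0)
                  else rs$fixed_buffer,
    rCore = if (is.null(rs$r_core)) c(0, 0) else unlist(rs$r_core),
    rQm = if (is.null(rs$r_qm)) c(0, 0) else unlist(rs$r_qm),
    rBuffer = if (is.null(rs$r_buffer)) c(0, 0) else unlist(rs$r_buffer),
    selectionSpeciesFilter = if (is.null(rs$species_filter)) character(0)
                             else rs$species_filter,
    wholeMolecules = if (is.null(rs$whole_molecules)) TRUE
                     else rs$whole_molecules,
    seedIsOnlyFixedCore = isTRUE(rs$seed_is_only_fixed_core),
    maxExtendedAtoms = if (is.null(rs$max_extended_atoms))
      .Machine$integer.max else rs$max_extended_atoms)
  tcfg <- y$thermostat
  th <- NULL
  if (!is.null(tcfg)) {
    temp <- if (is.null(tcfg$temperature)) 300 else tcfg$temperature
    type <- if (is.null(tcfg$type)) "ad_langevin" else tcfg$type
    th <- switch(type,
      ad_langevin = adLangevinThermostat(
        nAtoms, temp,
        tauLangevin = if (is.null(tcfg$tau_langevin)) 200
                      else tcfg$tau_langevin,
        tauNH = if (is.null(tcfg$tau_nh)) 200 else tcfg$tau_nh),
      ad_nhl = adNHCLThermostat(
        nAtoms, temp, chainLength = 1L,
        gammaL = 1 / (if (is.null(tcfg$tau_langevin)) 200
                      else tcfg$tau_langevin),
        tauNH = if (is.null(tcfg$tau_nh)) 200 else tcfg$tau_nh),
      ad_nhc = adNHCLThermostat(
        nAtoms, temp,
        chainLength = if (is.null(tcfg$chain_length)) 3L
                      else tcfg$chain_length,
        gammaL = 0,
        tauNH = if (is.null(tcfg$tau_nh)) 200 else tcfg$tau_nh),
      ad_nhcl = adNHCLThermostat(
        nAtoms, temp,
        chainLength = if (is.null(tcfg$chain_length)) 3L
                      else tcfg$chain_length,
        gammaL = 1 / (if (is.null(tcfg$tau_langevin)) 200
                      else tcfg$tau_langevin),
        tauNH = if (is.null(tcfg$tau_nh)) 200 else tcfg$tau_nh),
      stop("unknown thermostat type: ", type))
  }
  if (!is.null(y$model$preset) && y$model$preset != "default_water_like")
    stop("unknown model preset: ", y$model$preset)
  mom <- if (is.null(y$momentum)) momentumCorrectionSpec()
         else momentumCorrectionSpec(y$momentum$mode, y$momentum$region)
  restraints <- if (is.null(y$restraints)) list() else
    lapply(y$restraints, function(r) {
      if (!is.null(r$atoms)) r$atoms <- as.integer(unlist(r$atoms))
      if (!is.null(r$cv)) {
        for (f in c("hydrogens", "atoms")) {
          if (!is.null(r$cv[[f]])) r$cv[[f]] <- as.integer(unlist(r$cv[[f]]))
        }
      }
      r
    })
  variant <- if (is.null(y$variant)) "AdBF" else y$variant
  simulationConfig(
    dt = if (is.null(y$dt)) 0.5 else y$dt,
    nSteps = if (is.null(y$n_steps)) 1000L else y$n_steps,
    variant = variant,
    regionSpec = spec, modelA = mp$A, modelB = mp$B,
    provider = if (variant == "MD") mp$B else NULL,
    thermostat = th, momentum = mom, restraints = restraints,
    outputEvery = if (is.null(y$output_every)) 0L else y$output_every,
    regionUpdateEvery = if (is.null(y$region_update_every)) 1L
                        else y$region_update_every,
    seed = y$seed)
}
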