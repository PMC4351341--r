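#' Simulation configuration
#'
#' Bundles everything [runMD()] needs. `variant` selects the per-step force
#' assembly: one of the four QM/MM method variants ("Conv", "AdConv", "AdUF",
#' "AdBF", requiring `modelA`/`modelB` and a [RegionSpec-class]) or "MD" for
#' plain single-model dynamics with `provider`. Restraint and bias forces are
#' added after force mixing and before the momentum correction; the
#' correction therefore sees the total dynamical force.
#'
#' @param dt Time step (fs), default 0.5.
#' @param nSteps Number of steps.
#' @param variant "AdBF", "AdUF", "AdConv", "Conv" or "MD".
#' @param regionSpec A [RegionSpec-class] (variants other than "MD").
#' @param modelA,modelB [PairForceField-class] models (QM role, MM role).
#' @param provider Force provider for `variant = "MD"`.
#' @param thermostat Thermostat object or NULL (velocity Verlet, NVE-style).
#' @param momentum A [momentumCorrectionSpec()].
#' @param restraints List of restraint specs (see [restraintForces()]).
#' @param bias Optional umbrella bias: list(cv, k, x0) where `x0` is a scalar
#'   or a function of the 1-based step index (moving restraint center).
#' @param outputEvery Frame cadence (steps); 0 keeps only initial and final.
#' @param regionUpdateEvery Re-partition cadence (steps), default 1.
#' @param seed Optional integer seed set at the start of the run.
#' @return Config list for [runMD()].
#' @export
simulationConfig <- function(dt = 0.5, nSteps = 1000L,
                             variant = c("AdBF", "AdUF", "AdConv", "Conv",
                                         "MD"),
                             regionSpec = NULL, modelA = NULL, modelB = NULL,
                             provider = NULL, thermostat = NULL,
                             momentum = momentumCorrectionSpec(),
                             restraints = list(), bias = NULL,
                             outputEvery = 0L, regionUpdateEvery = 1L,
                             seed = NULL) {
  variant <- match.arg(variant)
  if (dt <= 0) stop("dt must be > 0")
  if (variant == "MD") {
    if (is.null(provider)) stop("variant 'MD' requires a provider")
  } else {
    if (is.null(regionSpec) || is.null(modelA) || is.null(modelB))
      stop("QM/MM variants require regionSpec, modelA and modelB")
    .validateVariantSpec(variant, regionSpec)
  }
  list(dt = dt, nSteps = as.integer(nSteps), variant = variant,
       regionSpec = regionSpec, modelA = modelA, modelB = modelB,
       provider = provider, thermostat = thermostat, momentum = momentum,
       restraints = restraints, bias = bias,
       outputEvery = as.integer(outputEvery),
       regionUpdateEvery = as.integer(regionUpdateEvery), seed = seed)
}

## assemble the total dynamical force for one step
.assembleForces <- function(state, config, prev, step) {
  if (config$variant == "MD") {
    f <- evaluateForces(config$provider, state)$forces
    mixed <- list(forces = f, labels = prev, nEvals = 1L)
  } else {
    mixed <- runVariantStep(state, config$regionSpec, config$variant,
                            config$modelA, config$modelB, prev,
                            momentum = momentumCorrectionSpec("none"))
  }
  biasCV <- NA_real_
  biasX0 <- NA_real_
  if (length(config$restraints)) {
    for (rs in config$restraints) {
      mixed$forces <- mixed$forces + restraintForces(state, rs)$forces
    }
  }
  if (!is.null(config$bias)) {
    x0 <- if (is.function(config$bias$x0)) config$bias$x0(step)
          else config$bias$x0
    rf <- restraintForces(state, list(kind = "harmonic_cv",
                                      cv = config$bias$cv, x0 = x0,
                                      k = config$bias$k))
    mixed$forces <- mixed$forces + rf$forces
    biasCV <- rf$cv
    biasX0 <- x0
  }
  cm <- correctMomentum(mixed$forces, masses(state), config$momentum,
                        mixed$labels)
  mixed$forces <- cm$forces
  mixed$netForceBeforeCorrection <- cm$netForceBeforeCorrection
  mixed$biasCV <- biasCV
  mixed$biasX0 <- biasX0
  mixed
}

#' Run adaptive force-mixing molecular dynamics
#'
#' Per step: (1) partition the regions (hysteretically, against the previous
#' step's labels), (2) run the extended and, if the variant requires it, the
#' reduced force evaluation, (3) mix forces abruptly per atom, (4) add
#' restraint and bias forces, (5) apply the momentum correction, (6) advance
#' one thermostatted integration step (palindromic splitting: half kick,
#' thermostat half-phase, drift, thermostat half-phase, half kick; plain
#' velocity Verlet when `thermostat` is NULL). Runs are bit-reproducible
#' under a fixed seed.
#'
#' @param initial A [SystemState].
#' @param config A [simulationConfig()].
#' @return A list (`trajectory`) with `frames` (list of [SystemState]),
#'   `frameSteps`, `frameLabels` (list of [RegionLabels-class] or NULL),
#'   `regionLog` (per-step data.frame of region sizes), `temperature`
#'   (per-step kinetic temperature), `netForceAfter` (per-step max |sum F|
#'   after correction), `cvLog` (per-step bias CV samples, if a bias is set),
#'   `finalState`, `finalLabels`, `thermostat`.
#' @export
runMD <- function(initial, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- initial
  th <- config$thermostat
  n <- nAtoms(state)
  m <- masses(state)
  dt <- config$dt
  nSteps <- config$nSteps
  prev <- NULL
  qmmm <- config$variant != "MD"

  frames <- list(state)
  frameSteps <- 0L
  frameLabels <- list(NULL)
  regionLog <- if (qmmm) matrix(0L, nSteps, 5L) else NULL
  temperature <- numeric(nSteps)
  netForceAfter <- numeric(nSteps)
  hasBias <- !is.null(config$bias)
  cvX0 <- if (hasBias) numeric(nSteps) else NULL
  cvVal <- if (hasBias) numeric(nSteps) else NULL

  ## thermostat fast path: bypass S4 dispatch inside the step loop
  m3 <- rep(m, 3L)
  kBT <- NULL; Q <- NULL; gammaL <- NULL; gammaAdl <- NULL
  thKind <- if (is.null(th)) {
    "none"
  } else if (is(th, "AdLangevinThermostat")) {
    kBT <- .kB * th@temperature
    Q <- kBT * th@tauNH^2
    gammaAdl <- if (is.finite(th@tauLangevin)) 1 / th@tauLangevin else 0
    "adl"
  } else {
    kBT <- .kB * th@temperature
    Q <- kBT * th@tauNH^2
    gammaL <- th@gammaL
    "nhcl"
  }
  thState <- if (thKind == "adl") as.vector(th@chi) else
    if (thKind == "nhcl") th@xi else NULL
  phase <- switch(thKind,
    none = NULL,
    adl = function(v, h) {
      r <- cpp_adl_phase(as.vector(v), thState, m3, h, gammaAdl, Q, kBT,
                         th@freezeChi)
      thState <<- r$chi
      matrix(r$v, n, 3L)
    },
    nhcl = function(v, h) {
      r <- cpp_nhcl_phase(as.vector(v), thState, m3, h, gammaL, Q, kBT)
      thState <<- r$xi
      matrix(r$v, n, 3L)
    })

  cur <- .assembleForces(state, config, prev, 1L)
  prev <- cur$labels
  stepNow <- 0L
  halfKick <- .acc * dt / 2
  tempDenom <- 3 * length(m) * .kB * .acc

  tryCatch(for (step in seq_len(nSteps)) {
    stepNow <- step
    v <- state@velocities
    v <- v + cur$forces / m * halfKick
    if (!is.null(phase)) v <- phase(v, dt / 2)
    state@positions <- state@positions + v * dt
    if (any(!is.finite(state@positions))) {
      stop("non-finite positions (blow-up)")
    }
    nxt <- if (qmmm && config$regionUpdateEvery > 1L &&
               step %% config$regionUpdateEvery != 0L) {
      ## reuse previous labels: only recompute forces
      .assembleForcesFixedLabels(state, config, prev, step + 1L)
    } else {
      .assembleForces(state, config, prev, step + 1L)
    }
    if (qmmm) prev <- nxt$labels
    if (!is.null(phase)) v <- phase(v, dt / 2)
    v <- v + nxt$forces / m * halfKick
    state@velocities <- v
    cur <- nxt

    temperature[step] <- sum(m * v * v) / tempDenom
    netForceAfter[step] <- max(abs(colSums(cur$forces)))
    if (qmmm) regionLog[step, ] <- regionCounts(prev)
    if (hasBias) {
      cvX0[step] <- cur$biasX0
      cvVal[step] <- cur$biasCV
    }
    if (config$outputEvery > 0L && step %% config$outputEvery == 0L) {
      frames[[length(frames) + 1L]] <- state
      frameSteps <- c(frameSteps, step)
      frameLabels[[length(frameLabels) + 1L]] <- prev
    }
  }, error = function(e) {
    stop(sprintf("step %d failed: %s", stepNow, conditionMessage(e)),
         call. = FALSE)
  })
  ## write the final thermostat state back into the S4 object
  if (thKind == "adl") th@chi <- matrix(thState, n, 3L)
  if (thKind == "nhcl") th@xi <- thState
  if (frameSteps[length(frameSteps)] != nSteps && nSteps > 0L) {
    frames[[length(frames) + 1L]] <- state
    frameSteps <- c(frameSteps, nSteps)
    frameLabels[[length(frameLabels) + 1L]] <- prev
  }
  if (qmmm) {
    regionLog <- as.data.frame(regionLog)
    names(regionLog) <- c("core", "dyn_qm", "buffer", "extended_qm", "mm")
    regionLog <- cbind(step = seq_len(nSteps), regionLog)
  }
  cvLog <- if (hasBias) {
    data.frame(step = seq_len(nSteps), x0 = cvX0, value = cvVal)
  } else {
    NULL
  }
  list(frames = frames, frameSteps = frameSteps, frameLabels = frameLabels,
       regionLog = regionLog, temperature = temperature,
       netForceAfter = netForceAfter, cvLog = cvLog, finalState = state,
       finalLabels = prev, thermostat = th)
}

## force assembly that keeps the previous labels (region update cadence > 1)
.assembleForcesFixedLabels <- function(state, config, labels, step) {
  comp <- compositeForceField(config$modelA, config$modelB)
  variant <- config$variant
  if (variant %in% c("Conv", "AdConv")) {
    qm <- if (variant == "Conv")
      sort(unique(c(config$regionSpec@fixedCore, config$regionSpec@fixedQm)))
    else dynamicalQMAtoms(labels)
    mixed <- list(forces = evaluateForces(comp, state, qm)$forces,
                  labels = labels, nEvals = 1L)
  } else {
    qmExt <- if (variant == "AdBF") extendedQMAtoms(labels)
             else dynamicalQMAtoms(labels)
    fExt <- evaluateForces(comp, state, qmExt)$forces
    fRed <- evaluateForces(comp, state, coreAtoms(labels))$forces
    mixed <- mixForces(fExt, fRed, labels)
    mixed$labels <- labels
  }
  biasCV <- NA_real_; biasX0 <- NA_real_
  if (length(config$restraints)) {
    for (rs in config$restraints) {
      mixed$forces <- mixed$forces + restraintForces(state, rs)$forces
    }
  }
  if (!is.null(config$bias)) {
    x0 <- if (is.function(config$bias$x0)) config$bias$x0(step)
          else config$bias$x0
    rf <- restraintForces(state, list(kind = "harmonic_cv",
                                      cv = config$bias$cv, x0 = x0,
                                      k = config$bias$k))
    mixed$forces <- mixed$forces + rf$forces
    biasCV <- rf$cv; biasX0 <- x0
  }
  cm <- correctMomentum(mixed$forces, masses(state), config$momentum, labels)
  mixed$forces <- cm$forces
  mixed$netForceBeforeCorrection <- cm$netForceBeforeCorrection
  mixed$biasCV <- biasCV
  mixed$biasX0 <- biasX0
  mixed
}

#' Steered umbrella schedule
#'
#' Moves the bias center linearly from window to window, holding at each
#' center for a sampling period, and collects the CV samples of each hold
#' into umbrella-integration windows. Window endpoints and hold durations are
#' logged in the returned schedule.
#'
#' @param initial A [SystemState].
#' @param config A [simulationConfig()] whose `bias` holds the CV and force
#'   constant (`x0` is managed by the schedule).
#' @param centers Numeric vector of window centers (CV units).
#' @param moveSteps Steps for each linear center-to-center move (0 = jump,
#'   equivalent to independent windows).
#' @param holdSteps Sampling steps at each center.
#' @param sampleEvery Keep every so-many-th CV sample within a hold.
#' @param equilibrationDrop Fraction of each hold discarded before analysis
#'   (default 0.18, mirroring a 5.5 ps trajectory of which 4.5 ps are used).
#' @return List with `windows` (list of [uiWindow()]), `schedule`
#'   (data.frame), `finalState`.
#' @export
steeredSchedule <- function(initial, config, centers, moveSteps = 0L,
                            holdSteps = 1000L, sampleEvery = 1L,
                            equilibrationDrop = 0.18) {
  if (is.null(config$bias)) stop("config must define a bias (cv, k)")
  state <- initial
  windows <- vector("list", length(centers))
  sched <- data.frame(window = seq_along(centers), x0 = centers,
                      moveSteps = c(0L, rep(moveSteps, length(centers) - 1L)),
                      holdSteps = holdSteps)
  prevCenter <- centers[1]
  for (w in seq_along(centers)) {
    x0 <- centers[w]
    if (w > 1L && moveSteps > 0L) {
      from <- prevCenter
      ramp <- function(step) from + (x0 - from) * min(1, step / moveSteps)
      cfgMove <- config
      cfgMove$bias$x0 <- ramp
      cfgMove$nSteps <- as.integer(moveSteps)
      cfgMove$seed <- NULL
      state <- runMD(state, cfgMove)$finalState
    }
    cfgHold <- config
    cfgHold$bias$x0 <- x0
    cfgHold$nSteps <- as.integer(holdSteps)
    cfgHold$seed <- NULL
    run <- runMD(state, cfgHold)
    state <- run$finalState
    samples <- run$cvLog$value[seq(sampleEvery, holdSteps, by = sampleEvery)]
    windows[[w]] <- uiWindow(x0 = x0, k = config$bias$k, samples = samples,
                             equilibrationDrop = equilibrationDrop)
    prevCenter <- x0
  }
  list(windows = windows, schedule = sched, finalState = state)
}
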