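#' Switching-function parameters for rational coordination numbers
#'
#' @param alpha,beta Positive even integer exponents, `alpha < beta`.
#' @param r0 Reference distance (A), > 0. Defaults are alpha = 6, beta = 18,
#'   r0 = 1.6 A, appropriate for O-H coordination in proton-transfer
#'   coordinates.
#' @return Named list of parameters.
#' @export
switchingParams <- function(alpha = 6, beta = 18, r0 = 1.6) {
  if (alpha <= 0 || beta <= alpha) stop("need 0 < alpha < beta")
  if (r0 <= 0) stop("r0 must be positive")
  list(alpha = alpha, beta = beta, r0 = r0)
}

#' Rational switching function ("coordination count" of one distance)
#'
#' `n(r) = (1 - (r/r0)^alpha) / (1 - (r/r0)^beta)`: smooth, strictly
#' decreasing, 1 at r = 0, alpha/beta at the removable singularity r = r0
#' (evaluated by series expansion within |r/r0 - 1| < 1e-4), and 0 as r grows.
#'
#' @param r Distance(s), >= 0 (A).
#' @param p [switchingParams()].
#' @param gradient Logical; also return dn/dr.
#' @return Numeric value(s) in (0, 1], or list(value, dvalue) when
#'   `gradient = TRUE`.
#' @export
rationalN <- function(r, p = switchingParams(), gradient = FALSE) {
  if (any(r < 0)) stop("negative distance")
  a <- p$alpha; b <- p$beta
  x <- r / p$r0
  val <- numeric(length(x))
  dval <- numeric(length(x))
  near <- abs(x - 1) < 1e-4
  xa <- x^a; xb <- x^b
  val[!near] <- (1 - xa[!near]) / (1 - xb[!near])
  ## series about x = 1: n = (a/b) [1 - (u/2)(a - b) ...] with u = x - 1
  ## n(x) = a/b * (1 + (a-b)/2 * u + O(u^2)) -- from L'Hopital expansions
  u <- x[near] - 1
  val[near] <- (a / b) * (1 + (a - b) / 2 * u)
  if (gradient) {
    nz <- !near & x > 0
    dval[nz] <- (-a * xa[nz] / x[nz] * (1 - xb[nz]) +
                 (1 - xa[nz]) * b * xb[nz] / x[nz]) / (1 - xb[nz])^2 / p$r0
    dval[near] <- (a / b) * (a - b) / 2 / p$r0
    dval[!near & x == 0] <- 0
    list(value = val, dvalue = dval)
  } else {
    val
  }
}

## minimum-image displacement vector a - b
.mic <- function(a, b, cell, pbc) {
  d <- a - b
  w <- pbc & cell > 0
  d[w] <- d[w] - cell[w] * round(d[w] / cell[w])
  d
}

#' Difference of rational coordination numbers (proton-transfer coordinate)
#'
#' `DRCN = sum_H n(r(acceptorO, H)) - sum_H n(r(donorO, H))` over an explicit
#' hydrogen list, with [rationalN()] as the switching function. DRCN = 0 for
#' two intact, well separated water molecules (reactant state); transferring
#' a proton from donor to acceptor drives it positive. Gradients are analytic
#' on the two oxygens and all listed hydrogens.
#'
#' @param state A [SystemState].
#' @param donorO,acceptorO Atom indices of the donor and acceptor oxygens.
#' @param hydrogens Integer vector of hydrogen atom indices (nonempty).
#' @param p [switchingParams()].
#' @return List with `value` (dimensionless) and `gradient` (n x 3 matrix,
#'   nonzero only on member atoms).
#' @export
drcn <- function(state, donorO, acceptorO, hydrogens, p = switchingParams()) {
  if (length(hydrogens) == 0L) stop("empty hydrogen list")
  ids <- c(donorO, acceptorO, hydrogens)
  if (anyDuplicated(ids)) stop("atom indices must be distinct")
  pos <- positions(state)
  cell <- state@cell; pbc <- state@pbc
  grad <- matrix(0, nAtoms(state), 3L)
  value <- 0
  for (h in hydrogens) {
    for (sgn_ox in list(c(1, acceptorO), c(-1, donorO))) {
      sgn <- sgn_ox[1]; ox <- sgn_ox[2]
      d <- .mic(pos[h, ], pos[ox, ], cell, pbc)
      r <- sqrt(sum(d * d))
      if (r < 1e-10) stop("coincident atoms: undefined gradient")
      nn <- rationalN(r, p, gradient = TRUE)
      value <- value + sgn * nn$value
      g <- sgn * nn$dvalue * d / r
      grad[h, ] <- grad[h, ] + g
      grad[ox, ] <- grad[ox, ] - g
    }
  }
  list(value = value, gradient = grad)
}

#' Distance-difference coordinate (phosphoryl-transfer coordinate)
#'
#' `DD = |r_L - r_P| - |r_A - r_P|` (A): distance from the leaving oxygen to
#' the central atom minus distance from the attacking oxygen, minimum-image.
#' Zero at the symmetric (transition-state-region) placement. Gradients are
#' analytic on the three atoms.
#'
#' @param state A [SystemState].
#' @param P Central (phosphorus-role) atom index.
#' @param oLeaving,oAttacking Leaving and attacking oxygen indices.
#' @return List with `value` (A) and `gradient` (n x 3).
#' @export
distanceDifference <- function(state, P, oLeaving, oAttacking) {
  if (anyDuplicated(c(P, oLeaving, oAttacking)))
    stop("atom indices must be distinct")
  pos <- positions(state)
  grad <- matrix(0, nAtoms(state), 3L)
  val <- 0
  for (sgn_ox in list(c(1, oLeaving), c(-1, oAttacking))) {
    sgn <- sgn_ox[1]; ox <- sgn_ox[2]
    d <- .mic(pos[ox, ], pos[P, ], state@cell, state@pbc)
    r <- sqrt(sum(d * d))
    if (r < 1e-10) stop("coincident atoms: undefined gradient")
    val <- val + sgn * r
    g <- sgn * d / r
    grad[ox, ] <- grad[ox, ] + g
    grad[P, ] <- grad[P, ] - g
  }
  list(value = val, gradient = grad)
}

#' Generic collective-variable evaluation
#'
#' Evaluates a CV described by a spec list on a state. Supported types:
#' `drcn` (fields donorO, acceptorO, hydrogens, params), `distance_difference`
#' (P, oLeaving, oAttacking), `distance` (i, j) and `coordinate` (atom, axis)
#' for plain Cartesian coordinates.
#'
#' @param cv CV spec list with a `type` field.
#' @param state A [SystemState].
#' @return List with `value` and `gradient` (n x 3).
#' @export
cvValue <- function(cv, state) {
  switch(cv$type,
    drcn = drcn(state, cv$donorO, cv$acceptorO, cv$hydrogens,
                if (is.null(cv$params)) switchingParams() else cv$params),
    distance_difference = distanceDifference(state, cv$P, cv$oLeaving,
                                             cv$oAttacking),
    distance = {
      d <- .mic(positions(state)[cv$i, ], positions(state)[cv$j, ],
                state@cell, state@pbc)
      r <- sqrt(sum(d * d))
      if (r < 1e-10) stop("coincident atoms: undefined gradient")
      grad <- matrix(0, nAtoms(state), 3L)
      grad[cv$i, ] <- d / r
      grad[cv$j, ] <- -d / r
      list(value = r, gradient = grad)
    },
    coordinate = {
      grad <- matrix(0, nAtoms(state), 3L)
      grad[cv$atom, cv$axis] <- 1
      list(value = positions(state)[cv$atom, cv$axis], gradient = grad)
    },
    stop("unknown CV type: ", cv$type))
}

#' Restraint and bias forces
#'
#' `harmonic_cv` adds the umbrella bias `U = (k/2) (x(r) - x0)^2` on a
#' collective variable; `one_sided_distance` adds the same on an interatomic
#' distance but only beyond (side = "upper") or below (side = "lower") a
#' threshold, with forces continuous at the threshold.
#'
#' @param state A [SystemState].
#' @param spec Restraint spec: for `harmonic_cv` a list(kind, cv, x0, k); for
#'   `one_sided_distance` a list(kind, atoms = c(i, j), threshold, k,
#'   side = "upper"|"lower").
#' @return List with `forces` (n x 3) and `energy`.
#' @export
restraintForces <- function(state, spec) {
  if (spec$k < 0) stop("force constant must be >= 0")
  if (spec$kind == "harmonic_cv") {
    cvr <- cvValue(spec$cv, state)
    dx <- cvr$value - spec$x0
    list(forces = -spec$k * dx * cvr$gradient,
         energy = 0.5 * spec$k * dx^2, cv = cvr$value)
  } else if (spec$kind == "one_sided_distance") {
    cvr <- cvValue(list(type = "distance", i = spec$atoms[1],
                        j = spec$atoms[2]), state)
    side <- if (is.null(spec$side)) "upper" else spec$side
    active <- if (side == "upper") cvr$value > spec$threshold
              else cvr$value < spec$threshold
    if (!active) {
      list(forces = matrix(0, nAtoms(state), 3L), energy = 0, cv = cvr$value)
    } else {
      dx <- cvr$value - spec$threshold
      list(forces = -spec$k * dx * cvr$gradient,
           energy = 0.5 * spec$k * dx^2, cv = cvr$value)
    }
  } else {
    stop("unknown restraint kind: ", spec$kind)
  }
}
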