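## Region labels use fixed codes: innermost first.
.REGIONS <- c("CORE", "DYN_QM", "BUFFER", "MM")
.R_CORE <- 1L; .R_DYNQM <- 2L; .R_BUFFER <- 3L; .R_MM <- 4L

#' RegionSpec: parameters of the adaptive region construction
#'
#' Radii come in hysteretic (inner, outer) pairs: an atom (or molecule) must
#' come closer than the inner radius to enter a region and farther than the
#' outer radius to leave it, which suppresses boundary flicker. Setting
#' inner = outer recovers a plain cutoff. Setting a pair to (0, 0) disables
#' adaptive selection for that region.
#'
#' @slot fixedCore,fixedQm,fixedBuffer Integer atom index vectors (pairwise
#'   disjoint as input; runtime geometry may still promote atoms inward).
#' @slot rCore,rQm,rBuffer Length-2 numeric `(inner, outer)` radii in
#'   Angstrom with inner <= outer.
#' @slot selectionSpeciesFilter Optional character vector of element symbols;
#'   when set, only distances between atoms of these species are tested for
#'   adaptive selection (e.g. `"O"` for oxygen-oxygen selection).
#' @slot wholeMolecules Logical; promote whole molecules to the innermost
#'   region any of their atoms reached (default TRUE).
#' @slot seedIsOnlyFixedCore Logical; when TRUE the dynamical QM selection
#'   measures distances only from the fixed core list rather than the full
#'   current core region.
#' @slot maxExtendedAtoms Integer cap on |dynamical QM + buffer|.
#' @export
setClass("RegionSpec",
  representation(
    fixedCore = "integer", fixedQm = "integer", fixedBuffer = "integer",
    rCore = "numeric", rQm = "numeric", rBuffer = "numeric",
    selectionSpeciesFilter = "character",
    wholeMolecules = "logical", seedIsOnlyFixedCore = "logical",
    maxExtendedAtoms = "integer"
  )
)

setValidity("RegionSpec", function(object) {
  msgs <- character(0)
  for (nm in c("rCore", "rQm", "rBuffer")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(r < 0)) {
      msgs <- c(msgs, paste(nm, "must be two nonnegative values"))
    } else if (r[1] > r[2]) {
      msgs <- c(msgs, paste(nm, "inner radius exceeds outer radius"))
    }
  }
  fx <- c(object@fixedCore, object@fixedQm, object@fixedBuffer)
  if (anyDuplicated(fx))
    msgs <- c(msgs, "fixed atom lists must be pairwise disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionSpec
#'
#' @param fixedCore,fixedQm,fixedBuffer Fixed atom index lists (disjoint).
#' @param rCore,rQm,rBuffer Hysteretic `(inner, outer)` radii pairs (A); a
#'   single value is treated as inner = outer.
#' @param selectionSpeciesFilter Optional species filter, e.g. `"O"`.
#' @param wholeMolecules Promote whole molecules (default TRUE).
#' @param seedIsOnlyFixedCore See [RegionSpec-class].
#' @param maxExtendedAtoms Cap on the extended QM region size.
#' @return A [RegionSpec-class].
#' @export
regionSpec <- function(fixedCore = integer(0), fixedQm = integer(0),
                       fixedBuffer = integer(0),
                       rCore = c(0, 0), rQm = c(0, 0), rBuffer = c(0, 0),
                       selectionSpeciesFilter = character(0),
                       wholeMolecules = TRUE, seedIsOnlyFixedCore = FALSE,
                       maxExtendedAtoms = .Machine$integer.max) {
  pairify <- function(r) if (length(r) == 1L) c(r, r) else as.numeric(r)
  new("RegionSpec",
      fixedCore = as.integer(fixedCore), fixedQm = as.integer(fixedQm),
      fixedBuffer = as.integer(fixedBuffer),
      rCore = pairify(rCore), rQm = pairify(rQm), rBuffer = pairify(rBuffer),
      selectionSpeciesFilter = as.character(selectionSpeciesFilter),
      wholeMolecules = wholeMolecules,
      seedIsOnlyFixedCore = seedIsOnlyFixedCore,
      maxExtendedAtoms = as.integer(maxExtendedAtoms))
}

#' RegionLabels: per-atom region membership
#'
#' @slot codes Integer vector; 1 = CORE, 2 = DYN_QM, 3 = BUFFER, 4 = MM.
#' @export
setClass("RegionLabels", representation(codes = "integer"))

setValidity("RegionLabels", function(object) {
  if (any(is.na(object@codes)) || any(object@codes < 1L | object@codes > 4L))
    return("codes must be in 1..4")
  TRUE
})

#' @rdname RegionLabels-class
#' @param codes Integer codes or character labels.
#' @export
regionLabels <- function(codes) {
  if (is.character(codes)) codes <- match(codes, .REGIONS)
  new("RegionLabels", codes = as.integer(codes))
}

#' @rdname regionOf
#' @export
setMethod("regionOf", "RegionLabels", function(x) .REGIONS[x@codes])

setMethod("show", "RegionLabels", function(object) {
  tb <- table(factor(.REGIONS[object@codes], levels = .REGIONS))
  cat("RegionLabels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "),
      "\n")
  invisible(object)
})

#' Atom index sets of the standard regions
#'
#' `dynamicalQMAtoms` returns CORE plus DYN_QM (the atoms propagated with
#' extended forces), `extendedQMAtoms` additionally includes BUFFER (the QM
#' set of the extended evaluation), and `coreAtoms` returns CORE only.
#'
#' @param labels A [RegionLabels-class].
#' @return Integer atom indices.
#' @export
dynamicalQMAtoms <- function(labels) which(labels@codes <= .R_DYNQM)

#' @rdname dynamicalQMAtoms
#' @export
extendedQMAtoms <- function(labels) which(labels@codes <= .R_BUFFER)

#' @rdname dynamicalQMAtoms
#' @export
coreAtoms <- function(labels) which(labels@codes == .R_CORE)

#' Hysteretic distance selection
#'
#' Returns the atoms of `candidates` whose minimum-image distance to the
#' nearest `reference` atom is within the inner radius, plus previous members
#' that are still within the outer radius:
#' `{a : d(a, ref) <= rIn} U {a in prev : d(a, ref) <= rOut}`.
#' With `rIn == rOut` this is a plain cutoff selection regardless of `prev`.
#' When a species filter is given, only candidate and reference atoms of the
#' listed species are tested (others are never selected directly).
#'
#' @param candidates Integer atom indices eligible for selection.
#' @param reference Integer atom indices distances are measured from
#'   (nonempty).
#' @param prevMembers Integer indices of previous members.
#' @param rIn,rOut Inner and outer radii (A), `rIn <= rOut`.
#' @param state A [SystemState].
#' @param speciesFilter Optional character vector of element symbols.
#' @return Integer vector of selected candidate indices (sorted).
#' @export
hystereticSelect <- function(candidates, reference, prevMembers, rIn, rOut,
                             state, speciesFilter = character(0)) {
  if (rIn > rOut) stop("rIn exceeds rOut")
  if (length(reference) == 0L) stop("reference set is empty")
  candidates <- as.integer(candidates)
  reference <- as.integer(reference)
  prevMembers <- as.integer(prevMembers)
  sp <- species(state)
  if (length(speciesFilter)) {
    candidates <- candidates[sp[candidates] %in% speciesFilter]
    reference <- reference[sp[reference] %in% speciesFilter]
    if (length(reference) == 0L) return(integer(0))
  }
  if (length(candidates) == 0L) return(integer(0))
  D <- minimumImageCrossDist(positions(state)[candidates, , drop = FALSE],
                             positions(state)[reference, , drop = FALSE],
                             state@cell, state@pbc)
  dmin <- apply(D, 1L, min)
  keep <- dmin <= rIn | (candidates %in% prevMembers & dmin <= rOut)
  sort(candidates[keep])
}

## previous members of a region (or any enclosing region), post-promotion
.prevMembersOf <- function(prev, code) {
  if (is.null(prev)) integer(0) else which(prev@codes <= code)
}

#' Partition a system into CORE, DYN_QM, BUFFER and MM regions
#'
#' Sequential construction: the core region is the fixed core list plus atoms
#' hysteretically selected within `rCore` of it; the dynamical QM region is
#' the core plus the fixed QM list plus atoms within `rQm` of the core (of
#' the fixed core only when `seedIsOnlyFixedCore`); the buffer is the fixed
#' buffer list plus atoms within `rBuffer` of the dynamical QM region, minus
#' the dynamical QM region. Distances are always measured against the current
#' step's reference sets. When `wholeMolecules` is set, each molecule is then
#' promoted wholly to the innermost region any of its atoms reached, and the
#' hysteresis memory is kept per (region, molecule). Label precedence is
#' CORE > DYN_QM > BUFFER > MM; a fixed-list atom of an outer region that
#' falls inside an inner selection is promoted inward. Previous-membership
#' tests use the post-promotion labels of the previous step.
#'
#' @param state A [SystemState].
#' @param spec A [RegionSpec-class].
#' @param prev Previous [RegionLabels-class] or NULL on the first call (all
#'   MM except the fixed lists).
#' @return A [RegionLabels-class].
#' @export
partitionRegions <- function(state, spec, prev = NULL) {
  validObject(spec)
  n <- nAtoms(state)
  all_atoms <- seq_len(n)
  filt <- spec@selectionSpeciesFilter

  selectInto <- function(reference, prevCode, r) {
    if (length(reference) == 0L || r[2] <= 0) return(integer(0))
    hystereticSelect(all_atoms, reference, .prevMembersOf(prev, prevCode),
                     r[1], r[2], state, filt)
  }

  core <- sort(unique(c(spec@fixedCore,
                        selectInto(spec@fixedCore, .R_CORE, spec@rCore))))
  qmSeed <- if (spec@seedIsOnlyFixedCore) spec@fixedCore else
    sort(unique(c(core, spec@fixedQm)))
  dynqm <- sort(unique(c(core, spec@fixedQm,
                         selectInto(qmSeed, .R_DYNQM, spec@rQm))))
  buffer <- sort(unique(c(spec@fixedBuffer,
                          selectInto(dynqm, .R_BUFFER, spec@rBuffer))))
  buffer <- setdiff(buffer, dynqm)

  codes <- rep(.R_MM, n)
  codes[buffer] <- .R_BUFFER
  codes[dynqm] <- .R_DYNQM
  codes[core] <- .R_CORE

  if (spec@wholeMolecules) {
    mol <- moleculeId(state)
    innermost <- tapply(codes, mol, min)
    codes <- as.integer(innermost[as.character(mol)])
  }
  nExt <- sum(codes <= .R_BUFFER)
  if (nExt > spec@maxExtendedAtoms) {
    stop(sprintf(
      "extended QM region has %d atoms, exceeding maxExtendedAtoms = %d",
      nExt, spec@maxExtendedAtoms))
  }
  regionLabels(codes)
}

#' Region size counts
#'
#' @param labels A [RegionLabels-class].
#' @return Named integer vector with counts of CORE, DYN_QM (incl. CORE),
#'   BUFFER, extended QM (DYN_QM + BUFFER) and MM atoms.
#' @export
regionCounts <- function(labels) {
  c(core = sum(labels@codes == .R_CORE),
    dyn_qm = sum(labels@codes <= .R_DYNQM),
    buffer = sum(labels@codes == .R_BUFFER),
    extended_qm = sum(labels@codes <= .R_BUFFER),
    mm = sum(labels@codes == .R_MM))
}
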