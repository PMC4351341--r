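## Extended-XYZ trajectory I/O. Comment line carries an orthorhombic
## Lattice="ax 0 0 0 ay 0 0 0 az", a Properties= column description, the pbc
## flags and the step index; per-atom columns are species, positions,
## molecule id, region label and (optionally) velocities.

.defaultMassTable <- c(O = 16, H = 1)

#' Write states to an extended-XYZ trajectory file
#'
#' @param states A [SystemState], list of states, or [runMD()] trajectory.
#' @param file Output path.
#' @param labels Optional [RegionLabels-class] or list thereof (one per
#'   frame); missing labels are written as MM.
#' @param steps Optional integer step indices (one per frame).
#' @param velocities Include a vel:R:3 column (default TRUE).
#' @return Invisibly, the file path.
#' @export
writeExtendedXYZ <- function(states, file, labels = NULL, steps = NULL,
                             velocities = TRUE) {
  if (is(states, "SystemState")) states <- list(states)
  if (is.list(states) && !is.null(states$frames)) {
    labels <- states$frameLabels
    steps <- states$frameSteps
    states <- states$frames
  }
  if (!is.null(labels) && is(labels, "RegionLabels")) labels <- list(labels)
  if (is.null(steps)) steps <- seq_along(states) - 1L
  con <- file(file, "w")
  on.exit(close(con))
  props <- paste0("species:S:1:pos:R:3:molecule_id:I:1:region_label:S:1",
                  if (velocities) ":vel:R:3" else "")
  for (i in seq_along(states)) {
    st <- states[[i]]
    lab <- if (!is.null(labels) && length(labels) >= i &&
               !is.null(labels[[i]])) {
      regionOf(labels[[i]])
    } else {
      rep("MM", nAtoms(st))
    }
    lat <- sprintf("%.10g 0 0 0 %.10g 0 0 0 %.10g",
                   st@cell[1], st@cell[2], st@cell[3])
    writeLines(as.character(nAtoms(st)), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=%s pbc="%s" step=%d', lat, props,
      paste(ifelse(st@pbc, "T", "F"), collapse = " "), steps[i]), con)
    pos <- positions(st)
    vel <- velocities(st)
    lines <- if (velocities) {
      sprintf("%s %.10f %.10f %.10f %d %s %.10g %.10g %.10g",
              species(st), pos[, 1], pos[, 2], pos[, 3], moleculeId(st), lab,
              vel[, 1], vel[, 2], vel[, 3])
    } else {
      sprintf("%s %.10f %.10f %.10f %d %s",
              species(st), pos[, 1], pos[, 2], pos[, 3], moleculeId(st), lab)
    }
    writeLines(lines, con)
  }
  invisible(file)
}

## parse a key=value comment line, honoring quoted values
.parseComment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_]+)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Read an extended-XYZ trajectory file
#'
#' Understands the `Lattice`/`Properties`/`pbc` comment-line dialect with
#' per-atom species, positions, molecule ids, region labels and (optionally)
#' velocities. Water-like bond/angle topology is reconstructed for molecules
#' of exactly one heavy and two light atoms.
#'
#' @param file Path to the file.
#' @param massTable Named vector mapping element symbols to masses (amu);
#'   unknown species get 12.
#' @return List of frames; each frame is a list with `state` ([SystemState]),
#'   `labels` ([RegionLabels-class]) and `step`.
#' @export
readExtendedXYZ <- function(file, massTable = .defaultMassTable) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    meta <- .parseComment(lines[i + 1L])
    lat <- as.numeric(strsplit(trimws(meta$Lattice), "\\s+")[[1]])
    cell <- lat[c(1, 5, 9)]
    pbc <- if (!is.null(meta$pbc)) {
      toupper(strsplit(trimws(meta$pbc), "\\s+")[[1]]) == "T"
    } else {
      rep(TRUE, 3L)
    }
    props <- strsplit(meta$Properties, ":")[[1]]
    cols <- list()
    at <- 1L
    for (k in seq(1, length(props), by = 3)) {
      w <- as.integer(props[k + 2])
      cols[[props[k]]] <- at:(at + w - 1L)
      at <- at + w
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "\\s+")
    getcol <- function(nm) t(vapply(tok, function(x) x[cols[[nm]]],
                                    character(length(cols[[nm]]))))
    sp <- as.vector(getcol("species"))
    pos <- matrix(as.numeric(getcol("pos")), n, 3L)
    mol <- as.integer(getcol("molecule_id"))
    lab <- if (!is.null(cols$region_label)) as.vector(getcol("region_label"))
           else rep("MM", n)
    vel <- if (!is.null(cols$vel)) matrix(as.numeric(getcol("vel")), n, 3L)
           else matrix(0, n, 3L)
    mass <- unname(massTable[sp])
    mass[is.na(mass)] <- 12
    topo <- .waterTopology(sp, mol, massTable)
    st <- systemState(pos, vel, mass, sp, mol, cell, pbc,
                      bonds = topo$bonds, angles = topo$angles)
    frames[[length(frames) + 1L]] <-
      list(state = st, labels = regionLabels(lab),
           step = if (is.null(meta$step)) NA_integer_
                  else as.integer(meta$step))
    i <- i + 2L + n
  }
  frames
}

## reconstruct heavy-light-light bond/angle topology per molecule
.waterTopology <- function(sp, mol, massTable) {
  bonds <- NULL
  angles <- NULL
  for (m in unique(mol)) {
    idx <- which(mol == m)
    if (length(idx) != 3L) next
    mass <- unname(massTable[sp[idx]])
    mass[is.na(mass)] <- 12
    heavy <- idx[which.max(mass)]
    light <- setdiff(idx, heavy)
    if (length(light) != 2L) next
    bonds <- rbind(bonds, c(heavy, light[1]), c(heavy, light[2]))
    angles <- rbind(angles, c(light[1], heavy, light[2]))
  }
  list(bonds = if (is.null(bonds)) matrix(integer(0), 0L, 2L) else bonds,
       angles = if (is.null(angles)) matrix(integer(0), 0L, 3L) else angles)
}
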