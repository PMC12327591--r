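# Multi-model PDB trajectories over one shared, validated topology.

#' Read an MD trajectory from a multi-model PDB file
#'
#' Model 1 defines the topology: it is cleaned with [validateStructure()]
#' (heteroatoms out, incomplete residues rejected) and every subsequent
#' model is then matched to that cleaned topology atom-for-atom by
#' (chain, residue number, insertion code, atom name). Frames must agree
#' exactly with the topology: an atom present in a later frame but absent
#' from the topology, or vice versa, is an error naming the offending frame
#' (frames are numbered 1-based).
#'
#' @param input path, connection or character lines of a multi-model PDB.
#' @return a list with elements `trajectory` ([Trajectory-class]) and
#'   `report` (the [ValidationReport-class] of model 1).
#' @examples
#' spec <- synthSpec(nResidues = 5, nFrames = 3)
#' tf <- tempfile(fileext = ".pdb")
#' writeTrajectory(makeTrajectory(spec), tf)
#' traj <- readTrajectory(tf)$trajectory
#' nFrames(traj)
#' @export
readTrajectory <- function(input) {
  models <- parsePDB(input)
  label <- if (is.character(input) && length(input) == 1L &&
               !grepl("\n", input, fixed = TRUE)) input else "trajectory"
  v <- validateStructure(models[[1L]], sourceLabel = label)
  topo <- v$model
  atoms <- topo@atoms
  topoKey <- paste(atoms$chainId, atoms$seqNum, atoms$insCode, atoms$name,
                   sep = "|")
  if (anyDuplicated(topoKey))
    stopSM("topology atoms are not uniquely addressable by ",
           "(chain, residue, insertion code, atom name)")
  nF <- length(models)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nF))
  coords[, , 1L] <- cbind(atoms$x, atoms$y, atoms$z)
  labels <- vapply(models, function(m) {
    l <- attr(m, "modelLabel"); if (is.null(l)) "" else l
  }, character(1))
  if (nF > 1L) {
    for (k in 2L:nF) {
      fm <- models[[k]]
      fm$name <- trimws(fm$name)
      fmKey <- paste(fm$chainId, fm$seqNum, fm$insCode, fm$name, sep = "|")
      pos <- match(topoKey, fmKey)
      if (nrow(fm) != length(topoKey) || anyNA(pos) || anyDuplicated(fmKey))
        stopSM("inconsistent topology at frame ", k)
      coords[, , k] <- cbind(fm$x, fm$y, fm$z)[pos, , drop = FALSE]
    }
  }
  traj <- new("Trajectory", topology = topo, coords = coords,
              frameLabels = labels)
  list(trajectory = traj, report = v$report)
}

#' Construct a Trajectory from a topology and coordinate frames
#'
#' @param topology a [StructureModel-class].
#' @param coords an n_atoms x 3 x F array, or a list of n_atoms x 3
#'   matrices.
#' @param frameLabels optional character labels (default "1".."F").
#' @return a [Trajectory-class]
#' @export
newTrajectory <- function(topology, coords, frameLabels = NULL) {
  if (is.list(coords)) {
    nF <- length(coords)
    arr <- array(NA_real_, dim = c(nrow(topology@atoms), 3L, nF))
    for (k in seq_len(nF)) arr[, , k] <- coords[[k]]
    coords <- arr
  }
  if (is.null(frameLabels)) frameLabels <- as.character(seq_len(dim(coords)[3]))
  new("Trajectory", topology = topology, coords = coords,
      frameLabels = frameLabels)
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, in frame order; coordinates are written
#' to the PDB 3-decimal convention, so a read/write round trip preserves
#' them to 1e-3 Angstrom. For an [AnnotatedTrajectory-class] the per-frame
#' B-factor annotation is written into the temperature-factor column.
#'
#' @param traj a [Trajectory-class] or [AnnotatedTrajectory-class].
#' @param path output file path or connection.
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  nF <- nFrames(traj)
  if (nF < 1L) stopSM("cannot write a trajectory with no frames")
  atoms <- traj@topology@atoms
  bf <- if (is(traj, "AnnotatedTrajectory")) traj@bFactors else NULL
  sink <- openTextSink(path)
  on.exit(if (sink$close) close(sink$con))
  out <- vector("list", nF)
  for (k in seq_len(nF)) {
    body <- .modelBodyLines(atoms, xyz = matrix(traj@coords[, , k], ncol = 3L),
                            bFactor = if (is.null(bf)) NULL else bf[, k])
    out[[k]] <- c(sprintf("MODEL     %4d", k), body, "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), sink$con)
  invisible(path)
}

#' @describeIn writePDB A Trajectory is written as multi-model PDB (same as
#'   [writeTrajectory()]).
#' @export
setMethod("writePDB", "Trajectory", function(x, path, ...) writeTrajectory(x, path))

#' Extract coordinates of selected atoms on one frame
#'
#' Stable-ordering contract: the same `atomIndices` yield coordinates in the
#' same (given) order on every frame.
#'
#' @param traj a [Trajectory-class].
#' @param frame 1-based frame index.
#' @param atomIndices integer indices into the topology atom table; defaults
#'   to all atoms.
#' @return numeric matrix, length(atomIndices) x 3.
#' @export
frameCoords <- function(traj, frame, atomIndices = NULL) {
  stopifnot(is(traj, "Trajectory"))
  nF <- nFrames(traj)
  if (length(frame) != 1L || is.na(frame) || frame < 1L || frame > nF)
    stopSM("frame index out of range: ", frame, " (trajectory has ", nF,
           " frames)")
  if (is.null(atomIndices))
    return(matrix(traj@coords[, , frame], ncol = 3L))
  if (!length(atomIndices))
    return(matrix(numeric(0), 0L, 3L))
  n <- dim(traj@coords)[1]
  if (any(atomIndices < 1L | atomIndices > n))
    stopSM("atom index out of range")
  matrix(traj@coords[atomIndices, , frame, drop = FALSE], ncol = 3L)
}

setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
setMethod("nResidues", "Trajectory", function(x) nrow(x@topology@residues))
setMethod("nResidues", "StructureModel", function(x) nrow(x@residues))
setMethod("residueIds", "StructureModel", function(x) residueIdsOf(x@residues))
setMethod("residueIds", "Trajectory", function(x) residueIds(x@topology))
setMethod("atomTable", "StructureModel", function(x) x@atoms)
setMethod("atomTable", "Trajectory", function(x) x@topology@atoms)
setMethod("residueTable", "StructureModel", function(x) x@residues)
setMethod("residueTable", "Trajectory", function(x) x@topology@residues)

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d residues, %d atoms, %d chain(s) [%s]\n",
              nrow(object@residues), nrow(object@atoms),
              length(unique(object@residues$chainId)), object@sourceLabel))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("%s: %d frames of %d residues (%d atoms)\n",
              class(object), nFrames(object), nResidues(object),
              nrow(object@topology@atoms)))
})

setMethod("show", "ValidationReport", function(object) {
  cat(report(object), sep = "\n")
})
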