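# Per-residue spatial spheres on the target frame. Membership is found with
# a cell-list spatial hash (cell edge = cutoff, 27-cell stencil), so lookup
# cost stays linear in atom count; results are identical to an all-pairs
# distance scan and independent of the index internals.

#' Validate the sphere radius
#'
#' The spatial proximity radius d must lie between 2 and 8 Angstrom
#' (inclusive); values outside that range are a configuration error.
#'
#' @param d proposed radius in Angstrom.
#' @return d, invisibly validated.
#' @export
checkRadius <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d))
    stopConfig("sphere radius must be a single finite number")
  if (d < 2 || d > 8)
    stopConfig("sphere radius ", format(d),
               " out of range: d is adjustable from 2 to 8 Angstrom")
  d
}

# For each row of `query`, the indices of rows of `ref` within `cutoff`
# (closed ball, Euclidean). Cell-list implementation.
.pointsWithin <- function(query, ref, cutoff) {
  nq <- nrow(query); nr <- nrow(ref)
  out <- vector("list", nq)
  if (!nq || !nr) { for (i in seq_len(nq)) out[[i]] <- integer(0); return(out) }
  rcell <- floor(ref / cutoff)
  key <- paste(rcell[, 1], rcell[, 2], rcell[, 3], sep = ",")
  buckets <- split(seq_len(nr), key)
  qcell <- floor(query / cutoff)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  c2 <- cutoff * cutoff
  for (i in seq_len(nq)) {
    cells <- sweep(offs, 2L, qcell[i, ], "+")
    ks <- paste(cells[, 1], cells[, 2], cells[, 3], sep = ",")
    cand <- unlist(buckets[ks], use.names = FALSE)
    if (is.null(cand) || !length(cand)) { out[[i]] <- integer(0); next }
    d2 <- (ref[cand, 1] - query[i, 1])^2 + (ref[cand, 2] - query[i, 2])^2 +
      (ref[cand, 3] - query[i, 3])^2
    out[[i]] <- sort(cand[d2 <= c2])
  }
  out
}

#' Build the per-residue spheres on the target frame
#'
#' For every residue of the trajectory topology, fixes the set of atoms that
#' will be compared across frames: all atoms within the sphere of radius
#' `radius` around the residue's C-alpha on the target frame. Membership is
#' computed once, on the target frame only, and never updated afterwards.
#'
#' Two membership modes are supported, reflecting two readings of "atoms in
#' spatial contact":
#' \describe{
#'   \item{residueCA (default)}{residue j belongs to residue i's sphere iff
#'     their C-alpha--C-alpha distance is at most `radius`; all (heavy)
#'     atoms of member residues are included.}
#'   \item{atomAny}{an atom belongs to the sphere iff its own distance to
#'     residue i's C-alpha is at most `radius`; the center residue's atoms
#'     are always included.}
#' }
#' The boundary is closed (distance equal to `radius` is inside). Hydrogens
#' are excluded unless `includeHydrogens = TRUE`, so results are comparable
#' between trajectories with and without explicit hydrogens. Spheres may
#' span chains.
#'
#' @param traj a [Trajectory-class].
#' @param radius sphere radius d in Angstrom, in [2, 8].
#' @param targetFrame 1-based frame on which membership is fixed (default
#'   1, the first frame).
#' @param membershipMode "residueCA" or "atomAny".
#' @param includeHydrogens logical; include hydrogen/deuterium atoms.
#' @return a [SphereSet-class] with one sphere per residue, in residue
#'   order.
#' @examples
#' traj <- makeTrajectory(synthSpec(nResidues = 10, nFrames = 2))
#' ss <- buildSpheres(traj, radius = 4)
#' ss
#' @export
buildSpheres <- function(traj, radius, targetFrame = 1L,
                         membershipMode = c("residueCA", "atomAny"),
                         includeHydrogens = FALSE) {
  stopifnot(is(traj, "Trajectory"))
  membershipMode <- match.arg(membershipMode)
  radius <- checkRadius(radius)
  nF <- nFrames(traj)
  if (length(targetFrame) != 1L || is.na(targetFrame) || targetFrame < 1L ||
      targetFrame > nF)
    stopConfig("target frame ", targetFrame, " out of range (trajectory has ",
               nF, " frames)")
  targetFrame <- as.integer(targetFrame)
  atoms <- traj@topology@atoms
  residues <- traj@topology@residues
  R <- nrow(residues)
  xyz <- frameCoords(traj, targetFrame)
  heavy <- if (includeHydrogens) rep(TRUE, nrow(atoms))
           else !isHydrogen(atoms$element)
  caIdx <- residues$caAtom
  caXYZ <- xyz[caIdx, , drop = FALSE]
  atomsOfResidue <- split(seq_len(nrow(atoms))[heavy[seq_len(nrow(atoms))]],
                          factor(atoms$residue[heavy], levels = seq_len(R)))

  memberResidues <- vector("list", R)
  memberAtoms <- vector("list", R)
  if (membershipMode == "residueCA") {
    near <- .pointsWithin(caXYZ, caXYZ, radius)
    for (i in seq_len(R)) {
      mres <- sort(unique(c(i, near[[i]])))
      memberResidues[[i]] <- mres
      memberAtoms[[i]] <- sort(unlist(atomsOfResidue[mres], use.names = FALSE))
    }
  } else {
    heavyIdx <- which(heavy)
    near <- .pointsWithin(caXYZ, xyz[heavyIdx, , drop = FALSE], radius)
    for (i in seq_len(R)) {
      matm <- heavyIdx[near[[i]]]
      matm <- sort(unique(c(matm, atomsOfResidue[[i]])))
      memberAtoms[[i]] <- matm
      memberResidues[[i]] <- sort(unique(atoms$residue[matm]))
    }
  }
  new("SphereSet", memberAtoms = memberAtoms,
      memberResidues = memberResidues, radius = radius,
      targetFrame = targetFrame, membershipMode = membershipMode,
      includeHydrogens = includeHydrogens,
      residueIds = residueIdsOf(residues))
}

#' Atoms of one sphere
#' @param spheres a [SphereSet-class]
#' @param i residue index (1-based); omit for the full list
#' @return integer vector of atom-table row indices (or the list of them)
#' @export
memberAtoms <- function(spheres, i = NULL) {
  stopifnot(is(spheres, "SphereSet"))
  if (is.null(i)) spheres@memberAtoms else spheres@memberAtoms[[i]]
}

#' Residues of one sphere
#' @inheritParams memberAtoms
#' @return integer vector of residue indices (or the list of them)
#' @export
memberResidues <- function(spheres, i = NULL) {
  stopifnot(is(spheres, "SphereSet"))
  if (is.null(i)) spheres@memberResidues else spheres@memberResidues[[i]]
}

setMethod("nResidues", "SphereSet", function(x) length(x@memberAtoms))
setMethod("residueIds", "SphereSet", function(x) x@residueIds)

setMethod("show", "SphereSet", function(object) {
  sizes <- vapply(object@memberResidues, length, 1L)
  cat(sprintf(paste0("SphereSet: %d spheres, d = %g A, target frame %d, ",
                     "mode %s\n  member residues per sphere: %d-%d ",
                     "(median %g)\n"),
              length(sizes), object@radius, object@targetFrame,
              object@membershipMode, min(sizes), max(sizes),
              stats::median(sizes)))
})
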