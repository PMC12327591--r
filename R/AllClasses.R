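#' @import methods
NULL

# Required columns of the atom table of a StructureModel. Coordinates are in
# Angstrom; `residue` is the 1-based index into the residue table.
.ATOM_COLS <- c("serial", "name", "element", "altLoc", "resName", "chainId",
                "seqNum", "insCode", "occupancy", "bFactor", "x", "y", "z",
                "residue")

.RESIDUE_COLS <- c("chainId", "seqNum", "insCode", "resName", "caAtom")

#' Validated single-conformer protein structure
#'
#' Holds one cleaned protein model: an atom table (one row per atom, fixed
#' PDB-style fields plus coordinates in Angstrom) and a residue table giving,
#' for every residue, its identity (chain, author sequence number, insertion
#' code, 3-letter name) and the row index of its C-alpha atom in the atom
#' table. Residue order follows file order; atoms of a residue are contiguous.
#'
#' Objects are normally created by [validateStructure()] or
#' [makeStructure()], not by hand.
#'
#' @slot atoms data.frame with columns serial, name, element, altLoc,
#'   resName, chainId, seqNum, insCode, occupancy, bFactor, x, y, z, residue.
#' @slot residues data.frame with columns chainId, seqNum, insCode, resName,
#'   caAtom (index into the atom table).
#' @slot sourceLabel character(1) provenance string.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", residues = "data.frame",
                 sourceLabel = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms; r <- object@residues
  msgs <- character(0)
  if (!all(.ATOM_COLS %in% names(a)))
    msgs <- c(msgs, paste("atom table lacks columns:",
                          paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  if (!all(.RESIDUE_COLS %in% names(r)))
    msgs <- c(msgs, paste("residue table lacks columns:",
                          paste(setdiff(.RESIDUE_COLS, names(r)), collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msgs <- c(msgs, "non-finite atom coordinates")
    if (any(!nzchar(trimws(a$name))))
      msgs <- c(msgs, "empty atom names")
    if (any(a$residue < 1L | a$residue > nrow(r)))
      msgs <- c(msgs, "atom residue index out of range")
  }
  if (nrow(r)) {
    ids <- paste(r$chainId, r$seqNum, r$insCode)
    if (anyDuplicated(ids))
      msgs <- c(msgs, "duplicate residue identifiers")
    ca <- r$caAtom
    if (any(ca < 1L | ca > nrow(a)) ||
        any(trimws(a$name[ca]) != "CA") ||
        any(a$residue[ca] != seq_len(nrow(r))))
      msgs <- c(msgs, "caAtom does not point at the residue's CA atom")
  }
  if (length(msgs)) msgs else TRUE
})

#' Structure validation report
#'
#' Records everything the cleaning step discarded and why: non-protein
#' chains removed whole, heteroatom groups removed by category (ligand, ion,
#' water), individual residues rejected with a reason, free-form format
#' anomalies, and the number of residues retained. Produced by
#' [validateStructure()]; rendered by [writeValidationLog()].
#'
#' @slot removedNonproteinChains character vector of chain identifiers.
#' @slot removedHetero named integer vector with elements ligand, ion, water
#'   (counts of removed heteroatom residue groups).
#' @slot rejectedResidues data.frame with columns chainId, seqNum, insCode,
#'   resName, reason.
#' @slot removedChainResidues data.frame (same identity columns) of ATOM
#'   residues discarded because their whole chain was non-protein.
#' @slot formatAnomalies character vector of messages.
#' @slot retainedResidueCount integer(1).
#' @export
setClass("ValidationReport",
  representation(removedNonproteinChains = "character",
                 removedHetero = "integer",
                 rejectedResidues = "data.frame",
                 removedChainResidues = "data.frame",
                 formatAnomalies = "character",
                 retainedResidueCount = "integer"))

setValidity("ValidationReport", function(object) {
  if (!all(c("ligand", "ion", "water") %in% names(object@removedHetero)))
    return("removedHetero must have named elements ligand, ion, water")
  if (length(object@retainedResidueCount) != 1L || object@retainedResidueCount < 0L)
    return("retainedResidueCount must be a single non-negative integer")
  TRUE
})

#' Molecular dynamics trajectory with a shared topology
#'
#' An ordered sequence of frames over one fixed atom topology. The topology
#' is a cleaned [StructureModel-class]; coordinates are stored as an
#' natoms x 3 x F array in Angstrom, aligned row-for-row with the topology's
#' atom table in every frame.
#'
#' @slot topology StructureModel defining atom identity and order.
#' @slot coords numeric array, dim = c(n_atoms, 3, n_frames).
#' @slot frameLabels character vector of length n_frames (MODEL serials by
#'   default).
#' @export
setClass("Trajectory",
  representation(topology = "StructureModel", coords = "array",
                 frameLabels = "character"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return("frame atom count differs from topology atom count")
  if (d[3] < 1L) return("a trajectory needs at least one frame")
  if (length(object@frameLabels) != d[3])
    return("frameLabels length differs from frame count")
  if (!all(is.finite(object@coords)))
    return("non-finite coordinates")
  TRUE
})

#' Trajectory carrying per-frame B-factor annotation
#'
#' A [Trajectory-class] whose atoms additionally carry one B-factor per
#' frame, used as a coloring channel for high-fluctuation motifs. Created by
#' [annotateFrames()]; [writeTrajectory()] writes the per-frame values into
#' the temperature-factor column.
#'
#' @slot bFactors numeric matrix, n_atoms x n_frames.
#' @export
setClass("AnnotatedTrajectory", contains = "Trajectory",
  representation(bFactors = "matrix"))

setValidity("AnnotatedTrajectory", function(object) {
  d <- dim(object@coords)
  if (!identical(dim(object@bFactors), c(d[1], d[3])))
    return("bFactors must be n_atoms x n_frames")
  TRUE
})

#' Per-residue spatial spheres fixed on the target frame
#'
#' For every residue of a trajectory's topology, the set of atoms (and the
#' residues they belong to) lying within the sphere of radius d around that
#' residue's C-alpha on the target frame. Membership is computed once and
#' never updated on later frames. Created by [buildSpheres()].
#'
#' @slot memberAtoms list of sorted integer vectors (atom-table row indices),
#'   one per residue.
#' @slot memberResidues list of sorted integer vectors (residue indices).
#' @slot radius numeric(1), Angstrom, in [2, 8].
#' @slot targetFrame integer(1), 1-based frame on which membership was fixed.
#' @slot membershipMode "residueCA" (whole residues by C-alpha--C-alpha
#'   distance) or "atomAny" (individual atoms by distance to the C-alpha).
#' @slot includeHydrogens logical(1).
#' @slot residueIds character vector echoing the topology residue labels.
#' @export
setClass("SphereSet",
  representation(memberAtoms = "list", memberResidues = "list",
                 radius = "numeric", targetFrame = "integer",
                 membershipMode = "character", includeHydrogens = "logical",
                 residueIds = "character"))

setValidity("SphereSet", function(object) {
  n <- length(object@memberAtoms)
  if (length(object@memberResidues) != n || length(object@residueIds) != n)
    return("memberAtoms, memberResidues and residueIds lengths differ")
  if (any(vapply(object@memberAtoms, length, 1L) == 0L))
    return("every sphere must contain at least one atom")
  for (i in seq_len(n))
    if (!(i %in% object@memberResidues[[i]]))
      return("a sphere must contain its own center residue")
  if (object@radius < 2 || object@radius > 8)
    return("radius must lie in [2, 8] Angstrom")
  TRUE
})

#' Sphere RMSD score matrix
#'
#' R x (F - 1) matrix of per-sphere RMSD scores in Angstrom: row i, column t
#' holds the deviation of residue i's sphere between frame t and frame t + 1.
#' Column labels name the later frame of each pair ("2" ... "F", 1-based).
#' Created by [scoreTransitions()]; serialized by [writeScoreCSV()].
#'
#' @slot scores numeric matrix, residues x transitions, all entries finite
#'   and non-negative.
#' @slot residueIds character row labels ("chain:seqnum:icode:resname").
#' @slot rmsdMode "raw" or "superposed".
#' @slot params list echoing the sphere parameters used.
#' @export
setClass("ScoreMatrix",
  representation(scores = "matrix", residueIds = "character",
                 rmsdMode = "character", params = "list"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s)) return("scores must be numeric")
  if (nrow(s) != length(object@residueIds))
    return("row count differs from residueIds length")
  if (any(!is.finite(s)) || any(s < 0))
    return("scores must be finite and non-negative")
  TRUE
})

#' Selected high-fluctuation motifs
#'
#' The top-p% (residue, frame transition) cells of a [ScoreMatrix-class],
#' ranked by descending score with a deterministic tie-break. Created by
#' [selectHighFluctuation()].
#'
#' @slot motifs data.frame with columns rank, residue (index), residueId,
#'   transition (t, meaning frame t -> t + 1), score.
#' @slot percentage numeric(1) in (0, 100].
#' @slot candidateCount integer(1), R x (F - 1).
#' @slot selectedCount integer(1), ceiling(p/100 x candidateCount).
#' @export
setClass("MotifSet",
  representation(motifs = "data.frame", percentage = "numeric",
                 candidateCount = "integer", selectedCount = "integer"))

setValidity("MotifSet", function(object) {
  m <- object@motifs
  need <- c("rank", "residue", "residueId", "transition", "score")
  if (!all(need %in% names(m)))
    return(paste("motifs table lacks columns:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (nrow(m)) {
    if (!identical(m$rank, seq_len(nrow(m))))
      return("ranks must be 1..n in order")
    if (is.unsorted(-m$score))
      return("scores must be non-increasing with rank")
  }
  if (object@selectedCount != nrow(m))
    return("selectedCount differs from number of motifs")
  expected <- as.integer(ceiling(object@percentage / 100 * object@candidateCount))
  if (object@candidateCount > 0L && object@selectedCount != expected)
    return("selectedCount must equal ceiling(p/100 * candidateCount)")
  TRUE
})
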