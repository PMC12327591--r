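#' Number of residues
#' @param x a StructureModel, Trajectory or related object
#' @return integer(1)
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Number of trajectory frames
#' @param x a Trajectory
#' @return integer(1)
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Residue identifier labels ("chain:seqnum:icode:resname")
#' @param x a StructureModel, Trajectory, SphereSet or ScoreMatrix
#' @return character vector, one label per residue
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' Atom table accessor
#' @param x a StructureModel or Trajectory
#' @return data.frame, one row per atom
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Residue table accessor
#' @param x a StructureModel or Trajectory
#' @return data.frame, one row per residue
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' Score matrix accessor
#' @param x a ScoreMatrix
#' @return numeric matrix, residues x transitions
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Motif table accessor
#' @param x a MotifSet
#' @return data.frame with columns rank, residue, residueId, transition, score
#' @export
setGeneric("motifTable", function(x) standardGeneric("motifTable"))

#' Write a structure or trajectory as PDB
#' @param x a StructureModel or Trajectory
#' @param path output file path or connection
#' @param ... unused
#' @return invisibly, the path
#' @export
setGeneric("writePDB", function(x, path, ...) standardGeneric("writePDB"))
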