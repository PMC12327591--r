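# Serialization of results: CSV score matrix, TSV motif report, B-factor
# annotated frames, viewer selection strings.

# Flag written into the temperature-factor column in "flag" mode: the
# largest value expressible in the PDB 6.2 fixed-width field.
.FLAG_BFACTOR <- 99.99

#' Write the RMSD score matrix as CSV
#'
#' One data row per residue; the first column is the residue identifier
#' "chain:seqnum:icode:resname" and the remaining columns are the
#' transitions, labelled by the later frame of each pair ("2" ... "F",
#' 1-based). Scores are fixed-point with 4 decimals, in Angstrom; quoting
#' follows RFC 4180.
#'
#' @param matrix a [ScoreMatrix-class].
#' @param path output file path or connection.
#' @return invisibly, the path.
#' @export
writeScoreCSV <- function(matrix, path) {
  stopifnot(is(matrix, "ScoreMatrix"))
  s <- matrix@scores
  header <- paste(c("residue", csvField(colnames(s))), collapse = ",")
  body <- vapply(seq_len(nrow(s)), function(i)
    paste(c(csvField(matrix@residueIds[i]), sprintf("%.4f", s[i, ])),
          collapse = ","), character(1))
  sink <- openTextSink(path)
  on.exit(if (sink$close) close(sink$con))
  writeLines(c(header, body), sink$con)
  invisible(path)
}

#' Write the high-fluctuation motif report
#'
#' Tab-separated summary of the selected motifs, ranks ascending: rank,
#' residue identifier, frame pair ("t-t+1", 1-based), score in Angstrom (4
#' decimals), and the identifiers of all residues belonging to the motif's
#' sphere.
#'
#' @param motifs a [MotifSet-class].
#' @param spheres the [SphereSet-class] the motifs were scored on.
#' @param path output file path or connection.
#' @return invisibly, the path.
#' @export
writeMotifReport <- function(motifs, spheres, path) {
  stopifnot(is(motifs, "MotifSet"), is(spheres, "SphereSet"))
  m <- motifs@motifs
  header <- paste(c("rank", "residue", "frames", "score_A",
                    "sphere_residues"), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(k) {
    members <- spheres@residueIds[spheres@memberResidues[[m$residue[k]]]]
    paste(c(m$rank[k], m$residueId[k],
            sprintf("%d-%d", m$transition[k], m$transition[k] + 1L),
            sprintf("%.4f", m$score[k]),
            paste(members, collapse = ",")), collapse = "\t")
  }, character(1))
  sink <- openTextSink(path)
  on.exit(if (sink$close) close(sink$con))
  writeLines(c(header, body), sink$con)
  invisible(path)
}

#' Annotate trajectory frames with motif flags in the B-factor channel
#'
#' Produces an [AnnotatedTrajectory-class] whose coordinates are identical
#' to the input but whose per-frame temperature factors mark the
#' high-fluctuation motifs, so any molecular viewer can color them: for
#' each selected motif (residue r, transition t), the member atoms of
#' sphere r receive, on the later frame t + 1, the value 99.99 ("flag"
#' mode) or the motif's score in Angstrom ("score" mode; overlaps keep the
#' larger score). All other atoms carry 0. Frame 1 additionally carries the
#' union of all motif spheres as an overview of every flagged region on the
#' input structure.
#'
#' @param traj the source [Trajectory-class].
#' @param motifs a [MotifSet-class] selected from scores on `traj`.
#' @param spheres the matching [SphereSet-class].
#' @param mode "flag" or "score".
#' @return an [AnnotatedTrajectory-class].
#' @export
annotateFrames <- function(traj, motifs, spheres, mode = c("flag", "score")) {
  stopifnot(is(traj, "Trajectory"), is(motifs, "MotifSet"),
            is(spheres, "SphereSet"))
  mode <- match.arg(mode)
  nF <- nFrames(traj)
  nA <- dim(traj@coords)[1]
  if (nResidues(spheres) != nResidues(traj))
    stopSM("sphere set does not match the trajectory")
  m <- motifs@motifs
  if (nrow(m) && (max(m$transition) + 1L > nF || max(m$residue) > nResidues(traj)))
    stopSM("motif set refers to frames or residues outside the trajectory")
  bf <- matrix(0, nA, nF)
  for (k in seq_len(nrow(m))) {
    ix <- spheres@memberAtoms[[m$residue[k]]]
    val <- if (mode == "flag") .FLAG_BFACTOR else m$score[k]
    f <- m$transition[k] + 1L
    bf[ix, f] <- if (mode == "flag") val else pmax(bf[ix, f], val)
    bf[ix, 1L] <- if (mode == "flag") val else pmax(bf[ix, 1L], val)
  }
  new("AnnotatedTrajectory", topology = traj@topology,
      coords = traj@coords, frameLabels = traj@frameLabels, bFactors = bf)
}

#' Viewer selection strings for the annotated frames
#'
#' For every frame that carries motif annotation (the overview frame 1 and
#' the later frame of each selected transition), builds a residue-range
#' selection expression in the generic grammar "chain X and resi a-b",
#' non-contiguous residues joined with "+" (e.g. "resi 4+6"), multiple
#' chains joined with " or ". Residues are deduplicated and sorted.
#'
#' @param motifs a [MotifSet-class].
#' @param spheres the matching [SphereSet-class].
#' @param topology the [StructureModel-class] the residues belong to.
#' @return named character vector, one selection string per annotated
#'   frame, names = 1-based frame numbers; empty for an empty motif set.
#' @export
viewerSelectionStrings <- function(motifs, spheres, topology) {
  stopifnot(is(motifs, "MotifSet"), is(spheres, "SphereSet"),
            is(topology, "StructureModel"))
  m <- motifs@motifs
  if (!nrow(m)) return(character(0))
  res <- topology@residues
  frames <- sort(unique(c(1L, m$transition + 1L)))
  out <- vapply(frames, function(f) {
    rows <- if (f == 1L) seq_len(nrow(m)) else which(m$transition + 1L == f)
    members <- sort(unique(unlist(spheres@memberResidues[m$residue[rows]],
                                  use.names = FALSE)))
    chains <- split(res$seqNum[members], res$chainId[members])
    paste(vapply(names(chains), function(ch)
      sprintf("chain %s and resi %s", ch, compressRanges(chains[[ch]])),
      character(1)), collapse = " or ")
  }, character(1))
  names(out) <- as.character(frames)
  out
}
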