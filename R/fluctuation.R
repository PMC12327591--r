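# Per-sphere frame-to-frame scoring, motif selection, and the per-residue
# RMSF baseline used for method comparison.

#' Score every sphere over every consecutive frame pair
#'
#' For each residue sphere and each transition t (frame t -> t + 1), computes
#' the RMSD between the sphere's member atoms in the two frames, with
#' membership fixed on the target frame. The result is the R x (F - 1) score
#' matrix whose cells are the motif candidates.
#'
#' `rmsdMode = "superposed"` (the default) removes rigid-body motion of the
#' sphere via Kabsch superposition before scoring, so global drift of the
#' molecule does not masquerade as local fluctuation. `rmsdMode = "raw"`
#' scores plain per-atom displacement and is appropriate for trajectories
#' that were already globally fitted.
#'
#' @param traj a [Trajectory-class] with at least 2 frames.
#' @param spheres a [SphereSet-class] from [buildSpheres()] on the same
#'   trajectory.
#' @param rmsdMode "superposed" or "raw".
#' @return a [ScoreMatrix-class].
#' @examples
#' traj <- makeTrajectory(synthSpec(nResidues = 8, nFrames = 4,
#'                                  perturbedWindow = c(4, 5),
#'                                  perturbationSigma = 1))
#' sm <- scoreTransitions(traj, buildSpheres(traj, 4), "superposed")
#' dim(scores(sm))
#' @export
scoreTransitions <- function(traj, spheres,
                             rmsdMode = c("superposed", "raw")) {
  stopifnot(is(traj, "Trajectory"), is(spheres, "SphereSet"))
  rmsdMode <- match.arg(rmsdMode)
  nF <- nFrames(traj)
  if (nF < 2L) stopSM("trajectory too short: at least 2 frames are needed")
  R <- nResidues(traj)
  if (nResidues(spheres) != R)
    stopSM("sphere set does not match the trajectory topology")
  s <- matrix(NA_real_, R, nF - 1L)
  idx <- spheres@memberAtoms
  for (t in seq_len(nF - 1L)) {
    A <- matrix(traj@coords[, , t], ncol = 3L)
    B <- matrix(traj@coords[, , t + 1L], ncol = 3L)
    if (rmsdMode == "raw") {
      disp2 <- rowSums((B - A)^2)
      s[, t] <- vapply(idx, function(ix) sqrt(mean(disp2[ix])), 0)
    } else {
      s[, t] <- vapply(idx, function(ix)
        kabschRMSD(A[ix, , drop = FALSE], B[ix, , drop = FALSE]), 0)
    }
  }
  dimnames(s) <- list(spheres@residueIds,
                      as.character(seq_len(nF - 1L) + 1L))
  new("ScoreMatrix", scores = s, residueIds = spheres@residueIds,
      rmsdMode = rmsdMode,
      params = list(radius = spheres@radius,
                    targetFrame = spheres@targetFrame,
                    membershipMode = spheres@membershipMode,
                    includeHydrogens = spheres@includeHydrogens))
}

#' Select the top-p% high-fluctuation motifs
#'
#' Ranks all R x (F - 1) (residue, transition) cells by descending score and
#' keeps the top ceiling(p/100 x R x (F - 1)) of them, so any p > 0 yields
#' at least one motif. Ties are broken deterministically: higher score
#' first, then earlier transition, then lower residue index; repeated calls
#' on the same inputs give byte-identical results.
#'
#' @param matrix a [ScoreMatrix-class].
#' @param p percentage of candidates to keep, in (0, 100].
#' @return a [MotifSet-class].
#' @export
selectHighFluctuation <- function(matrix, p) {
  stopifnot(is(matrix, "ScoreMatrix"))
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 100)
    stopConfig("motif percentage must lie in (0, 100], got ", format(p))
  s <- matrix@scores
  R <- nrow(s); Tn <- ncol(s)
  cand <- R * Tn
  nsel <- as.integer(ceiling(p / 100 * cand))
  res <- rep(seq_len(R), times = Tn)
  tra <- rep(seq_len(Tn), each = R)
  ord <- order(-as.vector(s), tra, res)
  pick <- ord[seq_len(nsel)]
  motifs <- data.frame(rank = seq_len(nsel),
                       residue = res[pick],
                       residueId = matrix@residueIds[res[pick]],
                       transition = tra[pick],
                       score = as.vector(s)[pick],
                       stringsAsFactors = FALSE)
  new("MotifSet", motifs = motifs, percentage = as.numeric(p),
      candidateCount = as.integer(cand), selectedCount = nsel)
}

#' Per-residue RMSF baseline
#'
#' The traditional flexibility measure used for comparison with the sphere
#' scores: for each residue, the root-mean-square fluctuation of its
#' C-alpha about its mean position across all frames,
#' sqrt(mean_f |r_f - mean(r)|^2).
#'
#' @param traj a [Trajectory-class] with at least 2 frames.
#' @return named numeric vector (one value per residue, Angstrom), names =
#'   residue identifiers.
#' @export
rmsfBaseline <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  nF <- nFrames(traj)
  if (nF < 2L) stopSM("trajectory too short: at least 2 frames are needed")
  ca <- traj@topology@residues$caAtom
  out <- vapply(ca, function(a) {
    X <- t(traj@coords[a, , ])            # F x 3
    mu <- colMeans(X)
    sqrt(mean(rowSums(sweep(X, 2L, mu)^2)))
  }, 0)
  names(out) <- residueIds(traj)
  out
}

setMethod("scores", "ScoreMatrix", function(x) x@scores)
setMethod("residueIds", "ScoreMatrix", function(x) x@residueIds)
setMethod("motifTable", "MotifSet", function(x) x@motifs)

setMethod("show", "ScoreMatrix", function(object) {
  s <- object@scores
  cat(sprintf(paste0("ScoreMatrix: %d residues x %d transitions (%s RMSD, ",
                     "d = %g A)\n  score range: %.4f - %.4f A\n"),
              nrow(s), ncol(s), object@rmsdMode, object@params$radius,
              min(s), max(s)))
})

setMethod("show", "MotifSet", function(object) {
  cat(sprintf(paste0("MotifSet: top %g%% = %d of %d candidate cells\n"),
              object@percentage, object@selectedCount,
              object@candidateCount))
  if (nrow(object@motifs))
    print(utils::head(object@motifs, 5L), row.names = FALSE)
})
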