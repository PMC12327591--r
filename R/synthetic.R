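# Deterministic synthetic structures and trajectories: an idealized
# poly-alanine backbone, optional per-frame rigid-body motion, and optional
# localized Gaussian perturbation of a residue window. These emulate the
# statistical shape the motif heuristic assumes -- a mostly stable fold with
# localized flexibility -- without any physics.

# Local heavy-atom offsets from the C-alpha (Angstrom). Geometric, not
# chemically refined; all five standard alanine heavy atoms are present so
# the generated structures exercise the full validation path.
.ALA_OFFSETS <- rbind(
  N  = c(-1.20,  0.80, 0.00),
  CA = c( 0.00,  0.00, 0.00),
  C  = c( 1.20,  0.80, 0.00),
  O  = c( 1.40,  1.90, 0.30),
  CB = c( 0.00, -1.00, 1.05))

#' Specification for a synthetic structure or trajectory
#'
#' Collects all knobs of the generator; every output is a deterministic
#' function of the spec (including its seed).
#'
#' @param nResidues number of poly-alanine residues (>= 1).
#' @param nFrames number of trajectory frames (>= 1).
#' @param backbone "helix" (rise 1.5 A, 100 degree turn per residue) or
#'   "extended" (3.5 A C-alpha spacing along x).
#' @param translation per-frame rigid translation, 3-vector in Angstrom.
#' @param rotationAngle per-frame rigid rotation in radians, about
#'   `rotationAxis` through the centroid of the base structure.
#' @param rotationAxis 3-vector, default z.
#' @param perturbedWindow NULL, or c(first, last) 1-based residue range to
#'   perturb.
#' @param perturbationSigma standard deviation (Angstrom) of the iid
#'   Gaussian displacement added to every coordinate of every atom in the
#'   perturbed window, redrawn independently on every frame.
#' @param seed integer RNG seed.
#' @return an object of class `synthSpec` (a validated list).
#' @export
synthSpec <- function(nResidues = 30L, nFrames = 5L,
                      backbone = c("helix", "extended"),
                      translation = c(0, 0, 0), rotationAngle = 0,
                      rotationAxis = c(0, 0, 1),
                      perturbedWindow = NULL, perturbationSigma = 0,
                      seed = 1L) {
  backbone <- match.arg(backbone)
  if (!is.numeric(nResidues) || nResidues < 1L)
    stopConfig("nResidues must be >= 1")
  if (!is.numeric(nFrames) || nFrames < 1L)
    stopConfig("nFrames must be >= 1")
  if (length(translation) != 3L || !all(is.finite(translation)))
    stopConfig("translation must be a finite 3-vector")
  if (!is.null(perturbedWindow)) {
    if (length(perturbedWindow) != 2L ||
        perturbedWindow[1L] > perturbedWindow[2L] ||
        perturbedWindow[1L] < 1L || perturbedWindow[2L] > nResidues)
      stopConfig("perturbedWindow must be c(first, last) within 1..nResidues")
    perturbedWindow <- as.integer(perturbedWindow)
  }
  if (perturbationSigma < 0) stopConfig("perturbationSigma must be >= 0")
  structure(list(nResidues = as.integer(nResidues),
                 nFrames = as.integer(nFrames), backbone = backbone,
                 translation = as.numeric(translation),
                 rotationAngle = as.numeric(rotationAngle),
                 rotationAxis = as.numeric(rotationAxis),
                 perturbedWindow = perturbedWindow,
                 perturbationSigma = as.numeric(perturbationSigma),
                 seed = as.integer(seed)),
            class = "synthSpec")
}

#' Generate an idealized poly-alanine structure
#'
#' Places one alanine (atoms N, CA, C, O, CB) per residue on an idealized
#' backbone: alpha-helical C-alpha trace (radius 2.3 A, rise 1.5 A, 100
#' degree turn per residue) or extended trace (3.5 A C-alpha spacing).
#' Output is deterministic and passes [validateStructure()] with no issues.
#'
#' @param spec a [synthSpec()].
#' @return a [StructureModel-class].
#' @export
makeStructure <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  n <- spec$nResidues
  i <- seq_len(n) - 1L
  ca <- if (spec$backbone == "extended") {
    cbind(3.5 * i, 0, 0)
  } else {
    th <- i * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
  }
  nAtoms <- nrow(.ALA_OFFSETS)
  xyz <- ca[rep(seq_len(n), each = nAtoms), , drop = FALSE] +
    .ALA_OFFSETS[rep(seq_len(nAtoms), times = n), , drop = FALSE]
  atoms <- data.frame(
    serial = seq_len(n * nAtoms),
    name = rep(rownames(.ALA_OFFSETS), times = n),
    element = rep(c("N", "C", "C", "O", "C"), times = n),
    altLoc = " ",
    resName = "ALA",
    chainId = "A",
    seqNum = rep(seq_len(n), each = nAtoms),
    insCode = " ",
    occupancy = 1,
    bFactor = 0,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    residue = rep(seq_len(n), each = nAtoms),
    stringsAsFactors = FALSE)
  residues <- data.frame(
    chainId = "A", seqNum = seq_len(n), insCode = " ", resName = "ALA",
    caAtom = (seq_len(n) - 1L) * nAtoms + 2L,
    stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms, residues = residues,
      sourceLabel = sprintf("synthetic:%s:%d", spec$backbone, n))
}

.rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c. <- cos(angle); s <- sin(angle); C <- 1 - c.
  rbind(c(c. + a[1]^2 * C, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s),
        c(a[2] * a[1] * C + a[3] * s, c. + a[2]^2 * C, a[2] * a[3] * C - a[1] * s),
        c(a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, c. + a[3]^2 * C))
}

#' Generate a synthetic trajectory
#'
#' Frame k carries the base structure transformed by (k - 1) applications
#' of the per-frame rigid motion (rotation about the base centroid, then
#' translation); atoms of residues inside `perturbedWindow` are
#' additionally displaced by iid Gaussian noise of standard deviation
#' `perturbationSigma` per coordinate, redrawn independently on every frame
#' (including the first) from the seeded generator. The topology is
#' constant across frames and every output byte is determined by the spec.
#'
#' @param spec a [synthSpec()].
#' @return a [Trajectory-class].
#' @examples
#' traj <- makeTrajectory(synthSpec(nResidues = 10, nFrames = 3,
#'                                  translation = c(1, 0, 0)))
#' nFrames(traj)
#' @export
makeTrajectory <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  base <- makeStructure(spec)
  X0 <- cbind(base@atoms$x, base@atoms$y, base@atoms$z)
  ctr <- colMeans(X0)
  Rm <- .rotationMatrix(spec$rotationAxis, spec$rotationAngle)
  doRotate <- spec$rotationAngle != 0
  perturbed <- if (is.null(spec$perturbedWindow)) integer(0) else
    which(base@atoms$residue >= spec$perturbedWindow[1L] &
          base@atoms$residue <= spec$perturbedWindow[2L])

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(spec$seed)

  frames <- vector("list", spec$nFrames)
  X <- X0
  for (k in seq_len(spec$nFrames)) {
    if (k > 1L) {
      if (doRotate)
        X <- sweep(sweep(X, 2L, ctr) %*% t(Rm), 2L, ctr, "+")
      X <- sweep(X, 2L, spec$translation, "+")
    }
    Xk <- X
    if (length(perturbed) && spec$perturbationSigma > 0)
      Xk[perturbed, ] <- Xk[perturbed, ] +
        matrix(stats::rnorm(3L * length(perturbed),
                            sd = spec$perturbationSigma),
               ncol = 3L)
    frames[[k]] <- Xk
  }
  newTrajectory(base, frames)
}
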