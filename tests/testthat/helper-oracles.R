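# Independent oracles, deliberately naive: no spatial index, no closed-form
# superposition, explicit loops.

# Brute-force O(n^2) neighborhood scan over C-alpha positions.
bruteSphereResidues <- function(caXYZ, d) {
  n <- nrow(caXYZ)
  lapply(seq_len(n), function(i) {
    keep <- integer(0)
    for (j in seq_len(n)) {
      if (sqrt(sum((caXYZ[i, ] - caXYZ[j, ])^2)) <= d)
        keep <- c(keep, j)
    }
    keep
  })
}

# Explicit per-atom loop RMSD (no vectorized shortcut).
directRawRMSD <- function(A, B) {
  total <- 0
  for (i in seq_len(nrow(A)))
    total <- total + sum((A[i, ] - B[i, ])^2)
  sqrt(total / nrow(A))
}

.rotX <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
.rotY <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
.rotZ <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
eulerRot <- function(a) .rotZ(a[3]) %*% .rotY(a[2]) %*% .rotX(a[1])

# Superposed RMSD by rotational grid search: coarse Euler-angle grid over
# SO(3), then iterative local refinement of the best starts down to a 1e-3
# rad step. Independent of the SVD route.
gridSearchRMSD <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  f <- function(a) {
    R <- eulerRot(a)
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  coarse <- expand.grid(a1 = seq(0, 2 * pi, by = 0.35),
                        a2 = seq(0, pi, by = 0.35),
                        a3 = seq(0, 2 * pi, by = 0.35))
  vals <- apply(coarse, 1, f)
  starts <- coarse[order(vals)[1:8], , drop = FALSE]
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    a <- as.numeric(starts[s, ])
    step <- 0.35
    v <- f(a)
    while (step > 5e-4) {
      improved <- FALSE
      for (dim in 1:3) for (sgn in c(-1, 1)) {
        cand <- a
        cand[dim] <- cand[dim] + sgn * step
        cv <- f(cand)
        if (cv < v) { a <- cand; v <- cv; improved <- TRUE }
      }
      if (!improved) step <- step / 2
    }
    if (v < best) best <- v
  }
  best
}

# Two-pass per-residue C-alpha RMSF: explicit mean, then explicit deviation.
twoPassRMSF <- function(traj) {
  ca <- residueTable(traj)$caAtom
  nF <- nFrames(traj)
  vapply(ca, function(a) {
    mu <- c(0, 0, 0)
    for (f in seq_len(nF)) mu <- mu + traj@coords[a, , f]
    mu <- mu / nF
    dev <- 0
    for (f in seq_len(nF)) dev <- dev + sum((traj@coords[a, , f] - mu)^2)
    sqrt(dev / nF)
  }, 0)
}
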