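# RMSD primitives. Both operate on paired n x 3 coordinate matrices in
# Angstrom; pairing is index-for-index and no re-matching is attempted.

.asXYZ <- function(m, what) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 3L)
    stopSM(what, " must be an n x 3 numeric matrix")
  m
}

#' Raw (unsuperposed) RMSD between paired coordinate sets
#'
#' sqrt(mean squared Euclidean displacement) over paired atoms, with no
#' superposition: rigid-body motion between the two sets contributes fully
#' to the score.
#'
#' @param A,B n x 3 numeric matrices, paired row-for-row, n >= 1.
#' @return RMSD in Angstrom.
#' @examples
#' A <- matrix(rnorm(12), 4, 3)
#' rawRMSD(A, A + rep(c(3, 4, 0), each = 4))  # 5: every displacement is 5 A
#' @export
rawRMSD <- function(A, B) {
  A <- .asXYZ(A, "A"); B <- .asXYZ(B, "B")
  if (nrow(A) != nrow(B)) stopSM("coordinate sets differ in length")
  if (!nrow(A)) stopSM("coordinate sets are empty")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Kabsch-superposed RMSD between paired coordinate sets
#'
#' The minimum RMSD over all proper rotations and translations of B onto A:
#' both sets are centered on their centroids and the optimal rotation is
#' obtained in closed form from the SVD of the 3 x 3 cross-covariance
#' matrix, with the determinant sign corrected so reflections are never
#' used. Rigid-body motion is invisible to this score, and the result never
#' exceeds [rawRMSD()].
#'
#' @param A,B n x 3 numeric matrices, paired row-for-row, n >= 1.
#' @return superposed RMSD in Angstrom.
#' @export
kabschRMSD <- function(A, B) {
  A <- .asXYZ(A, "A"); B <- .asXYZ(B, "B")
  if (nrow(A) != nrow(B)) stopSM("coordinate sets differ in length")
  if (!nrow(A)) stopSM("coordinate sets are empty")
  n <- nrow(A)
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  C <- crossprod(Bc, Ac)                 # 3 x 3 cross-covariance
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # rotates Bc onto Ac
  sqrt(max(0, mean(rowSums((Ac - Bc %*% R)^2))))
}
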