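#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rigid transform (rotation + translation, reflections
#' forbidden) that minimizes the r.m.s.d. between two point sets matched by
#' label, via singular value decomposition of the covariance matrix. This is
#' the superposition engine behind water transfer onto reference dinucleotides
#' and block overlay at prediction time.
#'
#' @param moving n x 3 matrix of coordinates to be transformed.
#' @param target n x 3 matrix of coordinates to superpose onto; row i of
#'   `moving` corresponds to row i of `target`.
#' @param weights optional nonnegative per-pair weights (default equal).
#' @return list with elements `rotation` (3 x 3 proper rotation matrix),
#'   `translation` (3-vector), and `rmsd` (Angstrom). The transform maps a
#'   coordinate x as `rotation %*% x + translation`.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' fit <- kabsch_superpose(a, a)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(moving, target, weights = NULL) {
  moving <- as.matrix(moving)
  target <- as.matrix(target)
  stopifnot(ncol(moving) == 3L, ncol(target) == 3L)
  n <- nrow(moving)
  if (n != nrow(target)) stop("point sets differ in size")
  if (n < 3L) stop("degenerate superposition: need at least 3 point pairs")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)

  cm <- colSums(moving * w)
  ct <- colSums(target * w)
  mm <- sweep(moving, 2L, cm)
  tt <- sweep(target, 2L, ct)

  h <- t(mm * w) %*% tt
  sv <- svd(h)
  if (min(sv$d) < 1e-12 && sv$d[2L] < 1e-12) {
    stop("degenerate superposition: collinear or coincident points")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ct - as.vector(rot %*% cm)

  moved <- apply_rigid(moving, rot, trans)
  rmsd <- sqrt(sum(w * rowSums((moved - target)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param fit result of [kabsch_superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, fit) {
  apply_rigid(as.matrix(xyz), fit$rotation, fit$translation)
}

#' r.m.s.d. after optimal superposition
#'
#' @inheritParams kabsch_superpose
#' @return r.m.s.d. in Angstrom.
#' @export
superposed_rmsd <- function(moving, target) {
  kabsch_superpose(moving, target)$rmsd
}
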