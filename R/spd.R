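# Affine-invariant Riemannian geometry on symmetric positive definite
# matrices.  The numerical work lives in compiled code; these wrappers
# add validation.

check_spd <- function(A, name = "matrix", tol = 1e-10) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("'%s' must be square", name)
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A))))
    stopf("'%s' is not symmetric", name)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("'%s' is not positive definite (min eigenvalue %.3e)", name, min(ev))
  invisible(A)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `d(A, B) = || log(A^{-1/2} B A^{-1/2}) ||_F`, invariant under
#' congruence transformations `A -> W A W'` for any invertible `W`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Non-negative scalar.
#' @export
airm_distance <- function(A, B) {
  check_spd(A, "A"); check_spd(B, "B")
  if (!all(dim(A) == dim(B))) stopf("dimension mismatch")
  airm_distance_cpp(A, B)
}

#' Fréchet (geometric) mean of SPD matrices
#'
#' Fixed-point iteration: at the current estimate, average the matrix
#' logarithms in the tangent space and map back through the exponential,
#' until the tangent-space step norm falls below `tol`.  Initialised at
#' the arithmetic mean.
#'
#' @param mats List of SPD matrices, or a `D x D x n` array.
#' @param tol Convergence tolerance on the tangent-step Frobenius norm.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return The mean SPD matrix, with attributes `iterations` and
#'   `step_norm`.
#' @export
frechet_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  cube <- as_spd_cube(mats)
  res <- frechet_mean_cpp(cube, tol, max_iter)
  if (!res$converged)
    stopf("Fréchet mean did not converge in %d iterations (step norm %.3e)",
          max_iter, res$step_norm)
  structure(res$mean, iterations = res$iterations, step_norm = res$step_norm)
}

#' Tangent-space coordinates of SPD matrices
#'
#' Maps `C` to `log(ref^{-1/2} C ref^{-1/2})` and vectorises the upper
#' triangle with off-diagonal entries scaled by `sqrt(2)`, so the
#' Euclidean norm of the vector equals the Riemannian distance from
#' `ref` to `C`.  The vector length is `D(D+1)/2`, the dimension of the
#' SPD manifold.
#'
#' @param mats One SPD matrix, a list of them, or a `D x D x n` array.
#' @param ref SPD reference matrix (usually the Fréchet mean).
#' @return A matrix with one row per input matrix.
#' @export
tangent_map <- function(mats, ref) {
  check_spd(ref, "ref")
  cube <- as_spd_cube(mats)
  if (dim(cube)[1] != nrow(ref)) stopf("dimension mismatch with 'ref'")
  tangent_map_cpp(cube, ref)
}

#' Inverse tangent map (exponential map at a reference)
#'
#' @param v Tangent vector as produced by [tangent_map()].
#' @param ref SPD reference matrix.
#' @return The reconstructed SPD matrix.
#' @export
tangent_unmap <- function(v, ref) {
  check_spd(ref, "ref")
  D <- nrow(ref)
  if (length(v) != D * (D + 1) / 2) stopf("tangent vector length mismatch")
  tangent_unmap_cpp(matrix(v, nrow = 1), ref)
}

as_spd_cube <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3) return(mats)
  if (is.matrix(mats)) return(array(mats, c(dim(mats), 1)))
  if (is.list(mats)) {
    if (length(mats) == 0) stopf("empty set of matrices")
    D <- nrow(mats[[1]])
    cube <- array(NA_real_, c(D, D, length(mats)))
    for (i in seq_along(mats)) cube[, , i] <- mats[[i]]
    return(cube)
  }
  stopf("expected a matrix, list of matrices, or 3-d array")
}
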