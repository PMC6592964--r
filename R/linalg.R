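# Shared SVD conventions.  Every pseudoinverse and every rank decision in the
# package goes through these two functions so that "rank" always means the
# same thing: singular values at or below max(dim) * eps * sigma_max are zero.

svd_tol <- function(d, dims) max(dims) * .Machine$double.eps * max(d, 0)

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse with the cutoff `max(dim(A)) * .Machine$double.eps
#' * sigma_max`.  Singular values at or below the cutoff are treated as zero,
#' which makes rank decisions reproducible across the whole package (the same
#' cutoff is used by [mat_rank()]).
#'
#' @param A numeric matrix.
#' @return The pseudoinverse, an `ncol(A) x nrow(A)` matrix.
#' @seealso [mat_rank()]
#' @export
#' @examples
#' A <- matrix(rnorm(12), 3, 4)
#' max(abs(A %*% pinv(A) %*% A - A)) < 1e-12
pinv <- function(A) {
  A <- as.matrix(A)
  s <- svd(A)
  keep <- s$d > svd_tol(s$d, dim(A))
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Numerical matrix rank
#'
#' Number of singular values above the shared SVD cutoff used by [pinv()].
#'
#' @param A numeric matrix.
#' @return Integer rank.
#' @export
mat_rank <- function(A) {
  A <- as.matrix(A)
  d <- svd(A)$d
  sum(d > svd_tol(d, dim(A)))
}

# Extract a plain gain matrix from a ur_leadfield or a matrix-like object.
as_gain <- function(K) {
  if (inherits(K, "ur_leadfield")) K$gain else as.matrix(K)
}

# Extract an operator matrix from ur_operator / ur_weights / matrix.
as_operator_matrix <- function(T_o) {
  if (inherits(T_o, "ur_operator")) {
    T_o$matrix
  } else if (inherits(T_o, "ur_weights")) {
    ur_operator(T_o)$matrix
  } else {
    as.matrix(T_o)
  }
}
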