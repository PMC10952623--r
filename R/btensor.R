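## b-tensor container and shape algebra. All b-tensors at the user interface
## are expressed in ms/um^2 (so that B:D is dimensionless when D is in
## um^2/ms); waveform code works in SI and converts on construction.

#' Construct a b-tensor from its 3x3 matrix
#'
#' @param matrix symmetric positive semidefinite 3x3 matrix, ms/um^2.
#' @param tol relative tolerance for symmetry and eigenvalue checks.
#' @return object of class `btensor` with fields `matrix`, `b` (trace),
#'   `b_delta` (shape, in `[-0.5, 1]`, `NA` for `b = 0`) and
#'   `principal_axis` (unit eigenvector of the eigenvalue farthest from
#'   `b/3`).
#' @export
btensor <- function(matrix, tol = 1e-8) {
  v <- to_voigt6(matrix, tol = tol)   # validates symmetry
  M <- from_voigt6(v)
  b <- sum(diag(M))
  eig <- eigen(M, symmetric = TRUE)
  if (min(eig$values) < -1e-12 * max(abs(b), max(abs(eig$values))))
    stop_validation("b-tensor is not positive semidefinite")
  if (b > 0) {
    i <- pick_unique_eigenvalue(eig$values, b)
    b_delta <- (3 * eig$values[i] / b - 1) / 2
    axis <- eig$vectors[, i]
  } else {
    b_delta <- NA_real_
    axis <- c(0, 0, 1)
  }
  structure(list(matrix = M, b = b, b_delta = b_delta,
                 principal_axis = axis),
            class = "btensor")
}

# Index of the eigenvalue farthest from b/3; ties resolved toward the larger
# eigenvalue (eigen() sorts decreasing, so which.max picks it first).
pick_unique_eigenvalue <- function(values, b) {
  dev <- abs(values - b / 3)
  which.max(dev)
}

#' Build an axisymmetric b-tensor from scalar b, shape, and symmetry axis
#'
#' Eigenvalues are `b/3 (1 + 2 b_delta)` along `axis` and `b/3 (1 - b_delta)`
#' on the two orthogonal axes; `b_delta = 1` is linear (LTE), `-0.5` planar
#' (PTE), `0` spherical (STE) encoding.
#'
#' @param b scalar b-value (ms/um^2), nonnegative.
#' @param b_delta shape parameter in `[-0.5, 1]`.
#' @param axis symmetry axis (any nonzero 3-vector; normalized internally).
#' @return a [btensor()].
#' @export
btensor_from_shape <- function(b, b_delta, axis = c(0, 0, 1)) {
  if (b < 0) stop_validation("b must be nonnegative")
  if (b_delta < -0.5 - 1e-9 || b_delta > 1 + 1e-9)
    stop_validation("b_delta must lie in [-0.5, 1]")
  n <- unit_vector(axis)
  lam_ax <- b / 3 * (1 + 2 * b_delta)
  lam_perp <- b / 3 * (1 - b_delta)
  M <- lam_perp * diag(3) + (lam_ax - lam_perp) * tcrossprod(n)
  btensor(M)
}

#' Shape parameter of a b-tensor
#'
#' `b_delta = (3 lambda_u / b - 1) / 2` where `lambda_u` is the eigenvalue
#' farthest from `b/3` (ties go to the larger eigenvalue). Returns 1 for
#' linear, -0.5 for planar and 0 for spherical encoding.
#'
#' @param B a [btensor()] or symmetric 3x3 matrix.
#' @return scalar shape parameter.
#' @export
btensor_shape <- function(B) {
  if (!inherits(B, "btensor")) B <- btensor(B)
  if (B$b <= 0) stop_validation("b-tensor shape is undefined for b = 0")
  B$b_delta
}

#' @export
print.btensor <- function(x, ...) {
  cat(sprintf("b-tensor: b = %.4g ms/um^2, b_delta = %.4g\n", x$b, x$b_delta))
  cat(sprintf("principal axis: [%.3f, %.3f, %.3f]\n",
              x$principal_axis[1], x$principal_axis[2], x$principal_axis[3]))
  invisible(x)
}

# Fractional anisotropy of a 3x3 diffusion tensor.
fa_of_tensor <- function(D) {
  lam <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  md <- mean(lam)
  num <- sum((lam - md)^2)
  den <- sum(lam^2)
  if (den <= 0) return(0)
  sqrt(1.5 * num / den)
}
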