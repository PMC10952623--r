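## Voigt-notation conventions shared by the fitting, simulation, and
## waveform code. Off-diagonal entries carry a factor sqrt(2) so that the
## Euclidean inner product of two Voigt vectors equals the full double
## contraction (sum over all index pairs) of the tensors they represent.
## Voigt6 order: [xx, yy, zz, sqrt2*yz, sqrt2*xz, sqrt2*xy].
## Voigt21: diagonal of the symmetric 6x6 matrix first (6 entries), then the
## strict upper triangle in column-major order scaled by sqrt(2) (15 entries).

#' Convert a symmetric 3x3 matrix to its 6-component Voigt vector
#'
#' Uses the normalized convention `[xx, yy, zz, sqrt(2) yz, sqrt(2) xz,
#' sqrt(2) xy]` so that `sum(to_voigt6(A) * to_voigt6(B))` equals the double
#' contraction `sum(A * B)`.
#'
#' @param D symmetric 3x3 numeric matrix.
#' @param tol relative asymmetry tolerated before an error is raised.
#' @return numeric vector of length 6.
#' @export
to_voigt6 <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || !all(dim(D) == c(3L, 3L)))
    stop_validation("expected a 3x3 matrix")
  scale <- max(abs(D), 1e-300)
  if (max(abs(D - t(D))) > tol * scale)
    stop_validation("matrix is not symmetric within tolerance")
  D <- (D + t(D)) / 2
  c(D[1, 1], D[2, 2], D[3, 3],
    sqrt(2) * D[2, 3], sqrt(2) * D[1, 3], sqrt(2) * D[1, 2])
}

#' Inverse of [to_voigt6()]
#' @param v numeric vector of length 6 in the normalized Voigt convention.
#' @return symmetric 3x3 matrix.
#' @export
from_voigt6 <- function(v) {
  stopifnot(length(v) == 6L)
  s <- 1 / sqrt(2)
  matrix(c(v[1],     s * v[6], s * v[5],
           s * v[6], v[2],     s * v[4],
           s * v[5], s * v[4], v[3]), 3L, 3L)
}

#' Convert a symmetric 6x6 matrix (fourth-order tensor in Voigt basis) to a
#' 21-vector
#'
#' Diagonal entries come first, then the strict upper triangle scaled by
#' sqrt(2), so that inner products of 21-vectors equal full fourth-order
#' double contractions.
#'
#' @param M symmetric 6x6 numeric matrix.
#' @param tol relative asymmetry tolerance.
#' @return numeric vector of length 21.
#' @export
to_voigt21 <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || !all(dim(M) == c(6L, 6L)))
    stop_validation("expected a 6x6 matrix")
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > tol * scale)
    stop_validation("matrix is not symmetric within tolerance")
  M <- (M + t(M)) / 2
  c(diag(M), sqrt(2) * M[upper.tri(M)])
}

#' Inverse of [to_voigt21()]
#' @param v numeric vector of length 21.
#' @return symmetric 6x6 matrix.
#' @export
from_voigt21 <- function(v) {
  stopifnot(length(v) == 21L)
  M <- matrix(0, 6L, 6L)
  diag(M) <- v[1:6]
  M[upper.tri(M)] <- v[7:21] / sqrt(2)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' Isotropic fourth-order bases used by the metric definitions
#'
#' Returns the bulk, shear and total isotropic projection tensors as 6x6
#' matrices in the normalized Voigt basis. For any symmetric `X` with Voigt
#' vector `x`: `t(x) %*% bulk %*% x = tr(X)^2 / 9`,
#' `t(x) %*% iso4 %*% x = sum(X^2) / 3`, and `shear = iso4 - bulk`.
#'
#' @return list with elements `bulk`, `iso4`, `shear` (6x6 matrices).
#' @export
iso_bases <- function() {
  e <- to_voigt6(diag(3))
  bulk <- tcrossprod(e) / 9
  iso4 <- diag(6) / 3
  list(bulk = bulk, iso4 = iso4, shear = iso4 - bulk)
}
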