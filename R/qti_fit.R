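## Covariance-tensor ("QTI") fit: the log-signal is linear in
## [ln S0, <D> (Voigt6), C (Voigt21)] with design row
## [1, -b6, 0.5 * voigt21(b6 b6^T)], so that
## ln S = ln S0 - B:<D> + 0.5 * (B ox B) :: C.

#' Design row of the covariance-tensor signal representation
#'
#' @param B a [btensor()] or symmetric 3x3 matrix (ms/um^2).
#' @return numeric vector of length 28 such that
#'   `row %*% c(log(s0), mean_tensor, covariance)` is the log-signal.
#' @export
design_row <- function(B) {
  if (inherits(B, "btensor")) B <- B$matrix
  b6 <- to_voigt6(B)
  c(1, -b6, 0.5 * to_voigt21(tcrossprod(b6)))
}

#' Full design matrix of an acquisition scheme
#' @param scheme an `acquisition_scheme`.
#' @return `n x 28` matrix of design rows.
#' @export
qti_design <- function(scheme) {
  V <- scheme_voigt6(scheme)
  t(apply(V, 1, function(v) c(1, -v, 0.5 * to_voigt21(tcrossprod(v)))))
}

#' Container for fitted covariance-model coefficients
#'
#' @param s0 non-diffusion-weighted signal.
#' @param mean_tensor Voigt6 vector of the mean diffusion tensor (um^2/ms).
#' @param covariance Voigt21 vector of the fourth-order covariance tensor
#'   ((um^2/ms)^2).
#' @param diagnostics optional list (condition number, residual norm,
#'   number of samples used).
#' @return object of class `qti_coefficients`.
#' @export
qti_coefficients <- function(s0, mean_tensor, covariance,
                             diagnostics = NULL) {
  stopifnot(length(mean_tensor) == 6L, length(covariance) == 21L)
  structure(list(s0 = s0, mean_tensor = as.numeric(mean_tensor),
                 covariance = as.numeric(covariance),
                 diagnostics = diagnostics),
            class = "qti_coefficients")
}

#' @export
print.qti_coefficients <- function(x, ...) {
  cat(sprintf("QTI coefficients: S0 = %.4g, MD = %.4g um^2/ms\n",
              x$s0, mean(x$mean_tensor[1:3])))
  if (!is.null(x$diagnostics))
    cat(sprintf("  n_used = %d, condition = %.3g, residual = %.3g\n",
                x$diagnostics$n_used, x$diagnostics$condition,
                x$diagnostics$residual_norm))
  invisible(x)
}

check_identifiable <- function(scheme) {
  e <- scheme$entries
  if (length(unique(round(e$b_delta, 6))) < 2)
    stop_validation("QTI fit is not identifiable: need at least 2 distinct ",
                    "b-tensor shapes (b_delta values)")
  if (length(unique(round(e$b, 9))) < 2)
    stop_validation("QTI fit is not identifiable: need at least 2 shells")
}

#' Fit the covariance-tensor model to diffusion-weighted signals
#'
#' Weighted linear least squares on the log-signal; default weights are the
#' squared signals (the first-order correction for log-domain noise).
#' Nonpositive signals are excluded per voxel and the fit requires at least
#' 28 usable samples spanning two b-tensor shapes and two shells.
#'
#' @param signals numeric vector (one voxel) or `n_voxels x n_volumes`
#'   matrix.
#' @param scheme the `acquisition_scheme` describing the volumes.
#' @param weighting `"signal2"` (default), `"none"`, or `"irls"`
#'   (iteratively reweighted with fitted signals, 3 iterations).
#' @param min_signals minimum number of usable samples (default 28, the
#'   parameter count).
#' @return a `qti_coefficients` object for vector input, or a list of them
#'   (with `NULL` for voxels that failed) for matrix input.
#' @export
fit_qti <- function(signals, scheme, weighting = c("signal2", "none", "irls"),
                    min_signals = 28L) {
  weighting <- match.arg(weighting)
  check_identifiable(scheme)
  X <- qti_design(scheme)
  if (is.matrix(signals)) {
    if (ncol(signals) != nrow(X))
      stop_validation("signal matrix has ", ncol(signals),
                      " volumes but the scheme lists ", nrow(X))
    out <- vector("list", nrow(signals))
    for (v in seq_len(nrow(signals))) {
      out[[v]] <- tryCatch(
        fit_qti_voxel(signals[v, ], X, weighting, min_signals),
        error = function(e) NULL)
    }
    if (any(vapply(out, is.null, logical(1))))
      warning(sum(vapply(out, is.null, logical(1))), " voxel(s) failed to fit")
    return(out)
  }
  if (length(signals) != nrow(X))
    stop_validation("got ", length(signals), " signals but the scheme lists ",
                    nrow(X), " volumes")
  fit_qti_voxel(as.numeric(signals), X, weighting, min_signals)
}

fit_qti_voxel <- function(s, X, weighting, min_signals) {
  keep <- is.finite(s) & s > 0
  n_used <- sum(keep)
  if (n_used < min_signals)
    stop_validation("only ", n_used, " positive signals; need at least ",
                    min_signals)
  Xk <- X[keep, , drop = FALSE]
  y <- log(s[keep])
  w <- switch(weighting, none = rep(1, n_used), s[keep]^2)
  beta <- solve_wls(Xk, y, w)
  if (weighting == "irls") {
    for (it in 1:3) {
      w <- exp(2 * as.numeric(Xk %*% beta))
      beta <- solve_wls(Xk, y, w)
    }
  }
  sw <- sqrt(w)
  sv <- svd(Xk * sw, nu = 0, nv = 0)$d
  resid <- sqrt(sum(((y - as.numeric(Xk %*% beta)) * sw)^2))
  qti_coefficients(
    s0 = exp(beta[1]),
    mean_tensor = beta[2:7],
    covariance = beta[8:28],
    diagnostics = list(condition = sv[1] / sv[length(sv)],
                       residual_norm = resid, n_used = n_used))
}

solve_wls <- function(X, y, w) {
  sw <- sqrt(w)
  dec <- qr(X * sw)
  if (dec$rank < ncol(X))
    stop_validation("design matrix is rank deficient (rank ", dec$rank,
                    " of ", ncol(X), "); add directions, shells, or shapes")
  qr.coef(dec, y * sw)
}
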