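## Powder averaging and the powder-averaged kurtosis model
##   S(b) ~= S0 exp(-b MD + (1/6) b^2 MD^2 (MKi + b_delta^2 MKa)),
## which separates isotropic from anisotropic kurtosis through the b-tensor
## shape dependence of the b^2 term.

#' Powder-average signals over rotations
#'
#' Arithmetic mean of the signal across rotations for every (shape, shell)
#' combination of the scheme.
#'
#' @param signals numeric vector, one value per scheme entry.
#' @param scheme an `acquisition_scheme`.
#' @return data frame with columns `shape`, `b`, `b_delta`, `n`, `signal`.
#' @export
powder_average <- function(signals, scheme) {
  e <- scheme$entries
  if (length(signals) != nrow(e))
    stop_validation("got ", length(signals), " signals but the scheme lists ",
                    nrow(e), " volumes")
  agg <- aggregate(list(signal = signals),
                   by = list(shape = e$shape, b = round(e$b, 9),
                             b_delta = e$b_delta), FUN = mean)
  cnt <- aggregate(list(n = signals),
                   by = list(shape = e$shape, b = round(e$b, 9),
                             b_delta = e$b_delta), FUN = length)
  out <- merge(agg, cnt, by = c("shape", "b", "b_delta"))
  out <- out[order(out$shape, out$b), c("shape", "b", "b_delta", "n",
                                        "signal")]
  rownames(out) <- NULL
  out
}

#' Fit the powder-averaged kurtosis model
#'
#' Nonlinear least squares on the log powder-averaged signal with an
#' analytic Jacobian, initialized from a log-linear fit to the two lowest
#' shells. Separating MKi from MKa requires at least two shapes with
#' distinct `b_delta^2` and at least three shells.
#'
#' @param powder data frame as produced by [powder_average()].
#' @return list with `S0`, `MD` (um^2/ms), `MKi`, `MKa`, `MKt`, the
#'   parameter covariance matrix `vcov`, and the `nls.lm` fit object.
#' @export
fit_powder_model <- function(powder) {
  req <- c("b", "b_delta", "signal")
  if (!all(req %in% names(powder)))
    stop_validation("powder table must have columns b, b_delta, signal")
  keep <- is.finite(powder$signal) & powder$signal > 0
  powder <- powder[keep, , drop = FALSE]
  if (length(unique(round(powder$b_delta^2, 9))) < 2)
    stop_validation("MKi and MKa are not separable from a single b-tensor ",
                    "shape; need >= 2 distinct b_delta^2 values")
  if (length(unique(round(powder$b, 9))) < 3)
    stop_validation("need at least 3 shells to fit the powder model")
  b <- powder$b
  bd2 <- powder$b_delta^2
  y <- log(powder$signal)

  model <- function(p) p[1] - b * p[2] +
    (1 / 6) * b^2 * p[2]^2 * (p[3] + bd2 * p[4])
  resid_fn <- function(p) model(p) - y
  jac_fn <- function(p) {
    cbind(1,
          -b + (1 / 3) * b^2 * p[2] * (p[3] + bd2 * p[4]),
          (1 / 6) * b^2 * p[2]^2,
          (1 / 6) * b^2 * p[2]^2 * bd2)
  }
  ord <- order(b)
  lo2 <- ord[b[ord] <= sort(unique(round(b, 9)))[2] + 1e-12]
  slope <- stats::coef(stats::lm(y[lo2] ~ b[lo2]))
  p0 <- c(slope[1], max(1e-3, -slope[2]), 0.1, 0.1)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  p <- unname(fit$par)
  vcov <- tryCatch({
    dof <- max(1, length(y) - 4)
    s2 <- sum(fit$fvec^2) / dof
    s2 * solve(crossprod(jac_fn(p)))
  }, error = function(e) matrix(NA_real_, 4, 4))
  list(S0 = exp(p[1]), MD = p[2], MKi = p[3], MKa = p[4],
       MKt = p[3] + p[4], vcov = vcov, fit = fit)
}
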