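## Microstructure metrics derived from the fitted mean diffusion tensor and
## fourth-order covariance tensor. With M2 = C + <D> ox <D> (the second
## moment of the underlying tensor distribution):
##   MD  = tr<D>/3
##   FA  = sqrt(3/2) sqrt( (<D> ox <D>):E_shear / (<D> ox <D>):E_iso )
##   uFA = sqrt(3/2) sqrt( M2:E_shear / (M2:E_shear + M2:E_bulk) )
##   MKi = 3 C:E_bulk / MD^2        (heterogeneity of isotropic diffusivities)
##   MKa = (6/5) M2:E_shear / MD^2  (microscopic anisotropy)
##   MKt = MKi + MKa
##   Cc  = FA^2 / uFA^2             (orientation coherence)

#' Derive microstructure metrics from covariance-model coefficients
#'
#' @param coef a [qti_coefficients()] object.
#' @return object of class `qti_metrics`: list with `MD` (um^2/ms), `FA`,
#'   `uFA`, `MKi`, `MKa`, `MKt`, `Cc` (dimensionless). `Cc` is clipped to
#'   `[0, 1]` and is `NaN` when `uFA < 1e-6`; all metrics are `NaN` (with a
#'   warning) when the fitted MD is nonpositive.
#' @export
metrics_from_coefficients <- function(coef) {
  stopifnot(inherits(coef, "qti_coefficients"))
  d6 <- coef$mean_tensor
  if (any(!is.finite(d6)) || any(!is.finite(coef$covariance))) {
    warning("non-finite coefficients; metrics set to NaN")
    return(qti_metrics_all_nan())
  }
  C6 <- from_voigt21(coef$covariance)
  md <- sum(d6[1:3]) / 3
  if (!is.finite(md) || md <= 0) {
    warning("nonpositive mean diffusivity; metrics set to NaN")
    return(qti_metrics_all_nan())
  }
  E <- iso_bases()
  DD <- tcrossprod(d6)
  M2 <- C6 + DD
  contr <- function(X, E_) sum(X * E_)
  dd_shear <- max(0, contr(DD, E$shear))
  dd_iso <- contr(DD, E$iso4)
  fa <- if (dd_iso > 0) sqrt(1.5 * dd_shear / dd_iso) else 0
  m2_shear <- max(0, contr(M2, E$shear))
  m2_bulk <- max(0, contr(M2, E$bulk))
  ufa <- if (m2_shear + m2_bulk > 0)
    sqrt(1.5 * m2_shear / (m2_shear + m2_bulk)) else 0
  mki <- 3 * contr(C6, E$bulk) / md^2
  mka <- (6 / 5) * m2_shear / md^2
  cc <- if (ufa < 1e-6) NaN else min(1, max(0, fa^2 / ufa^2))
  structure(list(MD = md, FA = fa, uFA = ufa,
                 MKi = mki, MKa = mka, MKt = mki + mka, Cc = cc),
            class = "qti_metrics")
}

qti_metrics_all_nan <- function() {
  structure(as.list(setNames(rep(NaN, 7),
                             c("MD", "FA", "uFA", "MKi", "MKa", "MKt", "Cc"))),
            class = "qti_metrics")
}

#' @export
print.qti_metrics <- function(x, ...) {
  cat(sprintf(paste0("MD = %.3f um^2/ms, FA = %.3f, uFA = %.3f, ",
                     "MKi = %.3f, MKa = %.3f, MKt = %.3f, Cc = %.3f\n"),
              x$MD, x$FA, x$uFA, x$MKi, x$MKa, x$MKt, x$Cc))
  invisible(x)
}

#' Names of the metric maps produced by the pipeline
#' @return character vector.
#' @export
qti_metric_names <- function() c("MD", "FA", "uFA", "MKi", "MKa", "MKt", "Cc")
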