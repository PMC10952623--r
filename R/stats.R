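## ROI statistics, Bland-Altman repeatability, the long/short diffusion-time
## comparison, and the restriction-time estimate.

#' Characteristic intermediate diffusion time for a restriction size
#'
#' `t = (d/2)^2 / (2 MD)`: the time at which free diffusion over half the
#' restriction dimension matches the restriction, i.e. when some water
#' molecules begin to feel the boundary. For human cardiomyocytes (length
#' ~141 um, width ~19 um) at MD = 1.6 um^2/ms this gives ~1.6 s and
#' ~28 ms.
#'
#' @param d restriction dimension (um).
#' @param MD mean diffusivity (um^2/ms).
#' @return list with `t_ms` and `t_s` (vectorized over `d`).
#' @export
restriction_time <- function(d, MD) {
  if (any(d <= 0)) stop_validation("d must be positive")
  if (any(MD <= 0)) stop_validation("MD must be positive")
  t_ms <- (d / 2)^2 / (2 * MD)
  list(t_ms = t_ms, t_s = t_ms / 1e3)
}

#' Mean, SD and count of a map within a mask
#'
#' @param map numeric array.
#' @param mask logical array (single ROI) or integer label array (one row
#'   per label); `NA`/`NaN` map values are ignored.
#' @return data frame with columns `roi`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(map, mask) {
  if (is.logical(mask)) mask <- ifelse(mask, 1L, 0L)
  labels <- sort(unique(mask[mask != 0 & !is.na(mask)]))
  if (!length(labels)) stop_validation("mask is empty")
  out <- lapply(labels, function(l) {
    v <- map[mask == l]
    v <- v[is.finite(v)]
    data.frame(roi = l, mean = mean(v), sd = sd(v), n = length(v))
  })
  do.call(rbind, out)
}

#' Bland-Altman agreement between paired measurements
#'
#' @param x1,x2 paired numeric vectors of equal length.
#' @return list with `mean_diff`, `sd_diff`, limits of agreement
#'   `lower`/`upper` (mean +/- 1.96 SD) and the number of complete pairs.
#' @export
bland_altman <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop_validation("bland_altman requires equal-length paired inputs")
  d <- x1 - x2
  d <- d[is.finite(d)]
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  list(mean_diff = m, sd_diff = s,
       lower = m - 1.96 * s, upper = m + 1.96 * s, n = length(d))
}

#' Compare DTI parameters between long and short diffusion-time encodings
#'
#' Pools MD and FA values over the ROI voxels of both map sets and applies a
#' two-sample t-test per parameter at alpha = 0.05.
#'
#' @param fit_long,fit_short lists with elements `MD` and `FA` (numeric
#'   arrays on the same grid).
#' @param rois logical or label array selecting the voxels to pool.
#' @return list keyed by parameter: `mean_long`, `mean_short`, `t`, `p`,
#'   `significant`, `direction`.
#' @export
compare_timedep <- function(fit_long, fit_short, rois) {
  sel <- if (is.logical(rois)) rois else (!is.na(rois) & rois != 0)
  out <- list()
  for (par in c("MD", "FA")) {
    a <- fit_long[[par]][sel]
    b <- fit_short[[par]][sel]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (sd(c(a - mean(a), b - mean(b))) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
    }
    out[[par]] <- list(mean_long = mean(a), mean_short = mean(b),
                       t = unname(tt$statistic), p = tt$p.value,
                       significant = tt$p.value < 0.05,
                       direction = if (mean(a) > mean(b)) "long > short"
                                   else if (mean(a) < mean(b)) "long < short"
                                   else "equal")
  }
  out
}
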