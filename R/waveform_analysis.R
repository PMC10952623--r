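## Waveform characterization: dephasing vector, b-tensor, motion-encoding
## moments, encoding power spectrum, concomitant-field (Maxwell) index,
## hardware-limit checks, and extraction of the two linear-encoding
## waveforms embedded in a planar one.

#' Dephasing vector q(t) of an effective waveform
#'
#' `q(t) = gamma * integral_0^t g(t') dt'`, computed by cumulative
#' trapezoidal quadrature on the raster. For a balanced spin-echo waveform
#' `q` returns to (approximately) zero at the end of the encoding.
#'
#' @param w an effective-polarity `gradient_waveform`.
#' @return `N x 3` matrix of q samples (rad/m).
#' @export
dephasing_vector <- function(w) {
  require_effective(w, "dephasing_vector")
  t <- waveform_times(w)
  w$gamma * pracma::cumtrapz(t, w$samples)
}

#' b-tensor of an effective waveform
#'
#' `B = integral q(t) q(t)^T dt`, converted from SI to ms/um^2. A warning is
#' issued when the waveform is not balanced (`|q(TE)|` not small).
#'
#' @param w an effective-polarity `gradient_waveform`.
#' @param balance_tol relative tolerance on `|q(TE)|` before warning.
#' @return a [btensor()] in ms/um^2.
#' @export
btensor_of_waveform <- function(w, balance_tol = 1e-3) {
  require_effective(w, "btensor_of_waveform")
  t <- waveform_times(w)
  q <- dephasing_vector(w)
  qmax <- max(sqrt(rowSums(q^2)))
  qend <- sqrt(sum(q[nrow(q), ]^2))
  if (qmax > 0 && qend > balance_tol * qmax)
    warning("waveform is not balanced: |q(TE)| = ",
            format(qend / qmax, digits = 3), " of max |q|")
  B <- matrix(0, 3, 3)
  for (i in 1:3)
    for (j in i:3)
      B[i, j] <- B[j, i] <- pracma::trapz(t, q[, i] * q[, j])
  btensor(B / B_SI_PER_MS_UM2)
}

#' Motion-encoding moment vectors
#'
#' `m_n = gamma * integral t^n g(t) dt` over the effective waveform, for
#' orders `0..n_max`; units m^-1 s^n. Zeroing `m_0..m_2` corresponds to
#' position, velocity, and acceleration (second-order) motion compensation.
#'
#' @param w an effective-polarity `gradient_waveform`.
#' @param n_max highest order, between 0 and 3.
#' @return object of class `moment_set`: list with `m` (list of 3-vectors
#'   indexed `"0"..`) and `magnitudes` (named numeric vector).
#' @export
moments <- function(w, n_max = 3L) {
  require_effective(w, "moments")
  if (n_max < 0 || n_max > 3) stop_validation("n_max must be in 0..3")
  t <- waveform_times(w)
  m <- list()
  for (n in 0:n_max) {
    m[[as.character(n)]] <- w$gamma *
      apply(w$samples, 2, function(g) pracma::trapz(t, t^n * g))
  }
  mags <- vapply(m, function(v) sqrt(sum(v^2)), numeric(1))
  structure(list(m = m, magnitudes = mags), class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  for (n in names(x$m))
    cat(sprintf("|m_%s| = %.4g s^%s/m\n", n, x$magnitudes[[n]], n))
  invisible(x)
}

# Per-order moment scale of a reference (uncompensated) PGSE of equal b in
# the same encoding window: the magnitude contributed by its first lobe,
# gamma * G_ref * delta^(n+1) / (n+1). Used for default pass thresholds.
reference_moment_scales <- function(w, n_max = 3L) {
  total <- (nrow(w$samples) - 1) * w$dt
  delta <- total / 4
  Delta <- total / 2
  b_si <- btensor_of_waveform(w)$b * B_SI_PER_MS_UM2
  G_ref <- sqrt(b_si / (w$gamma^2 * delta^2 * (Delta - delta / 3)))
  vapply(0:n_max, function(n) w$gamma * G_ref * delta^(n + 1) / (n + 1),
         numeric(1))
}

#' Check motion compensation up to a given order
#'
#' Passes when every moment magnitude `|m_n|`, `n <= order`, falls below its
#' tolerance. By default the tolerance for order n is `1e-4` times the
#' corresponding single-lobe moment of an uncompensated PGSE of equal b
#' spanning the same encoding window.
#'
#' @param w an effective-polarity `gradient_waveform`.
#' @param order compensation order to require (0..3).
#' @param tol numeric vector of per-order absolute tolerances
#'   (length `order + 1`), or `NULL` for the default.
#' @return list with `pass` (logical) and `per_order` data frame (order,
#'   magnitude, tol, pass).
#' @export
validate_motion_compensation <- function(w, order, tol = NULL) {
  if (order < 0 || order > 3) stop_validation("order must be in 0..3")
  ms <- moments(w, n_max = order)
  if (is.null(tol))
    tol <- 1e-4 * reference_moment_scales(w, n_max = order)
  tol <- rep_len(tol, order + 1)
  per <- data.frame(order = 0:order,
                    magnitude = unname(ms$magnitudes),
                    tol = tol)
  per$pass <- per$magnitude <= per$tol
  list(pass = all(per$pass), per_order = per)
}

#' Encoding power spectrum of the dephasing vector
#'
#' Discrete Fourier transform of each q-axis over the encoding window
#' (zero-padded for bin resolution), squared magnitude, reported for
#' nonnegative frequencies. The mean frequency is power-weighted over the
#' trace power.
#'
#' @param w an effective-polarity `gradient_waveform`.
#' @param zero_pad_factor zero-padding factor (default 8).
#' @return object of class `encoding_spectrum`: list with `frequencies`
#'   (Hz), `power` (matrix, one column per axis), `trace_power`,
#'   `mean_frequency`, `peak_frequency`.
#' @export
encoding_spectrum <- function(w, zero_pad_factor = 8L) {
  require_effective(w, "encoding_spectrum")
  if (zero_pad_factor < 1) stop_validation("zero_pad_factor must be >= 1")
  q <- dephasing_vector(w)
  n <- nrow(q)
  m <- n * as.integer(zero_pad_factor)
  P <- vapply(1:3, function(a) {
    Mod(stats::fft(c(q[, a], rep(0, m - n))))^2
  }, numeric(m))
  keep <- seq_len(floor(m / 2) + 1L)
  f <- (keep - 1) / (m * w$dt)
  P <- P[keep, , drop = FALSE]
  trace <- rowSums(P)
  tot <- sum(trace)
  mean_f <- if (tot > 0) sum(f * trace) / tot else 0
  peak_f <- if (tot > 0) f[which.max(trace)] else 0
  structure(list(frequencies = f, power = P, trace_power = trace,
                 mean_frequency = mean_f, peak_frequency = peak_f),
            class = "encoding_spectrum")
}

#' @export
print.encoding_spectrum <- function(x, ...) {
  cat(sprintf("encoding spectrum: mean %.2f Hz, peak %.2f Hz (%d bins)\n",
              x$mean_frequency, x$peak_frequency, length(x$frequencies)))
  invisible(x)
}

#' Concomitant-field (Maxwell) index
#'
#' `M = integral g(t) g(t)^T s(t) dt` on the laboratory-polarity waveform,
#' with `s = +1` before and `-1` after the refocusing pulse; the index is
#' the Frobenius norm of `M`, reported in (mT/m)^2 ms. A vanishing index
#' indicates balanced concomitant-gradient encoding across the refocusing
#' pulse.
#'
#' @param w a laboratory-polarity `gradient_waveform`.
#' @return scalar index, (mT/m)^2 ms.
#' @export
maxwell_index <- function(w) {
  stopifnot(inherits(w, "gradient_waveform"))
  if (w$stored_as_effective)
    stop_validation("maxwell_index requires laboratory polarity; the sign",
                    " function would be double-counted on an effective waveform")
  t <- waveform_times(w)
  s <- ifelse(t >= refocus_time(w) - 1e-12, -1, 1)
  M <- matrix(0, 3, 3)
  for (i in 1:3)
    for (j in i:3)
      M[i, j] <- M[j, i] <- pracma::trapz(t, w$samples[, i] * w$samples[, j] * s)
  sqrt(sum(M^2)) * 1e9   # (T/m)^2 s -> (mT/m)^2 ms
}

#' Peak gradient amplitude and slew rate
#'
#' Maximum Euclidean norm of the gradient vector and of its per-step
#' difference quotient, with pass flags against configurable hardware
#' limits.
#'
#' @param w a `gradient_waveform`.
#' @param amplitude_limit limit on `|g|` (T/m), default 0.080.
#' @param slew_limit limit on the slew rate (T/m/s), default 100.
#' @return list with `amplitude_mT_m`, `slew_T_m_s`, `amplitude_ok`,
#'   `slew_ok`, and the limits used.
#' @export
slew_and_amplitude <- function(w, amplitude_limit = 0.080,
                               slew_limit = 100) {
  g <- w$samples
  amp <- max(sqrt(rowSums(g^2)))
  dg <- diff(g)
  slew <- max(sqrt(rowSums(dg^2))) / w$dt
  list(amplitude_mT_m = amp * 1e3,
       slew_T_m_s = slew,
       amplitude_ok = amp <= amplitude_limit * (1 + 1e-9),
       slew_ok = slew <= slew_limit * (1 + 1e-9),
       amplitude_limit_mT_m = amplitude_limit * 1e3,
       slew_limit_T_m_s = slew_limit)
}

#' Extract the two linear-encoding waveforms from a planar one
#'
#' The planar waveform is decomposed along the eigenvectors of the gradient
#' power matrix `P = integral g(t) g(t)^T dt`. Each projection is a
#' single-axis (linear-encoding) waveform; the pair is labeled by diffusion
#' time. With `selection = "spectral"` (default) the candidate with the
#' lower spectral mean frequency is labeled `lte_long`; with
#' `selection = "gradient-power"` the projection onto the top eigenvector of
#' `P` is labeled `lte_long`.
#'
#' @param w_pte an effective-polarity planar-encoding `gradient_waveform`.
#' @param selection `"spectral"` or `"gradient-power"`.
#' @param planarity_tol the third b-tensor eigenvalue must be below this
#'   fraction of the trace (and the second above it).
#' @return list with `lte_long`, `lte_short` (effective waveforms) and a
#'   `report` (eigenvalues of P, mean frequencies, labels).
#' @export
extract_lte_from_pte <- function(w_pte,
                                 selection = c("spectral", "gradient-power"),
                                 planarity_tol = 0.01) {
  selection <- match.arg(selection)
  require_effective(w_pte, "extract_lte_from_pte")
  B <- btensor_of_waveform(w_pte)
  lam <- eigen(B$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (lam[3] > planarity_tol * B$b || lam[2] <= planarity_tol * B$b)
    stop_validation("b-tensor is not planar: eigenvalues ",
                    paste(format(lam, digits = 3), collapse = ", "))
  t <- waveform_times(w_pte)
  g <- w_pte$samples
  P <- matrix(0, 3, 3)
  for (i in 1:3)
    for (j in i:3)
      P[i, j] <- P[j, i] <- pracma::trapz(t, g[, i] * g[, j])
  eP <- eigen(P, symmetric = TRUE)
  project <- function(e) {
    w <- w_pte
    w$samples <- (g %*% e) %*% t(e)
    w
  }
  cand <- list(project(eP$vectors[, 1]), project(eP$vectors[, 2]))
  mf <- vapply(cand, function(x) encoding_spectrum(x)$mean_frequency,
               numeric(1))
  long_idx <- if (selection == "spectral") which.min(mf) else 1L
  report <- list(selection = selection,
                 power_eigenvalues = eP$values[1:2],
                 mean_frequencies_Hz = mf,
                 lte_long_from = c("top-eigenvector",
                                   "second-eigenvector")[long_idx])
  list(lte_long = cand[[long_idx]], lte_short = cand[[3L - long_idx]],
       report = report)
}
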