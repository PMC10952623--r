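## Gradient-waveform container and file I/O. A waveform samples the per-axis
## gradient amplitude (T/m) on a uniform raster spanning the whole encoding
## window: pre-refocusing encoding, a gap holding the (instantaneous,
## centered) refocusing pulse, and post-refocusing encoding. Sample i sits at
## t_i = (i - 1) * dt; all time integrals use the trapezoidal rule on this
## raster, matching the accuracy of scanner playback.

#' Construct a gradient waveform
#'
#' @param samples `N x 3` matrix of gradient amplitudes (T/m) on a uniform
#'   raster.
#' @param dt raster interval (s).
#' @param pre_duration encoding time before the refocusing pulse (s); by
#'   default the window minus `gap_duration` is split evenly.
#' @param gap_duration pause spanning the refocusing pulse (s); the pulse is
#'   treated as instantaneous at its center.
#' @param post_duration encoding time after the refocusing pulse (s).
#' @param stored_as_effective `TRUE` when the post-refocusing sign inversion
#'   has already been applied to the samples.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1); defaults to the proton
#'   value.
#' @return object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, dt, pre_duration = NULL,
                              gap_duration = 0, post_duration = NULL,
                              stored_as_effective = FALSE,
                              gamma = GAMMA_PROTON) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 3, byrow = TRUE)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop_validation("samples must have 3 columns")
  if (nrow(samples) < 2L) stop_validation("need at least 2 samples")
  if (!all(is.finite(samples))) stop_validation("samples must be finite")
  if (!is.numeric(dt) || dt <= 0) stop_validation("dt must be positive")
  if (gamma <= 0) stop_validation("gamma must be positive")
  duration <- (nrow(samples) - 1L) * dt
  if (is.null(pre_duration) && is.null(post_duration)) {
    pre_duration <- (duration - gap_duration) / 2
    post_duration <- pre_duration
  }
  if (is.null(post_duration))
    post_duration <- duration - gap_duration - pre_duration
  if (is.null(pre_duration))
    pre_duration <- duration - gap_duration - post_duration
  if (min(pre_duration, gap_duration, post_duration) < -1e-12)
    stop_validation("timing durations must be nonnegative")
  total <- pre_duration + gap_duration + post_duration
  if (abs(total - duration) > dt + 1e-12)
    stop_validation(sprintf(
      "timing (%g s) inconsistent with %d samples at dt = %g s",
      total, nrow(samples), dt))
  structure(list(samples = unname(samples), dt = dt,
                 pre_duration = pre_duration, gap_duration = gap_duration,
                 post_duration = post_duration,
                 stored_as_effective = isTRUE(stored_as_effective),
                 gamma = gamma),
            class = "gradient_waveform")
}

#' Sample times of a waveform
#' @param w a `gradient_waveform`.
#' @return numeric vector of sample times (s), starting at 0.
#' @export
waveform_times <- function(w) (seq_len(nrow(w$samples)) - 1) * w$dt

# Time of the (instantaneous) refocusing pulse: center of the gap.
refocus_time <- function(w) w$pre_duration + w$gap_duration / 2

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf(
    "gradient waveform: %d samples, dt = %g s, duration = %g ms (%s polarity)\n",
    nrow(x$samples), x$dt, 1e3 * (nrow(x$samples) - 1) * x$dt,
    if (x$stored_as_effective) "effective" else "laboratory"))
  invisible(x)
}

#' Apply the spin-echo sign reversal to a laboratory-polarity waveform
#'
#' All samples after the refocusing pulse are negated, producing the
#' effective gradient waveform whose running integral is the dephasing
#' vector.
#'
#' @param w a `gradient_waveform` in laboratory polarity.
#' @return the effective-polarity waveform (`stored_as_effective = TRUE`).
#' @export
effective_waveform <- function(w) {
  stopifnot(inherits(w, "gradient_waveform"))
  if (w$stored_as_effective)
    stop_validation("waveform is already in effective polarity")
  t <- waveform_times(w)
  flip <- t >= refocus_time(w) - 1e-12
  s <- w$samples
  s[flip, ] <- -s[flip, ]
  w$samples <- s
  w$stored_as_effective <- TRUE
  w
}

require_effective <- function(w, what) {
  if (!w$stored_as_effective)
    stop_validation(what, " requires an effective-polarity waveform; ",
                    "apply effective_waveform() first")
}

#' Synthesize a pulsed-gradient spin-echo (PGSE) waveform
#'
#' Two rectangular lobes of amplitude `G` and duration `delta`, the second
#' starting `Delta` after the first, in laboratory polarity. Lobe edges are
#' rasterized by cell averaging so the b-value matches the closed form
#' `gamma^2 G^2 delta^2 (Delta - delta/3)` to second order in `dt`.
#'
#' @param G gradient amplitude (T/m).
#' @param delta lobe duration (s).
#' @param Delta separation between lobe onsets (s); must exceed `delta`.
#' @param direction encoding direction (normalized internally).
#' @param dt raster interval (s).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return a laboratory-polarity `gradient_waveform`.
#' @export
make_pgse <- function(G, delta, Delta, direction = c(1, 0, 0), dt = 1e-5,
                      gamma = GAMMA_PROTON) {
  if (G <= 0) stop_validation("G must be positive")
  if (delta >= Delta) stop_validation("delta must be smaller than Delta")
  if (delta < 2 * dt)
    stop_validation("delta is not representable at this raster; reduce dt")
  total <- Delta + delta
  n <- round(total / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  lobe_cover <- function(a, b) {
    lo <- pmax(t - dt / 2, a)
    hi <- pmin(t + dt / 2, b)
    pmax(0, hi - lo) / dt
  }
  g <- G * (lobe_cover(0, delta) + lobe_cover(Delta, Delta + delta))
  samples <- outer(g, unit_vector(direction))
  gradient_waveform(samples, dt, pre_duration = total / 2, gap_duration = 0,
                    post_duration = total / 2, gamma = gamma)
}

#' Load a gradient waveform from a plain-text file
#'
#' One sample per row (`gx gy gz`), with optional `#`-prefixed header lines
#' of the form `# key value` for `dt`, `gmax`, `pre`, `gap`, `post`,
#' `effective`, and `gamma`. Header values take precedence over arguments.
#' Files whose largest absolute entry is <= 1 are taken as normalized and
#' scaled by `gmax` when one is available; otherwise entries are absolute
#' amplitudes in T/m.
#'
#' @param path waveform file.
#' @param dt raster interval (s); required unless in the header.
#' @param gmax peak amplitude (T/m) used to scale normalized files.
#' @param gamma gyromagnetic ratio, overridden by a header `gamma`.
#' @return a `gradient_waveform`.
#' @export
load_waveform <- function(path, dt = NULL, gmax = NULL,
                          gamma = GAMMA_PROTON) {
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines)
  hdr <- lines[is_hdr]
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (!length(body_idx)) stop_validation("waveform file is empty: ", path)
  header <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(strsplit(trimws(sub(paste0("^\\s*#\\s*", key, "\\s+"), "",
                                   m[1])), "\\s+")[[1]][1])
  }
  rows <- lapply(body_idx, function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                 "[[:space:],]+")[[1]]))
    if (length(vals) != 3L || any(is.na(vals)))
      stop_validation(sprintf("cannot parse waveform row at line %d of %s",
                              i, path))
    vals
  })
  samples <- do.call(rbind, rows)
  dt_final <- if (!is.null(header("dt"))) header("dt") else dt
  if (is.null(dt_final))
    stop_validation("no raster interval: pass dt or add a '# dt' header")
  gmax_final <- if (!is.null(header("gmax"))) header("gmax") else gmax
  if (!is.null(gmax_final) && max(abs(samples)) <= 1 + 1e-9)
    samples <- samples * gmax_final
  gamma_final <- if (!is.null(header("gamma"))) header("gamma") else gamma
  eff <- header("effective")
  gradient_waveform(samples, dt_final,
                    pre_duration = header("pre"),
                    gap_duration = if (is.null(header("gap"))) 0
                                   else header("gap"),
                    post_duration = header("post"),
                    stored_as_effective = !is.null(eff) && eff != 0,
                    gamma = gamma_final)
}

#' Write a gradient waveform to a plain-text file readable by
#' [load_waveform()]
#'
#' @param w a `gradient_waveform`.
#' @param path output path.
#' @param normalized if `TRUE`, samples are divided by their peak absolute
#'   value, which is recorded as a `# gmax` header.
#' @export
write_waveform <- function(w, path, normalized = FALSE) {
  s <- w$samples
  hdr <- c(sprintf("# dt %.17g", w$dt),
           sprintf("# pre %.17g", w$pre_duration),
           sprintf("# gap %.17g", w$gap_duration),
           sprintf("# post %.17g", w$post_duration),
           sprintf("# effective %d", as.integer(w$stored_as_effective)),
           sprintf("# gamma %.17g", w$gamma))
  if (normalized) {
    gmax <- max(abs(s))
    if (gmax > 0) s <- s / gmax
    hdr <- c(hdr, sprintf("# gmax %.17g", gmax))
  }
  body <- apply(s, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
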