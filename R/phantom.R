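## Multi-Gaussian phantom simulator and brute-force oracle. Voxels are
## modeled as discrete distributions of axisymmetric Gaussian diffusion
## tensors; the simulator provides exact ground-truth metrics (computed from
## the distribution's first and second moments via the same formulas the
## fitting pipeline uses) and exact sum-of-exponentials signals.

#' Discrete distribution of axisymmetric diffusion tensors
#'
#' @param weights positive component weights (normalized to sum to 1).
#' @param d_par axial diffusivities (um^2/ms), recycled to the number of
#'   components.
#' @param d_perp radial diffusivities (um^2/ms), recycled; must satisfy
#'   `d_par >= d_perp >= 0`.
#' @param orientations `n x 3` matrix of component orientations (normalized
#'   internally).
#' @return object of class `tensor_distribution`.
#' @export
tensor_distribution <- function(weights, d_par, d_perp, orientations) {
  if (is.vector(orientations)) orientations <- matrix(orientations, ncol = 3)
  orientations <- as.matrix(orientations)
  n <- nrow(orientations)
  weights <- rep_len(weights, n)
  d_par <- rep_len(d_par, n)
  d_perp <- rep_len(d_perp, n)
  if (any(weights <= 0)) stop_validation("weights must be positive")
  if (any(d_perp < 0) || any(d_par < d_perp))
    stop_validation("need d_par >= d_perp >= 0")
  orientations <- t(apply(orientations, 1, unit_vector))
  structure(list(weights = weights / sum(weights), d_par = d_par,
                 d_perp = d_perp, orientations = orientations),
            class = "tensor_distribution")
}

#' @export
print.tensor_distribution <- function(x, ...) {
  cat(sprintf("tensor distribution: %d components, MD = %.3f um^2/ms\n",
              length(x$weights),
              sum(x$weights * (x$d_par + 2 * x$d_perp) / 3)))
  invisible(x)
}

# 3x3 diffusion tensor of component i.
component_tensor <- function(dist, i) {
  n <- dist$orientations[i, ]
  dist$d_perp[i] * diag(3) + (dist$d_par[i] - dist$d_perp[i]) * tcrossprod(n)
}

#' Exact first and second moments of a tensor distribution
#'
#' @param dist a [tensor_distribution()].
#' @return list with `mean6` (Voigt6 of the mean tensor), `cov6` (6x6
#'   covariance in the Voigt basis), and `cov21` (its Voigt21 vector).
#' @export
distribution_moments <- function(dist) {
  n <- length(dist$weights)
  V <- t(vapply(seq_len(n),
                function(i) to_voigt6(component_tensor(dist, i)),
                numeric(6)))
  mean6 <- colSums(dist$weights * V)
  second <- matrix(0, 6, 6)
  for (i in seq_len(n))
    second <- second + dist$weights[i] * tcrossprod(V[i, ])
  cov6 <- second - tcrossprod(mean6)
  list(mean6 = mean6, cov6 = cov6, cov21 = to_voigt21(cov6))
}

#' Exact ground-truth metrics of a tensor distribution
#'
#' Computes the distribution's mean and covariance by weighted sums and
#' derives metrics through [metrics_from_coefficients()], so that fitted and
#' ground-truth metrics share one code path.
#'
#' @param dist a [tensor_distribution()].
#' @return a `qti_metrics` object.
#' @export
ground_truth_metrics <- function(dist) {
  mom <- distribution_moments(dist)
  metrics_from_coefficients(qti_coefficients(1, mom$mean6, mom$cov21))
}

#' Canonical orientation-dispersion scenarios
#'
#' The four regimes illustrated for myocardial tissue: a single coherent
#' population, a cone of dispersed orientations, two crossing populations,
#' and fully random orientations (for which FA of the mean tensor tends to
#' zero while the microscopic anisotropy is untouched).
#'
#' @param kind `"coherent"`, `"dispersed"`, `"crossing"`, or `"random"`.
#' @param params list of scenario parameters: `d_par`, `d_perp` (um^2/ms;
#'   defaults 2.0 and 0.6), `axis`, and per kind `half_angle_deg`
#'   (dispersed, default 30), `angle_deg` (crossing, default 90), `n`
#'   (dispersed/random component count, defaults 50/100).
#' @param seed seed for the quasi-uniform orientation sets.
#' @return a [tensor_distribution()].
#' @export
dispersion_scenarios <- function(kind = c("coherent", "dispersed",
                                          "crossing", "random"),
                                 params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(d_par = 2.0, d_perp = 0.6, axis = c(0, 0, 1),
                              half_angle_deg = 30, angle_deg = 90,
                              n = if (kind == "random") 100L else 50L),
                         params)
  axis <- unit_vector(p$axis)
  orientations <- switch(kind,
    coherent = matrix(axis, 1, 3),
    dispersed = {
      if (p$half_angle_deg == 0) matrix(axis, p$n, 3, byrow = TRUE)
      else {
        # uniform-in-area cone sampling with a golden-angle azimuth spiral
        i <- seq_len(p$n) - 0.5
        cmin <- cos(p$half_angle_deg * pi / 180)
        ct <- 1 - (i / p$n) * (1 - cmin)
        st <- sqrt(pmax(0, 1 - ct^2))
        phi <- 2 * pi * i * (sqrt(5) - 1) / 2
        local <- cbind(st * cos(phi), st * sin(phi), ct)
        local %*% t(rotation_z_to(axis))
      }
    },
    crossing = {
      a <- p$angle_deg * pi / 180
      perp <- if (abs(axis[3]) < 0.9) unit_vector(c(-axis[2], axis[1], 0))
              else unit_vector(c(1, 0, 0) - axis[1] * axis)
      rbind(axis, cos(a) * axis + sin(a) * perp)
    },
    random = {
      V <- fibonacci_hemisphere(p$n)
      R <- with_private_seed(seed, random_rotation())
      V %*% t(R)
    })
  tensor_distribution(rep(1, nrow(orientations)), p$d_par, p$d_perp,
                      orientations)
}

#' Two-block fiber phantom with adjustable interblock angle
#'
#' Emulates a phantom of two mating fiber blocks: slices 1 and 3 each
#' contain a single coherent fiber population, while slice 2 spans the
#' interface and mixes both orientations at equal weight, separated by the
#' interblock angle (0 = parallel, 90 = perpendicular).
#'
#' @param angle_deg interblock angle in degrees, in `[0, 90]`.
#' @param d_par,d_perp component diffusivities (um^2/ms); the defaults
#'   emulate water-filled hollow fibers.
#' @param grid `c(nx, ny, 3)` voxel grid; the third dimension indexes the
#'   slices.
#' @return object of class `phantom_spec`.
#' @export
two_block_phantom <- function(angle_deg, d_par = 2.0, d_perp = 0.6,
                              grid = c(6, 6, 3)) {
  if (angle_deg < 0 || angle_deg > 90)
    stop_validation("interblock angle must be in [0, 90] degrees")
  if (length(grid) != 3 || grid[3] != 3)
    stop_validation("two-block phantom needs a grid with 3 slices")
  a <- angle_deg * pi / 180
  u1 <- c(1, 0, 0)
  u2 <- c(cos(a), sin(a), 0)
  dists <- list(
    tensor_distribution(1, d_par, d_perp, u1),
    tensor_distribution(c(0.5, 0.5), d_par, d_perp, rbind(u1, u2)),
    tensor_distribution(1, d_par, d_perp, u2))
  labels <- array(0L, grid)
  for (z in 1:3) labels[, , z] <- z
  structure(list(grid = grid, labels = labels, dists = dists,
                 angle_deg = angle_deg,
                 params = list(d_par = d_par, d_perp = d_perp)),
            class = "phantom_spec")
}

#' Toy left-ventricle short-axis slice with a transmural helix
#'
#' An annular mask in which the fiber orientation rotates linearly from the
#' endocardial to the epicardial helix angle. Each voxel aggregates `n_sub`
#' sub-voxel orientations spanning its transmural extent, so voxel-level
#' ground truth shows FA < uFA wherever the helix range is nonzero.
#'
#' @param grid `c(nx, ny, 1)` voxel grid.
#' @param helix_range_deg endo and epi helix angles (degrees); default
#'   `c(60, -60)`. A scalar is taken as a constant (coherent) helix angle.
#' @param d_par,d_perp component diffusivities (um^2/ms).
#' @param n_sub sub-voxel orientations per voxel.
#' @return a `phantom_spec`; cavity and background voxels carry label 0 (no
#'   signal).
#' @export
ventricle_fixture <- function(grid = c(24, 24, 1),
                              helix_range_deg = c(60, -60),
                              d_par = 2.0, d_perp = 0.6, n_sub = 5L) {
  if (length(helix_range_deg) == 1)
    helix_range_deg <- rep(helix_range_deg, 2)
  nx <- grid[1]; ny <- grid[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_out <- 0.45 * min(nx, ny)
  r_in <- 0.22 * min(nx, ny)
  labels <- array(0L, grid)
  dists <- list()
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    r <- sqrt((ix - cx)^2 + (iy - cy)^2)
    if (r < r_in || r > r_out) next
    phi <- atan2(iy - cy, ix - cx)
    e_c <- c(-sin(phi), cos(phi), 0)
    tau_k <- (pmin(pmax((r + seq(-0.5, 0.5, length.out = n_sub)), r_in),
                   r_out) - r_in) / (r_out - r_in)
    alpha_k <- (helix_range_deg[1] +
                  tau_k * (helix_range_deg[2] - helix_range_deg[1])) * pi / 180
    fibers <- t(vapply(alpha_k,
                       function(al) cos(al) * e_c + sin(al) * c(0, 0, 1),
                       numeric(3)))
    dists[[length(dists) + 1L]] <-
      tensor_distribution(rep(1, n_sub), d_par, d_perp, fibers)
    labels[ix, iy, 1] <- length(dists)
  }
  structure(list(grid = grid, labels = labels, dists = dists,
                 helix_range_deg = helix_range_deg,
                 params = list(d_par = d_par, d_perp = d_perp)),
            class = "phantom_spec")
}

# Signal of one distribution over all scheme entries.
distribution_signal <- function(dist, scheme, s0 = 1,
                                mode = c("mixture", "cumulant")) {
  mode <- match.arg(mode)
  V <- scheme_voigt6(scheme)
  if (mode == "mixture") {
    n <- length(dist$weights)
    S <- 0
    for (i in seq_len(n)) {
      d6 <- to_voigt6(component_tensor(dist, i))
      S <- S + dist$weights[i] * exp(-as.numeric(V %*% d6))
    }
    s0 * S
  } else {
    mom <- distribution_moments(dist)
    lnS <- -as.numeric(V %*% mom$mean6) +
      0.5 * vapply(seq_len(nrow(V)),
                   function(k) sum(tcrossprod(V[k, ]) * mom$cov6),
                   numeric(1))
    s0 * exp(lnS)
  }
}

#' Synthesize diffusion-weighted signals
#'
#' Exact multi-Gaussian signal `S = S0 sum_i w_i exp(-B:D_i)` per voxel and
#' scheme entry; `mode = "cumulant"` instead generates from the truncated
#' cumulant representation (so the covariance fit recovers the ground truth
#' exactly, useful for inversion tests).
#'
#' @param x a [tensor_distribution()] or `phantom_spec`.
#' @param scheme an `acquisition_scheme`.
#' @param s0 non-diffusion-weighted signal level.
#' @param mode `"mixture"` (default) or `"cumulant"`.
#' @return object of class `synthetic_dataset`: list with `signals` (vector
#'   for a bare distribution; `nx x ny x nz x n` array for a phantom),
#'   `scheme`, `truth` (ground-truth metrics / metric maps), and a
#'   generation `log`.
#' @export
synthesize_signals <- function(x, scheme, s0 = 1,
                               mode = c("mixture", "cumulant")) {
  mode <- match.arg(mode)
  if (inherits(x, "tensor_distribution")) {
    sig <- distribution_signal(x, scheme, s0, mode)
    return(structure(list(signals = sig, scheme = scheme,
                          truth = ground_truth_metrics(x),
                          log = list(s0 = s0, mode = mode, snr = NA)),
                     class = "synthetic_dataset"))
  }
  if (!inherits(x, "phantom_spec"))
    stop_validation("x must be a tensor_distribution or phantom_spec")
  n_vol <- scheme_length(scheme)
  signals <- array(0, c(x$grid, n_vol))
  truth <- lapply(qti_metric_names(), function(m) array(NaN, x$grid))
  names(truth) <- qti_metric_names()
  per_label_sig <- lapply(x$dists, distribution_signal, scheme = scheme,
                          s0 = s0, mode = mode)
  per_label_truth <- lapply(x$dists, ground_truth_metrics)
  idx <- which(x$labels != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    l <- x$labels[idx[k, 1], idx[k, 2], idx[k, 3]]
    signals[idx[k, 1], idx[k, 2], idx[k, 3], ] <- per_label_sig[[l]]
    for (m in qti_metric_names())
      truth[[m]][idx[k, 1], idx[k, 2], idx[k, 3]] <- per_label_truth[[l]][[m]]
  }
  structure(list(signals = signals, scheme = scheme, truth = truth,
                 log = list(s0 = s0, mode = mode, snr = NA,
                            phantom = class(x)[1])),
            class = "synthetic_dataset")
}

#' Add Rician (magnitude-MRI) noise to a synthetic dataset
#'
#' `S_noisy = sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, s0/snr)`,
#' reproducible for a given seed.
#'
#' @param dataset a `synthetic_dataset` (or a bare numeric array/vector).
#' @param snr signal-to-noise ratio at the non-diffusion-weighted level.
#' @param seed integer seed.
#' @param s0 reference signal for the noise level; defaults to the dataset's
#'   generation S0 (1 for bare arrays).
#' @return the dataset with noisy signals (same class as the input).
#' @export
add_rician_noise <- function(dataset, snr, seed = 1L, s0 = NULL) {
  if (snr <= 0) stop_validation("snr must be positive")
  bare <- !inherits(dataset, "synthetic_dataset")
  S <- if (bare) dataset else dataset$signals
  if (is.null(s0)) s0 <- if (bare) 1 else dataset$log$s0
  sigma <- s0 / snr
  noisy <- with_private_seed(seed, {
    n1 <- array(rnorm(length(S), 0, sigma), dim = if (is.null(dim(S)))
      length(S) else dim(S))
    n2 <- array(rnorm(length(S), 0, sigma), dim = if (is.null(dim(S)))
      length(S) else dim(S))
    sqrt((S + n1)^2 + n2^2)
  })
  if (is.null(dim(S))) noisy <- as.numeric(noisy)
  if (bare) return(noisy)
  dataset$signals <- noisy
  dataset$log$snr <- snr
  dataset$log$noise_seed <- as.integer(seed)
  dataset
}

#' Random tissue-mimicking tensor distribution
#'
#' Draws a discrete multi-Gaussian voxel composition in the myocardial
#' operating regime: 2-4 components with axial diffusivities in
#' 1.0-2.2 um^2/ms, radial diffusivities in 0.3-1.0 um^2/ms, moderate
#' weight imbalance, and random orientations. Uses the current RNG state;
#' seed the session for reproducibility.
#'
#' @param n_components number of components; by default drawn from 2:4.
#' @return a [tensor_distribution()].
#' @export
random_tissue_distribution <- function(n_components = NULL) {
  n <- if (is.null(n_components)) sample(2:4, 1) else n_components
  d_par <- runif(n, 1.0, 2.2)
  d_perp <- pmin(runif(n, 0.3, 1.0), d_par)
  weights <- runif(n, 0.5, 1)
  orientations <- matrix(rnorm(3 * n), n, 3)
  tensor_distribution(weights, d_par, d_perp, orientations)
}
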