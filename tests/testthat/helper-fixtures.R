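# Shared fixture builders. All fixtures are constructed in code; no data
# files are shipped.

GAMMA <- 2.6752218744e8

# Closed-form PGSE b-value (ms/um^2) for rectangular lobes.
pgse_b_closed_form <- function(G, delta, Delta, gamma = GAMMA) {
  gamma^2 * G^2 * delta^2 * (Delta - delta / 3) / 1e9
}

# Effective-polarity waveform made of rectangular lobes at given start
# times, signed amplitudes (T/m), and common duration delta. Lobes are
# rasterized by cell averaging.
rect_lobe_waveform <- function(starts, amplitudes, delta, total, dt = 2e-5,
                               axis = c(1, 0, 0), effective = TRUE) {
  n <- round(total / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  g <- rep(0, n)
  for (k in seq_along(starts)) {
    lo <- pmax(t - dt / 2, starts[k])
    hi <- pmin(t + dt / 2, starts[k] + delta)
    g <- g + amplitudes[k] * pmax(0, hi - lo) / dt
  }
  gradient_waveform(outer(g, unit_vector_fixture(axis)), dt,
                    stored_as_effective = effective)
}

unit_vector_fixture <- function(v) v / sqrt(sum(v^2))

# Velocity-compensated (m0 = m1 = 0) effective waveform: four lobes with
# signs + - - + placed time-symmetrically, so both moments vanish by
# symmetry.
velocity_compensated_waveform <- function(G = 0.05, delta = 0.004,
                                          total = 0.04, dt = 2e-5) {
  starts <- c(0.002, 0.007, total - 0.007 - delta, total - 0.002 - delta)
  rect_lobe_waveform(starts, G * c(1, -1, -1, 1), delta, total, dt)
}

# Second-order-compensated fixture: five lobe slots, amplitudes chosen in
# the null space of the discrete m0/m1/m2 operator on the raster, so the
# measured moments vanish to numerical precision while m3 stays finite.
second_order_compensated_waveform <- function(total = 0.06, delta = 0.005,
                                              dt = 2e-5, scale = 0.05) {
  starts <- c(0.004, 0.015, 0.026, 0.04, 0.05)
  n <- round(total / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  basis <- vapply(starts, function(s) {
    lo <- pmax(t - dt / 2, s)
    hi <- pmin(t + dt / 2, s + delta)
    pmax(0, hi - lo) / dt
  }, numeric(n))
  M <- t(vapply(0:2, function(ord) {
    apply(basis, 2, function(g) pracma::trapz(t, t^ord * g))
  }, numeric(length(starts))))
  a <- svd(M, nv = length(starts))$v[, length(starts)]
  a <- a * scale / max(abs(a))
  g <- as.numeric(basis %*% a)
  gradient_waveform(cbind(g, 0, 0), dt, stored_as_effective = TRUE)
}

# Effective planar-encoding waveform built from two orthogonal sine-tone
# dephasing trajectories of equal q amplitude but distinct frequencies
# (f1 on x, f2 on y), over an integer number of periods of both.
two_tone_pte <- function(f1 = 25, f2 = 50, TE = 0.08, dt = 1e-4,
                         q_amp = 2e6) {
  t <- seq(0, TE, by = dt)
  gx <- q_amp * 2 * pi * f1 * cos(2 * pi * f1 * t) / GAMMA
  gy <- q_amp * 2 * pi * f2 * cos(2 * pi * f2 * t) / GAMMA
  gradient_waveform(cbind(gx, gy, 0), dt, stored_as_effective = TRUE)
}

# Small identifiable LTE+PTE scheme for fast fits.
small_scheme <- function(bmax = 0.45, seed = 7L) {
  build_protocol(bmax * c(1 / 3, 2 / 3, 1), c(8, 10, 14),
                 c("LTE", "PTE"), seed = seed)
}

# The in vivo protocol design scaled in b so that max b*MD stays below 0.5
# for the default phantom diffusivities.
scaled_invivo_scheme <- function(scale = 0.3, seed = 7L) {
  build_protocol(c(0.1, 0.4, 0.7, 1.1, 1.5) * scale,
                 c(10, 20, 30, 40, 50), c("LTE", "PTE"), seed = seed)
}

# Random symmetric 3x3 matrix.
random_symmetric3 <- function() {
  A <- matrix(rnorm(9), 3, 3)
  (A + t(A)) / 2
}

scheme_voigt6_for_test <- function(sch) {
  as.matrix(sch$entries[, c("bxx", "byy", "bzz", "byz", "bxz", "bxy")])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
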