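# Phantom simulator: distributions, scenarios, signals, noise, and the
# dispersion-invariance and oracle-equivalence properties.

test_that("tensor distributions validate and normalize their inputs", {
  d <- tensor_distribution(c(2, 2), 2, 0.5, rbind(c(1, 0, 0), c(0, 3, 0)))
  expect_equal(sum(d$weights), 1)
  expect_equal(sqrt(rowSums(d$orientations^2)), c(1, 1))
  expect_error(tensor_distribution(c(1, -1), 2, 0.5,
                                   rbind(c(1, 0, 0), c(0, 1, 0))),
               "positive")
  expect_error(tensor_distribution(1, 0.5, 2, c(1, 0, 0)), "d_par")
})

test_that("two-block phantom geometry follows the interblock angle", {
  ph0 <- two_block_phantom(0, grid = c(2, 2, 3))
  m1 <- ground_truth_metrics(ph0$dists[[1]])
  m2 <- ground_truth_metrics(ph0$dists[[2]])
  expect_equal(unlist(m2), unlist(m1), tolerance = 1e-12)
  # perpendicular sticks: mixed slice has FA = sqrt(0.5) and uFA = 1
  ph90 <- two_block_phantom(90, d_par = 2, d_perp = 0, grid = c(2, 2, 3))
  mm <- ground_truth_metrics(ph90$dists[[2]])
  expect_equal(mm$FA, sqrt(0.5), tolerance = 1e-12)
  expect_equal(mm$uFA, 1, tolerance = 1e-12)
  # MD is angle- and slice-invariant
  for (a in c(0, 30, 60, 90)) {
    ph <- two_block_phantom(a, grid = c(2, 2, 3))
    mds <- vapply(ph$dists, function(d) ground_truth_metrics(d)$MD,
                  numeric(1))
    expect_equal(mds, rep(mds[1], 3), tolerance = 1e-12)
  }
  expect_error(two_block_phantom(120), "angle")
})

test_that("dispersion scenarios span the coherence ladder", {
  coh <- ground_truth_metrics(dispersion_scenarios("coherent"))
  expect_equal(coh$uFA, coh$FA, tolerance = 1e-12)
  disp0 <- ground_truth_metrics(dispersion_scenarios("dispersed",
                                                     list(half_angle_deg = 0)))
  expect_equal(unlist(disp0), unlist(coh), tolerance = 1e-12)
  rand <- ground_truth_metrics(dispersion_scenarios("random",
                                                    list(n = 5000)))
  expect_lt(rand$FA, 0.03)
  expect_equal(rand$uFA, coh$uFA, tolerance = 0.01)
  disp <- ground_truth_metrics(dispersion_scenarios("dispersed",
                                                    list(half_angle_deg = 35)))
  expect_lt(disp$FA, coh$FA)
  expect_gt(disp$FA, rand$FA)
})

test_that("signal synthesis honors closed forms", {
  sch <- build_protocol(c(0.5, 1.0), c(6, 8), c("LTE", "PTE", "STE"),
                        seed = 2)
  iso <- tensor_distribution(1, 1.3, 1.3, c(0, 0, 1))
  ds <- synthesize_signals(iso, sch, s0 = 7)
  expect_equal(ds$signals, 7 * exp(-sch$entries$b * 1.3), tolerance = 1e-12)
  # a stick perpendicular to the LTE axis is not attenuated
  stick <- tensor_distribution(1, 2, 0, c(0, 0, 1))
  one <- build_protocol(1.0, 1, "LTE", seed = 1)
  one$entries[, c("bxx", "byy", "bzz", "byz", "bxz", "bxy")] <-
    rep(c(1, 0, 0, 0, 0, 0), each = 1)
  expect_equal(as.numeric(synthesize_signals(stick, one)$signals), 1,
               tolerance = 1e-12)
})

test_that("anisotropy separates LTE from PTE powder curves at high b only", {
  sch <- build_protocol(c(0.1, 0.8, 1.5), c(12, 16, 24), c("LTE", "PTE"),
                        seed = 8)
  aniso <- dispersion_scenarios("random", list(n = 200))
  tab_a <- powder_average(synthesize_signals(aniso, sch)$signals, sch)
  hi <- tab_a$b == 1.5
  gap_hi <- abs(diff(tab_a$signal[hi]))
  lo <- tab_a$b == 0.1
  gap_lo <- abs(diff(tab_a$signal[lo]))
  expect_gt(gap_hi, 10 * gap_lo)
  expect_gt(gap_hi, 0.01)
  iso <- tensor_distribution(c(0.5, 0.5), c(1, 2), c(1, 2),
                             rbind(c(0, 0, 1), c(0, 0, 1)))
  tab_i <- powder_average(synthesize_signals(iso, sch)$signals, sch)
  expect_lt(max(abs(tab_i$signal[tab_i$b_delta == 1] -
                      tab_i$signal[tab_i$b_delta == -0.5])), 1e-12)
})

test_that("pipeline metrics equal the brute-force oracle", {
  set.seed(91)
  sch <- small_scheme()
  for (rep in 1:5) {
    dist <- random_tissue_distribution()
    gt <- ground_truth_metrics(dist)
    # cumulant-generated signals invert exactly
    dsc <- synthesize_signals(dist, sch, mode = "cumulant")
    mc <- metrics_from_coefficients(fit_qti(dsc$signals, sch))
    expect_equal(unlist(mc), unlist(gt), tolerance = 1e-8)
    # exact mixture signals at b*MD <= 0.1 agree within 1%
    schl <- build_protocol(0.1 / gt$MD * c(1 / 3, 2 / 3, 1), c(16, 20, 28),
                           c("LTE", "PTE"), seed = rep)
    dsm <- synthesize_signals(dist, schl, mode = "mixture")
    mm <- metrics_from_coefficients(fit_qti(dsm$signals, schl))
    for (m in c("MD", "FA", "uFA", "MKi", "MKa", "Cc")) {
      if (is.na(gt[[m]]) || is.na(mm[[m]])) next
      expect_lt(abs(mm[[m]] - gt[[m]]), max(0.01 * abs(gt[[m]]), 0.01))
    }
    expect_identical(mm$MKt, mm$MKi + mm$MKa)
  }
})

test_that("uFA is insensitive to interblock angle while FA tracks dispersion", {
  sch <- scaled_invivo_scheme()
  angles <- seq(0, 90, by = 15)
  res <- t(vapply(angles, function(a) {
    ph <- two_block_phantom(a, grid = c(2, 2, 3))
    ds <- synthesize_signals(ph, sch)
    per_slice <- vapply(1:3, function(z) {
      m <- metrics_from_coefficients(fit_qti(ds$signals[1, 1, z, ], sch))
      c(m$MD, m$FA, m$uFA)
    }, numeric(3))
    c(MD2 = per_slice[1, 2], FA2 = per_slice[2, 2], uFA2 = per_slice[3, 2],
      FA1 = per_slice[2, 1], uFA3 = per_slice[3, 3])
  }, numeric(5)))
  expect_lt(diff(range(res[, "uFA2"])) / mean(res[, "uFA2"]), 0.02)
  expect_lt(diff(range(res[, "MD2"])) / mean(res[, "MD2"]), 0.005)
  expect_true(all(diff(res[, "FA2"]) < 0))
  # single-population slices are invariant to the rotation
  expect_lt(diff(range(res[, "FA1"])), 1e-9)
  expect_lt(diff(range(res[, "uFA3"])), 1e-9)
})

test_that("Rician noise is reproducible and has the Rayleigh floor", {
  sch <- small_scheme()
  dist <- dispersion_scenarios("coherent")
  ds <- synthesize_signals(dist, sch)
  almost <- add_rician_noise(ds, snr = 1e9, seed = 4)
  expect_equal(almost$signals, ds$signals, tolerance = 1e-6)
  n1 <- add_rician_noise(ds, snr = 20, seed = 4)
  n2 <- add_rician_noise(ds, snr = 20, seed = 4)
  expect_identical(n1$signals, n2$signals)
  n3 <- add_rician_noise(ds, snr = 20, seed = 5)
  expect_false(identical(n1$signals, n3$signals))
  # zero signal: the magnitude floor is sigma * sqrt(pi/2)
  zero <- add_rician_noise(rep(0, 20000), snr = 10, seed = 6)
  expect_equal(mean(zero), 0.1 * sqrt(pi / 2), tolerance = 0.02)
  expect_error(add_rician_noise(ds, snr = -1), "positive")
})

test_that("uFA bias under Rician noise stays small at SNR 50", {
  sch <- scaled_invivo_scheme()
  ph <- two_block_phantom(45, grid = c(2, 2, 3))
  clean <- synthesize_signals(ph, sch)$signals[1, 1, 2, ]
  ufa_clean <- metrics_from_coefficients(fit_qti(clean, sch))$uFA
  S <- matrix(rep(clean, each = 200), 200)
  noisy <- add_rician_noise(S, snr = 50, seed = 13)
  fits <- fit_qti(noisy, sch)
  ufa <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else metrics_from_coefficients(f)$uFA,
    numeric(1))
  expect_lt(abs(mean(ufa, na.rm = TRUE) - ufa_clean), 0.05)
})

test_that("the ventricle fixture shows dispersion only when the helix turns", {
  vf <- ventricle_fixture(grid = c(16, 16, 1))
  wall <- which(vf$labels != 0)
  expect_gt(length(wall), 10)
  mets <- lapply(vf$dists, ground_truth_metrics)
  fa <- vapply(mets, `[[`, numeric(1), "FA")
  ufa <- vapply(mets, `[[`, numeric(1), "uFA")
  expect_true(all(fa < ufa))
  # flat helix: every voxel is coherent
  vf0 <- ventricle_fixture(grid = c(16, 16, 1), helix_range_deg = 0)
  mets0 <- lapply(vf0$dists, ground_truth_metrics)
  expect_equal(vapply(mets0, `[[`, numeric(1), "FA"),
               vapply(mets0, `[[`, numeric(1), "uFA"), tolerance = 1e-9)
  # cavity voxels carry no signal
  sch <- build_protocol(c(0.3, 0.6), c(4, 6), c("LTE", "PTE"), seed = 3)
  ds <- synthesize_signals(vf, sch)
  cx <- round(dim(vf$labels)[1] / 2)
  expect_equal(ds$signals[cx, cx, 1, ], rep(0, scheme_length(sch)))
  expect_true(is.nan(ds$truth$MD[cx, cx, 1]))
})
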