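# Covariance-model design, fitting, and metric derivation.

test_that("design_row reproduces the log-signal by brute-force contraction", {
  # simple closed forms
  row <- design_row(diag(c(1, 0, 0)))
  coef <- c(log(2), to_voigt6(diag(c(0.8, 1, 1.2))), rep(0, 21))
  expect_equal(sum(row * coef), log(2) - 0.8, tolerance = 1e-12)
  rowS <- design_row(diag(3) * 0.5)   # spherical, b = 1.5
  coefS <- c(0, to_voigt6(diag(3) * 1.1), rep(0, 21))
  expect_equal(sum(rowS * coefS), -1.5 * 1.1, tolerance = 1e-12)
  # random case against a full 3x3x3x3 contraction oracle
  set.seed(21)
  for (rep in 1:10) {
    dist <- random_tissue_distribution()
    mom <- distribution_moments(dist)
    Dbar <- from_voigt6(mom$mean6)
    # full fourth-order covariance from the distribution definition
    C4 <- array(0, c(3, 3, 3, 3))
    for (i in seq_along(dist$weights)) {
      Di <- dist$d_perp[i] * diag(3) +
        (dist$d_par[i] - dist$d_perp[i]) * tcrossprod(dist$orientations[i, ])
      C4 <- C4 + dist$weights[i] * outer(Di, Di)
    }
    C4 <- C4 - outer(Dbar, Dbar)
    B <- btensor_from_shape(runif(1, 0.1, 1.5), runif(1, -0.5, 1),
                            rnorm(3))$matrix
    direct <- -sum(B * Dbar) + 0.5 * sum(outer(B, B) * C4)
    via_row <- sum(design_row(B) * c(0, mom$mean6, mom$cov21))
    expect_equal(via_row, direct, tolerance = 1e-12)
  }
})

test_that("noiseless cumulant signals are inverted essentially exactly", {
  set.seed(31)
  sch <- build_protocol(c(0.1, 0.4, 0.7, 1.1, 1.5), c(5, 10, 15, 20, 25),
                        c("LTE", "PTE"), seed = 3)
  expect_equal(scheme_length(sch), 150)
  dist <- random_tissue_distribution()
  mom <- distribution_moments(dist)
  ds <- synthesize_signals(dist, sch, s0 = 250, mode = "cumulant")
  cf <- fit_qti(ds$signals, sch)
  truth <- c(log(250), mom$mean6, mom$cov21)
  est <- c(log(cf$s0), cf$mean_tensor, cf$covariance)
  expect_lt(sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2)), 1e-8)
  expect_equal(cf$diagnostics$n_used, 150)
})

test_that("mono-exponential signals yield a vanishing covariance", {
  sch <- small_scheme(bmax = 1.5)
  D <- diag(c(1.8, 1.2, 0.9))
  V <- t(vapply(seq_len(scheme_length(sch)),
                function(i) to_voigt6(scheme_btensor(sch, i)$matrix),
                numeric(6)))
  s <- exp(-as.numeric(V %*% to_voigt6(D)))
  cf <- fit_qti(s, sch)
  md <- mean(cf$mean_tensor[1:3])
  expect_lt(max(abs(cf$covariance)), 1e-8 * md^2)
  met <- metrics_from_coefficients(cf)
  expect_equal(met$uFA, met$FA, tolerance = 1e-6)
  expect_equal(met$Cc, 1, tolerance = 1e-6)
})

test_that("non-identifiable or short designs raise informative errors", {
  lte_only <- build_protocol(c(0.5, 1, 1.5), c(10, 12, 14), "LTE", seed = 1)
  expect_error(fit_qti(rep(1, scheme_length(lte_only)), lte_only),
               "identifiable")
  one_shell <- build_protocol(1, 30, c("LTE", "PTE"), seed = 1)
  expect_error(fit_qti(rep(1, 60), one_shell), "shells")
  sch <- small_scheme()
  s <- rep(1, scheme_length(sch))
  s[-(1:20)] <- -1  # only 20 positive signals left
  expect_error(fit_qti(s, sch), "positive signals")
  expect_error(fit_qti(rep(1, 3), sch), "scheme lists")
})

test_that("metrics match hand-derived closed forms", {
  # equal mixture of isotropic tensors with diffusivities 1 and 2
  iso <- tensor_distribution(c(0.5, 0.5), c(1, 2), c(1, 2),
                             rbind(c(0, 0, 1), c(0, 0, 1)))
  m <- ground_truth_metrics(iso)
  expect_equal(m$MD, 1.5)
  expect_equal(m$FA, 0)
  expect_equal(m$uFA, 0)
  expect_equal(m$MKi, 1 / 3, tolerance = 1e-12)
  expect_equal(m$MKa, 0, tolerance = 1e-12)
  expect_equal(m$MKt, 1 / 3, tolerance = 1e-12)
  expect_true(is.nan(m$Cc))
  # uniformly oriented sticks: uFA = 1, MKa = 12/5, FA ~ 0
  sticks <- dispersion_scenarios("random", list(d_par = 1, d_perp = 0,
                                                n = 10000))
  ms <- ground_truth_metrics(sticks)
  expect_equal(ms$uFA, 1, tolerance = 0.01)
  expect_equal(ms$MKa, 2.4, tolerance = 0.01)
  expect_lt(ms$FA, 0.02)
  expect_equal(ms$MKi, 0, tolerance = 0.01)
  expect_lt(ms$Cc, 0.01)
  # a single anisotropic tensor: zero covariance, uFA = FA, Cc = 1
  single <- dispersion_scenarios("coherent")
  m1 <- ground_truth_metrics(single)
  expect_equal(m1$uFA, m1$FA, tolerance = 1e-12)
  expect_equal(m1$Cc, 1)
})

test_that("FA never exceeds uFA for shared-MD mixtures and rotations leave metrics fixed", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    dist <- tensor_distribution(runif(n, 0.5, 1), 1.9, 0.5,
                                matrix(rnorm(3 * n), n, 3))
    gt <- ground_truth_metrics(dist)
    expect_lte(gt$FA, gt$uFA + 1e-9)
    # joint rotation of all component orientations
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rdist <- dist
    rdist$orientations <- dist$orientations %*% t(R)
    rgt <- ground_truth_metrics(rdist)
    expect_equal(unlist(rgt), unlist(gt), tolerance = 1e-10)
  }
})

test_that("MKt equals MKi + MKa to machine precision on fitted data", {
  set.seed(51)
  sch <- small_scheme()
  for (rep in 1:5) {
    dist <- random_tissue_distribution()
    ds <- synthesize_signals(dist, sch, mode = "cumulant")
    met <- metrics_from_coefficients(fit_qti(ds$signals, sch))
    expect_identical(met$MKt, met$MKi + met$MKa)
  }
})

test_that("powder averaging matches single measurements and 1D quadrature", {
  sch <- small_scheme(bmax = 1.5)
  # direction-independent signal: the average equals any one measurement
  iso_sig <- exp(-sch$entries$b * 1.1)
  tab <- powder_average(iso_sig, sch)
  expect_equal(tab$signal,
               exp(-tab$b * 1.1), tolerance = 1e-12)
  # stick population on an LTE shell vs the analytic orientation integral
  lam <- 2.0; b <- 1.5
  dirs <- rotation_set(50, seed = 2)
  stick <- c(0, 0, 1)
  sig <- exp(-b * lam * (dirs %*% stick)^2)
  oracle <- stats::integrate(function(th) exp(-b * lam * cos(th)^2) * sin(th),
                             0, pi / 2)$value
  expect_equal(mean(sig), oracle, tolerance = 0.01)
  # permutation invariance of the grouped average
  perm <- sample(scheme_length(sch))
  sch_p <- sch
  sch_p$entries <- sch$entries[perm, ]
  tab_p <- powder_average(iso_sig[perm], sch_p)
  expect_equal(tab_p, tab)
})

test_that("the powder kurtosis model is recovered from noiseless curves", {
  MD <- 1.62; MKi <- 0.13; MKa <- 0.20   # in vivo average operating point
  tab <- expand.grid(b = c(0.1, 0.4, 0.7, 1.1, 1.5), b_delta = c(1, -0.5))
  tab$shape <- ifelse(tab$b_delta == 1, "LTE", "PTE")
  tab$signal <- exp(-tab$b * MD +
                      (1 / 6) * tab$b^2 * MD^2 * (MKi + tab$b_delta^2 * MKa))
  fit <- fit_powder_model(tab)
  expect_rel_equal(fit$MD, MD, 1e-6)
  expect_rel_equal(fit$MKi, MKi, 1e-6)
  expect_rel_equal(fit$MKa, MKa, 1e-6)
  # isotropic mixtures attenuate identically for every shape
  tab0 <- tab
  tab0$signal <- exp(-tab0$b * MD + (1 / 6) * tab0$b^2 * MD^2 * MKi)
  lte <- tab0$signal[tab0$b_delta == 1]
  pte <- tab0$signal[tab0$b_delta == -0.5]
  expect_equal(lte, pte)
  # single-shape input cannot separate MKi from MKa
  expect_error(fit_powder_model(tab[tab$b_delta == 1, ]), "separable")
})

test_that("QTI and powder fits agree at moderate encoding strength", {
  # The powder model describes orientationally averaged signal, so the
  # cross-method check uses dispersed voxel compositions and rotation sets
  # dense enough that the arithmetic powder mean approximates the
  # rotational average; coherent single-population voxels at sparse
  # sampling leave direction-sampling residuals that dominate the small
  # b^2 curvature.
  set.seed(61)
  sch <- build_protocol(c(0.1, 0.4, 0.7, 1.1, 1.5) * 0.3, rep(60, 5),
                        c("LTE", "PTE"), seed = 7)
  for (rep in 1:3) {
    o1 <- dispersion_scenarios("random", list(n = 100), seed = rep)
    o2 <- dispersion_scenarios("random", list(n = 100), seed = rep + 50)
    dist <- tensor_distribution(
      rep(1, 200),
      c(rep(runif(1, 1.4, 2.2), 100), rep(runif(1, 1.0, 1.8), 100)),
      c(rep(runif(1, 0.3, 0.6), 100), rep(runif(1, 0.5, 0.9), 100)),
      rbind(o1$orientations, o2$orientations))
    ds <- synthesize_signals(dist, sch, mode = "mixture")
    met_qti <- metrics_from_coefficients(fit_qti(ds$signals, sch))
    fit_p <- fit_powder_model(powder_average(ds$signals, sch))
    expect_rel_equal(fit_p$MD, met_qti$MD, 0.01)
    expect_lt(abs(fit_p$MKi - met_qti$MKi),
              max(0.01, 0.01 * abs(met_qti$MKi)))
    expect_lt(abs(fit_p$MKa - met_qti$MKa),
              max(0.01, 0.01 * abs(met_qti$MKa)))
  }
})

test_that("the DTI fit recovers tensors and crossing-fiber anisotropy", {
  sch <- build_protocol(c(0.4, 0.7), c(10, 12), c("LTE"), seed = 5)
  D <- from_voigt6(c(1.6, 1.1, 0.8, 0.1 * sqrt(2), 0, 0.2 * sqrt(2)))
  V <- scheme_voigt6_for_test(sch)
  s <- 3.4 * exp(-as.numeric(V %*% to_voigt6(D)))
  fit <- fit_dti(s, sch, b_range = c(0.4, 0.7))
  expect_equal(fit$tensor, D, tolerance = 1e-8)
  expect_equal(fit$s0, 3.4, tolerance = 1e-8)
  # 90-degree stick crossing: mean-tensor FA = sqrt(0.5)
  cross <- dispersion_scenarios("crossing",
                                list(angle_deg = 90, d_par = 2, d_perp = 0))
  low_sch <- build_protocol(c(0.04, 0.08), c(10, 12), c("LTE"), seed = 5)
  dsc <- synthesize_signals(cross, low_sch, mode = "mixture")
  fitc <- fit_dti(dsc$signals, low_sch, b_range = c(0.0, 0.1))
  expect_equal(fitc$FA, sqrt(0.5), tolerance = 0.01)
  expect_error(fit_dti(s, sch, b_range = c(5, 6)), "b_range")
})

test_that("restriction time reproduces the cardiomyocyte worked example", {
  rt <- restriction_time(c(141, 19), 1.6)
  expect_equal(rt$t_s[1], 1.6, tolerance = 0.05)
  expect_equal(rt$t_ms[2], 28, tolerance = 0.01)
  # quadratic scaling with the restriction size
  expect_equal(restriction_time(38, 1.6)$t_ms, 4 * rt$t_ms[2],
               tolerance = 1e-12)
  expect_error(restriction_time(-1, 1.6), "positive")
  expect_error(restriction_time(10, 0), "positive")
})

test_that("ROI statistics and Bland-Altman agree with hand computation", {
  map <- array(c(1, 2, 3, NaN), c(2, 2, 1))
  mask <- array(c(TRUE, TRUE, TRUE, TRUE), c(2, 2, 1))
  st <- roi_stats(map, mask)
  expect_equal(st$mean, 2)
  expect_equal(st$n, 3)
  expect_error(roi_stats(map, array(FALSE, c(2, 2, 1))), "empty")
  # identical inputs: zero difference and zero-width limits
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(c(ba0$mean_diff, ba0$lower, ba0$upper), c(0, 0, 0))
  # constant offset
  bac <- bland_altman(1:5 + 2.5, 1:5)
  expect_equal(bac$mean_diff, 2.5)
  expect_equal(bac$sd_diff, 0)
  # worked numbers: pairs (1,2), (2,2), (3,5)
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 5))
  expect_equal(ba$mean_diff, -1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$lower, -1 - 1.96)
  expect_equal(ba$upper, -1 + 1.96)
  expect_error(bland_altman(1:3, 1:4), "equal-length")
})

test_that("the long/short diffusion-time comparison behaves under null and shift", {
  grid <- c(4, 4, 1)
  base <- array(rnorm(16, 1.5, 0.05), grid)
  fa <- array(rnorm(16, 0.3, 0.02), grid)
  rois <- array(TRUE, grid)
  same <- compare_timedep(list(MD = base, FA = fa),
                          list(MD = base, FA = fa), rois)
  expect_equal(same$MD$t, 0)
  expect_equal(same$MD$p, 1)
  shifted <- compare_timedep(list(MD = base + 5, FA = fa + 1),
                             list(MD = base, FA = fa), rois)
  expect_lt(shifted$MD$p, 1e-6)
  expect_equal(shifted$MD$direction, "long > short")
})

test_that("the two-sample t-test holds its nominal type-I error rate", {
  set.seed(71)
  grid <- c(5, 4, 1)
  rois <- array(TRUE, grid)
  rejections <- 0L
  for (rep in 1:1000) {
    a <- array(rnorm(20, 1.5, 0.1), grid)
    b <- array(rnorm(20, 1.5, 0.1), grid)
    res <- compare_timedep(list(MD = a, FA = a), list(MD = b, FA = b), rois)
    if (res$MD$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
})
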