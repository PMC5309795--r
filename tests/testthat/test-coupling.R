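# PLV, circular-linear PAC, z-PAC, lag-PAC.

test_that("PLV equals one for constant phase differences and is bounded", {
  fs <- 200
  phi <- theta_phase(10 * fs, fs, seed = 1)
  r <- plv(phi, phi, fs)
  expect_equal(r$mean, 1)
  r2 <- plv(phi, lfpcoupling:::wrap_phase(phi + 1.1), fs)
  expect_equal(r2$mean, 1, tolerance = 1e-12)
  expect_error(plv(phi[1:100], phi[1:100], fs), "shorter")
})

test_that("PLV is invariant to a common phase offset", {
  fs <- 200
  p1 <- theta_phase(8 * fs, fs, seed = 2)
  p2 <- theta_phase(8 * fs, fs, f0 = 7, seed = 3)
  r0 <- plv(p1, p2, fs)$mean
  r1 <- plv(lfpcoupling:::wrap_phase(p1 + 0.8),
            lfpcoupling:::wrap_phase(p2 + 0.8), fs)$mean
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("window PLV of independent phases matches the Rayleigh bias", {
  # brute-force expectation of |mean of N unit phasors| under independence
  set.seed(4)
  for (N in c(50, 200)) {
    expected <- mean(replicate(3000, Mod(mean(exp(1i * runif(N, -pi, pi))))))
    observed <- mean(replicate(200, {
      plv_brute(runif(N, -pi, pi), runif(N, -pi, pi))
    }))
    expect_lt(abs(observed - expected) / expected, 0.1)
  }
  # bias decreases with N
  e50 <- mean(replicate(1000, Mod(mean(exp(1i * runif(50, -pi, pi))))))
  e200 <- mean(replicate(1000, Mod(mean(exp(1i * runif(200, -pi, pi))))))
  expect_gt(e50, e200)
})

test_that("PAC rho is exact for perfect dependence and null for none", {
  fs <- 200
  phi <- theta_phase(20 * fs, fs, seed = 5)
  expect_equal(pac_circular_linear(phi, cos(phi))$rho, 1, tolerance = 1e-9)
  # independent amplitude: rho below its permutation 95th percentile
  set.seed(6)
  amp <- abs(rnorm(length(phi)))
  rho0 <- pac_circular_linear(phi, amp)$rho
  null <- replicate(199, {
    pac_circular_linear(phi, sample(amp))$rho
  })
  expect_lt(rho0, quantile(null, 0.95) * 2)
  expect_lt(rho0, 0.05)
  # degenerate amplitude
  d <- pac_circular_linear(phi, rep(2, length(phi)))
  expect_equal(d$rho, 0)
  expect_true(d$degenerate)
})

test_that("PLV and rho match brute-force loop implementations to 1e-10", {
  set.seed(7)
  n <- 1000
  p1 <- runif(n, -pi, pi)
  p2 <- runif(n, -pi, pi)
  fs <- n  # single 1 s window
  expect_equal(plv(p1, p2, fs)$mean, plv_brute(p1, p2), tolerance = 1e-10)
  phi <- theta_phase(n, 200, seed = 8)
  amp <- 1 + 0.5 * cos(phi - pi) + rnorm(n, sd = 0.2)
  amp <- amp - min(amp) + 0.01
  expect_equal(pac_circular_linear(phi, amp)$rho, rho_brute(phi, amp),
               tolerance = 1e-12)
})

test_that("PAC rho is invariant to affine rescaling of the amplitude", {
  phi <- theta_phase(2000, 200, seed = 9)
  amp <- 1 + 0.4 * cos(phi) + abs(rnorm(2000, sd = 0.3))
  r1 <- pac_circular_linear(phi, amp)$rho
  r2 <- pac_circular_linear(phi, 3.7 * amp + 11)$rho
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("two-step PLV contrast recovers stronger aversive coupling", {
  rec <- small_sim(1)
  fs <- rec$fs
  labels <- sample_conditions(rec)
  p_amy <- Arg(hilfun(bandpass_fir(channel_signal(rec, "AMY1"), 4, 8, fs = fs)))
  p_hip <- Arg(hilfun(bandpass_fir(channel_signal(rec, "HIP1"), 4.5, 8.5,
                                   fs = fs)))
  res <- plv_pair_contrast(p_amy, p_hip, labels, fs, n_perm = 100, seed = 1)
  expect_true(res$passed)
  expect_gt(res$difference, 0)
  expect_lt(res$p_difference, 0.05)
  # identical conditions -> zero difference by construction
  lab_same <- labels
  lab_same[lab_same == "neutral"] <- "aversive"
  lab_half <- lab_same
  half <- which(lab_half == "aversive")
  lab_half[half[seq_len(length(half) / 2)]] <- "neutral"
  res2 <- plv_pair_contrast(p_amy, p_amy, lab_half, fs, n_perm = 50, seed = 2)
  expect_equal(res2$difference, 0, tolerance = 1e-12)
})

test_that("z-PAC detects aversive-only coupling at the true bands", {
  hits <- sapply(1:10, function(sd) {
    rec <- small_sim(sd, coupling_ground_truth(
      modulation_depth_aversive = 0.6, modulation_depth_neutral = 0,
      line_noise_amp = 0))
    fs <- rec$fs
    labels <- sample_conditions(rec)
    ph <- Arg(hilfun(bandpass_fir(channel_signal(rec, "AMY1"), 4, 8, fs = fs)))
    amp <- analytic_signal(bandpass_fir(channel_signal(rec, "HIP1"), 80, 120,
                                        fs = fs), fs)$amplitude
    z_pac(ph, amp, labels, fs, n_perm = 100, seed = sd)$z > 2.33
  })
  expect_gte(mean(hits), 0.9)
})

test_that("lag-PAC peaks at zero for zero-lag coupling and flags no peak when uncoupled", {
  fs <- 500
  n <- 120 * fs
  set.seed(10)
  osc <- lfpcoupling:::narrowband_noise(n, fs, 6, bw_hz = 2)
  phi <- Arg(hilfun(osc))
  amp <- 0.3 + 0.6 * (1 + cos(phi)) / 2 + rnorm(n, sd = 0.1)
  lp <- lag_pac(phi, amp, fs)
  expect_lte(abs(lp$peak_lag_ms), 10)
  # uncoupled: profile is flat and weak
  lp0 <- lag_pac(phi, abs(rnorm(n)), fs)
  expect_lt(max(lp0$rho), 0.05)
  expect_error(lag_pac(phi[1:100], amp[1:100], fs), "twice the maximum lag")
})

test_that("PLV difference spectra localise the coupled band and interpolate", {
  rec <- small_sim(1)
  labels <- sample_conditions(rec)
  sp <- plv_spectrum(channel_signal(rec, "AMY1"), channel_signal(rec, "HIP1"),
                     labels, rec$fs, 3, 15)
  pk <- sp$centres[which.max(sp$z)]
  expect_gte(pk, 4); expect_lte(pk, 8)
  # the order-5 spline interpolates the bin values exactly
  at_bins <- spline_interp(sp$centres, sp$z, sp$centres, order = 5L)
  expect_equal(at_bins, sp$z, tolerance = 1e-8)
})
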