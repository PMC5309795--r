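# Event-locked high gamma, ERPs, trough-locked time-frequency maps.

test_that("high-gamma z-scoring is centred, NaN-free and affine-invariant", {
  rec <- small_sim(12, coupling_ground_truth(
    modulation_depth_aversive = 0, modulation_depth_neutral = 0,
    evoked_amp_aversive = 0, evoked_amp_neutral = 0, line_noise_amp = 0))
  tc <- hg_timecourse(rec, "AMY1")
  expect_false(anyNA(tc$z))
  # the session-blank baseline is a common (if noisy) offset, so the
  # condition difference must be null even if the absolute level is not
  d <- colMeans(tc$z[tc$condition == "aversive", , drop = FALSE]) -
    colMeans(tc$z[tc$condition == "neutral", , drop = FALSE])
  expect_lt(abs(mean(d[tc$times >= 0])), 0.15)
  # the per-trial baseline centres the pre-stimulus window exactly
  tc_t <- hg_timecourse(rec, "AMY1", baseline = "trial")
  expect_lt(abs(mean(tc_t$z[, tc_t$times >= 0])), 0.1)
  # scaling the raw recording leaves the z-scores unchanged
  rec2 <- rec; rec2$data <- rec$data * 7.3
  tc2 <- hg_timecourse(rec2, "AMY1")
  expect_equal(tc2$z, tc$z, tolerance = 1e-10)
  # constant signal: all-zero z-scores, no NaNs
  recc <- rec
  recc$data[1, ] <- 5
  expect_warning(tcc <- hg_timecourse(recc, 1), NA)
  expect_false(anyNA(tcc$z))
})

test_that("evoked aversive high gamma produces a detected condition cluster", {
  rec <- small_sim(13, coupling_ground_truth(
    evoked_amp_aversive = 0.8, evoked_amp_neutral = 0, line_noise_amp = 0))
  tc <- hg_timecourse(rec, "AMY2")
  ct <- hg_condition_contrast(tc, n_perm = 300, seed = 13)
  oo <- onset_offset_from_clusters(ct)
  expect_false(is.null(oo))
  # the significant cluster begins after the configured onset latency
  expect_gte(attr(ct, "times")[oo["onset"]], 0.08)
})

test_that("peak latency uses the trial average with the earliest-tie rule", {
  times <- seq(-0.5, 1.5, by = 0.001)[-2001]
  tri <- pmax(0, 1 - abs(times - 0.5) / 0.2)
  expect_equal(peak_latency(tri, times, c(0, 1)), 500)
  plateau <- as.numeric(times >= 0.4 & times <= 0.6)
  expect_equal(peak_latency(plateau, times, c(0, 1)), 400)
  expect_null(peak_latency(tri, times, NULL))
  # injected two-channel peaks at 490 / 640 ms recovered within 25 ms
  set.seed(1)
  mk <- function(centre) {
    t(replicate(30, pmax(0, 1 - abs(times - centre) / 0.15) +
                  rnorm(length(times), sd = 0.3)))
  }
  expect_lt(abs(peak_latency(mk(0.49), times, c(0, 1.2)) - 490), 25)
  expect_lt(abs(peak_latency(mk(0.64), times, c(0, 1.2)) - 640), 25)
})

test_that("ERPs are baseline-corrected and calibrated under the null", {
  # calibration on epochs that are genuinely independent across trials
  # (ongoing oscillations make neighbouring clips of a block correlated, so
  # white noise is the clean exchangeable null here)
  sch <- small_schedule()
  fs <- 250
  n <- ceiling(max(sch$onset_s + sch$duration_s) * fs) + fs
  fracs <- sapply(1:3, function(sd) {
    set.seed(sd)
    recw <- lfp_recording(matrix(rnorm(n), 1), fs,
                          data.frame(label = "C1", region = "amygdala-BLA",
                                     shaft = "A", contact = 1),
                          events = sch)
    mean(erp(recw, 1)$p < 0.05)
  })
  expect_lt(mean(fracs), 0.10)
  expect_gt(mean(fracs), 0.005)
  rec <- small_sim(14, coupling_ground_truth(
    evoked_amp_aversive = 0, evoked_amp_neutral = 0, line_noise_amp = 0))
  # a DC offset is removed by the baseline correction
  rec2 <- rec
  rec2$data[1, ] <- rec2$data[1, ] + 50
  res2 <- erp(rec2, "AMY1")
  res1 <- erp(rec, "AMY1")
  expect_equal(res2$mean_aversive, res1$mean_aversive, tolerance = 1e-8)
  expect_equal(res2$mean_neutral, res1$mean_neutral, tolerance = 1e-8)
  # an injected evoked wave is detected
  rec3 <- rec
  t_all <- seq_len(ncol(rec3$data)) / rec3$fs
  for (i in which(rec3$events$condition == "aversive")) {
    i0 <- round(rec3$events$onset_s[i] * rec3$fs)
    idx <- i0 + seq_len(rec3$fs / 2)
    rec3$data[1, idx] <- rec3$data[1, idx] +
      3 * sin(2 * pi * 10 * seq_along(idx) / rec3$fs)
  }
  res3 <- erp(rec3, "AMY1")
  expect_lt(min(res3$p[res3$times > 0 & res3$times < 0.5]), 1e-4)
})

test_that("theta troughs are located at filtered-signal minima", {
  fs <- 500
  t <- seq(1 / fs, 60, 1 / fs)
  set.seed(21)
  x <- cos(2 * pi * 6 * t) + rnorm(length(t), sd = 0.05)
  tf <- trough_locked_tf(x, fs, band_spec(6), freq_range = c(30, 60),
                         n_perm = 0)
  gaps <- diff(tf$trough_idx) / fs
  expect_lt(max(abs(gaps - 1 / 6)), 3 / fs)
  # phase convention check: filtered signal at troughs is a local minimum
  xb <- bandpass_fir(x, 4, 8, fs = fs)
  ok <- sapply(tf$trough_idx, function(i) {
    xb[i] <= xb[i - 1] + 1e-9 && xb[i] <= xb[i + 1] + 1e-9
  })
  expect_gte(mean(ok), 0.99)
  expect_error(trough_locked_tf(rnorm(300), fs, band_spec(6)), "troughs")
})

test_that("trough-locked gamma power peaks where bursts were constructed", {
  fs <- 500
  t <- seq(1 / fs, 90, 1 / fs)
  set.seed(15)
  theta <- cos(2 * pi * 6 * t)
  # gamma bursts at theta troughs (theta minimum = phase +/- pi)
  burst_env <- (1 - theta) / 2
  x <- theta + 0.5 * burst_env * sin(2 * pi * 90 * t) +
    rnorm(length(t), sd = 0.2)
  tf <- trough_locked_tf(x, fs, band_spec(6), freq_range = c(70, 110),
                         n_perm = 0)
  gp <- colMeans(tf$power)
  # bursts recur at every trough (the signal is periodic), so the centre must
  # sit at a local maximum within 90% of the global one
  centre <- which.min(abs(tf$times))
  expect_gte(gp[centre], 0.9 * max(gp))
  # and the epoch-centre peak is a genuine modulation: trough-to-peak ratio
  mid <- which(abs(tf$times) < 1 / 12)  # within a half theta cycle
  expect_gt(max(gp[mid]), 1.3 * min(gp[mid]))
  # uncoupled gamma: flat trough-locked power
  x0 <- theta + 0.5 * sin(2 * pi * 90 * t) + rnorm(length(t), sd = 0.2)
  tf0 <- trough_locked_tf(x0, fs, band_spec(6), freq_range = c(70, 110),
                          n_perm = 0)
  gp0 <- colMeans(tf0$power)
  expect_lt((max(gp0) - min(gp0)) / (max(gp) - min(gp)), 0.5)
})
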