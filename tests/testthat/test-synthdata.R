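# Synthetic task schedule and LFP/EOG generators.

test_that("default schedule reproduces the study's block and clip structure", {
  sch <- make_task_schedule()
  blocks <- unique(sch[, c("block", "condition")])
  expect_equal(sum(blocks$condition == "neutral"), 9)
  expect_equal(sum(blocks$condition == "aversive"), 8)
  expect_equal(sum(sch$condition == "neutral"), 70)
  expect_equal(sum(sch$condition == "aversive"), 71)
  # alternation starts with neutral
  expect_equal(blocks$condition[order(blocks$block)][1:4],
               c("neutral", "aversive", "neutral", "aversive"))
  # pre-session blank precedes block 1
  expect_equal(min(sch$onset_s), 0.5)
})

test_that("clips exactly tile each block and are contiguous", {
  sch <- make_task_schedule()
  per_block <- split(sch, sch$block)
  for (b in per_block) {
    expect_equal(sum(b$duration_s), 24, tolerance = 1e-9)
    if (nrow(b) > 1) {
      gaps <- b$onset_s[-1] - (b$onset_s[-nrow(b)] + b$duration_s[-nrow(b)])
      expect_true(all(abs(gaps) < 1e-9))
    }
  }
  expect_true(all(sch$duration_s > 0))
})

test_that("degenerate one-block schedule yields a single spanning event", {
  p <- task_schedule_params(n_neutral_blocks = 1, n_aversive_blocks = 0,
                            n_neutral_clips = 1)
  sch <- make_task_schedule(p)
  expect_equal(nrow(sch), 1)
  expect_equal(sch$duration_s, 24)
})

test_that("fewer clips than blocks is a schedule error", {
  p <- task_schedule_params(n_neutral_clips = 5)  # 5 clips for 9 blocks
  expect_error(make_task_schedule(p), "fewer")
})

test_that("identical seeds give bit-identical recordings", {
  r1 <- simulate_lfp(small_schedule(), fs = 500, seed = 42)
  r2 <- simulate_lfp(small_schedule(), fs = 500, seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_lfp(small_schedule(), fs = 500, seed = 43)
  expect_false(identical(r1$data, r3$data))
})

test_that("simulator refuses out-of-range lags and low sampling rates", {
  expect_error(coupling_ground_truth(conduction_lag_ms = 250), "200 ms")
  expect_error(simulate_lfp(small_schedule(),
                            coupling_ground_truth(f_gamma_receiver_hz = 150),
                            fs = 500),
               "4x")
})

test_that("zero modulation depth gives no phase-amplitude coupling", {
  truth <- coupling_ground_truth(modulation_depth_aversive = 0,
                                 modulation_depth_neutral = 0,
                                 lf_coupling_aversive = 0,
                                 lf_coupling_neutral = 0,
                                 line_noise_amp = 0)
  rec <- small_sim(5, truth)
  fs <- rec$fs
  ph <- Arg(hilfun(bandpass_fir(channel_signal(rec, "AMY1"), 4, 8, fs = fs)))
  amp <- analytic_signal(bandpass_fir(channel_signal(rec, "HIP1"), 80, 120,
                                      fs = fs), fs)$amplitude
  expect_lt(pac_circular_linear(ph, amp)$rho, 0.05)
})

test_that("downstream PAC is non-decreasing in modulation depth", {
  depths <- c(0, 0.3, 0.6, 0.9)
  mean_rho <- sapply(depths, function(d) {
    mean(sapply(1:4, function(sd) {
      truth <- coupling_ground_truth(modulation_depth_aversive = d,
                                     modulation_depth_neutral = d,
                                     line_noise_amp = 0)
      rec <- small_sim(sd, truth)
      ph <- Arg(hilfun(bandpass_fir(channel_signal(rec, "AMY1"), 4, 8,
                                    fs = rec$fs)))
      amp <- analytic_signal(bandpass_fir(channel_signal(rec, "HIP1"),
                                          80, 120, fs = rec$fs),
                             rec$fs)$amplitude
      pac_circular_linear(ph, amp)$rho
    }))
  })
  expect_true(all(diff(mean_rho) > 0))
})

test_that("EOG generator respects the saccade refractory period and rate", {
  # rate 0 -> no saccades
  eog0 <- simulate_eog(small_schedule(), saccade_rate_hz = 0, seed = 1)
  expect_length(eog0$meta$saccade_times_s, 0)
  # all inter-saccade intervals >= 200 ms; counts near the thinned rate
  counts <- sapply(1:10, function(sd) {
    eog <- simulate_eog(small_schedule(), saccade_rate_hz = 1, seed = sd)
    gaps <- diff(eog$meta$saccade_times_s)
    expect_true(all(gaps >= 0.2))
    length(eog$meta$saccade_times_s)
  })
  # session is 112.5 s; Poisson 95% interval around 112 after thinning
  expect_gt(mean(counts), 112.5 - 1.96 * sqrt(112.5) - 20)
  expect_lt(mean(counts), 112.5 + 1.96 * sqrt(112.5))
})

test_that("line noise is common across contacts and removable", {
  truth <- coupling_ground_truth(line_noise_amp = 0.5)
  rec <- small_sim(6, truth)
  reref <- rereference_white_matter(rec)
  p_before <- welch_psd(channel_signal(rec, "AMY1"), rec$fs)
  p_after <- welch_psd(channel_signal(reref, "AMY1"), rec$fs)
  i60 <- which.min(abs(p_before$freq - 60))
  expect_gt(10 * log10(p_before$power[i60] / p_after$power[i60]), 20)
})
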