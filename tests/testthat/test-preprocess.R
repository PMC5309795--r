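# Filtering, line-noise regression, re-referencing, epoching, saccades.

test_that("band-pass is unit-gain and zero-phase in the pass band", {
  fs <- 500
  t <- seq(1 / fs, 10, 1 / fs)
  x <- sin(2 * pi * 6 * t)
  y <- bandpass_fir(x, 4, 8, fs = fs)
  core <- 1000:4000
  expect_lt(abs(max(abs(y[core])) - 1), 0.05)
  cc <- ccf(y[core], x[core], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stop-band attenuation matches the designed frequency response", {
  fs <- 500
  h <- design_bandpass(fs, 4, 8)
  # oracle: evaluate the two-pass (squared) amplitude response by DFT
  nfft <- 2^15
  H <- Mod(fft(c(h, numeric(nfft - length(h)))))^2
  f <- (seq_len(nfft) - 1) * fs / nfft
  stop30 <- H[which.min(abs(f - 30))]
  expect_lt(sqrt(stop30), 0.05)
  # and the filtered signal agrees with that prediction
  t <- seq(1 / fs, 10, 1 / fs)
  y <- bandpass_fir(sin(2 * pi * 30 * t), 4, 8, fs = fs)
  expect_lt(sqrt(mean(y[1000:4000]^2)), 0.05)
})

test_that("broadband conditioning and down-sampling preserve in-band content", {
  fs <- 5000
  t <- seq(1 / fs, 4, 1 / fs)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 900 * t)
  y <- bandpass_fir(x, 0.5, 350, fs = fs, cycles = 2)
  y2 <- resample_recording(y, 2000, fs = fs)
  expect_equal(length(y2), round(length(x) * 2000 / fs))
  t2 <- seq(1 / 2000, 4, 1 / 2000)
  core <- 1000:7000
  expect_lt(sqrt(mean((y2[core] - sin(2 * pi * 10 * t2[core]))^2)), 0.1)
})

test_that("filtering is idempotent in pass-band energy", {
  fs <- 500
  t <- seq(1 / fs, 10, 1 / fs)
  x <- sin(2 * pi * 6 * t)   # pass-band content
  y1 <- bandpass_fir(x, 4, 8, fs = fs)
  y2 <- bandpass_fir(y1, 4, 8, fs = fs)
  core <- 500:4500
  expect_lt(abs(sqrt(mean(y2[core]^2)) / sqrt(mean(y1[core]^2)) - 1), 0.01)
})

test_that("line-noise regression removes mains and spares neighbours", {
  fs <- 500
  t <- seq(1 / fs, 60, 1 / fs)
  # pure 60 Hz: residual < 1%
  r <- remove_line_noise(sin(2 * pi * 60 * t), fs = fs)
  expect_lt(sqrt(mean(r^2)), 0.01)
  # 6 Hz + 60 Hz: the 6 Hz component survives within 1%
  x <- sin(2 * pi * 6 * t) + sin(2 * pi * 60 * t)
  cleaned <- remove_line_noise(x, fs = fs)
  b_ref <- bandpass_fir(sin(2 * pi * 6 * t), 4, 8, fs = fs)
  b_cln <- bandpass_fir(cleaned, 4, 8, fs = fs)
  core <- 2000:28000
  expect_lt(abs(sqrt(mean(b_cln[core]^2)) / sqrt(mean(b_ref[core]^2)) - 1),
            0.01)
  # white noise: broadband PSD essentially untouched away from harmonics
  set.seed(2)
  w <- rnorm(60 * fs)
  wc <- remove_line_noise(w, fs = fs)
  pw <- welch_psd(w, fs); pc <- welch_psd(wc, fs)
  away <- abs(pw$freq - 60) > 1 & abs(pw$freq - 120) > 1 &
    abs(pw$freq - 180) > 1 & pw$freq > 0
  expect_lt(abs(sum(pc$power[away]) / sum(pw$power[away]) - 1), 0.01)
})

test_that("white-matter re-referencing picks the nearest shaft contact", {
  cm <- data.frame(label = c("G1", "G2", "G3", "W4"),
                   region = c("amygdala-BLA", "amygdala-BLA", "amygdala-BLA",
                              "white-matter"),
                   shaft = "A", contact = 1:4)
  set.seed(3)
  dat <- matrix(rnorm(4 * 100), 4)
  rec <- lfp_recording(dat, 100, cm)
  out <- rereference_white_matter(rec)
  expect_equal(out$channel_meta$reference[1:3], rep("W4", 3))
  for (ch in 1:3) expect_equal(out$data[ch, ], dat[ch, ] - dat[4, ],
                               ignore_attr = TRUE)
  # identical target and reference -> zero output
  rec2 <- lfp_recording(rbind(dat[4, ], dat[4, ]), 100,
                        data.frame(label = c("G1", "W2"),
                                   region = c("amygdala-BLA", "white-matter"),
                                   shaft = "A", contact = 1:2))
  expect_true(all(rereference_white_matter(rec2)$data[1, ] == 0))
  # no white matter available -> configuration error
  cm_bad <- cm; cm_bad$region[4] <- "amygdala-BLA"
  expect_error(rereference_white_matter(lfp_recording(dat, 100, cm_bad)),
               "white-matter")
})

test_that("re-referencing is invertible by adding the reference back", {
  rec <- small_sim(7)
  out <- rereference_white_matter(rec)
  ref <- out$channel_meta$reference[1]
  restored <- out$data[1, ] + rec$data[rec$channel_meta$label == ref, ]
  expect_equal(restored, rec$data[1, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("epoching yields one flagged-aware trial per clip", {
  sch <- make_task_schedule()
  fs <- 100
  n <- ceiling(max(sch$onset_s + sch$duration_s) * fs) + 200
  set.seed(4)
  rec <- lfp_recording(matrix(rnorm(n), 1), fs,
                       data.frame(label = "C1", region = "amygdala-BLA",
                                  shaft = "A", contact = 1),
                       events = sch)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data)[1], 141)
  # epoching conserves samples
  i <- 5
  c0 <- round(sch$onset_s[i] * fs) + 1
  expect_equal(ep$data[i, 1, ], rec$data[1, c0 + seq(-50, 149)],
               ignore_attr = TRUE)
  # event too close to the recording start is flagged incomplete
  ev2 <- data.frame(onset_s = 0.2, duration_s = 1, condition = "neutral",
                    block = 1)
  ep2 <- epoch_recording(rec, ev2)
  expect_true(ep2$bad[1])
  expect_match(ep2$bad_reason[1], "incomplete")
  # empty events give empty epochs
  ep0 <- epoch_recording(rec, sch[0, ])
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("saccade detection recovers ground truth with 200 ms spacing", {
  expect_equal(nrow(detect_saccades(matrix(1, 2, 1000), fs = 500)), 0)
  # two large steps 100 ms apart merge into one detected event
  fs <- 500
  set.seed(5)
  n <- 30 * fs
  drift_h <- 5 * lfpcoupling:::narrowband_noise(n, fs, 0.3, bw_hz = 0.4)
  drift_v <- 5 * lfpcoupling:::narrowband_noise(n, fs, 0.3, bw_hz = 0.4)
  h <- drift_h +
    c(rep(0, 15 * fs - 1), rep(40, n - 15 * fs + 1)) +     # step at 15 s
    c(rep(0, 15 * fs + 49), rep(30, n - 15 * fs - 49))     # +100 ms later
  det <- detect_saccades(rbind(h, drift_v), fs = fs)
  near <- det$time_s[abs(det$time_s - 15) < 0.3]
  expect_equal(length(near), 1)
  # recovery against generator metadata
  eog <- simulate_eog(small_schedule(), saccade_rate_hz = 0.5, seed = 11)
  truth <- eog$meta$saccade_times_s
  det2 <- detect_saccades(eog)
  hit <- sapply(truth, function(tt) any(abs(det2$time_s - tt) < 0.02))
  expect_gte(mean(hit), 0.9)
})

test_that("perisaccadic high gamma is calibrated and detects injections", {
  fs <- 500
  sch <- small_schedule()
  # null: LFP independent of saccade times -> ~5% significant points
  frac <- sapply(1:6, function(sd) {
    rec <- small_sim(sd + 20)
    eog <- simulate_eog(sch, saccade_rate_hz = 1, fs = fs, seed = sd)
    sac <- data.frame(time_s = eog$meta$saccade_times_s)
    res <- perisaccadic_hg(rec, sac, channel = "AMY1")
    mean(res$p < 0.05)
  })
  expect_gt(mean(frac), 0.01)
  expect_lt(mean(frac), 0.12)
  # injection: gamma burst at each saccade is detected
  rec <- small_sim(30)
  set.seed(6)
  sac_t <- sort(runif(60, 1, recording_duration(rec) - 1))
  sac_t <- sac_t[c(TRUE, diff(sac_t) > 0.25)]
  burst <- sin(2 * pi * 100 * seq(0, 0.1, 1 / fs)) *
    sin(pi * seq(0, 1, length.out = fs / 10 + 1))
  x <- rec$data[1, ]
  for (tt in sac_t) {
    i0 <- round((tt + 0.05) * fs)
    x[i0:(i0 + length(burst) - 1)] <- x[i0:(i0 + length(burst) - 1)] + 3 * burst
  }
  rec$data[1, ] <- x
  res <- perisaccadic_hg(rec, data.frame(time_s = sac_t), channel = 1)
  post <- res$times > 0 & res$times < 0.2
  base <- res$times < 0
  m <- res$mean_aversive + res$mean_neutral
  expect_gt(max(m[post]), max(m[base]) + 0.2)
  # zero saccades -> warning and NULL
  expect_warning(out <- perisaccadic_hg(rec, data.frame(time_s = numeric(0))),
                 "no saccades")
  expect_null(out)
})
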