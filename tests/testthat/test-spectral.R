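# Welch PSD, power-law slope, band selection, filter bank, envelope PSD.

test_that("Welch PSD satisfies Parseval and localises a sine", {
  fs <- 500
  set.seed(1)
  x <- rnorm(60 * fs)
  ps <- welch_psd(x, fs)
  df <- ps$freq[2] - ps$freq[1]
  expect_lt(abs(sum(ps$power) * df - 1), 0.05)
  t <- seq(1 / fs, 30, 1 / fs)
  ps6 <- welch_psd(sin(2 * pi * 6 * t), fs)
  expect_equal(ps6$freq[which.max(ps6$power)], 6)
  expect_error(welch_psd(rnorm(100), fs), "short")
})

test_that("power-law fit recovers exact and simulated exponents", {
  # flat spectrum: beta = 0, chi = 0
  flat <- structure(data.frame(freq = 1:100, power = rep(2, 100)),
                    class = c("power_spectrum", "data.frame"))
  fit <- fit_powerlaw(flat, c(1, 100))
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$chi, 0, tolerance = 1e-12)
  # exact P = f^(-2): chi = 2 to machine precision in log-log space
  exact <- structure(data.frame(freq = 1:100, power = (1:100)^(-2)),
                     class = c("power_spectrum", "data.frame"))
  expect_equal(fit_powerlaw(exact, c(1, 100))$chi, 2, tolerance = 1e-10)
  expect_error(fit_powerlaw(exact, c(50, 50.5)), "fewer than 3")
  # simulated 1/f^1.5 noise: recovered within 0.2
  fs <- 500
  chis <- sapply(1:5, function(sd) {
    set.seed(sd)
    x <- lfpcoupling:::powerlaw_noise(120 * fs, fs, 1.5)
    fit_powerlaw(welch_psd(x, fs), c(2, 80))$chi
  })
  expect_lt(max(abs(chis - 1.5)), 0.2)
})

test_that("subject band selection finds peaks above the aperiodic fit", {
  fs <- 500
  set.seed(7)
  n <- 120 * fs
  bg <- lfpcoupling:::powerlaw_noise(n, fs, 2)
  osc <- lfpcoupling:::narrowband_noise(n, fs, 6, bw_hz = 2)
  ps <- welch_psd(bg + 2 * osc, fs)
  fit <- fit_powerlaw(ps, c(2, 80))
  bs <- select_subject_band(ps, fit)
  expect_lt(abs(bs$centre_hz - 6), 0.5)
  expect_equal(bs$high_hz - bs$low_hz, 4)
  expect_false(bs$fallback)
  # two bumps: the one farther above the aperiodic fit wins (distances are
  # measured in log-power, so the 10 Hz bump must be clearly smaller)
  osc10 <- lfpcoupling:::narrowband_noise(n, fs, 10, bw_hz = 2)
  ps2 <- welch_psd(bg + 2 * osc + 0.3 * osc10, fs)
  bs2 <- select_subject_band(ps2, fit_powerlaw(ps2, c(2, 80)))
  expect_lt(abs(bs2$centre_hz - 6), 0.5)
  # exact power law: no peak -> fallback flag
  exact <- structure(data.frame(freq = seq(0.5, 100, 0.5),
                                power = seq(0.5, 100, 0.5)^(-2)),
                     class = c("power_spectrum", "data.frame"))
  expect_warning(bs3 <- select_subject_band(exact,
                                            fit_powerlaw(exact, c(2, 80))),
                 "no oscillatory peak")
  expect_true(bs3$fallback)
  expect_equal(bs3$centre_hz, 8)
  # scaling invariance
  ps_scaled <- ps; ps_scaled$power <- ps$power * 37
  bs4 <- select_subject_band(ps_scaled, fit_powerlaw(ps_scaled, c(2, 80)))
  expect_equal(bs4$centre_hz, bs$centre_hz)
})

test_that("filter-bank grid follows the 10% spacing / 0.3 fractional width", {
  centres <- filterbank_centres(1, 30)
  i10 <- which.min(abs(centres - 10))
  expect_equal(centres[i10 + 1], centres[i10] * 1.1)
  # consecutive bands overlap: c_{k+1} - 0.3 c_{k+1} < c_k + 0.3 c_k
  expect_true(all(centres[-1] * 0.7 < centres[-length(centres)] * 1.3))
})

test_that("filter-bank analytic signals have the cosine phase convention", {
  fs <- 500
  t <- seq(1 / fs, 20, 1 / fs)
  bank <- filterbank_decompose(cos(2 * pi * 10 * t), fs, 9, 12)
  b10 <- bank[[which.min(abs(sapply(bank, function(b) b$band$centre_hz) - 10))]]
  core <- 2000:8000
  expect_lt(abs(mean(b10$amplitude[core]) - 1), 0.05)
  peaks <- core[cos(2 * pi * 10 * t[core]) > 0.9999]
  expect_lt(max(abs(b10$phase[peaks])), 0.1)
})

test_that("analytic amplitude and phase reconstruct the band-passed signal", {
  fs <- 500
  rec <- small_sim(8)
  xb <- bandpass_fir(channel_signal(rec, "AMY1"), 4, 8, fs = fs)
  a <- analytic_signal(xb, fs)
  recon <- a$amplitude * cos(a$phase)
  expect_gt(cor(recon, xb), 0.99)
})

test_that("gamma envelope PSD exposes the modulating rhythm", {
  fs <- 500
  t <- seq(1 / fs, 120, 1 / fs)
  set.seed(9)
  carrier <- sin(2 * pi * 100 * t)
  am <- (1 + 0.8 * cos(2 * pi * 6 * t)) * carrier + rnorm(length(t), sd = 0.3)
  ps <- hg_envelope_psd(am, fs, 100)
  sel <- ps$freq >= 3 & ps$freq <= 12
  expect_equal(ps$freq[sel][which.max(ps$power[sel])], 6)
  # unmodulated carrier: no comparable low-frequency envelope peak
  un <- carrier + rnorm(length(t), sd = 0.3)
  ps0 <- hg_envelope_psd(un, fs, 100)
  expect_gt(max(ps$power[sel]) / max(ps0$power[sel]), 10)
  # simulation: envelope peak at the driver's low frequency
  rec <- small_sim(8)
  pse <- hg_envelope_psd(channel_signal(rec, "HIP1"), rec$fs, 100)
  sel2 <- pse$freq >= 4 & pse$freq <= 12
  expect_lt(abs(pse$freq[sel2][which.max(pse$power[sel2])] - 6), 1)
})
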