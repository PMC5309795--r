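#!/usr/bin/env Rscript
# Step 5 — phase locking and directional phase-amplitude coupling.
#
# All 3 x 4 medial amygdala-hippocampus pairs enter the two-step PLV
# analysis (within-condition 99th-percentile thresholds, then a label
# permutation on the difference); the most significant pair is forwarded to
# the directional analyses: z-PAC in both directions, the +/-200 ms lag-PAC
# profile, the PLV difference spectrum (1-30 Hz) and the high-gamma envelope
# PSD. Outputs under results/coupling/.

suppressMessages(library(lfpcoupling))
dir.create("results/coupling", recursive = TRUE, showWarnings = FALSE)

rec <- load_recording("results/data/session_clean")
seed <- 20260925
fs <- rec$fs
labels <- sample_conditions(rec)

bands <- read.delim("results/spectral/bands.tsv")
centre <- mean(bands$centre_hz)
pair_band <- band_spec(centre)
cat(sprintf("pair-analysis band: %.1f-%.1f Hz\n", pair_band$low_hz,
            pair_band$high_hz))

pairs <- select_pairs(rec$channel_meta)
pl <- plv_contrast(rec, pairs, pair_band, n_perm = 200, seed = seed)
write.table(pl$table, "results/coupling/plv_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tab <- pl$table
cat(sprintf("%d/%d pairs pass both within-condition thresholds\n",
            sum(tab$passed), nrow(tab)))
best <- which(tab$passed)[order(tab$p[tab$passed])][1]
cat(sprintf("most significant pair: %s-%s (diff %.3f, p = %.4g)\n",
            tab$chan_i[best], tab$chan_j[best], tab$difference[best],
            tab$p[best]))

ch_a <- tab$chan_i[best]; ch_h <- tab$chan_j[best]
b_a <- bands[bands$channel == ch_a, ]
b_h <- bands[bands$channel == ch_h, ]
x_a <- channel_signal(rec, ch_a); x_h <- channel_signal(rec, ch_h)
ph_a <- analytic_signal(bandpass_fir(x_a, b_a$low_hz, b_a$high_hz, fs = fs), fs)$phase
ph_h <- analytic_signal(bandpass_fir(x_h, b_h$low_hz, b_h$high_hz, fs = fs), fs)$phase
amp_h <- analytic_signal(bandpass_fir(x_h, 70, 180, fs = fs), fs)$amplitude
amp_a <- analytic_signal(bandpass_fir(x_a, 70, 180, fs = fs), fs)$amplitude

zf <- z_pac(ph_a, amp_h, labels, fs, n_perm = 200, seed = seed)
zr <- z_pac(ph_h, amp_a, labels, fs, n_perm = 200, seed = seed + 1)
cat(sprintf("z-PAC amygdala-phase -> hippocampal-HG: %.2f\n", zf$z))
cat(sprintf("z-PAC hippocampal-phase -> amygdala-HG: %.2f\n", zr$z))

lf <- lag_pac(ph_a, amp_h, fs, labels = labels)
lr <- lag_pac(ph_h, amp_a, fs, labels = labels)
cat(sprintf("lag-PAC peak (forward): %g ms (negative = amygdala leads)\n",
            lf$peak_lag_ms))
write.table(data.frame(lag_ms = lf$lags_ms, rho_forward = lf$rho,
                       rho_reverse = lr$rho),
            "results/coupling/lag_pac.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sp <- plv_spectrum(x_a, x_h, labels, fs, 2, 30)
write.table(sp$smooth, "results/coupling/plv_spectrum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PLV difference spectrum peaks at %.1f Hz\n",
            sp$centres[which.max(sp$z)]))

env <- hg_envelope_psd(x_h, fs, 100)
write.table(env, "results/coupling/hg_envelope_psd.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sel <- env$freq >= 4 & env$freq <= 12
cat(sprintf("HG envelope PSD peak (4-12 Hz): %.1f Hz\n",
            env$freq[sel][which.max(env$power[sel])]))

summary <- list(pair = c(ch_a, ch_h), z_pac_forward = zf$z,
                z_pac_reverse = zr$z, peak_lag_forward_ms = lf$peak_lag_ms,
                peak_lag_reverse_ms = lr$peak_lag_ms,
                envelope_peak_hz = env$freq[sel][which.max(env$power[sel])])
jsonlite::write_json(summary, "results/coupling/summary.json",
                     auto_unbox = TRUE, digits = NA)
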