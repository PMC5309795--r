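#!/usr/bin/env Rscript
# Step 6 — phase slope index and spectral Granger causality.
#
# PSI is computed between the amygdala band-limited signal and the
# hippocampal high-gamma envelope (1 s windows per condition; the 8*delta_f
# estimation band coincides with the subject band). Granger causality uses
# the raw pair low-passed at 85 Hz and down-sampled to 250 Hz, with 1.5 s
# clip epochs as trial realizations, AIC order selection, and the
# condition-flip null for the aversive-neutral contrast.
# Outputs under results/directionality/.

suppressMessages(library(lfpcoupling))
dir.create("results/directionality", recursive = TRUE, showWarnings = FALSE)

rec <- load_recording("results/data/session_clean")
seed <- 20260925
fs <- rec$fs
labels <- sample_conditions(rec)
pair <- jsonlite::read_json("results/coupling/summary.json",
                            simplifyVector = TRUE)$pair
bands <- read.delim("results/spectral/bands.tsv")
b_a <- bands[bands$channel == pair[1], ]
x_a <- channel_signal(rec, pair[1]); x_h <- channel_signal(rec, pair[2])

# --- PSI ---
xb <- bandpass_fir(x_a, b_a$low_hz, b_a$high_hz, fs = fs)
amp_h <- analytic_signal(bandpass_fir(x_h, 70, 180, fs = fs), fs)$amplitude
psi_by_cond <- sapply(c("aversive", "neutral"), function(cond) {
  starts <- seq(1L, length(xb) - fs, by = fs %/% 2L)
  keep <- starts[vapply(starts, function(s) {
    all(labels[s:(s + fs - 1L)] == cond)
  }, logical(1))]
  seg <- function(s) t(vapply(keep, function(c0) s[c0:(c0 + fs - 1L)],
                              numeric(fs)))
  psi(seg(xb), seg(amp_h), fs, nu_hz = b_a$centre_hz,
      delta_f_hz = (b_a$high_hz - b_a$low_hz) / 8)$psi
})
cat(sprintf("PSI amygdala -> hippocampal HG envelope: aversive %.3f, neutral %.3f\n",
            psi_by_cond["aversive"], psi_by_cond["neutral"]))

# --- Granger ---
dn <- function(x) resample_recording(lowpass_fir(x, 85, fs = fs), 250, fs = fs)
fsg <- 250
xg <- dn(x_a); yg <- dn(x_h)
sch <- rec$events
idx <- which(sch$duration_s >= 1.5)
nsg <- round(1.5 * fsg)
segg <- function(s) t(vapply(idx, function(i) {
  c0 <- round(sch$onset_s[i] * fsg) + 1L
  s[c0:(c0 + nsg - 1L)]
}, numeric(nsg)))
gx <- segg(xg); gy <- segg(yg)
cond <- as.character(sch$condition[idx])
ct <- granger_condition_contrast(gx, gy, cond, fsg, n_perm = 200,
                                 seed = seed, order_range = 1:12,
                                 freqs = seq(1, 85, 0.5))
cat(sprintf("VAR order (AIC): %d\n", ct$fit1$order))
lowf <- ct$freqs <= 12
cat(sprintf("low-frequency GC diff (aversive-neutral): forward %.4f, reverse %.4f\n",
            mean(ct$xy$diff[lowf]), mean(ct$yx$diff[lowf])))
cat(sprintf("frequencies flagged aversive>neutral: forward %.0f%%, reverse %.0f%%\n",
            100 * mean(ct$xy$diff > ct$xy$upper),
            100 * mean(ct$yx$diff > ct$yx$upper)))
write.table(data.frame(freq = ct$freqs,
                       diff_forward = ct$xy$diff, lower_f = ct$xy$lower,
                       upper_f = ct$xy$upper, diff_reverse = ct$yx$diff,
                       lower_r = ct$yx$lower, upper_r = ct$yx$upper),
            "results/directionality/granger_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

direction <- if (psi_by_cond["aversive"] > 0 &&
                 mean(ct$xy$diff[lowf]) > mean(ct$yx$diff[lowf])) {
  "amygdala->hippocampus"
} else {
  "inconclusive"
}
cat("direction call:", direction, "\n")
jsonlite::write_json(list(psi = as.list(psi_by_cond),
                          granger_order = ct$fit1$order,
                          direction = direction),
                     "results/directionality/summary.json",
                     auto_unbox = TRUE, digits = NA)
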