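#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study session.
#
# Builds the block/clip schedule (9 neutral landscape blocks alternating with
# 8 aversive fearful-face blocks, ~24 s each, 70 + 71 clips), then simulates
# a two-shaft recording in which amygdala theta (6 Hz) entrains hippocampal
# high gamma (100 Hz) with a 15 ms conduction lag, more strongly during
# aversive blocks. An EOG pair with saccades is generated alongside.
# Outputs: results/data/session.{edf,events.tsv,json}, eog.{edf,...}

suppressMessages(library(lfpcoupling))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

fs <- 500          # simulation rate: keeps the session tractable while
                   # leaving the 70-180 Hz band fully resolvable
seed <- 20260925

sch <- make_task_schedule()
truth <- coupling_ground_truth()
rec <- simulate_lfp(sch, truth, fs = fs, seed = seed)
print(rec)
write_recording(rec, "results/data/session")

eog <- simulate_eog(sch, saccade_rate_hz = 2, fs = fs, seed = seed + 1)
write_recording(eog, "results/data/eog")

cat(sprintf("session: %.1f s, %d clips; ground truth: depth %.2f/%.2f, lag %g ms\n",
            recording_duration(rec), nrow(sch),
            truth$modulation_depth_aversive, truth$modulation_depth_neutral,
            truth$conduction_lag_ms))
cat(sprintf("EOG: %d ground-truth saccades\n", length(eog$meta$saccade_times_s)))
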