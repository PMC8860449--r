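#!/usr/bin/env Rscript
# Step 2 — refine and characterize spike-wave discharges.
#
# Consumes the simulated session from step 1. Coarse windows emulate the
# manual (blinded) annotation stage: ground-truth bounds grown by 1 s and
# jittered by 0.25 s. Each candidate is then refined to its first/last
# supra-threshold peak (2.5 x pre-event RMS), filtered at 2 s, checked
# for EMG atonia, and characterized by dominant frequency and harmonic
# score.

library(swdquant)

rec <- read_recording("scratch/session/recording.csv")
truth <- read_events("results/session/ground_truth_events.csv")

set.seed(2)
coarse <- coarse_events(
  pmax(0.1, truth$t_start - 1 + rnorm(nrow(truth), 0, 0.25)),
  pmin(rec$duration, truth$t_end + 1 + rnorm(nrow(truth), 0, 0.25)))

events <- process_events(rec, coarse, swd_config())
rej <- attr(events, "rejections")

write.csv(events, "results/session/events.csv", row.names = FALSE)
write.csv(rej, "results/session/rejections.csv", row.names = FALSE)

cat(sprintf("Accepted %d of %d candidates (%d rejected)\n",
            nrow(events), nrow(coarse), nrow(rej)))
cat(sprintf("  duration: %.1f +/- %.1f s (mean +/- SD)\n",
            mean(events$duration), sd(events$duration)))
cat(sprintf("  dominant frequency: %.2f +/- %.2f Hz\n",
            mean(events$dominant_freq), sd(events$dominant_freq)))
cat(sprintf("  harmonic score: median %.1f (all flagged harmonic: %s)\n",
            median(events$harmonic_score), all(events$is_harmonic)))

# boundary accuracy against ground truth (matched by overlap)
match <- vapply(seq_len(nrow(events)), function(i) {
  ov <- pmin(events$t_offset[i], truth$t_end) -
    pmax(events$t_onset[i], truth$t_start)
  which.max(ov)
}, integer(1))
on_err <- events$t_onset - truth$t_start[match]
off_err <- events$t_offset - truth$t_end[match]
cat(sprintf("  boundary error: onset %.0f ms, offset %.0f ms (median abs)\n",
            1000 * median(abs(on_err)), 1000 * median(abs(off_err))))
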