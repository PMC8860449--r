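#!/usr/bin/env Rscript
# Step 1 — simulate one instrumented-rat session.
#
# Generates the default 60-min session (40 min normoxia, 20 min hypoxia,
# gas exchange at t = 2400 s) with ground truth, and writes it for the
# downstream steps. The full multi-channel recording is large, so it goes
# under scratch/ (regenerable); the small ground-truth tables go under
# results/session/.

library(swdquant)

dir.create("scratch/session", showWarnings = FALSE, recursive = TRUE)
dir.create("results/session", showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(seed = 1)
sess <- generate_session(cfg)

write_recording(sess$recording, "scratch/session/recording.csv")
write_events(data.frame(t_start = sess$truth$events$t_start,
                        t_end = sess$truth$events$t_end,
                        label = "ground_truth"),
             "results/session/ground_truth_events.csv")
write_protocol(sess$truth$timeline, "results/session/protocol.json")
write.csv(sess$truth$resp_schedule,
          "results/session/resp_schedule.csv", row.names = FALSE)

ev <- sess$truth$events
pre <- sum(ev$t_start < cfg$t_zero)
cat(sprintf("Simulated %d s session at %g Hz with %d injected SWDs\n",
            round(sess$recording$duration), cfg$fs, nrow(ev)))
cat(sprintf("  %d before gas exchange, %d during hypoxia\n",
            pre, nrow(ev) - pre))
cat(sprintf("  mean injected duration %.1f s, f0 range %.1f-%.1f Hz\n",
            mean(ev$t_end - ev$t_start), min(ev$f0), max(ev$f0)))
cat("Recording written to scratch/session/recording.csv\n")
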