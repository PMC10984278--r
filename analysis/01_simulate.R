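#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Emits one Karman-gait, one braking and one still trial (pose CSV in the
# DeepLabCut dialect, EMG CSV, ground-truth events/bursts) under
# results/trials/. These three trials are re-read by the later steps, so
# the whole workflow exercises the same file formats the lab instruments
# produce.

library(finwake)

out_dir <- "results/trials"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

meta <- trial_meta(body_length_L = 21.7, flow_speed_U = 65,
                   cylinder_origin = c(200, 300))
seed <- 2024

for (beh in c("karman_gait", "braking", "still")) {
  cfg <- default_synth_config(beh, meta, seed = seed)
  trial <- simulate_trial(cfg)
  base <- file.path(out_dir, beh)
  write_pose_csv(trial$pose, paste0(base, "_pose.csv"), meta,
                 pixel_to_cm = 0.05)
  write_emg_csv(trial$emg, paste0(base, "_emg.csv"))
  if (nrow(trial$truth$events) > 0)
    write.csv(trial$truth$events, paste0(base, "_truth_events.csv"),
              row.names = FALSE)
  if (nrow(trial$truth$bursts) > 0)
    write.csv(trial$truth$bursts, paste0(base, "_truth_bursts.csv"),
              row.names = FALSE)
  cat(sprintf("%-12s %d frames, %d EMG samples, %d planted events, %d bursts\n",
              beh, nrow(trial$pose$x), nrow(trial$emg$channels),
              nrow(trial$truth$events), nrow(trial$truth$bursts)))
}
cat("trial files under", out_dir, "\n")
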