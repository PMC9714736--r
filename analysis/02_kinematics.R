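#!/usr/bin/env Rscript
# Stage 2 — sperm kinematics.
#
# Two jobs: (a) demonstrate the track-level path — circular tracks at a known
# speed, VCL recomputed from raw coordinates and compared with the request —
# and (b) collapse the per-sperm velocity tables from stage 1 into per-sample
# summaries (motile-only mean VCL + motile fraction, threshold 5 um/s).

library(echinofert)

dir.create("results/kinematics", recursive = TRUE, showWarnings = FALSE)

tracks <- generate_tracks(25, mean_speed = 300, radius = 50, frame_rate = 60,
                          duration = 10, seed = 20260102)
write_track_csv(tracks, "results/kinematics/demo_tracks.csv")
smry <- summarize_sample(tracks, sample_id = "demo_300")
cat(sprintf("demo tracks: requested 300 um/s, mean VCL %.4f um/s, motile %.0f%%\n",
            smry$mean_vcl, 100 * smry$motile_fraction))

for (sp in c("sand", "urchin", "factorial")) {
  vel <- read_velocity_csv(sprintf("results/data/%s_velocity.csv", sp))
  agg <- aggregate_velocity(vel, threshold = 5)
  write.csv(agg, sprintf("results/kinematics/%s_vcl.csv", sp),
            row.names = FALSE)
  cat(sprintf("%s: %d samples, VCL %.0f-%.0f um/s, motility %.2f-%.2f\n",
              sp, nrow(agg), min(agg$mean_vcl), max(agg$mean_vcl),
              min(agg$motile_fraction), max(agg$motile_fraction)))
}
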