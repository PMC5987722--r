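#!/usr/bin/env Rscript
## Mechanical coupling of neighboring domains from paired trajectories:
## per-step correlation angles, the <alpha>(distance) profile, the
## two-regression transition point, and the coarser-time-step control.

suppressMessages(library(domainscope))
dir.create("results", showWarnings = FALSE)

raw <- read.csv("results/trajectory_pairs.csv")
tracks <- structure(raw, frame_interval = 0.5,
                    class = c("track_set", "data.frame"))

prof <- coupling_profile(tracks, bin_width = 50)
print(prof)
fit <- fit_transition(prof, near_cut = 400, far_cut = 600)
print(fit)

write.csv(prof$points, "results/coupling_points.csv", row.names = FALSE)
write.csv(prof$bins, "results/coupling_bins.csv", row.names = FALSE)

## stability control: reanalyze at a 10x coarser time step. The simulated
## tracks span 20 s, so a 10-s step leaves 2 steps/pair; the transition
## estimate should stay within ~15%.
slow <- resample_time_step(tracks, 5)
fit5 <- fit_transition(coupling_profile(slow))
cat(sprintf("transition at 0.5-s step: %.0f nm; at 5-s step: %.0f nm (%.1f%% change)\n",
            fit$d_star_nm, fit5$d_star_nm,
            100 * (fit5$d_star_nm / fit$d_star_nm - 1)))

jsonlite::write_json(list(
  d_star_nm = fit$d_star_nm, alpha_star_deg = fit$alpha_star_deg,
  n_near = fit$n_near, n_far = fit$n_far,
  d_star_resampled_nm = fit5$d_star_nm),
  "results/coupling_fit.json", auto_unbox = TRUE, digits = NA)
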