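#!/usr/bin/env Rscript
## Generate the default synthetic datasets every later stage consumes:
## a ground-truth replication-domain scene, its STORM acquisition, a
## dual-color confocal scene per pulse interval, coupled trajectory
## pairs, and combed-fiber standards.

suppressMessages(library(domainscope))
dir.create("results", showWarnings = FALSE)

seed <- 1L

scene <- sample_scene(scene_config(), seed = seed)
print(scene)
write_scene_csv(scene, "results/scene_ground_truth.csv")

img <- imaging_config(loc_precision_sigma = 8)
events <- simulate_event_list(scene, img, seed = seed + 1L)
print(events)
write.csv(as.data.frame(events), "results/storm_events.csv",
          row.names = FALSE)

tru <- scene_truth(scene)
cat(sprintf(
  "ground truth: %d domains, median %.0f stretches/domain, median intra-NND %.1f nm, %.1f%% solitary\n",
  nrow(scene$centers), tru$median_stretches, tru$median_intra_nnd,
  100 * tru$solitary_fraction))

## distances drawn uniformly over the observed range of the live-cell data
set.seed(seed + 2L)
d <- runif(2000, 50, 1500)
tracks <- simulate_trajectory_pairs(2000, d, motion_model(), n_frames = 40,
                                    seed = seed + 2L)
write.csv(as.data.frame(tracks), "results/trajectory_pairs.csv",
          row.names = FALSE)
cat("simulated", length(unique(tracks$pair_id)), "trajectory pairs\n")

fibers <- simulate_combed_fibers(c(4.36, 9.41, 23.13), 1.77,
                                 length_noise_cv = 0.1, n_per_class = 200,
                                 seed = seed + 3L)
write.csv(fibers, "results/combed_standards.csv", row.names = FALSE)
cat("simulated", nrow(fibers), "combed lambda-DNA standards\n")
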