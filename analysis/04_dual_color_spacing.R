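#!/usr/bin/env Rscript
## Inter-domain spacing from dual-color 3D confocal scenes: simulate
## neighbor-pair scenes across pulse intervals, detect diffraction-limited
## domains per channel, and measure directed cross-channel
## nearest-neighbor distances.

suppressMessages(library(domainscope))
dir.create("results", showWarnings = FALSE)

seed <- 1L
img <- imaging_config()
cfg <- scene_config(n_rds = 20, field_size = c(10000, 10000, 4000),
                    min_center_spacing = 1800, solitary_fraction = 0)

dts <- c(0, 15, 30, 45, 60, 90, 120)
measure_cells <- function(dt, n_cells = 3) {
  nnd <- unlist(lapply(seq_len(n_cells), function(cell) {
    dsc <- sample_dual_scene(cfg, delta_t = dt,
                             seed = seed + 100 * dt + cell)
    d1 <- detect_particles_3d(simulate_confocal_stack(dsc, img, channel = 1))
    d2 <- detect_particles_3d(simulate_confocal_stack(dsc, img, channel = 2))
    cross_channel_nnd(d1, d2, delta_t = dt)$nnd_nm
  }))
  structure(data.frame(nnd_nm = nnd), delta_t = dt,
            class = c("nnd_table", "data.frame"))
}
tables <- lapply(dts, measure_cells)

s <- summarize_by_dt(tables)
print(s)
cat("median NND increases monotonically with the pulse interval:",
    attr(s, "monotone_median"), "\n")
cat(sprintf("median spacing at dt = 60 min: %.0f nm\n",
            s$median_nm[s$delta_t == 60]))
write.csv(s, "results/spacing_by_dt.csv", row.names = FALSE)

all_nnd <- do.call(rbind, lapply(tables, function(t)
  data.frame(delta_t = attr(t, "delta_t"), nnd_nm = t$nnd_nm)))
write.csv(all_nnd, "results/spacing_nnd_all.csv", row.names = FALSE)
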