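#!/usr/bin/env Rscript
## DNA combing length calibration: fit the stretching rate from simulated
## lambda-DNA standards, convert comet lengths to kbp, and run the
## fork-yield consistency arithmetic.

suppressMessages(library(domainscope))
dir.create("results", showWarnings = FALSE)

standards <- read.csv("results/combed_standards.csv")
fit <- fit_stretching_rate(standards, through_origin = TRUE)
print(fit)

## convert a batch of comet lengths simulated from an 18.2-kbp truth
comets <- simulate_combed_fibers(18.2, fit$rate_kb_per_um,
                                 length_noise_cv = 0.25, n_per_class = 300,
                                 seed = 4L)
conv <- comet_length_to_kbp(comets$measured_um, fit)
cat(sprintf("comet lengths: mean %.1f kbp (sd %.1f) from 300 comets\n",
            mean(conv$kbp), sd(conv$kbp)))
write.csv(conv, "results/comet_lengths_kbp.csv", row.names = FALSE)

## consistency: four forks at ~2 kb/min over the ~60-min domain
## replication window account for the genomic size of one domain
yield <- replication_yield(n_forks = 4, fork_speed_kb_per_min = 2,
                           duration_min = 60)
cat(sprintf("4 forks x 2 kb/min x 60 min = %.0f kb (~500-kbp domain)\n",
            yield))
cat(sprintf("domain/linker compaction ratio: %.0f-fold; linker gap: %.0f nm\n",
            compaction_ratio(), linker_gap()))

jsonlite::write_json(list(rate_kb_per_um = fit$rate_kb_per_um,
                          rate_se = fit$rate_se,
                          comet_mean_kbp = mean(conv$kbp),
                          replication_yield_kb = yield),
                     "results/combing_summary.json",
                     auto_unbox = TRUE, digits = NA)
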