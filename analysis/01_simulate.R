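#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs — a two-group cohort of task
# trajectories with known effect structure, a pre-intervention clinical
# table, and pre/post EEG+EMG recordings with lateralized beta coupling.
#
# Writes delimited-text artifacts under results/01_simulate/.

suppressPackageStartupMessages(library(sonirehab))
seed <- 20260920
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating cohort: 14 + 14 patients, 15 sessions + baseline, ",
        "group effect 0.5 SD")
design <- cohort_design(seed = seed)
cohort <- gen_cohort(design)
write_table_prov(cohort$truth, file.path(out, "cohort_truth.csv"),
                 provenance = list(seed = seed))
# a few example trajectories for inspection
for (i in c(1, 2)) {
  write_trajectory(cohort$sets[[i]]$trajectory,
                   file.path(out, sprintf("example_trajectory_%d.csv", i)),
                   provenance = c(cohort$sets[[i]]$meta, list(seed = seed)))
}
message("  wrote cohort truth table (", nrow(cohort$truth), " patient-sessions)")

message("Simulating clinical table (14/group, null offsets)")
clin <- gen_clinical_table(14, seed = seed)
write_table_prov(clin, file.path(out, "clinical_table.csv"),
                 provenance = list(seed = seed))

message("Simulating pre/post ephys for one subject (C3-lateralized coupling)")
pre <- gen_ephys(coupling_design(coupling_strength = 0, n_trials = 100,
                                 seed = seed))
post <- gen_ephys(coupling_design(coupling_strength = 0.6,
                                  coupled_channels = c("C3", "F3", "P3"),
                                  n_trials = 100, seed = seed + 1))
write_ephys(pre, file.path(out, "ephys_pre.csv"))
write_ephys(post, file.path(out, "ephys_post.csv"))
message("  pre: ", length(pre$events), " trials; post: ",
        length(post$events), " trials")
message("Done: ", out)
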