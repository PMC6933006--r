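#!/usr/bin/env Rscript
# Stage 5: cortico-muscular coherence. Preprocesses the pre/post recordings,
# detects EMG onsets, epochs around them, computes the low-beta (14-20 Hz)
# EEG-EMG weighted phase lag index per channel, and runs the cluster-based
# permutation comparison of post vs. pre maps.

suppressPackageStartupMessages(library(sonirehab))
seed <- 20260920
out <- "results/05_coherence"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pre_rec <- preprocess(gen_ephys(coupling_design(coupling_strength = 0,
                                                n_trials = 100, seed = seed)))
post_rec <- preprocess(gen_ephys(coupling_design(
  coupling_strength = 0.6, coupled_channels = c("C3", "F3", "P3"),
  n_trials = 100, seed = seed + 1)))

onsets_pre <- detect_onsets(pre_rec)
onsets_post <- detect_onsets(post_rec)
message(sprintf("EMG onsets: %d pre, %d post", length(onsets_pre),
                length(onsets_post)))

tr_pre <- epoch_recording(pre_rec, events = onsets_pre)
tr_post <- epoch_recording(post_rec, events = onsets_post)
message(sprintf("Epochs kept: %d pre (%d rejected), %d post (%d rejected)",
                dim(tr_pre$epochs)[1], nrow(tr_pre$rejected),
                dim(tr_post$epochs)[1], nrow(tr_post$rejected)))

w_pre <- wpli(tr_pre)
w_post <- wpli(tr_post)
maps <- merge(as.data.frame(w_pre)[, c("channel", "wpli", "significant")],
              as.data.frame(w_post)[, c("channel", "wpli", "significant")],
              by = "channel", suffixes = c("_pre", "_post"))
write_table_prov(maps, file.path(out, "wpli_maps.csv"),
                 provenance = list(seed = seed, band = "14-20 Hz"))
message("Top post-therapy WPLI channels:")
print(head(maps[order(-maps$wpli_post), ], 5), digits = 2, row.names = FALSE)

cl <- cluster_permutation(tr_pre, tr_post, n_perm = 1000, seed = seed)
print(cl)
cl_tab <- if (length(cl$clusters)) do.call(rbind, lapply(cl$clusters,
  function(c) data.frame(channels = paste(c$channels, collapse = "+"),
                         sign = c$sign, stat = c$stat, p = c$p))) else
  data.frame(channels = character(0), sign = character(0),
             stat = numeric(0), p = numeric(0))
write_table_prov(cl_tab, file.path(out, "clusters.csv"),
                 provenance = list(seed = seed, n_perm = 1000))
# channel/value pairs for external topographic plotting
topo <- merge(montage_1020(), maps, by = "channel")
write_table_prov(topo[, c("channel", "x", "y", "wpli_pre", "wpli_post")],
                 file.path(out, "topography.csv"),
                 provenance = list(seed = seed))
message("Done: ", out)
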