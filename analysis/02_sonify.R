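#!/usr/bin/env Rscript
# Stage 2: movement-to-music mapping. Renders the reference event stream for
# the daily scale task, sonifies a clean and a corrupted trajectory, and
# writes JSON-lines and MIDI event files under results/02_sonify/.

suppressPackageStartupMessages(library(sonirehab))
seed <- 20260920
out <- "results/02_sonify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

task <- task_spec()          # four up-down scales at field 1
ref <- task_events(task)
write_events(ref, file.path(out, "task_reference.jsonl"))
message("Reference stream: ", nrow(ref), " events (",
        paste(head(ref$pitch_index, 11), collapse = " "), " ...)")

clean <- resample_trajectory(gen_trajectory(task, corruption = 0, seed = seed))
ev_clean <- sonify(clean)
write_events(ev_clean, file.path(out, "clean_events.jsonl"))
write_events(ev_clean, file.path(out, "clean_events.mid"), format = "midi")

rough <- resample_trajectory(gen_trajectory(task, corruption = 6, seed = seed))
ev_rough <- sonify(rough)
write_events(ev_rough, file.path(out, "rough_events.jsonl"))

message(sprintf("Clean trajectory: %d events; corrupted trajectory: %d events",
                nrow(ev_clean), nrow(ev_rough)))
message("A corrupted movement re-crosses pitch boundaries, so any events ",
        "beyond the clean trajectory's ", nrow(ev_clean), " are audible ",
        "feedback of sub-movements.")
message("Done: ", out)
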