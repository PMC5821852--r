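#!/usr/bin/env Rscript
# Stage 1 — synthesize the study's raw materials: cluttered images, music-like
# clips with known event rates, and the tag matrix used for stimulus
# selection. Everything downstream is reproducible from the seeds used here.

library(complexcortex)

out <- "scratch/stimuli"
dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "audio"), recursive = TRUE, showWarnings = FALSE)

seed <- 20260927

# -- images: 64 stimuli, clutter 0..50 shapes, 128 px ------------------------
gi <- gen_images(64, clutter_range = c(0, 50), size = 128, seed = seed)
for (i in seq_along(gi$images))
  png::writePNG(gi$images[[i]] / 255,
                file.path(out, "images", sprintf("img%03d.png", i)))
write.table(data.frame(stimulus_id = sprintf("img%03d", seq_along(gi$images)),
                       clutter = gi$clutter),
            file.path(out, "images_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d images (clutter %d..%d)\n", length(gi$images),
            min(gi$clutter), max(gi$clutter)))

# -- audio: 12 clips of 29 s at 16 kHz, event rates 1..8 Hz ------------------
ga <- gen_audio(12, rate_range = c(1, 8), duration = 29, seed = seed + 1)
for (i in seq_along(ga$clips))
  write_wav(ga$clips[[i]], file.path(out, "audio", sprintf("clip%02d.wav", i)))
write.table(data.frame(stimulus_id = sprintf("clip%02d", seq_along(ga$clips)),
                       rate = ga$rates,
                       realized_rate = vapply(ga$onsets, length, 1) / 29),
            file.path(out, "audio_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d clips (planted rates %.1f..%.1f Hz)\n",
            length(ga$clips), min(ga$rates), max(ga$rates)))

# -- tag matrix: 16 planted style clusters of 9 excerpts ---------------------
gt <- gen_tag_matrix(k = 16, per_cluster = 9, n_tags = 136, seed = seed + 2)
write.table(gt$tags, file.path(out, "tags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
sel <- cluster_select_stimuli(gt$tags, k = 16, per_cluster_train = 8)
write.table(sel, file.path(out, "stimulus_selection.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("tag clustering: %d test / %d train stimuli selected\n",
            sum(sel$assignment == "test"), sum(sel$assignment == "train")))
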