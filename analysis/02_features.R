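#!/usr/bin/env Rscript
# Stage 2 — objective complexity measures for the synthetic stimuli written by
# 01_simulate.R, plus the inter-measure correlation matrices that describe how
# strongly the three measures of each modality agree.

library(complexcortex)

data_dir <- "scratch/stimuli"
stopifnot(dir.exists(data_dir))  # run analysis/01_simulate.R first
dir.create("results", showWarnings = FALSE)

# -- visual measures ----------------------------------------------------------
paths <- sort(list.files(file.path(data_dir, "images"), full.names = TRUE))
vis <- visual_complexity_table(paths, ids = sub("\\.png$", "", basename(paths)),
                               size = 128)
write.table(vis, "results/visual_features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
truth <- read.delim(file.path(data_dir, "images_truth.tsv"))
cv <- cor(cbind(clutter = truth$clutter, vis[, -1]), method = "spearman")
cat("rank correlation of clutter with each visual measure:\n")
print(round(cv["clutter", -1], 2))
cat("\nvisual measure inter-correlations (Pearson):\n")
print(round(cor(vis[, -1]), 2))
write.table(round(cor(vis[, -1]), 4), "results/visual_measure_correlations.tsv",
            sep = "\t", quote = FALSE)

# -- auditory measures (28-point sliding-window series per clip) -------------
wavs <- sort(list.files(file.path(data_dir, "audio"), full.names = TRUE))
clips <- lapply(wavs, read_wav)
aud <- audio_complexity_table(clips, ids = sub("\\.wav$", "", basename(wavs)))
write.table(aud, "results/audio_features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
wide <- reshape(aud, idvar = c("stimulus_id", "window_index"),
                timevar = "measure", direction = "wide")
names(wide) <- sub("^value\\.", "", names(wide))
cat(sprintf("\naudio series: %d windows per clip\n",
            max(aud$window_index)))
cat("auditory measure inter-correlations (Pearson, across windows):\n")
print(round(cor(wide[, c("event_density", "flac", "ogg")]), 2))
write.table(round(cor(wide[, c("event_density", "flac", "ogg")]), 4),
            "results/audio_measure_correlations.tsv", sep = "\t",
            quote = FALSE)
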