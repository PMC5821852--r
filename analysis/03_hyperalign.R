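#!/usr/bin/env Rscript
# Stage 3 — multi-subject hyperalignment on synthetic subjects built as
# rotated/scaled/translated copies of a common response space, with unequal
# voxel counts, verifying that the common space has the maximum voxel count
# and that the iteration residuals shrink.

library(complexcortex)

seed <- 20260930
set.seed(seed)

n_trials <- 60
qs <- c(81, 90, 128)            # per-subject voxel counts for one ROI
common <- response_matrix(matrix(rnorm(n_trials * max(qs)), n_trials),
                          subject = "COMMON", roi = "synthROI")

# full-dimension, noise-free copies must align to numerical precision
gs0 <- gen_subjects(common, 3, noise_sd = 0, seed = seed - 1)
cs0 <- hyperalign(gs0$subjects, iterations = 2)
al0 <- lapply(gs0$subjects, function(s)
  apply_transform(s$data, cs0$transforms[[s$subject]]))
cat(sprintf("noise-free, untruncated: max pairwise aligned distance %.3g\n",
            max(procrustes_distance(al0[[1]], al0[[2]]),
                procrustes_distance(al0[[1]], al0[[3]]),
                procrustes_distance(al0[[2]], al0[[3]]))))

# truncating subjects to fewer voxels discards information, so aligned
# distances stay finite even without noise; they grow smoothly with noise
rows <- list()
for (noise in c(0, 0.25, 0.5)) {
  gs <- gen_subjects(common, length(qs), noise_sd = noise, truncate_q = qs,
                     seed = seed + round(noise * 100))
  cs <- hyperalign(gs$subjects, iterations = 3)
  aligned <- lapply(gs$subjects, function(s)
    apply_transform(pad_to_dimension(s, cs$d)$data, cs$transforms[[s$subject]]))
  pd <- c(procrustes_distance(aligned[[1]], aligned[[2]]),
          procrustes_distance(aligned[[1]], aligned[[3]]),
          procrustes_distance(aligned[[2]], aligned[[3]]))
  rows[[length(rows) + 1]] <- data.frame(
    noise_sd = noise, common_dim = cs$d,
    mean_pairwise_distance = mean(pd),
    final_residual = tail(cs$residual_log, 1))
  cat(sprintf("truncated (%s), noise %.2f: common dim %d, mean pairwise aligned distance %.3g\n",
              paste(qs, collapse = "/"), noise, cs$d, mean(pd)))
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/hyperalignment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
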