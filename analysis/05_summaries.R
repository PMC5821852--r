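#!/usr/bin/env Rscript
# Stage 5 — overlap and sensitivity summaries from the stage-4 score tables:
# which voxels are significantly predicted by several complexity measures at
# once, and how the encoding slopes fall along the simulated hierarchy.

library(complexcortex)

dir <- "results/pipeline_visual"
stopifnot(dir.exists(dir))  # run analysis/04_encode_decode.R first

enc <- read.delim(file.path(dir, "encoding_voxels.tsv"), comment.char = "#")
sens <- read.delim(file.path(dir, "sensitivity.tsv"), comment.char = "#")

measures <- unique(enc$measure)
for (g in unique(enc$group)) {
  sub <- enc[enc$group == g, ]
  masks <- lapply(measures, function(m)
    significance_mask(sub$p[sub$measure == m])$p05)
  names(masks) <- measures
  ov <- overlap_fractions(masks)
  cat(sprintf("\nVenn overlap of significant voxels, %s group (union n = %d):\n",
              g, attr(ov, "n_union")))
  print(round(100 * ov, 1))
}

cat("\nmean |beta| over significant voxels along the hierarchy:\n")
print(reshape(sens[, c("roi", "measure", "mean_abs_beta")],
              idvar = "roi", timevar = "measure", direction = "wide"),
      digits = 3)
cat("\npercent positive slopes (complexity-preferring voxels):\n")
print(reshape(sens[, c("roi", "measure", "pct_positive")],
              idvar = "roi", timevar = "measure", direction = "wide"),
      digits = 3)
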