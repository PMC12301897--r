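#!/usr/bin/env Rscript
# Amplitude-gradient saliency: channel x frequency-band maps of the final
# evaluation models, grouped by pathology status, plus the difference map.
# In this synthetic world age is encoded occipitally in the alpha band, so
# the map should peak there.

library(eegbrainage)

pl <- readRDS("scratch/pipeline.rds")
env <- readRDS("scratch/cohort.rds")

pp <- lapply(env$cohort$recordings, preprocess_recording,
             config = preproc_config(channels = env$cfg$channels,
                                     drop_head_s = 0, min_duration_s = 30))
meta_subj <- vapply(pp, `[[`, "", "subject_id")
eval_recs <- pp[meta_subj %in% pl$eval_subjects]

sal <- group_saliency(pl$fe$fits, eval_recs)

flat <- function(m, group) {
  d <- as.data.frame(as.table(m))
  names(d) <- c("channel", "band", "gradient")
  d$group <- group
  d
}
out <- rbind(flat(sal$np, "non_pathological"),
             flat(sal$p, "pathological"),
             flat(sal$difference, "difference"))
write.csv(out, "results/saliency_bands.csv", row.names = FALSE)

m <- abs(sal$np)
idx <- which(m == max(m), arr.ind = TRUE)[1, ]
cat(sprintf("strongest non-pathological saliency: %s / %s\n",
            rownames(m)[idx[1]], colnames(m)[idx[2]]))
print(round(sal$np * 1000, 3))
cat("wrote results/saliency_bands.csv\n")
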