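#!/usr/bin/env Rscript
# Simulate the synthetic clinical-EEG cohort used by the downstream
# analysis scripts: 80 subjects with repeated sessions, a planted 4-year
# trait component, no state component, 25% once-transitioning subjects.
# Writes the manifest and a cohort summary under results/, caches the
# generated cohort object under scratch/ for the next scripts, and exports
# one example recording as EDF.

library(eegbrainage)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- cohort_config(n_subjects = 80, recordings_per_subject_mean = 2.5,
                     duration_s = 60, pathology_fraction = 0.25,
                     transition_fraction = 0.25, trait_sd = 4,
                     state_effect = 0, age_mismatch_fraction = 0.05,
                     seed = 7L)
cohort <- generate_cohort(cfg)
saveRDS(list(cfg = cfg, cohort = cohort), "scratch/cohort.rds")

manifest <- cohort_manifest(cohort$recordings)
write_manifest(manifest, "results/manifest.csv")

write_edf(cohort$recordings[[1]]$signal, "scratch/example_recording.edf",
          sfreq = cfg$sfreq)

counts <- table(manifest$subject_id)
cats <- derive_categories(manifest[manifest$subject_id %in%
                                     names(counts)[counts >= 2], ])
summary <- data.frame(
  n_subjects = length(counts),
  n_recordings = nrow(manifest),
  mean_recordings_per_subject = mean(counts),
  pct_pathological_recordings = 100 * mean(manifest$pathology),
  n_RNP = sum(cats$category == "RNP"), n_RP = sum(cats$category == "RP"),
  n_TNPP = sum(cats$category == "TNPP"),
  n_TPNP = sum(cats$category == "TPNP"))
write.csv(summary, "results/cohort_summary.csv", row.names = FALSE)
cat("cohort:", summary$n_recordings, "recordings from",
    summary$n_subjects, "subjects;",
    summary$n_TNPP + summary$n_TPNP, "transition subjects\n")
cat("wrote results/manifest.csv, results/cohort_summary.csv\n")
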