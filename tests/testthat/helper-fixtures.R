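# shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

# small fast cohort config for structural tests
tiny_cfg <- function(...) {
  cohort_config(n_subjects = 8, recordings_per_subject_mean = 2,
                duration_s = 20, sfreq = 100, seed = 42L, ...)
}

desk_channels <- c("Fp1", "Fp2", "C3", "C4", "T5", "T6", "O1", "O2")

# n standard normal draws under a local seed
with_seed_vec <- function(seed, n) {
  withr::with_seed(seed, stats::rnorm(n))
}

fast_pre <- function(cfg) {
  preproc_config(channels = cfg$channels, drop_head_s = 0,
                 min_duration_s = min(10, cfg$duration_s))
}

# one trained model on a small cohort where only occipital alpha encodes
# age; reused by decoding, saliency and acceptance tests
trained_fixture <- function() {
  if (!is.null(.fixture_env$trained)) return(.fixture_env$trained)
  cfg <- cohort_config(n_subjects = 70, recordings_per_subject_mean = 1,
                       duration_s = 60, pathology_fraction = 0.3,
                       seed = 1301L)
  coh <- generate_cohort(cfg)
  pc <- fast_pre(cfg)
  pp <- lapply(coh$recordings, preprocess_recording, config = pc)
  meta <- data.frame(
    subject_id = vapply(pp, `[[`, "", "subject_id"),
    ca = vapply(pp, `[[`, 0, "age_header"),
    pathology = vapply(pp, `[[`, TRUE, "pathology"))
  subj <- unique(meta$subject_id)
  eval_subj <- subj[57:70]
  tr_sel <- !(meta$subject_id %in% eval_subj) & !meta$pathology
  trr <- pp[tr_sel]
  stats <- fit_normalization(trr, meta$ca[tr_sel])
  fit <- train_age_model(
    trr, meta$ca[tr_sel], model_config(),
    train_config(epochs = 30, crops_per_recording = 20, seed = 5L), stats)
  .fixture_env$trained <- list(
    fit = fit, cohort = coh, preprocessed = pp, meta = meta,
    eval_idx = which(meta$subject_id %in% eval_subj),
    train_ca = meta$ca[tr_sel])
  .fixture_env$trained
}
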