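test_that("crop materialization: counts, starts and reconstruction", {
  sig <- matrix(seq_len(3 * 1000), 3)
  crops <- make_crops(sig, 600)
  expect_length(crops, 401)
  expect_equal(crops[[1]], sig[, 1:600])
  expect_equal(crops[[401]], sig[, 401:1000])
  starts <- vapply(seq_along(crops), function(i) crops[[i]][1, 1], 0)
  expect_equal(starts, as.numeric(seq_len(401) * 3 - 2))

  expect_length(make_crops(sig[, 1:600], 600), 1)
  expect_error(make_crops(sig[, 1:10], 600), "shorter")
})

test_that("channel dropout zeroes channels at the configured rate and reproducibly", {
  crop <- matrix(1, 8, 50)
  expect_identical(channel_dropout(crop, 0), crop)

  set.seed(71)
  p <- 0.3
  zeroed <- replicate(2000, sum(rowSums(channel_dropout(crop, p)) == 0))
  expect_equal(mean(zeroed) / 8, p, tolerance = 0.05)

  m1 <- channel_dropout(crop, 0.5, seed = 9)
  m2 <- channel_dropout(crop, 0.5, seed = 9)
  expect_identical(m1, m2)
})

test_that("model configuration derives the receptive field", {
  expect_equal(model_config(n_blocks = 3, kernel_size = 5)$receptive_field,
               1 + 2 * 4 * 7)
  expect_equal(model_config(n_blocks = 1, kernel_size = 2)$receptive_field,
               3)
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("a two-recording dataset is overfit to near-zero L1 (capacity check)", {
  # well-posed toy: two recordings with widely separated ages
  cfg <- cohort_config(duration_s = 10, seed = 81L)
  pp <- lapply(c(25, 75), function(a) {
    structure(list(recording_id = paste0("toy", a),
                   subject_id = paste0("toy", a), age_header = a,
                   pathology = FALSE, date_days = 0,
                   signal = simulate_recording(a, FALSE, cfg, 80L + a),
                   sfreq = cfg$sfreq, channel_names = cfg$channels,
                   duration_s = cfg$duration_s), class = "eeg_recording")
  })
  ages <- vapply(pp, `[[`, 0, "age_header")
  st <- fit_normalization(pp, ages)
  fit <- train_age_model(pp, ages, model_config(n_filters = 16),
                         train_config(epochs = 200, batch_size = 32,
                                      crops_per_recording = 32,
                                      channel_dropout_p = 0, seed = 3L),
                         st)
  expect_lt(utils::tail(fit$loss_history, 1), 0.05)
  # loss trend decreases
  n <- length(fit$loss_history)
  expect_lt(mean(fit$loss_history[(n - 4):n]),
            mean(fit$loss_history[1:5]))
})

test_that("training is deterministic given the seed and rejects short recordings", {
  cfg <- cohort_config(n_subjects = 2, recordings_per_subject_mean = 1,
                       duration_s = 5, pathology_fraction = 0, seed = 91L)
  coh <- generate_cohort(cfg)
  pp <- lapply(coh$recordings, preprocess_recording, config = fast_pre(cfg))
  ages <- vapply(pp, `[[`, 0, "age_header")
  st <- fit_normalization(pp, ages)
  tc <- train_config(epochs = 3, batch_size = 16, crops_per_recording = 4,
                     seed = 13L)
  f1 <- train_age_model(pp, ages, model_config(n_filters = 8), tc, st)
  f2 <- train_age_model(pp, ages, model_config(n_filters = 8), tc, st)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_equal(predict_recording(f1, pp[[1]]),
               predict_recording(f2, pp[[1]]))

  short <- pp[[1]]
  short$signal <- short$signal[, 1:20]
  expect_error(train_age_model(list(short), 30, model_config(), tc, st),
               "too short")
  expect_error(predict_recording(f1, short), "too short")
})

test_that("a constant-output model predicts the midpoint age and crop aggregation equals the materialized-crop mean", {
  fx <- trained_fixture()
  fit <- fx$fit
  rec <- fx$preprocessed[[fx$eval_idx[1]]]

  # constant model: zero head weights, bias 0 -> sigmoid 0.5 -> midrange age
  const_fit <- fit
  const_fit$model$head_w <- const_fit$model$head_w * 0
  const_fit$model$head_b <- 0
  expect_equal(predict_recording(const_fit, rec),
               unscale_age(fit$stats, 0.5))

  short <- rec
  short$signal <- rec$signal[, 1:300]
  dense <- predict_crop_outputs(fit, short)
  crops <- make_crops(apply_normalization(fit$stats, short$signal),
                      fit$model$cfg$receptive_field)
  each <- vapply(crops, function(cr)
    tcn_forward(fit$model, t(cr), 1L)$out, 0)
  expect_length(dense, length(crops))
  expect_equal(dense, each, tolerance = 1e-12)
  expect_equal(predict_recording(fit, short),
               unscale_age(fit$stats, mean(each)))
})

test_that("trained model beats the predict-the-mean baseline on held-out subjects", {
  fx <- trained_fixture()
  ba <- vapply(fx$eval_idx, function(i)
    predict_recording(fx$fit, fx$preprocessed[[i]]), 0)
  ca <- fx$meta$ca[fx$eval_idx]
  baseline <- mae(ca, rep(mean(fx$train_ca), length(ca)))
  expect_lt(mae(ca, ba), 0.6 * baseline)
})

test_that("subject-wise folds partition subjects for every seed (fuzz)", {
  subjects <- sprintf("S%03d", 1:47)
  reps <- rep(subjects, times = sample(1:3, 47, replace = TRUE))
  for (seed in 1:50) {
    folds <- eegbrainage:::subject_folds(reps, 5, seed)
    all_subj <- unlist(folds)
    expect_setequal(all_subj, subjects)
    expect_equal(length(all_subj), length(unique(all_subj)))
  }
  expect_error(eegbrainage:::subject_folds(c("a", "b"), 5), "at least k")
})

test_that("cross-validation: leakage-free folds, every recording predicted once, non-pathological training only", {
  cfg <- cohort_config(n_subjects = 10, recordings_per_subject_mean = 2,
                       duration_s = 5, pathology_fraction = 0.3, seed = 111L)
  coh <- generate_cohort(cfg)
  pp <- lapply(coh$recordings, preprocess_recording, config = fast_pre(cfg))
  cv <- run_cv(pp, k = 5, mc = model_config(n_filters = 4),
               tc = train_config(epochs = 1, batch_size = 16,
                                 crops_per_recording = 2, seed = 7L),
               seed = 3L)
  meta <- eegbrainage:::rec_meta(pp)
  # each fold holds 2 validation subjects; union of predictions = manifest
  expect_setequal(cv$predictions$recording_id, meta$recording_id)
  expect_equal(nrow(cv$predictions), nrow(meta))
  per_subj_folds <- tapply(cv$predictions$split, cv$predictions$subject_id,
                           function(s) length(unique(s)))
  expect_true(all(per_subj_folds == 1))
  expect_equal(unname(table(vapply(cv$folds, length, 1L))[["2"]]), 5)
  # training recordings were all non-pathological and from other folds
  for (i in seq_len(5)) {
    fit_ids <- cv$fits[[i]]$stats$fit_on
    train_meta <- meta[meta$recording_id %in% fit_ids, ]
    expect_false(any(train_meta$pathology))
    expect_length(intersect(train_meta$subject_id, cv$folds[[i]]), 0)
  }
})

test_that("final evaluation averages runs, is identity for one run, and refuses subject overlap", {
  cfg <- cohort_config(n_subjects = 6, recordings_per_subject_mean = 1,
                       duration_s = 5, pathology_fraction = 0, seed = 121L)
  coh <- generate_cohort(cfg)
  pp <- lapply(coh$recordings, preprocess_recording, config = fast_pre(cfg))
  tr <- pp[1:4]; ev <- pp[5:6]
  mc <- model_config(n_filters = 4)
  tc <- train_config(epochs = 1, batch_size = 8, crops_per_recording = 2,
                     seed = 5L)
  fe1 <- run_final_evaluation(tr, ev, n_runs = 1, mc = mc, tc = tc)
  tc_run1 <- tc; tc_run1$seed <- tc$seed + 1L   # the seed run 1 used
  single <- train_age_model(tr, vapply(tr, `[[`, 0, "age_header"), mc,
                            tc_run1, fe1$fits[[1]]$stats)
  expect_equal(fe1$predictions$ba,
               vapply(ev, function(r) predict_recording(single, r), 0))

  # identical seeds: averaging is identity
  fe_same <- run_final_evaluation(tr, ev, n_runs = 3, mc = mc, tc = tc,
                                  seeds = c(9L, 9L, 9L))
  expect_equal(fe_same$predictions$ba,
               fe_same$per_run$ba[fe_same$per_run$run == 1])

  expect_error(run_final_evaluation(pp[1:4], pp[4:6], n_runs = 1,
                                    mc = mc, tc = tc), "leakage")
})
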