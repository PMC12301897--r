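#' Simulate gap records directly from cohort latents
#'
#' Statistics-level shortcut around the decoder: the decoded brain age is
#' modeled as the latent effective age plus zero-mean Gaussian decoding
#' noise. This preserves exactly the structure the signal pipeline recovers
#' (trait offsets, state shifts, longitudinal dates, label patterns) at
#' negligible cost, and is used for test-calibration and power studies where
#' hundreds of replicate cohorts are needed.
#'
#' @param cohort a [generate_cohort()] result (signals not required).
#' @param decode_noise_sd standard deviation of decoding noise, years
#'   (default 5, of the order of the achievable decoding error on clinical
#'   EEG).
#' @param seed integer seed for the noise draws.
#' @return gap-record data.frame: recording_id, subject_id, ca, ba,
#'   pathology, date_days, gap_raw, gap_corrected (noise-only correction:
#'   raw gap minus nothing is deliberately *not* applied here; records pass
#'   through [fit_bias()]/[apply_bias()] like decoded ones).
#' @export
synth_gap_records <- function(cohort, decode_noise_sd = 5, seed = 1L) {
  lat <- cohort$latents
  meta <- rec_meta(cohort$recordings)
  stopifnot(nrow(lat) == nrow(meta))
  ba <- lat$effective_age +
    with_local_seed(seed, stats::rnorm(nrow(lat), 0, decode_noise_sd))
  gap_records(data.frame(
    recording_id = meta$recording_id, subject_id = meta$subject_id,
    ca = meta$ca, ba = ba, pathology = meta$pathology,
    date_days = meta$date_days, stringsAsFactors = FALSE))
}

#' Longitudinal state-vs-trait statistics on gap records
#'
#' Runs the analysis battery downstream of decoding: quadratic bias
#' correction (fit on non-pathological records), per-subject average gaps
#' with a permutation test of the non-pathological minus pathological mean
#' difference, the two-threshold biomarker with a balanced-accuracy
#' permutation test, derivative categorization, within-status change rates
#' (repeated cohorts compared by KS/WMW/Brunner-Munzel), and
#' moment-of-transition rates for the transition cohorts (permutation test
#' of the NP-to-P versus P-to-NP rate means, plus KS/WMW/BM), and a
#' trait-consistency check (split-half correlation of per-subject gaps).
#'
#' @param records gap-record data.frame with recording_id, subject_id, ca,
#'   ba, pathology, date_days, gap_raw.
#' @param bias a prefit [fit_bias()] model, or `NULL` to fit on the
#'   non-pathological records here.
#' @param pair a prefit threshold pair, or `NULL` to optimize here on
#'   subject-average gaps.
#' @param n_perm permutation samples (default 100000).
#' @param seed integer seed.
#' @return list of class `brainage_analysis`; see elements.
#' @export
analyze_gaps <- function(records, bias = NULL, pair = NULL,
                         n_perm = 100000L, seed = 1L) {
  if (is.null(bias))
    bias <- fit_bias(records$ca[!records$pathology],
                     records$gap_raw[!records$pathology])
  records <- apply_bias(bias, records)
  subj <- subject_average_gap(records)
  gap_test <- if (any(subj$pathology) && !all(subj$pathology)) {
    perm_test_mean_diff(subj$mean_gap[!subj$pathology],
                        subj$mean_gap[subj$pathology],
                        n = n_perm, seed = seed)
  } else NULL
  if (is.null(pair) && !is.null(gap_test))
    pair <- optimize_thresholds(subj$mean_gap, subj$pathology)
  bacc_test <- if (!is.null(pair) && !is.null(gap_test)) {
    perm_test_bacc(subj$mean_gap, subj$pathology, pair,
                   n = n_perm, seed = seed + 1L)
  } else NULL
  counts <- table(records$subject_id)
  multi <- records[records$subject_id %in% names(counts)[counts >= 2], ]
  categories <- if (nrow(multi) > 0) derive_categories(multi) else NULL
  rates <- trans <- rate_tests <- trans_tests <- NULL
  if (!is.null(categories)) {
    rnp <- categories$subject_id[categories$category == "RNP"]
    rp <- categories$subject_id[categories$category == "RP"]
    tr_ids <- categories$subject_id[categories$category %in%
                                      c("TNPP", "TPNP")]
    rates <- change_rates(multi[multi$subject_id %in% c(rnp, rp), ])
    r_np <- rates$rate[rates$subject_id %in% rnp]
    r_p <- rates$rate[rates$subject_id %in% rp]
    if (length(r_np) >= 2 && length(r_p) >= 2) {
      rate_tests <- list(
        ks = ks_test(r_np, r_p), wmw = wmw_test(r_np, r_p),
        bm = suppressWarnings(brunner_munzel(r_np, r_p)),
        perm = perm_test_mean_diff(r_np, r_p, n = n_perm, seed = seed + 2L))
    }
    if (length(tr_ids) > 0) {
      trans <- transition_rates(multi[multi$subject_id %in% tr_ids, ])
      r_tnpp <- trans$rate[trans$direction == "NP->P"]
      r_tpnp <- trans$rate[trans$direction == "P->NP"]
      if (length(r_tnpp) >= 2 && length(r_tpnp) >= 2) {
        trans_tests <- list(
          ks = ks_test(r_tnpp, r_tpnp), wmw = wmw_test(r_tnpp, r_tpnp),
          bm = suppressWarnings(brunner_munzel(r_tnpp, r_tpnp)),
          perm = perm_test_mean_diff(r_tnpp, r_tpnp, n = n_perm,
                                     seed = seed + 3L))
      }
    }
  }
  trait <- trait_consistency(records)
  structure(list(bias = bias, records = records, subject_gaps = subj,
                 gap_test = gap_test, pair = pair, bacc_test = bacc_test,
                 categories = categories, rates = rates,
                 rate_tests = rate_tests, transitions = trans,
                 transition_tests = trans_tests, trait = trait),
            class = "brainage_analysis")
}

#' Split-half trait consistency of the corrected gap
#'
#' For subjects with >= 2 recordings, correlates the corrected gap of the
#' chronologically first recording with the mean corrected gap of the
#' remaining recordings. A stable (trait-like) gap gives a positive
#' correlation; a purely state-driven or noisy gap gives none. One-sided
#' (greater): only a positive correlation evidences a trait.
#'
#' Because a subject's chronological age is nearly constant across visits,
#' any residual age-dependent decoder bias beyond the quadratic correction
#' is shared between the two halves and would masquerade as a trait. Both
#' halves are therefore deconfounded by partialling out a cubic polynomial
#' of their own chronological ages before correlating (skipped below 10
#' subjects).
#'
#' @param records bias-corrected gap records.
#' @return list with `r`, `p`, `n` (subjects), or `NULL` if under 3
#'   multi-recording subjects.
#' @export
trait_consistency <- function(records) {
  counts <- table(records$subject_id)
  ids <- names(counts)[counts >= 2]
  if (length(ids) < 3) return(NULL)
  firsts <- rest <- ca_first <- ca_rest <- numeric(length(ids))
  for (i in seq_along(ids)) {
    d <- records[records$subject_id == ids[i], ]
    d <- d[order(d$date_days), ]
    firsts[i] <- d$gap_corrected[1]
    rest[i] <- mean(d$gap_corrected[-1])
    ca_first[i] <- d$ca[1]
    ca_rest[i] <- mean(d$ca[-1])
  }
  if (length(ids) >= 10 && length(unique(ca_first)) > 4) {
    firsts <- stats::resid(stats::lm(firsts ~ stats::poly(ca_first, 3)))
    rest <- stats::resid(stats::lm(rest ~ stats::poly(ca_rest, 3)))
  }
  ct <- stats::cor.test(firsts, rest, alternative = "greater")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}

#' Full synthetic-cohort brain-age pipeline
#'
#' Generates a cohort, preprocesses it, decodes age by subject-wise
#' cross-validation plus repeated final evaluation, fits and applies the
#' quadratic bias model (CV non-pathological validation predictions only),
#' optimizes the biomarker thresholds per CV fold, and runs the full gap
#' analysis battery on the pooled out-of-sample predictions (CV validation
#' plus final evaluation; every recording appears exactly once).
#'
#' @param cohort_cfg a [cohort_config()].
#' @param pre_cfg a [preproc_config()].
#' @param mc,tc model and training configuration.
#' @param k CV folds.
#' @param n_runs final-evaluation repetitions.
#' @param eval_fraction fraction of subjects held out for final evaluation.
#' @param n_perm permutation samples for the analysis battery.
#' @param seed master seed.
#' @return list of class `brainage_pipeline`: `cv`, `fe`, `bias`,
#'   `fold_pairs`, `cv_metrics`, `fe_metrics`, `analysis`, `latents`.
#' @export
run_brainage_pipeline <- function(cohort_cfg,
                                  pre_cfg = preproc_config(
                                    channels = cohort_cfg$channels,
                                    drop_head_s = 10, min_duration_s = 60),
                                  mc = model_config(),
                                  tc = train_config(),
                                  k = 5, n_runs = 5,
                                  eval_fraction = 0.2,
                                  n_perm = 10000L,
                                  seed = 1L) {
  cohort <- generate_cohort(cohort_cfg)
  pp <- lapply(cohort$recordings, preprocess_recording, config = pre_cfg)
  keep <- !vapply(pp, is.null, TRUE)
  pp <- pp[keep]
  meta <- rec_meta(pp)
  subjects <- unique(meta$subject_id)
  n_eval <- max(1L, round(length(subjects) * eval_fraction))
  eval_subj <- with_local_seed(seed, sample(subjects, n_eval))
  train_recs <- pp[!(meta$subject_id %in% eval_subj)]
  eval_recs <- pp[meta$subject_id %in% eval_subj]

  cv <- run_cv(train_recs, k = k, mc = mc, tc = tc, seed = seed)
  cvp <- gap_records(transform_pred(cv$predictions))
  bias <- fit_bias(cvp$ca[!cvp$pathology], cvp$gap_raw[!cvp$pathology])
  cvp <- apply_bias(bias, cvp)
  fold_pairs <- lapply(seq_len(k), function(i) {
    d <- cvp[cvp$split == sprintf("cv_fold_%d", i), ]
    if (any(d$pathology) && !all(d$pathology))
      optimize_thresholds(d$gap_corrected, d$pathology) else NULL
  })

  fe <- run_final_evaluation(train_recs, eval_recs, n_runs = n_runs,
                             mc = mc, tc = tc,
                             seeds = seed + 100L + seq_len(n_runs))
  fep <- apply_bias(bias, gap_records(transform_pred(fe$predictions)))

  cv_np <- cvp[!cvp$pathology, ]
  fe_np <- fep[!fep$pathology, ]
  pooled_pair <- if (any(cvp$pathology))
    optimize_thresholds(cvp$gap_corrected, cvp$pathology) else NULL
  # every recording is predicted out of sample exactly once (CV validation
  # for training subjects, FE for held-out subjects); the longitudinal
  # analysis battery pools them for subject-level power
  all_oos <- rbind(cvp, fep)
  analysis <- analyze_gaps(all_oos, bias = bias, pair = pooled_pair,
                           n_perm = n_perm, seed = seed + 7L)
  structure(list(
    cv = cv, fe = fe, bias = bias, fold_pairs = fold_pairs,
    cv_predictions = cvp, fe_predictions = fep,
    cv_metrics = list(
      mae = mae(cv_np$ca, cv_np$ca + cv_np$gap_corrected),
      mae_raw = mae(cv_np$ca, cv_np$ba),
      r2 = r2(cv_np$ca, cv_np$ca + cv_np$gap_corrected)),
    fe_metrics = list(
      mae = mae(fe_np$ca, fe_np$ca + fe_np$gap_corrected),
      mae_raw = mae(fe_np$ca, fe_np$ba),
      r2 = r2(fe_np$ca, fe_np$ca + fe_np$gap_corrected),
      baseline_mae = mae(fe_np$ca, rep(mean(cv_np$ca), nrow(fe_np)))),
    analysis = analysis, latents = cohort$latents,
    eval_subjects = eval_subj), class = "brainage_pipeline")
}

transform_pred <- function(p) {
  data.frame(recording_id = p$recording_id, subject_id = p$subject_id,
             ca = p$ca, ba = p$ba, pathology = p$pathology,
             date_days = p$date_days,
             split = if ("split" %in% names(p)) p$split else NA_character_,
             stringsAsFactors = FALSE)
}

#' Transfer study: train on one cohort, analyze another longitudinally
#'
#' Mirrors the design in which the decoder is trained on a reference corpus
#' and the longitudinal derivative cohorts are predicted afterwards with
#' the ensemble of final-evaluation runs: `n_runs` models are trained on
#' the non-pathological recordings of a dedicated training cohort, the
#' quadratic bias model is fit on ensemble predictions of a held-out
#' non-pathological calibration split of that same cohort, and the frozen
#' ensemble plus bias model are applied to every recording of the analysis
#' cohort, whose gap records then run through [analyze_gaps()].
#' Run-averaging also shrinks the subject-stable component of decoder
#' miscalibration, which matters for trait-consistency inference.
#'
#' @param train_cfg [cohort_config()] for the training cohort (its
#'   pathological recordings are ignored).
#' @param analysis_cfg [cohort_config()] for the longitudinal analysis
#'   cohort.
#' @param pre_cfg preprocessing configuration applied to both cohorts.
#' @param mc,tc model and training configuration.
#' @param n_runs ensemble size (default 4).
#' @param bias_fraction fraction of training-cohort subjects held out for
#'   bias calibration (default 0.25).
#' @param n_perm permutation samples for the analysis battery.
#' @param seed master seed.
#' @return list of class `transfer_study`: `fits`, `bias`, `analysis`,
#'   `records`, `calibration` (MAE of the ensemble on the calibration
#'   split, raw and corrected).
#' @export
run_transfer_study <- function(train_cfg, analysis_cfg,
                               pre_cfg = preproc_config(
                                 channels = train_cfg$channels,
                                 drop_head_s = 0, min_duration_s = 30),
                               mc = model_config(), tc = train_config(),
                               n_runs = 4, bias_fraction = 0.25,
                               n_perm = 10000L, seed = 1L) {
  tr_cohort <- generate_cohort(train_cfg)
  # keep subject ids of the two cohorts disjoint
  for (i in seq_along(tr_cohort$recordings)) {
    tr_cohort$recordings[[i]]$subject_id <-
      paste0("TR", tr_cohort$recordings[[i]]$subject_id)
  }
  an_cohort <- generate_cohort(analysis_cfg)
  tr_pp <- Filter(Negate(is.null),
                  lapply(tr_cohort$recordings, preprocess_recording,
                         config = pre_cfg))
  an_pp <- Filter(Negate(is.null),
                  lapply(an_cohort$recordings, preprocess_recording,
                         config = pre_cfg))
  tr_meta <- rec_meta(tr_pp)
  np <- which(!tr_meta$pathology)
  subj <- unique(tr_meta$subject_id[np])
  n_cal <- max(2L, round(length(subj) * bias_fraction))
  cal_subj <- with_local_seed(seed, sample(subj, n_cal))
  fit_idx <- np[!(tr_meta$subject_id[np] %in% cal_subj)]
  cal_idx <- np[tr_meta$subject_id[np] %in% cal_subj]
  stats <- fit_normalization(tr_pp[fit_idx], tr_meta$ca[fit_idx],
                             split_tag = "transfer_train")
  fits <- lapply(seq_len(n_runs), function(r) {
    tcr <- tc; tcr$seed <- as.integer(tc$seed + 10L * r)
    train_age_model(tr_pp[fit_idx], tr_meta$ca[fit_idx], mc, tcr, stats)
  })
  ens_predict <- function(recs) {
    rowMeans(vapply(fits, function(f)
      vapply(recs, function(r) predict_recording(f, r), 0),
      numeric(length(recs))))
  }
  cal_ba <- ens_predict(tr_pp[cal_idx])
  bias <- fit_bias(tr_meta$ca[cal_idx], cal_ba - tr_meta$ca[cal_idx])
  an_meta <- rec_meta(an_pp)
  records <- gap_records(data.frame(
    recording_id = an_meta$recording_id, subject_id = an_meta$subject_id,
    ca = an_meta$ca, ba = ens_predict(an_pp),
    pathology = an_meta$pathology, date_days = an_meta$date_days,
    stringsAsFactors = FALSE))
  analysis <- analyze_gaps(records, bias = bias, n_perm = n_perm,
                           seed = seed + 5L)
  cal_rec <- apply_bias(bias, data.frame(ca = tr_meta$ca[cal_idx],
                                         gap_raw = cal_ba -
                                           tr_meta$ca[cal_idx]))
  structure(list(
    fits = fits, bias = bias, analysis = analysis, records = records,
    calibration = list(
      mae_raw = mae(tr_meta$ca[cal_idx], cal_ba),
      mae = mean(abs(cal_rec$gap_corrected)),
      n = length(cal_idx))), class = "transfer_study")
}
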