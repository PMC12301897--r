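#' Materialize maximally overlapping crops
#'
#' Sliding window with one-sample stride; crop `i` starts at sample `i`.
#' Used directly only in tests and small analyses — the dense forward pass of
#' the network evaluates every crop implicitly.
#'
#' @param signal channels x samples matrix.
#' @param crop_len crop length in samples (<= signal length).
#' @return list of `samples - crop_len + 1` channels x crop_len matrices.
#' @export
make_crops <- function(signal, crop_len) {
  n <- ncol(signal)
  if (n < crop_len)
    stop("signal (", n, " samples) shorter than crop length ", crop_len,
         call. = FALSE)
  lapply(seq_len(n - crop_len + 1L), function(i)
    signal[, i:(i + crop_len - 1L), drop = FALSE])
}

#' Channel dropout augmentation
#'
#' Each channel of a crop is independently zeroed with probability `p`.
#' Training-time augmentation only.
#'
#' @param crop channels x samples matrix.
#' @param p zeroing probability in `[0, 1)`.
#' @param seed optional integer seed for a reproducible mask; `NULL` draws
#'   from the current RNG stream.
#' @return the crop with a random subset of channels zeroed.
#' @export
channel_dropout <- function(crop, p, seed = NULL) {
  stopifnot(p >= 0, p < 1)
  if (p == 0) return(crop)
  mask <- if (is.null(seed)) stats::runif(nrow(crop)) >= p else
    with_local_seed(seed, stats::runif(nrow(crop)) >= p)
  crop * mask
}

# assemble crops (list of start indices per recording) into the
# (B*T) x C batch layout; standardized signals are C x T matrices
build_batch <- function(signals, rec_idx, starts, crop_len, chdrop_p) {
  B <- length(rec_idx)
  C <- nrow(signals[[1]])
  arr <- array(0, dim = c(B, crop_len, C))
  for (b in seq_len(B)) {
    crop <- signals[[rec_idx[b]]][, starts[b]:(starts[b] + crop_len - 1L),
                                  drop = FALSE]
    if (chdrop_p > 0) crop <- channel_dropout(crop, chdrop_p)
    arr[b, , ] <- t(crop)
  }
  matrix(arr, nrow = B * crop_len)
}

#' Train the temporal convolutional age regressor
#'
#' Cropped decoding: every epoch samples random crops of receptive-field
#' length from each training recording, standardizes nothing further (the
#' recordings must already be standardized with the supplied statistics) and
#' minimizes the L1 loss between sigmoid outputs and min-max-scaled ages
#' with AdamW under cosine learning-rate annealing. Deterministic given
#' `tc$seed` up to floating-point reduction order.
#'
#' @param recordings list of preprocessed `eeg_recording`s (training split;
#'   callers enforce the non-pathological-only rule).
#' @param ages chronological ages (years), one per recording.
#' @param mc a [model_config()].
#' @param tc a [train_config()].
#' @param stats a [fit_normalization()] result used to standardize signals
#'   and scale targets.
#' @return list of class `tcn_fit`: `model`, `stats`, `loss_history`
#'   (mean batch L1 per epoch, scaled-target units).
#' @export
train_age_model <- function(recordings, ages, mc = model_config(),
                            tc = train_config(), stats) {
  stopifnot(length(recordings) == length(ages), length(recordings) > 0)
  rf <- mc$receptive_field
  signals <- lapply(recordings, function(r) {
    if (ncol(r$signal) < rf)
      stop("too short: recording ", r$recording_id, " has ", ncol(r$signal),
           " samples, receptive field is ", rf, call. = FALSE)
    apply_normalization(stats, r$signal)
  })
  y <- scale_age(stats, ages)
  n_rec <- length(signals)
  with_local_seed(tc$seed, {
    model <- tcn_init(mc, nrow(signals[[1]]))
    opt <- adamw_init(model)
    steps_per_epoch <- ceiling(n_rec * tc$crops_per_recording / tc$batch_size)
    total_steps <- tc$epochs * steps_per_epoch
    loss_history <- numeric(tc$epochs)
    step <- 0L
    for (epoch in seq_len(tc$epochs)) {
      rec_idx <- rep(seq_len(n_rec), each = tc$crops_per_recording)
      starts <- vapply(rec_idx, function(i)
        sample.int(ncol(signals[[i]]) - rf + 1L, 1L), 1L)
      ord <- sample.int(length(rec_idx))
      rec_idx <- rec_idx[ord]; starts <- starts[ord]
      ep_loss <- 0; n_batches <- 0L
      for (b0 in seq(1L, length(rec_idx), by = tc$batch_size)) {
        sel <- b0:min(b0 + tc$batch_size - 1L, length(rec_idx))
        X <- build_batch(signals, rec_idx[sel], starts[sel], rf,
                         tc$channel_dropout_p)
        fwd <- tcn_forward(model, X, B = length(sel), train = TRUE)
        err <- fwd$out - y[rec_idx[sel]]
        ep_loss <- ep_loss + mean(abs(err)); n_batches <- n_batches + 1L
        dout <- sign(err) / length(sel)
        grads <- tcn_backward(model, fwd, dout)
        step <- step + 1L
        lr <- cosine_lr(step, total_steps, tc$lr)
        st <- adamw_step(model, grads, opt, lr, tc$weight_decay)
        model <- st$model; opt <- st$opt
      }
      loss_history[epoch] <- ep_loss / n_batches
    }
    structure(list(model = model, stats = stats,
                   loss_history = loss_history, mc = mc, tc = tc),
              class = "tcn_fit")
  })
}

#' Predict the brain age of one recording
#'
#' Dense cropped decoding: the network is run convolutionally over the whole
#' standardized recording, which yields the sigmoid output of every
#' receptive-field-length crop at one-sample stride; the crop outputs are
#' averaged and unscaled to years. No clamping is applied after unscaling.
#'
#' @param fit a [train_age_model()] result (or list with `model`, `stats`).
#' @param recording a preprocessed `eeg_recording`.
#' @return brain age in years.
#' @export
predict_recording <- function(fit, recording) {
  rf <- fit$model$cfg$receptive_field
  if (ncol(recording$signal) < rf)
    stop("too short: recording has ", ncol(recording$signal),
         " samples, receptive field is ", rf, call. = FALSE)
  X <- t(apply_normalization(fit$stats, recording$signal))
  fwd <- tcn_forward(fit$model, X, B = 1L, train = FALSE)
  unscale_age(fit$stats, mean(fwd$out))
}

#' Per-crop sigmoid outputs of one recording
#'
#' @param fit a [train_age_model()] result.
#' @param recording a preprocessed `eeg_recording`.
#' @return numeric vector of length `samples - receptive_field + 1`, one
#'   sigmoid output per crop.
#' @export
predict_crop_outputs <- function(fit, recording) {
  X <- t(apply_normalization(fit$stats, recording$signal))
  tcn_forward(fit$model, X, B = 1L, train = FALSE)$out
}

subject_folds <- function(subjects, k, seed) {
  u <- unique(subjects)
  if (length(u) < k) stop("need at least k subjects", call. = FALSE)
  shuffled <- with_local_seed(seed, sample(u))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

rec_meta <- function(recordings) {
  data.frame(
    recording_id = vapply(recordings, `[[`, "", "recording_id"),
    subject_id = vapply(recordings, `[[`, "", "subject_id"),
    ca = vapply(recordings, `[[`, 0, "age_header"),
    pathology = vapply(recordings, `[[`, TRUE, "pathology"),
    date_days = vapply(recordings, `[[`, 0, "date_days"),
    stringsAsFactors = FALSE)
}

#' Subject-wise cross-validated age decoding
#'
#' Splits subjects (never recordings) into `k` folds with a fixed seed. For
#' each fold a model is trained on the *non-pathological* recordings of the
#' other folds and predicts every recording (both classes) of the held-out
#' subjects, so each recording is a validation prediction exactly once.
#' Normalization statistics are fit per fold on that fold's training split
#' only.
#'
#' @param recordings list of preprocessed `eeg_recording`s.
#' @param k number of folds (default 5).
#' @param mc,tc model and training configuration.
#' @param seed integer seed for the subject shuffle; fold `i` trains with
#'   seed `tc$seed + i`.
#' @return list of class `cv_result`: `predictions` (data.frame with
#'   recording_id, subject_id, ca, ba, pathology, date_days, split), `fits`
#'   (per-fold `tcn_fit`), `folds`.
#' @export
run_cv <- function(recordings, k = 5, mc = model_config(),
                   tc = train_config(), seed = 1L) {
  meta <- rec_meta(recordings)
  folds <- subject_folds(meta$subject_id, k, seed)
  fits <- vector("list", k)
  preds <- list()
  for (i in seq_len(k)) {
    val_subj <- folds[[i]]
    tr_sel <- !(meta$subject_id %in% val_subj) & !meta$pathology
    if (!any(tr_sel))
      stop("fold ", i, " has no non-pathological training recordings",
           call. = FALSE)
    tr_recs <- recordings[tr_sel]
    stats <- fit_normalization(tr_recs, meta$ca[tr_sel],
                               split_tag = sprintf("cv_fold_%d_train", i))
    tci <- tc; tci$seed <- tc$seed + i
    fits[[i]] <- train_age_model(tr_recs, meta$ca[tr_sel], mc, tci, stats)
    val_idx <- which(meta$subject_id %in% val_subj)
    ba <- vapply(val_idx, function(j)
      predict_recording(fits[[i]], recordings[[j]]), 0)
    p <- meta[val_idx, ]
    p$ba <- ba
    p$split <- sprintf("cv_fold_%d", i)
    preds[[i]] <- p
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  structure(list(predictions = predictions, fits = fits, folds = folds),
            class = "cv_result")
}

#' Final evaluation with repeated training runs
#'
#' Trains `n_runs` models (varying seeds) on the non-pathological training
#' recordings and predicts every evaluation recording with each; the
#' reported brain age is the mean over runs. Train and evaluation subject
#' sets must be disjoint.
#'
#' @param train_recordings,eval_recordings preprocessed `eeg_recording`s.
#' @param n_runs number of repetitions (default 5).
#' @param mc,tc model and training configuration.
#' @param seeds integer seeds, one per run (default `tc$seed + 1:n_runs`).
#' @return list of class `fe_result`: `predictions` (mean over runs, split
#'   `"final_eval"`), `per_run` (long data.frame with `run`), `fits`.
#' @export
run_final_evaluation <- function(train_recordings, eval_recordings,
                                 n_runs = 5, mc = model_config(),
                                 tc = train_config(), seeds = NULL) {
  tr_meta <- rec_meta(train_recordings)
  ev_meta <- rec_meta(eval_recordings)
  overlap <- intersect(tr_meta$subject_id, ev_meta$subject_id)
  if (length(overlap) > 0)
    stop("leakage error: subject(s) in both splits: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  if (is.null(seeds)) seeds <- tc$seed + seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  tr_sel <- !tr_meta$pathology
  tr_recs <- train_recordings[tr_sel]
  stats <- fit_normalization(tr_recs, tr_meta$ca[tr_sel],
                             split_tag = "fe_train")
  fits <- vector("list", n_runs)
  run_preds <- list()
  for (r in seq_len(n_runs)) {
    tcr <- tc; tcr$seed <- as.integer(seeds[r])
    fits[[r]] <- train_age_model(tr_recs, tr_meta$ca[tr_sel], mc, tcr, stats)
    ba <- vapply(eval_recordings, function(rec)
      predict_recording(fits[[r]], rec), 0)
    p <- ev_meta
    p$ba <- ba
    p$run <- r
    run_preds[[r]] <- p
  }
  per_run <- do.call(rbind, run_preds)
  rownames(per_run) <- NULL
  predictions <- ev_meta
  predictions$ba <- rowMeans(
    vapply(run_preds, function(p) p$ba, numeric(nrow(ev_meta))))
  predictions$split <- "final_eval"
  structure(list(predictions = predictions, per_run = per_run, fits = fits),
            class = "fe_result")
}
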