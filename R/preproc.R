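#' Preprocessing configuration
#'
#' The chain is applied in fixed order: select channels, clip amplitudes,
#' common average reference, resample, drop the first seconds.
#'
#' @param channels ordered channel set to retain (default the 21-electrode
#'   10-20 set).
#' @param clip_uv symmetric amplitude bound in microvolts (default 800).
#' @param target_sfreq resampling target in Hz (default 100).
#' @param drop_head_s seconds removed from the start of each recording
#'   (default 60; the first minute of clinical recordings carries most
#'   technical outliers).
#' @param min_duration_s minimum usable duration after preprocessing
#'   (default 120).
#' @return object of class `preproc_config`.
#' @export
preproc_config <- function(channels = TEN_TWENTY_21, clip_uv = 800,
                           target_sfreq = 100, drop_head_s = 60,
                           min_duration_s = 120) {
  stopifnot(clip_uv > 0, target_sfreq > 0, drop_head_s >= 0,
            min_duration_s > 0)
  structure(list(channels = channels, clip_uv = clip_uv,
                 target_sfreq = target_sfreq, drop_head_s = drop_head_s,
                 min_duration_s = min_duration_s),
            class = "preproc_config")
}

#' Restrict and reorder channels
#'
#' @param signal channels x samples matrix with `rownames` or `labels` given.
#' @param labels channel labels (default `rownames(signal)`); normalized via
#'   [normalize_channel_label()] before matching.
#' @param config a [preproc_config()]; output rows follow `config$channels`.
#' @return reordered signal restricted to the configured channels.
#' @export
select_channels <- function(signal, labels = rownames(signal), config) {
  norm <- normalize_channel_label(labels)
  idx <- match(toupper(config$channels), toupper(norm))
  if (anyNA(idx)) {
    stop("montage error: missing channel(s): ",
         paste(config$channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- signal[idx, , drop = FALSE]
  rownames(out) <- config$channels
  out
}

#' Clip amplitudes to a symmetric bound
#'
#' @param signal numeric matrix or vector, microvolts.
#' @param clip_uv positive bound; output lies in `[-clip_uv, clip_uv]` and
#'   in-range samples are unchanged.
#' @return clipped signal.
#' @export
clip_amplitudes <- function(signal, clip_uv = 800) {
  stopifnot(clip_uv > 0)
  pmin(pmax(signal, -clip_uv), clip_uv)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each time point has zero mean over the montage.
#'
#' @param signal channels x samples matrix (>= 2 channels).
#' @return re-referenced signal.
#' @export
common_average_reference <- function(signal) {
  if (nrow(signal) < 2)
    stop("common average reference needs >= 2 channels", call. = FALSE)
  sweep(signal, 2, colMeans(signal))
}

#' Band-limited resampling
#'
#' FFT-based resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) at the new Nyquist frequency and inverted at the
#' new length `round(n * sfreq_out / sfreq_in)`. Deterministic, exact for
#' equal rates.
#'
#' @param signal channels x samples matrix or numeric vector.
#' @param sfreq_in,sfreq_out sampling rates in Hz.
#' @return resampled signal of the same shape class.
#' @export
resample_signal <- function(signal, sfreq_in, sfreq_out) {
  stopifnot(sfreq_in > 0, sfreq_out > 0)
  if (sfreq_in == sfreq_out) return(signal)
  vec <- !is.matrix(signal)
  x <- if (vec) matrix(signal, 1) else signal
  n <- ncol(x)
  n_out <- round(n * sfreq_out / sfreq_in)
  out <- matrix(0, nrow(x), n_out, dimnames = list(rownames(x), NULL))
  for (c in seq_len(nrow(x))) {
    sp <- stats::fft(x[c, ])
    new_sp <- complex(length.out = n_out)
    keep <- min(floor(n / 2), floor(n_out / 2))
    new_sp[1] <- sp[1]
    if (keep >= 1) {
      new_sp[2:(keep + 1)] <- sp[2:(keep + 1)]
      new_sp[(n_out - keep + 1):n_out] <- sp[(n - keep + 1):n]
    }
    # enforce conjugate symmetry at the shared Nyquist bin if present
    if (n_out %% 2 == 0 && keep == n_out / 2)
      new_sp[keep + 1] <- Re(new_sp[keep + 1])
    # dividing by the *input* length preserves amplitude:
    # IDFT(1/n_out) x carried coefficients x (n_out/n) rescale = 1/n
    out[c, ] <- Re(stats::fft(new_sp, inverse = TRUE)) / n
  }
  if (vec) drop(out) else out
}

#' Drop the head of a recording
#'
#' @param signal channels x samples matrix or vector.
#' @param sfreq sampling rate, Hz.
#' @param drop_head_s seconds to remove from the start.
#' @return shortened signal; errors if nothing would remain.
#' @export
drop_head <- function(signal, sfreq, drop_head_s) {
  n_drop <- round(drop_head_s * sfreq)
  n <- if (is.matrix(signal)) ncol(signal) else length(signal)
  if (n <= n_drop)
    stop("too short: recording of ", n / sfreq,
         " s cannot lose its first ", drop_head_s, " s", call. = FALSE)
  if (n_drop == 0) return(signal)
  if (is.matrix(signal)) signal[, -(seq_len(n_drop)), drop = FALSE]
  else signal[-(seq_len(n_drop))]
}

#' Preprocess one recording
#'
#' Applies the full chain in order: select channels, clip, common average
#' reference, resample, drop head. Returns `NULL` (with a log attribute
#' handled by the caller) if the result is shorter than
#' `config$min_duration_s`.
#'
#' @param recording an `eeg_recording` (or list with `signal`,
#'   `channel_names`, `sfreq`).
#' @param config a [preproc_config()].
#' @return the recording with `signal`/`sfreq`/`duration_s` replaced, or
#'   `NULL` when excluded for short duration.
#' @export
preprocess_recording <- function(recording, config = preproc_config()) {
  sig <- recording$signal
  rownames(sig) <- recording$channel_names
  sig <- select_channels(sig, recording$channel_names, config)
  sig <- clip_amplitudes(sig, config$clip_uv)
  sig <- common_average_reference(sig)
  sig <- resample_signal(sig, recording$sfreq, config$target_sfreq)
  dur <- ncol(sig) / config$target_sfreq
  if (dur <= config$drop_head_s) return(NULL)
  sig <- drop_head(sig, config$target_sfreq, config$drop_head_s)
  if (ncol(sig) / config$target_sfreq < config$min_duration_s) return(NULL)
  recording$signal <- sig
  recording$sfreq <- config$target_sfreq
  recording$channel_names <- config$channels
  recording$duration_s <- ncol(sig) / config$target_sfreq
  recording
}

#' Fit channel-wise normalization statistics
#'
#' Mean and standard deviation per channel pooled over all training
#' recordings, plus the min/max of training ages for target scaling. Tagged
#' with the recordings it was fit on so leakage can be audited.
#'
#' @param recordings list of preprocessed recordings (training split only).
#' @param ages chronological ages of the training recordings, years.
#' @param split_tag provenance label stored on the statistics.
#' @return object of class `normalization_stats` with `mean`, `sd` (per
#'   channel), `age_min`, `age_max`, `fit_on`, `split_tag`.
#' @export
fit_normalization <- function(recordings, ages, split_tag = "train") {
  stopifnot(length(recordings) > 0, length(ages) == length(recordings))
  nch <- nrow(recordings[[1]]$signal)
  s <- numeric(nch); s2 <- numeric(nch); n <- 0
  for (r in recordings) {
    s <- s + rowSums(r$signal)
    s2 <- s2 + rowSums(r$signal^2)
    n <- n + ncol(r$signal)
  }
  m <- s / n
  v <- (s2 - n * m^2) / (n - 1)
  if (any(v <= 0))
    stop("degenerate data: zero-variance channel(s): ",
         paste(recordings[[1]]$channel_names[v <= 0], collapse = ", "),
         call. = FALSE)
  structure(list(mean = m, sd = sqrt(v),
                 age_min = min(ages), age_max = max(ages),
                 fit_on = vapply(recordings, `[[`, "", "recording_id"),
                 split_tag = split_tag),
            class = "normalization_stats")
}

#' Apply channel-wise normalization
#'
#' @param stats a [fit_normalization()] result.
#' @param signal channels x samples matrix, channel order as at fit time.
#' @return standardized signal.
#' @export
apply_normalization <- function(stats, signal) {
  sweep(sweep(signal, 1, stats$mean), 1, stats$sd, `/`)
}

#' Min-max age scaling
#'
#' Maps training-range ages to `[0, 1]`; out-of-range ages are clamped with a
#' warning at scale time (evaluation sets may exceed the training range).
#' `unscale_age` inverts the map without clamping, so sigmoid outputs can
#' express ages beyond the training range boundaries only at 0/1.
#'
#' @param stats a [fit_normalization()] result.
#' @param age years (`scale_age`) or value in `[0, 1]` (`unscale_age`).
#' @return scaled value in `[0, 1]`, or years.
#' @export
scale_age <- function(stats, age) {
  y <- (age - stats$age_min) / (stats$age_max - stats$age_min)
  if (any(y < 0 | y > 1)) {
    warning("age(s) outside the training range [", stats$age_min, ", ",
            stats$age_max, "] clamped to [0, 1]")
    y <- pmin(1, pmax(0, y))
  }
  y
}

#' @rdname scale_age
#' @export
unscale_age <- function(stats, age) {
  stats$age_min + age * (stats$age_max - stats$age_min)
}
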