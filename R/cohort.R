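#' Synthetic clinical-EEG cohort configuration
#'
#' Describes a cohort of subjects with repeated EEG sessions, month-scale
#' inter-recording intervals, a per-subject stable ("trait") brain-age offset,
#' and an optional pathology-linked ("state") offset. The spectral aging model
#' planted in the signals is: alpha peak frequency
#' `f_peak = alpha_f0 - alpha_slope * effective_age` Hz with amplitude largest
#' occipitally over a 1/f ("pink") background; pathological recordings gain
#' 50% delta/theta power and lose 30% alpha amplitude. Effective age is
#' chronological age + trait offset (+ state effect while pathological).
#'
#' @param n_subjects number of subjects.
#' @param age_range years, `c(lo, hi)` for age at first recording.
#' @param sex_ratio fraction of female subjects.
#' @param recordings_per_subject_mean mean recordings per subject
#'   (shifted Poisson, minimum 1; transition subjects minimum 2).
#' @param interval_months_mean mean interval between recordings in months
#'   (lognormal, sigma = 0.5 on the log scale).
#' @param pathology_fraction fraction of non-transition subjects whose
#'   recordings are all pathological.
#' @param transition_fraction fraction of subjects whose pathology label flips
#'   exactly once (direction split 50/50).
#' @param trait_sd standard deviation (years) of the per-subject stable gap
#'   offset.
#' @param state_effect years added to effective age while a recording is
#'   labeled pathological; 0 encodes the trait-only hypothesis.
#' @param channels 10-20 channel labels to synthesize.
#' @param sfreq sampling frequency, Hz.
#' @param duration_s recording duration, seconds.
#' @param age_mismatch_fraction fraction of recordings whose two age sources
#'   disagree by more than 1 year (uniform 1-5 years, random sign).
#' @param alpha_f0,alpha_slope planted aging model (Hz, Hz/year).
#' @param alpha_session_jitter_hz session-to-session standard deviation of
#'   the alpha peak frequency (Hz). Repeated sessions of a real subject do
#'   not have identical spectra; without this term any deterministic
#'   decoder shows perfect split-half gap consistency and the state-vs-trait
#'   contrast degenerates. The default 0.1 Hz is at the conservative end of
#'   reported individual-alpha-frequency test-retest variability.
#' @param alpha_amp_uv alpha amplitude at unit spatial weight (microvolts).
#' @param pink_sd_uv standard deviation of the pink background (microvolts).
#' @param pink_exponent exponent of the 1/f^x background power spectrum.
#' @param pathology_lowband_gain multiplicative delta/theta (0.5-8 Hz) power
#'   gain for pathological recordings.
#' @param pathology_alpha_gain multiplicative alpha amplitude factor for
#'   pathological recordings.
#' @param seed integer seed; fixed seed gives a bit-identical cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 100,
                          age_range = c(18, 86),
                          sex_ratio = 0.55,
                          recordings_per_subject_mean = 2.5,
                          interval_months_mean = 12,
                          pathology_fraction = 0.4,
                          transition_fraction = 0,
                          trait_sd = 0,
                          state_effect = 0,
                          channels = c("Fp1", "Fp2", "C3", "C4",
                                       "T5", "T6", "O1", "O2"),
                          sfreq = 100,
                          duration_s = 120,
                          age_mismatch_fraction = 0,
                          alpha_f0 = 11.0,
                          alpha_slope = 0.03,
                          alpha_session_jitter_hz = 0.1,
                          alpha_amp_uv = 20,
                          pink_sd_uv = 10,
                          pink_exponent = 1,
                          pathology_lowband_gain = 1.5,
                          pathology_alpha_gain = 0.7,
                          seed = 1L) {
  cfg <- list(n_subjects = n_subjects, age_range = age_range,
              sex_ratio = sex_ratio,
              recordings_per_subject_mean = recordings_per_subject_mean,
              interval_months_mean = interval_months_mean,
              pathology_fraction = pathology_fraction,
              transition_fraction = transition_fraction,
              trait_sd = trait_sd, state_effect = state_effect,
              channels = channels, sfreq = sfreq, duration_s = duration_s,
              age_mismatch_fraction = age_mismatch_fraction,
              alpha_f0 = alpha_f0, alpha_slope = alpha_slope,
              alpha_session_jitter_hz = alpha_session_jitter_hz,
              alpha_amp_uv = alpha_amp_uv, pink_sd_uv = pink_sd_uv,
              pink_exponent = pink_exponent,
              pathology_lowband_gain = pathology_lowband_gain,
              pathology_alpha_gain = pathology_alpha_gain,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid cohort configuration: ", ...,
                                 call. = FALSE)
  fr <- c(sex_ratio = cfg$sex_ratio,
          pathology_fraction = cfg$pathology_fraction,
          transition_fraction = cfg$transition_fraction,
          age_mismatch_fraction = cfg$age_mismatch_fraction)
  bad <- fr < 0 | fr > 1
  if (any(bad)) stop_cfg(paste(names(fr)[bad], collapse = ", "),
                         " must lie in [0, 1]")
  if (cfg$n_subjects < 0) stop_cfg("n_subjects must be >= 0")
  if (cfg$age_range[1] >= cfg$age_range[2])
    stop_cfg("age_range must satisfy lo < hi")
  if (cfg$sfreq <= 0) stop_cfg("sfreq must be > 0")
  if (cfg$duration_s <= 0) stop_cfg("duration_s must be > 0")
  if (cfg$trait_sd < 0) stop_cfg("trait_sd must be >= 0")
  if (cfg$recordings_per_subject_mean < 1)
    stop_cfg("recordings_per_subject_mean must be >= 1")
  if (cfg$interval_months_mean <= 0)
    stop_cfg("interval_months_mean must be > 0")
  invisible(cfg)
}

# run code under a local RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# spatial weight of the alpha rhythm by 10-20 label: occipital maximum,
# falling off toward frontal sites
alpha_spatial_weight <- function(channel_names) {
  w <- rep(0.25, length(channel_names))
  w[grepl("^O", channel_names, ignore.case = TRUE)] <- 1
  w[grepl("^(P|T5|T6)", channel_names, ignore.case = TRUE)] <- 0.5
  w[grepl("^C", channel_names, ignore.case = TRUE)] <- 0.25
  w[grepl("^F", channel_names, ignore.case = TRUE)] <- 0.1
  w
}

#' Simulate one synthetic EEG recording
#'
#' Pink background noise plus an occipitally weighted alpha oscillation whose
#' peak frequency declines linearly with effective age; pathological
#' recordings get extra delta/theta power and attenuated alpha.
#'
#' @param effective_age years (clipped to `[0, 120]`).
#' @param pathological logical.
#' @param config a [cohort_config()].
#' @param seed integer RNG state for this recording; identical arguments give
#'   an identical matrix.
#' @return channels x samples matrix in microvolts, rows named by channel.
#' @export
simulate_recording <- function(effective_age, pathological, config, seed) {
  effective_age <- min(120, max(0, effective_age))
  n <- round(config$duration_s * config$sfreq)
  nch <- length(config$channels)
  with_local_seed(seed, {
    sig <- matrix(0, nch, n, dimnames = list(config$channels, NULL))
    freqs <- seq_len(floor(n / 2)) * config$sfreq / n  # positive FFT bins
    # 1/f amplitude shaping; pathological: +lowband power in delta/theta
    amp <- freqs^(-config$pink_exponent / 2)
    if (pathological) {
      low <- freqs >= 0.5 & freqs < 8
      amp[low] <- amp[low] * sqrt(config$pathology_lowband_gain)
    }
    for (c in seq_len(nch)) {
      z <- complex(real = stats::rnorm(length(freqs)),
                   imaginary = stats::rnorm(length(freqs))) * amp
      spec <- complex(length.out = n)
      spec[2:(length(freqs) + 1)] <- z
      spec[n:(n - length(freqs) + 2)] <- Conj(z[seq_len(length(freqs) - 1)])
      x <- Re(stats::fft(spec, inverse = TRUE)) / n
      sig[c, ] <- x / stats::sd(x) * config$pink_sd_uv
    }
    # alpha rhythm: one waveform, spatially weighted; slow waxing/waning;
    # session jitter keeps repeated sessions spectrally non-identical
    f_peak <- config$alpha_f0 - config$alpha_slope * effective_age +
      stats::rnorm(1, 0, config$alpha_session_jitter_hz)
    t <- (seq_len(n) - 1) / config$sfreq
    phase <- stats::runif(1, 0, 2 * pi)
    env <- 1 + 0.3 * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi))
    a_amp <- config$alpha_amp_uv *
      if (pathological) config$pathology_alpha_gain else 1
    alpha <- a_amp * env * sin(2 * pi * f_peak * t + phase)
    w <- alpha_spatial_weight(config$channels)
    sig <- sig + outer(w, rep(1, n)) * matrix(alpha, nch, n, byrow = TRUE)
    sig
  })
}

#' Generate a synthetic clinical-EEG cohort
#'
#' Draws subjects with repeated recordings (shifted-Poisson counts, lognormal
#' month-scale intervals), assigns stable or once-flipping pathology labels,
#' plants per-subject trait offsets and an optional state effect, and
#' synthesizes signals via [simulate_recording()]. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param signals if `FALSE`, skip signal synthesis (metadata and latents
#'   only); useful for statistics-level simulations.
#' @return list with `recordings` (list of `eeg_recording`) and `latents`
#'   (data.frame: subject_id, recording_id, trait_offset, state_active,
#'   chronological_age, effective_age).
#' @export
generate_cohort <- function(config, signals = TRUE) {
  validate_cohort_config(config)
  if (config$n_subjects == 0)
    return(list(recordings = list(), latents = empty_latents()))
  with_local_seed(config$seed, {
    recs <- list()
    lat <- list()
    rec_counter <- 0L
    conditions <- c("schizoaffective disorder", "major depressive episode",
                    "ischemic stroke")
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%04d", i)
      sex <- if (stats::runif(1) < config$sex_ratio) "F" else "M"
      is_transition <- stats::runif(1) < config$transition_fraction
      if (is_transition) {
        n_rec <- 2L + stats::rpois(1, max(0, config$recordings_per_subject_mean - 2))
      } else {
        n_rec <- 1L + stats::rpois(1, config$recordings_per_subject_mean - 1)
      }
      mean_days <- config$interval_months_mean * 30.44
      sigma <- 0.5
      gaps <- stats::rlnorm(max(0, n_rec - 1),
                            meanlog = log(mean_days) - sigma^2 / 2,
                            sdlog = sigma)
      dates <- round(stats::runif(1, 0, 365) + cumsum(c(0, gaps)), 4)
      age0 <- stats::runif(1, config$age_range[1], config$age_range[2])
      ages <- round(age0 + (dates - dates[1]) / 365.25, 4)
      if (is_transition) {
        flip_after <- sample.int(n_rec - 1L, 1L)
        np_first <- stats::runif(1) < 0.5
        labels <- rep(!np_first, n_rec)
        labels[seq_len(flip_after)] <- np_first
        labels <- !labels  # np_first TRUE => first block non-pathological
      } else {
        labels <- rep(stats::runif(1) < config$pathology_fraction, n_rec)
      }
      trait <- stats::rnorm(1, 0, config$trait_sd)
      condition <- if (any(labels) && stats::runif(1) < 0.5)
        sample(conditions, 1) else NA_character_
      for (r in seq_len(n_rec)) {
        rec_counter <- rec_counter + 1L
        rid <- sprintf("%s_R%02d", sid, r)
        eff_age <- ages[r] + trait + if (labels[r]) config$state_effect else 0
        age_header <- ages[r]
        age_report <- age_header
        if (stats::runif(1) < config$age_mismatch_fraction) {
          age_report <- round(age_header +
                                sample(c(-1, 1), 1) * stats::runif(1, 1, 5), 4)
        }
        report <- make_report(labels[r], condition)
        sig <- if (signals) {
          rec_seed <- (config$seed %% 100000L) * 10000L + rec_counter
          simulate_recording(eff_age, labels[r], config, rec_seed)
        } else NULL
        recs[[rec_counter]] <- structure(list(
          subject_id = sid, recording_id = rid, date_days = dates[r],
          age_header = age_header, age_report = age_report, sex = sex,
          pathology = labels[r], report = report, signal = sig,
          sfreq = config$sfreq, channel_names = config$channels,
          duration_s = config$duration_s), class = "eeg_recording")
        lat[[rec_counter]] <- data.frame(
          subject_id = sid, recording_id = rid, trait_offset = trait,
          state_active = labels[r], chronological_age = ages[r],
          effective_age = eff_age, stringsAsFactors = FALSE)
      }
    }
    list(recordings = recs, latents = do.call(rbind, lat))
  })
}

empty_latents <- function() {
  data.frame(subject_id = character(), recording_id = character(),
             trait_offset = numeric(), state_active = logical(),
             chronological_age = numeric(), effective_age = numeric(),
             stringsAsFactors = FALSE)
}

make_report <- function(pathological, condition) {
  if (!pathological) {
    base <- "Normal awake EEG. No epileptiform discharges."
  } else {
    base <- "Abnormal EEG with diffuse background slowing."
  }
  if (pathological && !is.na(condition)) {
    paste0(base, " Hx of ", condition, ".")
  } else base
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s subj %s age %.1f %s %s>\n",
              x$recording_id, x$subject_id, x$age_header,
              if (isTRUE(x$pathology)) "pathological" else "non-pathological",
              if (is.null(x$signal)) "(no signal)"
              else sprintf("%d ch x %d samples @ %g Hz", nrow(x$signal),
                           ncol(x$signal), x$sfreq)))
  invisible(x)
}

#' Build a manifest table from recordings
#'
#' One row per recording with the metadata columns in fixed order.
#'
#' @param recordings list of `eeg_recording` objects.
#' @return data.frame with columns subject_id, recording_id, date_days,
#'   age_header, age_report, sex, pathology, report, edf_path, duration_s,
#'   excluded_corpus.
#' @export
cohort_manifest <- function(recordings) {
  cols <- c("subject_id", "recording_id", "date_days", "age_header",
            "age_report", "sex", "pathology", "report", "edf_path",
            "duration_s", "excluded_corpus")
  if (length(recordings) == 0) {
    m <- data.frame(subject_id = character(), recording_id = character(),
                    date_days = numeric(), age_header = numeric(),
                    age_report = numeric(), sex = character(),
                    pathology = logical(), report = character(),
                    edf_path = character(), duration_s = numeric(),
                    excluded_corpus = logical(), stringsAsFactors = FALSE)
    return(m[, cols])
  }
  rows <- lapply(recordings, function(r) data.frame(
    subject_id = r$subject_id, recording_id = r$recording_id,
    date_days = r$date_days, age_header = r$age_header,
    age_report = r$age_report, sex = r$sex, pathology = r$pathology,
    report = r$report,
    edf_path = if (is.null(r$edf_path)) NA_character_ else r$edf_path,
    duration_s = r$duration_s,
    excluded_corpus = isTRUE(r$excluded_corpus),
    stringsAsFactors = FALSE))
  do.call(rbind, rows)[, cols]
}

#' Write / read a cohort manifest CSV
#'
#' The manifest round-trips losslessly: ages and dates are generated at
#' 1e-4 precision so the decimal text representation is exact.
#'
#' @param recordings list of `eeg_recording` objects or a manifest data.frame.
#' @param path output CSV path.
#' @return `write_manifest`: the path, invisibly. `read_manifest`: data.frame.
#' @export
write_manifest <- function(recordings, path) {
  m <- if (is.data.frame(recordings)) recordings else cohort_manifest(recordings)
  ok <- tryCatch({
    utils::write.csv(m, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write manifest to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      recording_id = "character",
                                      report = "character",
                                      edf_path = "character",
                                      sex = "character"))
  m$pathology <- as.logical(m$pathology)
  if ("excluded_corpus" %in% names(m))
    m$excluded_corpus <- as.logical(m$excluded_corpus)
  m
}
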