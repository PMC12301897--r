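#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-50 Hz.
#'
#' @return data.frame with `name`, `lo`, `hi` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 12, 30),
             hi = c(4, 8, 12, 30, 50),
             stringsAsFactors = FALSE)
}

#' Gradient of the model output with respect to input samples
#'
#' For a `tcn_fit` the gradient of the mean per-crop sigmoid output with
#' respect to the *standardized* crop samples is obtained from the network's
#' backward pass. Test doubles are supported: a list with elements
#' `value_fn(crop)` and `grad_fn(crop)` is differentiated by its own
#' `grad_fn`.
#'
#' @param fit a [train_age_model()] result or a test double.
#' @param crop channels x samples matrix in *raw* (unstandardized) units for
#'   a `tcn_fit`; passed through unchanged for test doubles.
#' @return list with `grad` (channels x samples matrix, d output / d sample)
#'   and `crop_std` (the crop actually differentiated).
#' @export
input_gradient <- function(fit, crop) {
  if (!is.null(fit$grad_fn)) {
    return(list(grad = fit$grad_fn(crop), crop_std = crop))
  }
  if (is.null(fit$model) || !inherits(fit$model, "tcn_model"))
    stop("capability error: model is not differentiable", call. = FALSE)
  std <- apply_normalization(fit$stats, crop)
  X <- t(std)
  fwd <- tcn_forward(fit$model, X, B = 1L, train = FALSE)
  n_out <- length(fwd$out)
  grads <- tcn_backward(fit$model, fwd, rep(1 / n_out, n_out),
                        want_input_grad = TRUE)
  list(grad = t(grads$input), crop_std = std)
}

#' Amplitude gradients of a model on one crop
#'
#' Represents each channel of the crop as an inverse DFT of amplitudes and
#' phases, `x_t = sum_f A_f cos(2 pi f t / N + phi_f)`, and chain-rules the
#' time-domain gradient through that parameterization:
#' `d out / d A_{c,f} = sum_t g_{c,t} cos(2 pi f t / N + phi_{c,f})`,
#' with phases held fixed. Positive values mean that more amplitude at that
#' channel/frequency raises the predicted age.
#'
#' @param fit a [train_age_model()] result or test double (see
#'   [input_gradient()]).
#' @param crop channels x samples matrix.
#' @param sfreq sampling frequency, Hz.
#' @return list with `grad` (channels x frequency-bin matrix), `freq`
#'   (Hz per bin, DC through Nyquist), `phase` (matching phases).
#' @export
amplitude_gradients <- function(fit, crop, sfreq) {
  ig <- input_gradient(fit, crop)
  g <- ig$grad
  x <- ig$crop_std
  n <- ncol(x)
  nbin <- floor(n / 2) + 1L
  freq <- (seq_len(nbin) - 1) * sfreq / n
  out <- matrix(0, nrow(x), nbin,
                dimnames = list(rownames(crop), NULL))
  ph <- matrix(0, nrow(x), nbin)
  for (c in seq_len(nrow(x))) {
    phase <- Arg(stats::fft(x[c, ])[seq_len(nbin)])
    # sum_t g_t cos(2 pi f t / N + phi) = Re(e^{i phi} conj(DFT(g))_f)
    out[c, ] <- Re(exp(1i * phase) * Conj(stats::fft(g[c, ]))[seq_len(nbin)])
    ph[c, ] <- phase
  }
  list(grad = out, freq = freq, phase = ph)
}

#' Aggregate bin gradients into frequency bands
#'
#' Mean of signed bin gradients whose center frequency lies in `[lo, hi)` of
#' each band.
#'
#' @param bin_grad channels x bins matrix from [amplitude_gradients()].
#' @param freq bin center frequencies, Hz.
#' @param bands a [band_definitions()]-shaped data.frame.
#' @return channels x bands matrix (column names = band names; bands with no
#'   bins are NA).
#' @export
band_aggregate <- function(bin_grad, freq, bands = band_definitions()) {
  stopifnot(ncol(bin_grad) == length(freq))
  out <- matrix(NA_real_, nrow(bin_grad), nrow(bands),
                dimnames = list(rownames(bin_grad), bands$name))
  for (b in seq_len(nrow(bands))) {
    sel <- freq >= bands$lo[b] & freq < bands$hi[b]
    if (any(sel)) out[, b] <- rowMeans(bin_grad[, sel, drop = FALSE])
  }
  out
}

#' Group-level saliency maps
#'
#' Averages channel x band amplitude-gradient maps over crops within a
#' recording, recordings within a subject, subjects within a pathology
#' group, and finally over model runs; the difference map is
#' non-pathological minus pathological.
#'
#' @param fits list of fitted models (one per final-evaluation run).
#' @param recordings list of preprocessed `eeg_recording`s.
#' @param crop_stride stride (samples) between analyzed crops; the default
#'   (receptive field length) covers the recording with non-overlapping
#'   crops, `1` reproduces fully dense decoding at proportional cost.
#' @param bands band definitions.
#' @return list of class `saliency_maps`: `np`, `p`, `difference`
#'   (channel x band matrices), `n_recordings`, `n_runs`.
#' @export
group_saliency <- function(fits, recordings, crop_stride = NULL,
                           bands = band_definitions()) {
  stopifnot(length(fits) > 0, length(recordings) > 0)
  labels <- vapply(recordings, `[[`, TRUE, "pathology")
  if (!any(labels) || all(labels))
    stop("need at least one recording per pathology group", call. = FALSE)
  rf <- fits[[1]]$model$cfg$receptive_field
  if (is.null(crop_stride)) crop_stride <- rf
  sfreq <- recordings[[1]]$sfreq
  rec_map <- function(fit, rec) {
    starts <- seq(1L, ncol(rec$signal) - rf + 1L, by = crop_stride)
    maps <- lapply(starts, function(s) {
      crop <- rec$signal[, s:(s + rf - 1L), drop = FALSE]
      ag <- amplitude_gradients(fit, crop, sfreq)
      band_aggregate(ag$grad, ag$freq, bands)
    })
    Reduce(`+`, maps) / length(maps)
  }
  group_map <- function(fit, recs) {
    subj <- vapply(recs, `[[`, "", "subject_id")
    subj_maps <- lapply(split(seq_along(recs), subj), function(idx) {
      m <- lapply(idx, function(j) rec_map(fit, recs[[j]]))
      Reduce(`+`, m) / length(m)
    })
    Reduce(`+`, subj_maps) / length(subj_maps)
  }
  np_runs <- lapply(fits, group_map, recs = recordings[!labels])
  p_runs <- lapply(fits, group_map, recs = recordings[labels])
  np <- Reduce(`+`, np_runs) / length(np_runs)
  p <- Reduce(`+`, p_runs) / length(p_runs)
  structure(list(np = np, p = p, difference = np - p,
                 n_recordings = length(recordings), n_runs = length(fits)),
            class = "saliency_maps")
}

#' @export
print.saliency_maps <- function(x, ...) {
  cat(sprintf("<saliency_maps: %d recordings, %d runs>\n",
              x$n_recordings, x$n_runs))
  cat("difference map (non-pathological - pathological):\n")
  print(round(x$difference, 5))
  invisible(x)
}
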