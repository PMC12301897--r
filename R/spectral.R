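#' Welch power spectral density
#'
#' Averaged-periodogram PSD estimate with a Hann window, used both by the
#' synthetic-cohort sanity oracles and by the spectral baseline age decoder.
#'
#' @param x numeric vector, one channel of signal.
#' @param sfreq sampling frequency in Hz.
#' @param nperseg segment length in samples (default `min(length(x), 4 * sfreq)`).
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz), one value per
#'   non-negative frequency bin of the segment length.
#' @export
welch_psd <- function(x, sfreq, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, round(4 * sfreq))
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  norm <- sum(win^2) * sfreq
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(seg)[seq_len(nfreq)]
    p <- Re(sp * Conj(sp)) / norm
    # one-sided: double everything except DC (and Nyquist for even nperseg)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nperseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * sfreq / nperseg, psd = acc / length(starts))
}

#' Band power from a PSD
#'
#' Integrates a Welch PSD over `[lo, hi)` Hz by the rectangle rule.
#'
#' @param x numeric vector or the list returned by [welch_psd()].
#' @param sfreq sampling frequency (ignored when `x` is already a PSD).
#' @param lo,hi band edges in Hz.
#' @param ... passed on to [welch_psd()].
#' @return scalar band power.
#' @export
band_power <- function(x, sfreq, lo, hi, ...) {
  psd <- if (is.list(x)) x else welch_psd(x, sfreq, ...)
  sel <- psd$freq >= lo & psd$freq < hi
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[sel]) * df
}

#' Alpha peak frequency
#'
#' Location of the maximum of the Welch PSD within the alpha search band,
#' refined by parabolic interpolation around the peak bin. This is the
#' feature the synthetic aging model plants, so it doubles as the
#' model-free baseline decoder.
#'
#' @param x numeric vector, one channel.
#' @param sfreq sampling frequency in Hz.
#' @param band search band in Hz (default `c(7, 13)`).
#' @param nperseg Welch segment length (default 8 s worth of samples).
#' @return peak frequency in Hz, or `NA` if the band holds fewer than 3 bins.
#' @export
alpha_peak_frequency <- function(x, sfreq, band = c(7, 13), nperseg = NULL) {
  if (is.null(nperseg)) nperseg <- min(length(x), round(8 * sfreq))
  psd <- welch_psd(x, sfreq, nperseg = nperseg)
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  if (length(sel) < 3) return(NA_real_)
  i <- sel[which.max(psd$psd[sel])]
  if (i <= 1L || i >= length(psd$freq)) return(psd$freq[i])
  # parabolic refinement on log power
  y <- log(psd$psd[(i - 1):(i + 1)] + .Machine$double.xmin)
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y[1] - y[3]) / denom
  df <- psd$freq[2] - psd$freq[1]
  psd$freq[i] + max(-0.5, min(0.5, delta)) * df
}

#' Spectral baseline age estimate
#'
#' Inverts the planted linear alpha-peak aging model
#' `f_peak = f0 - slope * age` on the occipital channel average. Used as an
#' independent check that the synthetic decoding task is solvable before any
#' network is trained.
#'
#' @param signal channels x samples matrix (microvolts).
#' @param channel_names channel labels for the rows of `signal`.
#' @param sfreq sampling frequency in Hz.
#' @param f0 intercept of the planted aging model (Hz).
#' @param slope decline of alpha peak frequency per year (Hz/year).
#' @return estimated age in years.
#' @export
spectral_age_estimate <- function(signal, channel_names, sfreq,
                                  f0 = 11.0, slope = 0.03) {
  occ <- grep("^O", channel_names)
  if (length(occ) == 0) occ <- seq_len(nrow(signal))
  x <- colMeans(signal[occ, , drop = FALSE])
  fp <- alpha_peak_frequency(x, sfreq)
  (f0 - fp) / slope
}
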