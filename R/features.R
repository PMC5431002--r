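#' EEG frequency bands
#'
#' Band edges in Hz used by the feature battery: delta 0.5-4, alpha 8.5-13,
#' beta 13-30, gamma 30-128.  (The 4-8.5 Hz gap between delta and alpha is
#' deliberate; no theta band is computed.)  Bands are half-open
#' `[lo, hi)` so adjacent bands never double-count a bin, except that the
#' gamma upper edge equals the Nyquist frequency at 256 Hz and the Nyquist
#' bin is included.
#' @export
eeg_bands <- function() list(delta = c(0.5, 4), alpha = c(8.5, 13),
                             beta = c(13, 30), gamma = c(30, 128))

# PSD defaults: Hann, 1-s segments, 50% overlap, 2x zero-padding so the
# frequency resolution is fs/512 = 0.5 Hz at 256 Hz.
psd_default <- function() list(nperseg = 256, overlap = 0.5, pad = 2)

welch <- function(x, fs, params = psd_default()) {
  nperseg <- params$nperseg
  if (length(x) < nperseg) {
    message(sprintf(
      "window of %d samples shorter than one PSD segment (%d); using a single periodogram",
      length(x), nperseg))
    nperseg <- length(x)
  }
  welch_psd_padded(x, fs, nperseg, params$overlap, params$pad)
}

welch_psd_padded <- function(x, fs, nperseg, overlap, pad) {
  x <- as.numeric(x) - mean(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples for a PSD", call. = FALSE)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- if (nperseg > 1)
    0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1)) else 1
  nfft <- pad * nperseg
  scale <- fs * sum(w^2)
  nf <- nfft %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- c(x[s:(s + nperseg - 1L)] * w, numeric(nfft - nperseg))
    p <- abs(stats::fft(seg))^2 / scale
    acc <- acc + p[1:nf]
  }
  psd <- acc / length(starts)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nfft, psd = psd * dbl, df = fs / nfft)
}

#' Band power of an EEG window
#'
#' Integral of the Welch power spectral density over a frequency band
#' (mean-subtracted input, Hann window, 1-s segments, 50% overlap).
#' Windows shorter than one PSD segment fall back to a single periodogram
#' with a message.
#'
#' @param x numeric samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param band numeric `c(f_lo, f_hi)` in Hz, `f_hi <= fs/2`.
#' @param params PSD parameters, see `psd_default()`.
#' @return Band power in microvolt^2.
#' @export
band_power <- function(x, fs, band, params = psd_default()) {
  stopifnot(band[2] <= fs / 2 + 1e-9)
  ps <- welch(x, fs, params)
  sel <- ps$freq >= band[1] &
    (ps$freq < band[2] | (band[2] >= fs / 2 & ps$freq <= band[2]))
  sum(ps$psd[sel]) * ps$df
}

#' Alpha-delta power ratio
#'
#' Ratio of alpha-band (8.5-13 Hz) to delta-band (0.5-4 Hz) power.  When
#' the delta power underflows to zero the ratio is capped at `cap` to keep
#' downstream normalization finite.
#'
#' @inheritParams band_power
#' @param cap sentinel value returned when delta power is zero (default 1e6).
#' @return Dimensionless ratio in `[0, cap]`.
#' @export
alpha_delta_ratio <- function(x, fs, params = psd_default(), cap = 1e6) {
  b <- eeg_bands()
  a <- band_power(x, fs, b$alpha, params)
  d <- band_power(x, fs, b$delta, params)
  if (d == 0) return(if (a == 0) 0 else cap)
  min(a / d, cap)
}

#' Peak frequency of an EEG window
#'
#' Frequency of the PSD maximum within `[0.5, 128]` Hz (clipped to
#' Nyquist); ties, including an all-zero PSD, resolve to the lowest
#' in-range frequency bin.
#'
#' @inheritParams band_power
#' @return Frequency in Hz.
#' @export
peak_frequency <- function(x, fs, params = psd_default()) {
  ps <- welch(x, fs, params)
  sel <- which(ps$freq >= 0.5 & ps$freq <= min(128, fs / 2))
  ps$freq[sel][which.max(ps$psd[sel])]
}

#' Line length of an EEG window
#'
#' Sum of absolute successive sample differences, a classic seizure-energy
#' surrogate.
#'
#' @param x numeric samples, microvolts (>= 2 samples).
#' @return Line length in microvolts.
#' @export
line_length <- function(x) {
  stopifnot(length(x) >= 2)
  sum(abs(diff(x)))
}

#' Teager-Kaiser energy of an EEG window
#'
#' The nonlinear energy operator `psi[n] = x[n]^2 - x[n-1] * x[n+1]`,
#' evaluated on interior samples.
#'
#' @param x numeric samples (>= 3 samples).
#' @return list with `mean` and `sd` (population SD) of psi, microvolt^2.
#' @export
teager_kaiser <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  psi <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  m <- mean(psi)
  list(mean = m, sd = sqrt(mean((psi - m)^2)))
}

#' Detect spikes of one polarity in an EEG window
#'
#' Local extrema of the requested polarity whose magnitude exceeds
#' `threshold_k` times the robust SD of the window (median absolute
#' deviation scaled by 1.4826), kept greedily in descending magnitude
#' subject to a minimum separation.  Deterministic: magnitude ties break to
#' the earlier sample.
#'
#' @param x numeric samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param polarity `"positive"` or `"negative"`.
#' @param threshold_k robust-SD multiple for the detection threshold
#'   (default 4).
#' @param min_separation_s minimum separation between accepted spikes in
#'   seconds (default 0.08).
#' @return An object of class `spike_train`: list with `polarity`,
#'   `times_s` (strictly increasing, relative to window start) and `amps`
#'   (magnitudes, microvolts).
#' @export
detect_spikes <- function(x, fs, polarity = c("positive", "negative"),
                          threshold_k = 4, min_separation_s = 0.08) {
  polarity <- match.arg(polarity)
  y <- if (polarity == "negative") -x else x
  n <- length(y)
  thr <- threshold_k * stats::mad(x, constant = 1.4826)
  idx <- integer(); amp <- numeric()
  if (n >= 3) {
    i <- 2:(n - 1)
    is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > thr & y[i] > 0
    idx <- i[is_max]; amp <- y[idx]
  }
  if (length(idx)) {
    ord <- order(-amp, idx)
    kept <- integer()
    min_gap <- min_separation_s * fs
    for (j in ord) {
      if (!length(kept) || all(abs(idx[j] - kept) >= min_gap))
        kept <- c(kept, idx[j])
    }
    kept <- sort(kept)
    idx <- kept; amp <- y[kept]
  }
  structure(list(polarity = polarity, times_s = (idx - 1) / fs, amps = amp),
            class = "spike_train")
}

#' Summary statistics of a spike train
#'
#' With no spikes the interval is imputed as the window length and the
#' amplitude as 0; with one spike the interval is the window length and
#' the amplitude is that spike's.  This keeps downstream feature matrices
#' free of NaN.
#'
#' @param train a [detect_spikes()] result.
#' @param window_length_s length of the analysed window in seconds.
#' @return list with `n`, `median_interval_s`, `median_amp`.
#' @export
spike_stats <- function(train, window_length_s) {
  n <- length(train$times_s)
  if (n == 0)
    return(list(n = 0L, median_interval_s = window_length_s, median_amp = 0))
  if (n == 1)
    return(list(n = 1L, median_interval_s = window_length_s,
                median_amp = train$amps))
  list(n = n, median_interval_s = stats::median(diff(train$times_s)),
       median_amp = stats::median(train$amps))
}

#' Canonical names of the 44-feature seizure descriptor
#'
#' Fourteen features are computed in each of three windows (whole seizure,
#' first 10 s, last 10 s, the latter two clipped to the seizure length):
#' alpha/beta/gamma band power, alpha-delta ratio, peak frequency, line
#' length, positive and negative spike count / median interval / median
#' amplitude, and Teager-Kaiser energy mean and SD.  Delta power is computed
#' only in the first 10 s (it is movement-artifact dominated later) and
#' seizure length only once, giving 14 x 3 + 2 = 44 features.
#'
#' @return Character vector of length 44, in canonical order.
#' @export
feature_names <- function() {
  per_window <- c("alpha_power", "beta_power", "gamma_power",
                  "alpha_delta_ratio", "peak_frequency", "line_length",
                  "n_pos_spikes", "n_neg_spikes",
                  "med_interval_pos", "med_interval_neg",
                  "med_amp_pos", "med_amp_neg", "tke_mean", "tke_sd")
  c(paste0(rep(per_window, 3), "_",
           rep(c("whole", "first10", "last10"), each = length(per_window))),
    "delta_power_first10", "seizure_length")
}

#' Extract the 44-feature descriptor of one seizure
#'
#' @param segment a [seizure_segment()].
#' @param psd_params PSD parameters, see `psd_default()`.
#' @param threshold_k,min_separation_s spike-detector parameters, see
#'   [detect_spikes()].
#' @return Named numeric vector of length 44 in [feature_names()] order.
#' @export
extract_features <- function(segment, psd_params = psd_default(),
                             threshold_k = 4, min_separation_s = 0.08) {
  x <- seizure_samples(segment)
  fs <- segment$fs_hz
  if (length(x) < 3)
    stop("seizure shorter than 3 samples; features undefined", call. = FALSE)
  n10 <- min(length(x), round(10 * fs))
  windows <- list(whole = x, first10 = x[1:n10],
                  last10 = x[(length(x) - n10 + 1):length(x)])
  bands <- eeg_bands()
  vals <- unlist(lapply(windows, function(w) {
    len_s <- length(w) / fs
    tk <- teager_kaiser(w)
    pos <- spike_stats(detect_spikes(w, fs, "positive", threshold_k,
                                     min_separation_s), len_s)
    neg <- spike_stats(detect_spikes(w, fs, "negative", threshold_k,
                                     min_separation_s), len_s)
    c(band_power(w, fs, bands$alpha, psd_params),
      band_power(w, fs, bands$beta, psd_params),
      band_power(w, fs, bands$gamma, psd_params),
      alpha_delta_ratio(w, fs, psd_params),
      peak_frequency(w, fs, psd_params),
      line_length(w),
      pos$n, neg$n, pos$median_interval_s, neg$median_interval_s,
      pos$median_amp, neg$median_amp, tk$mean, tk$sd)
  }), use.names = FALSE)
  out <- c(vals,
           band_power(windows$first10, fs, bands$delta, psd_params),
           seizure_length_s(segment))
  names(out) <- feature_names()
  out
}

#' Feature table for a set of seizure segments
#'
#' @param segments list of [seizure_segment()] objects.
#' @param ... passed to [extract_features()].
#' @return data.frame with `animal_id`, `seizure_id`, `label` and the 44
#'   canonical feature columns, one row per seizure.
#' @export
feature_table <- function(segments, ...) {
  rows <- lapply(segments, function(s) {
    f <- extract_features(s, ...)
    cbind(data.frame(animal_id = s$animal_id, seizure_id = s$seizure_id,
                     label = s$label, stringsAsFactors = FALSE),
          as.data.frame(as.list(f), check.names = FALSE))
  })
  do.call(rbind, rows)
}
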