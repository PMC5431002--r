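#' Morlet wavelet spectrogram of a seizure segment
#'
#' Time-frequency power via an FFT-based continuous wavelet transform with
#' an analytic Morlet mother wavelet (Gaussian-windowed complex sinusoid,
#' `omega0` cycles, default 6).  The transform covers the seizure plus the
#' surrounding context in the trace; if fewer than `context_s` seconds of
#' context are available on either side the trace is zero-padded with a
#' warning.  Frequencies are log-spaced over `f_range` (clipped to Nyquist
#' with a warning if needed).
#'
#' @param segment a [seizure_segment()].
#' @param f_range frequency range in Hz, default `c(0.5, 60)`.
#' @param n_freq number of log-spaced frequencies (default 64).
#' @param omega0 Morlet center-frequency parameter (cycles, default 6).
#' @param context_s context to include before onset and after offset
#'   (default 10 s).
#' @return An object of class `morlet_spectrogram`: list with `power`
#'   (`n_freq` x n_time matrix, microvolt^2), `freq_hz`, and `time_s`
#'   (relative to seizure onset).
#' @export
morlet_spectrogram <- function(segment, f_range = c(0.5, 60), n_freq = 64,
                               omega0 = 6, context_s = 10) {
  fs <- segment$fs_hz
  nyq <- fs / 2
  if (f_range[2] > nyq) {
    warning(sprintf("f_range upper edge %g Hz exceeds Nyquist %g Hz; clipped",
                    f_range[2], nyq), call. = FALSE)
    f_range[2] <- nyq
  }
  ctx <- round(context_s * fs)
  pre_pad <- max(0L, ctx - (segment$onset_index - 1L))
  post_pad <- max(0L, ctx - (length(segment$samples) - segment$offset_index
                             + 1L))
  if (pre_pad > 0 || post_pad > 0)
    warning(sprintf(
      "only %.1f / %.1f s of pre/post context available; zero-padding",
      (segment$onset_index - 1L) / fs,
      (length(segment$samples) - segment$offset_index + 1L) / fs),
      call. = FALSE)
  i0 <- max(1L, segment$onset_index - ctx)
  i1 <- min(length(segment$samples), segment$offset_index + ctx - 1L)
  x <- c(numeric(pre_pad), segment$samples[i0:i1], numeric(post_pad))

  n <- length(x)
  freqs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freq))
  xf <- stats::fft(x)
  k_idx <- 0:(n - 1)
  pos <- k_idx > 0 & k_idx <= n / 2          # analytic: positive freqs only
  omega <- 2 * pi * fs * k_idx / n
  power <- matrix(0, nrow = n_freq, ncol = n)
  for (k in seq_len(n_freq)) {
    s <- omega0 / (2 * pi * freqs[k])
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * s * fs) *
      exp(-0.5 * (s * omega - omega0)^2) * pos
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / n
    power[k, ] <- Mod(w)^2
  }
  t0 <- (i0 - pre_pad - segment$onset_index) / fs
  structure(list(power = power, freq_hz = freqs,
                 time_s = t0 + (seq_len(n) - 1) / fs),
            class = "morlet_spectrogram")
}

#' @export
print.morlet_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<morlet_spectrogram> %d freqs [%.2g, %.3g] Hz x %d times [%.1f, %.1f] s\n",
    length(x$freq_hz), min(x$freq_hz), max(x$freq_hz), length(x$time_s),
    min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Write a spectrogram as a CSV matrix
#'
#' Rows are frequencies (first column `freq_hz`), remaining columns are time
#' points named by time in seconds relative to seizure onset.
#'
#' @param spec a [morlet_spectrogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_csv <- function(spec, path) {
  df <- data.frame(freq_hz = spec$freq_hz, spec$power, check.names = FALSE)
  names(df)[-1] <- sprintf("t%.4f", spec$time_s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
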