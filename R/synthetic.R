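#' Specification of a simulated injection cohort
#'
#' Event timelines are drawn from an inhomogeneous Poisson process over the
#' observation window [-3 h, +5 h]: rate `baseline_rate` outside the
#' injection period, and `baseline_rate * m(t)` during the 3-h injection
#' period `[0, 3 h)`, where `m(t)` is either a step at
#' `experimental_multiplier` or a linear ramp reaching it at 3 h (the
#' latter mimics a steadily accumulating injection effect).  Accepted
#' events impose a refractory gap: no further event within `refractory_s`
#' seconds, emulating post-ictal recovery and matching the 5-minute
#' at-risk rule of the hazard estimator.
#'
#' @param n_experiments number of experiments.
#' @param baseline_rate baseline seizure rate, seizures/hour.
#' @param experimental_multiplier rate multiplier during `[0, 3 h)`.
#' @param ramp `"step"` or `"linear"`.
#' @param refractory_s refractory gap in seconds (default 300).
#' @param injection_type label stamped on the timelines (default `"KCl"`).
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_experiments = 24, baseline_rate = 0.28,
                        experimental_multiplier = 48 / 20,
                        ramp = c("step", "linear"), refractory_s = 300,
                        injection_type = "KCl", seed = 1) {
  ramp <- match.arg(ramp)
  stopifnot(baseline_rate >= 0, experimental_multiplier >= 0,
            refractory_s >= 0, n_experiments >= 1)
  structure(list(n_experiments = n_experiments,
                 baseline_rate = baseline_rate,
                 experimental_multiplier = experimental_multiplier,
                 ramp = ramp, refractory_s = refractory_s,
                 injection_type = injection_type, seed = seed),
            class = "cohort_spec")
}

#' Simulate seizure event timelines
#'
#' @param spec a [cohort_spec()].
#' @return list of [experiment_timeline()] objects, one per experiment.
#' @export
simulate_timeline <- function(spec) {
  set.seed(spec$seed)
  lam0 <- spec$baseline_rate
  m <- spec$experimental_multiplier
  rate <- function(t_h) {          # t in hours relative to injection start
    inj <- t_h >= 0 & t_h < 3
    mult <- if (spec$ramp == "step") m else 1 + (m - 1) * pmax(t_h, 0) / 3
    lam0 * ifelse(inj, mult, 1)
  }
  lam_max <- lam0 * max(1, m)
  lapply(seq_len(spec$n_experiments), function(i) {
    onsets <- numeric()
    if (lam_max > 0) {
      n_cand <- stats::rpois(1, lam_max * 8)
      cand <- sort(stats::runif(n_cand, -3, 5))
      acc <- cand[stats::runif(n_cand) < rate(cand) / lam_max]
      last <- -Inf
      for (t in acc) {
        if ((t - last) * 3600 > spec$refractory_s) {
          onsets <- c(onsets, t)
          last <- t
        }
      }
    }
    experiment_timeline(sprintf("sim%03d", i), sprintf("sim%03d", i),
                        spec$injection_type, onsets * 3600)
  })
}

#' Specification of one animal's seizure archetype
#'
#' A simulated seizure is a train of spike-wave complexes over 1/f
#' background: sharp biphasic transients (width `spike_width_s`, amplitude
#' `spike_amp`) ride on a slow-wave chirp locked to the instantaneous
#' discharge rate, which sweeps linearly from `spike_rate_start` to
#' `spike_rate_end` over the seizure.  The wave component (amplitude
#' `wave_amp_frac * spike_amp`) carries most of the low-frequency power, so
#' the spectral peak tracks the discharge-rate trajectory as it does in
#' recorded spike-wave seizures.  Rates and amplitude are jittered between
#' seizures by the fractional SD `within_animal_jitter`, and the duration
#' is drawn from a normal distribution truncated at 3 s.  Between-animal
#' differences in these parameters are the "archetype" the classifier is
#' expected to recognise.
#'
#' @param animal_id character id.
#' @param spike_rate_start,spike_rate_end discharge rate trajectory, Hz
#'   (each within (0.5, 30)).
#' @param spike_amp transient amplitude, microvolts.
#' @param spike_width_s transient width, seconds.
#' @param wave_amp_frac slow-wave amplitude as a fraction of `spike_amp`
#'   (default 0.8; 0 disables the wave component).
#' @param background_1f_level SD of the 1/f background, microvolts.
#' @param duration_mean_s,duration_sd_s seizure duration distribution, s.
#' @param within_animal_jitter fractional SD applied to rates and
#'   amplitude between seizures of the same animal.
#' @param seed integer RNG seed.
#' @return list of class `archetype_spec`.
#' @export
archetype_spec <- function(animal_id, spike_rate_start = 3,
                           spike_rate_end = 8, spike_amp = 400,
                           spike_width_s = 0.06, wave_amp_frac = 0.8,
                           background_1f_level = 40,
                           duration_mean_s = 40, duration_sd_s = 8,
                           within_animal_jitter = 0.08, seed = 1) {
  stopifnot(spike_rate_start > 0.5, spike_rate_start < 30,
            spike_rate_end > 0.5, spike_rate_end < 30,
            duration_mean_s > 3)
  structure(list(animal_id = as.character(animal_id),
                 spike_rate_start = spike_rate_start,
                 spike_rate_end = spike_rate_end, spike_amp = spike_amp,
                 spike_width_s = spike_width_s,
                 wave_amp_frac = wave_amp_frac,
                 background_1f_level = background_1f_level,
                 duration_mean_s = duration_mean_s,
                 duration_sd_s = duration_sd_s,
                 within_animal_jitter = within_animal_jitter, seed = seed),
            class = "archetype_spec")
}

# 1/f (pink) background noise with unit SD, via spectral shaping.
pink_noise <- function(n) {
  nf <- n %/% 2 + 1L
  amp <- c(0, 1 / sqrt(1:(nf - 1)))
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  s <- stats::sd(x)
  if (s == 0) numeric(n) else (x - mean(x)) / s
}

# biphasic transient: Ricker (Mexican-hat) pulse, unit peak, width w seconds
ricker_pulse <- function(w, fs) {
  sigma <- w / 4
  t <- seq(-3 * sigma, 3 * sigma, by = 1 / fs)
  (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
}

#' Simulate one seizure EEG segment
#'
#' @param spec an [archetype_spec()].
#' @param label seizure label to stamp (default `"spontaneous"`).
#' @param seizure_id identifier (default derived from the seed).
#' @param seed RNG seed for this seizure (default `spec$seed`); distinct
#'   seeds give distinct within-archetype seizures.
#' @param fs_hz sampling rate (default 256).
#' @param context_s background context before and after the seizure
#'   (default 10 s).
#' @return A [seizure_segment()].
#' @export
simulate_seizure <- function(spec, label = "spontaneous",
                             seizure_id = sprintf("sz%d", seed),
                             seed = spec$seed, fs_hz = 256, context_s = 10) {
  set.seed(seed)
  jit <- function(v) v * (1 + spec$within_animal_jitter * stats::rnorm(1))
  dur <- max(3, stats::rnorm(1, spec$duration_mean_s, spec$duration_sd_s))
  r0 <- min(max(jit(spec$spike_rate_start), 0.6), 29.9)
  r1 <- min(max(jit(spec$spike_rate_end), 0.6), 29.9)
  amp <- jit(spec$spike_amp)

  n_ctx <- round(context_s * fs_hz)
  n_sz <- round(dur * fs_hz)
  n <- n_sz + 2L * n_ctx
  x <- if (spec$background_1f_level > 0)
    spec$background_1f_level * pink_noise(n) else numeric(n)

  # slow-wave chirp locked to the instantaneous discharge rate, with a
  # cosine taper over the first and last second of the seizure
  if (spec$wave_amp_frac > 0 && amp != 0) {
    t_sz <- (seq_len(n_sz) - 1) / fs_hz
    phase <- 2 * pi * (r0 * t_sz + (r1 - r0) * t_sz^2 / (2 * dur))
    taper <- pmin(1, t_sz, dur - t_sz)
    taper <- 0.5 - 0.5 * cos(pi * pmax(taper, 0))
    x[n_ctx + seq_len(n_sz)] <- x[n_ctx + seq_len(n_sz)] +
      spec$wave_amp_frac * amp * taper * sin(phase)
  }

  # spike times by inverting the integrated rate r(t) = r0 + (r1-r0) t/dur
  total <- r0 * dur + (r1 - r0) * dur / 2
  if (total >= 1 && amp != 0) {
    ks <- seq_len(floor(total))
    times <- if (abs(r1 - r0) < 1e-9) ks / r0 else
      (-r0 + sqrt(r0^2 + 2 * (r1 - r0) * ks / dur)) / ((r1 - r0) / dur)
    times <- times + 0.1 * spec$within_animal_jitter *
      stats::rnorm(length(times)) / max(r0, r1)
    times <- sort(times[times > 0 & times < dur])
    pulse <- ricker_pulse(jit(spec$spike_width_s), fs_hz)
    half <- (length(pulse) - 1L) %/% 2L
    for (tk in times) {
      c0 <- n_ctx + round(tk * fs_hz)
      i0 <- c0 - half; i1 <- c0 + (length(pulse) - 1L - half)
      if (i0 < 1L || i1 > n) next
      x[i0:i1] <- x[i0:i1] + amp *
        (1 + 0.3 * spec$within_animal_jitter * stats::rnorm(1)) * pulse
    }
  }
  seizure_segment(spec$animal_id, seizure_id, label, fs_hz, x,
                  onset_index = n_ctx + 1L, offset_index = n_ctx + n_sz + 1L)
}

#' Build a synthetic multi-animal seizure cohort
#'
#' Places `n_animals` archetypes with controlled between-animal separation
#' and draws, for each animal, spontaneous seizures, same-archetype
#' "induced" (KCl-reuniens) seizures, and optional distorted-archetype
#' negative controls (kainic acid: triple duration and up-shifted rates;
#' electrical: low-voltage fast activity).  `separation` scales how far
#' apart the archetypes sit in discharge rate and amplitude: 0 makes all
#' animals exchangeable; the default 1.5 gives between-animal differences
#' comfortably larger than the within-animal jitter.
#'
#' @param n_animals number of animals (>= 2, default 4).
#' @param n_spontaneous,n_induced,n_kainic,n_electrical seizures per animal
#'   of each label (defaults 10, 2, 1, 1).
#' @param separation archetype separation (default 1.5; rate offset in Hz
#'   per animal, with a proportional amplitude offset).
#' @param seed integer RNG seed.
#' @return list with `segments` (list of [seizure_segment()]) and `meta`
#'   (data.frame of ids and truth labels).
#' @export
make_cohort <- function(n_animals = 4, n_spontaneous = 10, n_induced = 2,
                        n_kainic = 1, n_electrical = 1, separation = 1.5,
                        seed = 1) {
  stopifnot(n_animals >= 2)
  segments <- list()
  sub_seed <- seed * 1000L
  for (i in seq_len(n_animals)) {
    spec <- archetype_spec(
      animal_id = sprintf("animal%02d", i),
      spike_rate_start = 2.5 + (i - 1) * separation,
      spike_rate_end = 6.5 + (i - 1) * separation,
      spike_amp = 300 + 80 * (i - 1) * separation,
      spike_width_s = 0.05 + 0.004 * (i - 1) * separation,
      seed = seed)
    draw <- function(label, count, mutate = identity) {
      lapply(seq_len(count), function(k) {
        sub_seed <<- sub_seed + 1L
        simulate_seizure(mutate(spec), label,
                         seizure_id = sprintf("%s_%s%02d", spec$animal_id,
                                              label, k),
                         seed = sub_seed)
      })
    }
    segments <- c(
      segments,
      draw("spontaneous", n_spontaneous),
      draw("kcl_reuniens", n_induced),
      draw("kainic_acid", n_kainic, function(s) {
        s$duration_mean_s <- 3 * s$duration_mean_s
        s$spike_rate_start <- min(s$spike_rate_start + 4, 29)
        s$spike_rate_end <- min(s$spike_rate_end + 6, 29)
        s
      }),
      draw("electrical", n_electrical, function(s) {
        s$spike_amp <- 0.2 * s$spike_amp
        s$spike_rate_start <- 15
        s$spike_rate_end <- 22
        s$spike_width_s <- 0.02
        s
      }))
  }
  meta <- data.frame(
    animal_id = vapply(segments, `[[`, character(1), "animal_id"),
    seizure_id = vapply(segments, `[[`, character(1), "seizure_id"),
    label = vapply(segments, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  list(segments = segments, meta = meta)
}
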