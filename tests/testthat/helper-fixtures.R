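# Shared fixture builders and brute-force oracles.

# A timeline with given onsets (seconds), KCl by default.
tl <- function(onsets, id = "e1", animal = "a1", type = "KCl")
  experiment_timeline(id, animal, type, onsets)

# Literal transcription of the at-risk definition: loop over experiments and
# events, open interval on both ends.
brute_at_risk <- function(timelines, t, w = 300) {
  n <- 0L
  for (x in timelines) {
    excluded <- FALSE
    for (ev in x$onsets_s)
      if (ev > t - w && ev < t) excluded <- TRUE
    if (!excluded) n <- n + 1L
  }
  n
}

# Tone/chirp makers at a given sampling rate.
tone <- function(f, dur_s, fs = 256, amp = 1)
  amp * sin(2 * pi * f * (0:(dur_s * fs - 1)) / fs)

chirp <- function(f0, f1, dur_s, fs = 256) {
  t <- (0:(dur_s * fs - 1)) / fs
  sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur_s)))
}

# Wrap raw samples as a segment whose seizure spans the whole trace.
as_segment <- function(x, fs = 256, animal = "a1", id = "s1",
                       label = "spontaneous")
  seizure_segment(animal, id, label, fs, x, 1L, length(x) + 1L)

# Segment with explicit context around the seizure.
segment_with_context <- function(core, ctx_s = 10, fs = 256, ...) {
  n_ctx <- round(ctx_s * fs)
  seizure_segment("a1", "s1", "spontaneous", fs,
                  c(numeric(n_ctx), core, numeric(n_ctx)),
                  n_ctx + 1L, n_ctx + length(core) + 1L, ...)
}

# Random feature table (not EEG-derived) for pipeline bookkeeping tests:
# per animal a Gaussian cluster at a distinct centre.
random_feature_table <- function(n_animals, n_spont, n_induced = 0,
                                 spread = 0.5, seed = 42) {
  set.seed(seed)
  fn <- feature_names()
  rows <- list()
  for (i in seq_len(n_animals)) {
    centre <- rnorm(length(fn), mean = 3 * i, sd = 2)
    n <- n_spont + n_induced
    m <- matrix(rnorm(n * length(fn), sd = spread), n) +
      matrix(centre, n, length(fn), byrow = TRUE)
    colnames(m) <- fn
    rows[[i]] <- cbind(
      data.frame(animal_id = sprintf("a%02d", i),
                 seizure_id = sprintf("a%02d_s%02d", i, seq_len(n)),
                 label = rep(c("spontaneous", "kcl_reuniens"),
                             c(n_spont, n_induced)),
                 stringsAsFactors = FALSE),
      as.data.frame(m))
  }
  do.call(rbind, rows)
}
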