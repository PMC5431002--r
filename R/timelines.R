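#' Seizure event timelines
#'
#' An `experiment_timeline` holds the seizure onset times of one injection
#' experiment, expressed in seconds relative to the start of the first
#' injection (t = 0).  Negative onsets fall in the baseline period.  The
#' observation window runs from 3 h before to 5 h after the first injection;
#' the baseline window is [-10800, 0) s and the experimental window
#' [0, 10800) s.
#'
#' @param experiment_id,animal_id character scalars identifying the
#'   experiment and the animal.
#' @param injection_type one of `"KCl"`, `"PBS"`, `"none"`.
#' @param onsets_s numeric vector of seizure onset times in seconds relative
#'   to injection start; may be empty (an event-free experiment).
#' @param durations_s optional numeric vector of seizure durations in
#'   seconds (`NA` allowed); recycled checks require the same length as
#'   `onsets_s`.  Durations are carried but ignored by the risk statistics,
#'   which treat seizures as point events at onset.
#' @return An object of class `experiment_timeline`.
#' @export
experiment_timeline <- function(experiment_id, animal_id,
                                injection_type = c("KCl", "PBS", "none"),
                                onsets_s = numeric(),
                                durations_s = NULL) {
  injection_type <- match.arg(injection_type)
  onsets_s <- as.numeric(onsets_s)
  if (anyNA(onsets_s) || any(!is.finite(onsets_s)))
    stop("onset times must be finite", call. = FALSE)
  if (!is.null(durations_s)) {
    if (length(durations_s) != length(onsets_s))
      stop("durations_s must match onsets_s in length", call. = FALSE)
    if (any(durations_s[!is.na(durations_s)] <= 0))
      stop("durations must be > 0 when present", call. = FALSE)
  }
  ord <- order(onsets_s)
  onsets_s <- onsets_s[ord]
  if (!is.null(durations_s)) durations_s <- durations_s[ord]
  lo <- timeline_window()[1]; hi <- timeline_window()[2]
  if (length(onsets_s) && (min(onsets_s) < lo || max(onsets_s) > hi))
    stop(sprintf("onsets must lie within [%g, %g] s", lo, hi), call. = FALSE)
  structure(
    list(experiment_id = as.character(experiment_id),
         animal_id = as.character(animal_id),
         injection_type = injection_type,
         onsets_s = onsets_s,
         durations_s = durations_s),
    class = "experiment_timeline")
}

#' @export
print.experiment_timeline <- function(x, ...) {
  cat(sprintf("<experiment_timeline> %s (animal %s, %s): %d seizure(s)\n",
              x$experiment_id, x$animal_id, x$injection_type,
              length(x$onsets_s)))
  if (length(x$onsets_s))
    cat("  onsets (s): ", paste(signif(x$onsets_s, 6), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# Observation window in seconds: [-3 h, +5 h] around the first injection.
timeline_window <- function() c(-10800, 18000)

#' Read seizure event timelines from a CSV file
#'
#' The file must have header columns `animal_id`, `experiment_id`,
#' `injection_type` (`KCl`/`PBS`/`none`) and `onset_s`, with an optional
#' `duration_s`.  Each row is one seizure; a row with an empty `onset_s`
#' declares an event-free experiment, so experiments with zero seizures are
#' preserved.
#'
#' @param path path to the events CSV.
#' @return A list of [experiment_timeline()] objects, one per distinct
#'   `experiment_id`, events sorted by onset.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = TRUE)
  required <- c("animal_id", "experiment_id", "injection_type", "onset_s")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("events CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(list())

  onset_raw <- df$onset_s
  blank <- is.na(onset_raw) | onset_raw == ""
  onset <- suppressWarnings(as.numeric(onset_raw))
  bad <- which(!blank & is.na(onset))
  if (length(bad))
    stop(sprintf("non-numeric onset_s at line %d: '%s'",
                 bad[1] + 1L, onset_raw[bad[1]]), call. = FALSE)
  dur <- if ("duration_s" %in% names(df))
    suppressWarnings(as.numeric(df$duration_s)) else rep(NA_real_, nrow(df))

  ids <- unique(df$experiment_id)
  lapply(ids, function(id) {
    rows <- df$experiment_id == id
    keep <- rows & !blank
    experiment_timeline(
      experiment_id = id,
      animal_id = df$animal_id[rows][1],
      injection_type = df$injection_type[rows][1],
      onsets_s = onset[keep],
      durations_s = if (any(keep) && any(!is.na(dur[keep]))) dur[keep] else NULL)
  })
}

#' Write seizure event timelines to a CSV file
#'
#' Inverse of [read_events()]: event-free experiments are written as a single
#' row with an empty `onset_s` so they survive a round trip.
#'
#' @param timelines list of [experiment_timeline()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(timelines, path) {
  rows <- lapply(timelines, function(tl) {
    n <- length(tl$onsets_s)
    if (n == 0) {
      data.frame(animal_id = tl$animal_id, experiment_id = tl$experiment_id,
                 injection_type = tl$injection_type, onset_s = "",
                 duration_s = "", stringsAsFactors = FALSE)
    } else {
      dur <- if (is.null(tl$durations_s)) rep("", n) else
        ifelse(is.na(tl$durations_s), "", format(tl$durations_s, digits = 10))
      data.frame(animal_id = tl$animal_id, experiment_id = tl$experiment_id,
                 injection_type = tl$injection_type,
                 onset_s = format(tl$onsets_s, digits = 12, trim = TRUE,
                                  scientific = FALSE),
                 duration_s = dur, stringsAsFactors = FALSE)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count seizures in a half-open time window
#'
#' Windows are half-open, `[t0, t1)`, so counts over disjoint adjacent
#' windows are additive.
#'
#' @param timeline an [experiment_timeline()].
#' @param window numeric length-2, `c(t0, t1)` in seconds, `t0 < t1`.
#' @return integer count of events with `t0 <= onset < t1`.
#' @export
count_events <- function(timeline, window) {
  stopifnot(length(window) == 2)
  if (window[1] >= window[2] && !(window[1] == window[2]))
    stop("window must satisfy t0 < t1", call. = FALSE)
  sum(timeline$onsets_s >= window[1] & timeline$onsets_s < window[2])
}

#' Tally injection outcomes across experiments
#'
#' Summarises a cohort of injection experiments the way an induction-success
#' table is usually read: how many experiments of a given injection type had
#' at least one seizure in the experimental window, how many animals ever
#' did, and how many did on their first attempt.  The "first attempt" for an
#' animal is its earliest experiment of that type; ordering uses the `day`
#' argument if given, otherwise a day number parsed from a `d<number>` token
#' in the experiment id, otherwise list order.
#'
#' @param timelines list of [experiment_timeline()] objects.
#' @param injection_type injection type to tally (default `"KCl"`).
#' @param window experimental window in seconds, default `c(0, 10800)`.
#' @param day optional numeric vector of experiment days, parallel to
#'   `timelines`.
#' @return list with `n_experiments`, `n_experiments_with_seizure`,
#'   `n_animals`, `n_animals_with_seizure`, `n_animals_first_attempt`.
#' @export
injection_tally <- function(timelines, injection_type = "KCl",
                            window = c(0, 10800), day = NULL) {
  if (is.null(day)) {
    day <- vapply(timelines, function(tl) {
      m <- regmatches(tl$experiment_id,
                      regexpr("d[0-9]+", tl$experiment_id))
      if (length(m)) as.numeric(sub("d", "", m)) else NA_real_
    }, numeric(1))
    if (anyNA(day)) day <- seq_along(timelines)
  }
  sel <- vapply(timelines, function(tl) tl$injection_type == injection_type,
                logical(1))
  tls <- timelines[sel]; day <- day[sel]
  hit <- vapply(tls, function(tl) count_events(tl, window) > 0, logical(1))
  animal <- vapply(tls, function(tl) tl$animal_id, character(1))
  first_hit <- vapply(unique(animal), function(a) {
    i <- which(animal == a)
    hit[i[which.min(day[i])]]
  }, logical(1))
  any_hit <- vapply(unique(animal), function(a) any(hit[animal == a]),
                    logical(1))
  list(n_experiments = length(tls),
       n_experiments_with_seizure = sum(hit),
       n_animals = length(unique(animal)),
       n_animals_with_seizure = sum(any_hit),
       n_animals_first_attempt = sum(first_hit))
}

#' Path to the bundled example injection cohort
#'
#' An events CSV describing 24 KCl and 5 PBS injection experiments in 16
#' epileptic rats.  The per-window seizure counts per experiment are those
#' observed in a real KCl-reuniens ictogenesis study; since only counts per
#' 3-h window are published, the onset times within each window are
#' synthetic (evenly spaced placements consistent with the counts).  Rate
#' and tally statistics depend only on the counts and are therefore exact;
#' hazard-curve shapes computed from this file reflect the synthetic
#' placements, not recorded onset times.
#'
#' @return Path to the installed CSV.
#' @export
example_events_path <- function()
  system.file("extdata", "kcl_reuniens_cohort.csv", package = "ictal",
              mustWork = TRUE)
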