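#' Annotated seizure EEG segment
#'
#' One single-channel EEG trace containing an annotated seizure.  The trace
#' may (and for spectrograms should) include context before the onset and
#' after the offset; `onset_index`/`offset_index` delimit the seizure within
#' the trace, in samples (1-based, half-open: the seizure spans
#' `samples[onset_index .. offset_index - 1]`).
#'
#' @param animal_id,seizure_id character identifiers.
#' @param label seizure provenance: `"spontaneous"`, `"kcl_reuniens"`,
#'   `"kainic_acid"` or `"electrical"`.
#' @param fs_hz sampling rate in Hz (the study standard is 256).
#' @param samples numeric vector, microvolts.
#' @param onset_index,offset_index sample indices delimiting the seizure;
#'   `1 <= onset_index < offset_index <= length(samples) + 1`.
#' @return An object of class `seizure_segment`.
#' @export
seizure_segment <- function(animal_id, seizure_id,
                            label = c("spontaneous", "kcl_reuniens",
                                      "kainic_acid", "electrical"),
                            fs_hz, samples, onset_index, offset_index) {
  label <- match.arg(label)
  stopifnot(fs_hz > 0)
  onset_index <- as.integer(onset_index)
  offset_index <- as.integer(offset_index)
  if (onset_index < 1L || onset_index >= offset_index ||
      offset_index > length(samples) + 1L)
    stop("require 1 <= onset_index < offset_index <= length(samples) + 1",
         call. = FALSE)
  structure(
    list(animal_id = as.character(animal_id),
         seizure_id = as.character(seizure_id),
         label = label, fs_hz = fs_hz, samples = as.numeric(samples),
         onset_index = onset_index, offset_index = offset_index),
    class = "seizure_segment")
}

#' @export
print.seizure_segment <- function(x, ...) {
  cat(sprintf(
    "<seizure_segment> %s/%s [%s]: %.1f s seizure in %.1f s trace @ %g Hz\n",
    x$animal_id, x$seizure_id, x$label, seizure_length_s(x),
    length(x$samples) / x$fs_hz, x$fs_hz))
  invisible(x)
}

#' @rdname seizure_segment
#' @param segment a `seizure_segment`.
#' @export
seizure_length_s <- function(segment)
  (segment$offset_index - segment$onset_index) / segment$fs_hz

# Seizure-only samples (context stripped).
seizure_samples <- function(segment)
  segment$samples[segment$onset_index:(segment$offset_index - 1L)]

#' Read an annotated EEG seizure segment from EDF or CSV
#'
#' CSV input is two columns `time_s, uV` preceded by a metadata comment line
#' `# fs_hz=<rate>`; EDF input must contain a single signal.  The annotation
#' gives seizure onset and offset in seconds from the start of the record;
#' sample indices are computed by rounding `annotation * fs_hz` to the
#' nearest integer.
#'
#' @param path path to the recording.
#' @param annotation numeric length-2, `c(onset_s, offset_s)` within the
#'   record duration.
#' @param animal_id,seizure_id,label metadata stamped onto the segment.
#' @return A [seizure_segment()].
#' @export
read_segment <- function(path, annotation, animal_id = "unknown",
                         seizure_id = basename(path),
                         label = "spontaneous") {
  stopifnot(length(annotation) == 2, annotation[1] < annotation[2])
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
    fs <- rec$fs_hz; x <- rec$samples
  } else {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexpr("fs_hz\\s*=\\s*[0-9.]+", first))
    if (!length(m))
      stop("CSV EEG file must start with a '# fs_hz=<rate>' metadata line",
           call. = FALSE)
    fs <- as.numeric(sub(".*=\\s*", "", m))
    df <- utils::read.csv(path, comment.char = "#")
    x <- df[[2]]
  }
  dur <- length(x) / fs
  if (annotation[1] < 0 || annotation[2] > dur)
    stop(sprintf("annotation [%g, %g] s outside record duration %g s",
                 annotation[1], annotation[2], dur), call. = FALSE)
  seizure_segment(animal_id, seizure_id, label, fs, x,
                  onset_index = round(annotation[1] * fs) + 1L,
                  offset_index = round(annotation[2] * fs) + 1L)
}

#' Write an EEG trace as a two-column CSV with a sampling-rate header
#'
#' @param samples numeric vector, microvolts.
#' @param fs_hz sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segment_csv <- function(samples, fs_hz, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%g", fs_hz), con)
  utils::write.csv(
    data.frame(time_s = (seq_along(samples) - 1) / fs_hz,
               uV = samples),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
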