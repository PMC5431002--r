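#' Run configuration for the analysis commands
#'
#' Assembles a fully-defaulted configuration for the command-level entry
#' points.  Values supplied in `...` (or read from YAML by
#' [read_run_config()]) override the defaults; unknown keys are rejected.
#' The complete configuration is serialized into every command's JSON
#' provenance block.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    events_csv = NULL,          # input events CSV
    manifest_json = NULL,       # input EEG manifest (from cmd_simulate)
    features_csv = NULL,        # alternative input: precomputed features
    output_dir = ".",
    # feature parameters
    psd_nperseg = 256, psd_overlap = 0.5, psd_pad = 2,
    spike_threshold_k = 4, spike_min_separation_s = 0.08,
    # pipeline parameters
    nu = 0.05, kernel_scale = 50, n_components = 2,
    normalize_on = "all",
    # hazard parameters
    grid_step_h = 1 / 60, risk_window_s = 300, range_h = c(-3, 5),
    # simulation parameters
    n_experiments = 24, baseline_rate = 0.28,
    experimental_multiplier = 48 / 20, ramp = "step", refractory_s = 300,
    n_animals = 4, n_spontaneous = 10, n_induced = 2, n_kainic = 1,
    n_electrical = 1, separation = 1.5, eeg_format = "csv",
    seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(override)] <- override
  structure(defaults, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_psd <- function(config)
  list(nperseg = config$psd_nperseg, overlap = config$psd_overlap,
       pad = config$psd_pad)

provenance <- function(config)
  list(package = "ictal",
       version = as.character(utils::packageVersion("ictal")),
       seed = config$seed, config = unclass(config))

write_provenance_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ictal %s seed=%s",
                     utils::packageVersion("ictal"), config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

out_path <- function(config, name) {
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  file.path(config$output_dir, name)
}

#' Mean seizure-rate table per injection type
#'
#' Computes, per injection type present in the events CSV, the pooled
#' baseline and experimental seizure rates with Poisson uncertainties and
#' the one-degree-of-freedom chi-square p-value for their difference, and
#' writes them as `rates.csv` in the output directory.
#'
#' @param config a [run_config()] with `events_csv` set.
#' @return The rates data.frame, invisibly.
#' @export
cmd_rates <- function(config) {
  timelines <- read_events(config$events_csv)
  rows <- list()
  for (type in c("KCl", "PBS", "none")) {
    tls <- Filter(function(tl) tl$injection_type == type, timelines)
    if (!length(tls)) {
      if (type != "none")
        warning("no experiments of type ", type, "; row omitted",
                call. = FALSE)
      next
    }
    base <- mean_rate(tls, c(-10800, 0))
    expm <- mean_rate(tls, c(0, 10800))
    pt <- poisson_rate_test(base$n_events, expm$n_events,
                            base$exposure_h, expm$exposure_h)
    rows[[type]] <- data.frame(
      injection = type, n_experiments = length(tls),
      baseline_rate = base$rate, baseline_uncertainty = base$uncertainty,
      experimental_rate = expm$rate,
      experimental_uncertainty = expm$uncertainty,
      chi2 = pt$chi2, p = pt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_provenance_csv(out, out_path(config, "rates.csv"), config)
  invisible(out)
}

#' Time-dependent hazard curves per injection type
#'
#' Computes the kernel-smoothed Nelson-Aalen hazard per injection type,
#' together with the pooled baseline/experimental rates and the time of
#' most significant divergence from baseline.  Writes
#' `hazard_<type>.csv` (columns `t_h`, `hazard_per_h`, `variance`) and a
#' JSON sidecar `hazard_<type>.json` per type.
#'
#' @param config a [run_config()] with `events_csv` set.
#' @return Named list of `list(curve, baseline, experimental, divergence)`
#'   per injection type, invisibly.
#' @export
cmd_hazard <- function(config) {
  timelines <- read_events(config$events_csv)
  out <- list()
  for (type in unique(vapply(timelines, `[[`, character(1),
                             "injection_type"))) {
    tls <- Filter(function(tl) tl$injection_type == type, timelines)
    n_ev <- sum(vapply(tls, function(tl) length(tl$onsets_s), integer(1)))
    if (n_ev == 0)
      stop("no seizures in any ", type,
           " experiment; hazard undefined for this type", call. = FALSE)
    curve <- nelson_aalen_hazard(tls, config$grid_step_h, config$range_h,
                                 config$risk_window_s)
    base <- mean_rate(tls, c(-10800, 0))
    expm <- mean_rate(tls, c(0, 10800))
    div <- max_divergence_time(curve, base)
    write_provenance_csv(
      data.frame(t_h = curve$grid_t_h, hazard_per_h = curve$hazard,
                 variance = curve$variance),
      out_path(config, sprintf("hazard_%s.csv", type)), config)
    jsonlite::write_json(
      list(bandwidth_h = curve$bandwidth_h, n_events = curve$n_events_used,
           baseline_rate = base$rate, experimental_rate = expm$rate,
           argmax_t_h = div$t_h, chi2 = div$chi2, p = div$p,
           provenance = provenance(config)),
      out_path(config, sprintf("hazard_%s.json", type)),
      auto_unbox = TRUE, digits = NA)
    out[[type]] <- list(curve = curve, baseline = base,
                        experimental = expm, divergence = div)
  }
  invisible(out)
}

# Load a feature table from whichever input the config provides.
load_features <- function(config) {
  if (!is.null(config$features_csv))
    return(utils::read.csv(config$features_csv, comment.char = "#",
                           check.names = FALSE))
  if (!is.null(config$manifest_json)) {
    man <- jsonlite::read_json(config$manifest_json, simplifyVector = TRUE)
    root <- dirname(config$manifest_json)
    segs <- lapply(seq_len(nrow(man$segments)), function(i) {
      r <- man$segments[i, ]
      read_segment(file.path(root, r$path),
                   c(r$onset_s, r$offset_s), animal_id = r$animal_id,
                   seizure_id = r$seizure_id, label = r$label)
    })
    return(feature_table(segs, psd_params = config_psd(config),
                         threshold_k = config$spike_threshold_k,
                         min_separation_s = config$spike_min_separation_s))
  }
  stop("config must set features_csv or manifest_json", call. = FALSE)
}

#' Seizure-similarity classification report
#'
#' Runs the full per-animal pipeline (normalization, PCA, one-class SVM on
#' spontaneous seizures) and tabulates own- and other-animal similarity
#' proportions per seizure group.  Writes `similarity_report.csv`,
#' `per_seizure.csv`, and `pc_coordinates.csv` (per-animal PC scores plus
#' decision values, for boundary plotting).  Animals with fewer than two
#' spontaneous seizures are not modelled (warning) but are still classified
#' against the other animals' models.
#'
#' @param config a [run_config()] with `features_csv` or `manifest_json`.
#' @return The [similarity_report()], invisibly.
#' @export
cmd_classify <- function(config) {
  features <- load_features(config)
  models <- list()
  for (a in unique(features$animal_id)) {
    fa <- features[features$animal_id == a, ]
    if (sum(fa$label == "spontaneous") < 2) {
      warning("animal ", a, " has < 2 spontaneous seizures; ",
              "no model fitted for it", call. = FALSE)
      next
    }
    models[[a]] <- fit_animal_model(
      fa, normalize_on = config$normalize_on, nu = config$nu,
      kernel_scale = config$kernel_scale,
      n_components = config$n_components)
  }
  rep <- similarity_report(models, features)
  write_provenance_csv(rep$table,
                       out_path(config, "similarity_report.csv"), config)
  write_provenance_csv(rep$per_seizure,
                       out_path(config, "per_seizure.csv"), config)
  pcs <- do.call(rbind, lapply(names(models), function(a) {
    sc <- project_features(models[[a]], features[, feature_names()])
    data.frame(model_animal = a, animal_id = features$animal_id,
               seizure_id = features$seizure_id, label = features$label,
               pc1 = sc[, 1], pc2 = if (ncol(sc) > 1) sc[, 2] else 0,
               decision = ocsvm_decision(models[[a]]$ocsvm, sc),
               stringsAsFactors = FALSE)
  }))
  write_provenance_csv(pcs, out_path(config, "pc_coordinates.csv"), config)
  invisible(rep)
}

#' Simulate a complete fixture bundle
#'
#' Writes an events CSV (simulated injection timelines), per-seizure EEG
#' files (CSV or EDF according to `eeg_format`), and a `manifest.json`
#' recording paths, annotations, labels and the full configuration, all
#' under `output_dir`.  The bundle round-trips through [read_events()],
#' [read_segment()], [cmd_rates()], [cmd_hazard()] and [cmd_classify()].
#'
#' @param config a [run_config()].
#' @return Path to the manifest, invisibly.
#' @export
cmd_simulate <- function(config) {
  timelines <- simulate_timeline(cohort_spec(
    n_experiments = config$n_experiments,
    baseline_rate = config$baseline_rate,
    experimental_multiplier = config$experimental_multiplier,
    ramp = config$ramp, refractory_s = config$refractory_s,
    seed = config$seed))
  events_path <- out_path(config, "events.csv")
  write_events(timelines, events_path)

  cohort <- make_cohort(n_animals = config$n_animals,
                        n_spontaneous = config$n_spontaneous,
                        n_induced = config$n_induced,
                        n_kainic = config$n_kainic,
                        n_electrical = config$n_electrical,
                        separation = config$separation, seed = config$seed)
  rows <- lapply(cohort$segments, function(s) {
    fname <- sprintf("%s.%s", s$seizure_id,
                     if (config$eeg_format == "edf") "edf" else "csv")
    path <- out_path(config, fname)
    if (config$eeg_format == "edf") write_edf(s$samples, s$fs_hz, path)
    else write_segment_csv(s$samples, s$fs_hz, path)
    data.frame(path = fname, animal_id = s$animal_id,
               seizure_id = s$seizure_id, label = s$label,
               onset_s = (s$onset_index - 1) / s$fs_hz,
               offset_s = (s$offset_index - 1) / s$fs_hz,
               stringsAsFactors = FALSE)
  })
  manifest_path <- out_path(config, "manifest.json")
  jsonlite::write_json(
    list(events_csv = basename(events_path),
         segments = do.call(rbind, rows),
         provenance = provenance(config)),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
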