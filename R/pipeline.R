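#' Configuration of an end-to-end synthetic run
#'
#' Collects every tunable parameter of the pipeline with its documented
#' default. The default cohort mirrors the study layout: 20 participants,
#' awakening counts 14x3 + 4x2 + 2x1 (52 awakenings), TMS available for 17
#' of the 20 participants, wake recordings with eyes open and closed,
#' sedation recordings of 60 s before each awakening (the protocol's
#' one-minute pre-awakening recording). Synthesis runs at desk scale: 250
#' Hz, 8 channels, 40-s wake recordings; TMS epochs span -250..+500 ms.
#'
#' @param seed global integer seed; all per-recording seeds derive from it.
#' @param n_channels EEG channels to synthesize.
#' @param fs sampling rate, Hz.
#' @param wake_duration wake spontaneous recording length, s.
#' @param sedation_duration per-awakening sedation recording length, s.
#' @param awakening_counts per-participant awakening counts.
#' @param n_tms_participants number of participants (taken from the front of
#'   the cohort) with TMS recordings.
#' @param tep_window TMS epoch window, ms.
#' @param n_trials trials per TMS recording.
#' @param wake_tep_spec,sedation_tep_spec [tep_spec()]s for wake and
#'   sedation evoked responses (defaults: 8 spatiotemporally distinct
#'   components in wake, a single slow damped component in sedation).
#' @param lzc_epoch_length LZc window length, s.
#' @param pcist_parameters a [pcist_params()].
#' @param rule a [classification_rule()].
#' @param alpha Holm family-wise error level.
#' @param df_method LMM denominator-df approximation.
#' @param output_dir optional directory; when given, all tables and the run
#'   log are written there.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_channels = 8L,
                       fs = 250,
                       wake_duration = 40,
                       sedation_duration = 60,
                       awakening_counts = c(rep(3L, 14), rep(2L, 4), rep(1L, 2)),
                       n_tms_participants = 17L,
                       tep_window = c(-250, 500),
                       n_trials = 60L,
                       wake_tep_spec = tep_spec(k = 8L, n_trials = n_trials),
                       sedation_tep_spec = tep_spec(
                         k = 1L, freqs = 5, damping = 150, latencies = 30,
                         amplitudes = 6, n_trials = n_trials),
                       lzc_epoch_length = 5,
                       pcist_parameters = pcist_params(),
                       rule = classification_rule(),
                       alpha = 0.05,
                       df_method = "Satterthwaite",
                       output_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_channels = as.integer(n_channels),
              fs = fs, wake_duration = wake_duration,
              sedation_duration = sedation_duration,
              awakening_counts = as.integer(awakening_counts),
              n_tms_participants = as.integer(n_tms_participants),
              tep_window = tep_window, n_trials = as.integer(n_trials),
              wake_tep_spec = wake_tep_spec,
              sedation_tep_spec = sedation_tep_spec,
              lzc_epoch_length = lzc_epoch_length,
              pcist_parameters = pcist_parameters, rule = rule,
              alpha = alpha, df_method = df_method, output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates awakening reports and classifies them, synthesizes spontaneous
#' EEG (wake eyes-open/eyes-closed per participant; one sedation recording
#' per awakening) and TMS-evoked trial sets (wake and per-awakening
#' sedation, for the TMS subset of participants), computes LZc and PCIst
#' per recording, assembles the measure table, and runs the statistical
#' battery. Deterministic given `config$seed`. When `config$output_dir` is
#' set, writes `measures.csv`, `stat_tests.csv`, `outliers.csv`,
#' `report_tabulation.csv`, `reports.csv`, and `run_log.json` (every
#' resolved parameter).
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with `measures`
#'   (`measure_table`), `stats` (`stat_report`), `reports` (classified
#'   report tibble), `tabulation` (`report_tabulation`), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config", call. = FALSE)
  cfg <- config
  n_part <- length(cfg$awakening_counts)
  pid <- sprintf("P%02d", seq_len(n_part))
  tms_ids <- pid[seq_len(min(cfg$n_tms_participants, n_part))]

  marg <- report_marginals()
  # the packaged marginals describe the 52-awakening cohort; for other
  # cohort sizes classes are drawn per-awakening from the same proportions
  n_awake <- sum(cfg$awakening_counts)
  reports <- if (n_awake == marg$n_awakenings) {
    gen_reports(marg, cfg$awakening_counts, seed = derive_seed(cfg$seed, 1),
                rule = cfg$rule)
  } else {
    with_seed(derive_seed(cfg$seed, 1), {
      q1 <- sample(rep(names(marg$q1_counts), marg$q1_counts), n_awake, replace = TRUE)
      q2 <- sample(rep(names(marg$q2_counts), marg$q2_counts), n_awake, replace = TRUE)
      tibble::tibble(
        participant_id = rep(pid, cfg$awakening_counts),
        awakening_idx = unlist(lapply(cfg$awakening_counts, seq_len), use.names = FALSE),
        q1 = factor(q1, levels = q1_levels()),
        q2 = factor(q2, levels = q2_levels()))
    })
  }
  reports <- classify_reports(reports, rule = cfg$rule)

  profiles <- list(wake_eo = state_profile("wake_eo"),
                   wake_ec = state_profile("wake_ec"),
                   sedation = state_profile("sedation"))

  rows <- list()
  add_row <- function(participant, condition, measure, value, cls = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      participant_id = participant, condition = condition, measure = measure,
      value = value, experience_class = cls)
  }

  for (i in seq_len(n_part)) {
    p <- pid[i]
    for (cond in c("wake_eo", "wake_ec")) {
      code <- if (cond == "wake_eo") 2L else 3L
      e <- gen_spontaneous(profiles[[cond]], cfg$n_channels, cfg$wake_duration,
                           cfg$fs, seed = derive_seed(cfg$seed, i, code))
      r <- lzc_recording(e, epoch_length = cfg$lzc_epoch_length,
                         seed = derive_seed(cfg$seed, i, code, 99L))
      add_row(p, cond, "lzc", r$recording_value)
    }
    if (p %in% tms_ids) {
      tw <- gen_tep(cfg$wake_tep_spec, cfg$n_channels, cfg$fs, cfg$tep_window,
                    seed = derive_seed(cfg$seed, i, 4L))
      add_row(p, "wake_ec", "pcist", pcist(tw, cfg$pcist_parameters)$value)
    }
    prep <- reports[reports$participant_id == p, , drop = FALSE]
    for (k in seq_len(nrow(prep))) {
      cls <- as.character(prep$experience_class[k])
      cond <- sprintf("sedation_%d", prep$awakening_idx[k])
      es <- gen_spontaneous(profiles$sedation, cfg$n_channels,
                            cfg$sedation_duration, cfg$fs,
                            seed = derive_seed(cfg$seed, i, 10L + k))
      r <- lzc_recording(es, epoch_length = cfg$lzc_epoch_length,
                         seed = derive_seed(cfg$seed, i, 10L + k, 99L))
      add_row(p, cond, "lzc", r$recording_value, cls)
      if (p %in% tms_ids) {
        ts <- gen_tep(cfg$sedation_tep_spec, cfg$n_channels, cfg$fs,
                      cfg$tep_window, seed = derive_seed(cfg$seed, i, 20L + k))
        add_row(p, cond, "pcist", pcist(ts, cfg$pcist_parameters)$value, cls)
      }
    }
  }
  measures <- as_measure_table(dplyr::bind_rows(rows))
  stats_rep <- run_paper_tests(measures, alpha = cfg$alpha,
                               df_method = cfg$df_method)
  tabulation <- if (nrow(reports) > 0L) {
    tabulate_reports(reports, rule = cfg$rule)
  }

  result <- structure(
    list(measures = measures, stats = stats_rep, reports = reports,
         tabulation = tabulation, config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(cfg$output_dir)) write_pipeline_result(result, cfg$output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d measure rows, %d awakenings\n",
              nrow(x$measures), nrow(x$reports)))
  print(x$stats)
  invisible(x)
}

#' Write all pipeline tables and the run log
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(dir, name), row.names = FALSE)
  }
  wcsv(result$measures, "measures.csv")
  wcsv(result$stats$tests, "stat_tests.csv")
  wcsv(result$stats$outliers, "outliers.csv")
  wcsv(result$reports, "reports.csv")
  tab <- result$tabulation
  wcsv(dplyr::bind_rows(
    dplyr::mutate(tab$q1, variable = "q1"),
    dplyr::mutate(tab$q2, variable = "q2"),
    dplyr::mutate(tab$class, variable = "class")
  )[, c("variable", "category", "n")], "report_tabulation.csv")
  cfg <- result$config
  log <- list(
    seed = cfg$seed, n_channels = cfg$n_channels, fs = cfg$fs,
    wake_duration = cfg$wake_duration, sedation_duration = cfg$sedation_duration,
    awakening_counts = cfg$awakening_counts,
    n_tms_participants = cfg$n_tms_participants,
    tep_window = cfg$tep_window, n_trials = cfg$n_trials,
    wake_tep_spec = unclass(cfg$wake_tep_spec),
    sedation_tep_spec = unclass(cfg$sedation_tep_spec),
    lzc_epoch_length = cfg$lzc_epoch_length,
    pcist_parameters = unclass(cfg$pcist_parameters),
    classification_rule = apply(unclass(cfg$rule), 1L, identity, simplify = FALSE),
    alpha = cfg$alpha, df_method = cfg$df_method
  )
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Rebuild a run configuration from a written run log
#'
#' Re-running [run_pipeline()] on the returned configuration reproduces the
#' original outputs bitwise.
#'
#' @param path path to a `run_log.json` written by [write_pipeline_result()].
#' @param output_dir optional output directory for the re-run.
#' @return a `run_config`.
#' @export
read_run_log <- function(path, output_dir = NULL) {
  log <- jsonlite::fromJSON(path)
  wts <- do.call(tep_spec, log$wake_tep_spec[
    c("k", "freqs", "damping", "latencies", "amplitudes", "trial_noise_rms", "n_trials")])
  sts <- do.call(tep_spec, log$sedation_tep_spec[
    c("k", "freqs", "damping", "latencies", "amplitudes", "trial_noise_rms", "n_trials")])
  rule_tab <- do.call(rbind, log$classification_rule)
  dimnames(rule_tab) <- list(q1_levels(), q2_levels())
  run_config(
    seed = log$seed, n_channels = log$n_channels, fs = log$fs,
    wake_duration = log$wake_duration, sedation_duration = log$sedation_duration,
    awakening_counts = log$awakening_counts,
    n_tms_participants = log$n_tms_participants,
    tep_window = log$tep_window, n_trials = log$n_trials,
    wake_tep_spec = wts, sedation_tep_spec = sts,
    lzc_epoch_length = log$lzc_epoch_length,
    pcist_parameters = do.call(pcist_params, log$pcist_parameters[
      c("baseline_window", "response_window", "variance_retained",
        "max_components", "k_weight", "epsilon_grid_size", "min_component_snr")]),
    rule = classification_rule(rule_tab),
    alpha = log$alpha, df_method = log$df_method,
    output_dir = output_dir
  )
}

#' Read epochs or trial sets from a supported file format
#'
#' Supported formats: the package's plain-text epoch container
#' ([write_epochs()]), BrainVision triplets (`.vhdr`/`.vmrk`/`.eeg`), and
#' EDF/EDF+ recordings. BrainVision and EDF recordings are continuous; use
#' [epoch_continuous()] or [epoch_around_events()] on the returned
#' recording to obtain an `epoch_set`/`tep_set`.
#'
#' @param path input file path.
#' @param format `"auto"` (by extension), `"container"`, `"brainvision"`,
#'   or `"edf"`.
#' @param downsample_to optional target sampling rate in Hz for continuous
#'   formats (must divide the file's rate or be related by a rational
#'   factor).
#' @return an `epoch_set`/`tep_set` (container) or a continuous recording
#'   list with `data`, `fs`, `channels`, `markers` (BrainVision/EDF).
#' @export
read_epochs <- function(path, format = c("auto", "container", "brainvision", "edf"),
                        downsample_to = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     "vhdr" = "brainvision",
                     "edf" = "edf",
                     "txt" = , "epochs" = , "container" = "container",
                     stop(sprintf(
                       "unsupported format '.%s'; supported: container (.epochs/.txt), brainvision (.vhdr), edf (.edf)",
                       ext), call. = FALSE))
  }
  out <- switch(format,
                container = read_epoch_container(path),
                brainvision = read_brainvision(path),
                edf = read_edf(path))
  if (!is.null(downsample_to) && !inherits(out, c("epoch_set", "tep_set"))) {
    out <- downsample_recording(out, downsample_to)
  }
  out
}
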