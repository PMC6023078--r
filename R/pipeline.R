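# Orchestration of the two operational modes: Offline (training-library
# construction from WAV recordings) and Online (live classification to a
# phrase), plus the seeded synthetic experiment that evaluates both
# distance metrics across simulated subjects. Training and live audio pass
# through the identical processing chain: Wiener denoising at the native
# rate, anti-aliased sub-sampling to the intermediate rate, envelope
# extraction, and per-pattern normalisation.

#' Pipeline configuration
#'
#' Validated bundle of every tunable in the processing and evaluation
#' chain.
#'
#' @param sample_rate_hz Acquisition rate (default 22050 Hz).
#' @param duration_s Recording window (default 10 s).
#' @param lead_silence_s Leading silence used for noise estimation
#'   (default 1 s; must be shorter than the window).
#' @param intermediate_rate_hz First sub-sampling target (default
#'   1000 Hz).
#' @param envelope_rate_hz Final envelope rate (default 100 Hz).
#' @param cutoff_hz Envelope low-pass cutoff (default 2 Hz).
#' @param wiener A [wiener_params()].
#' @param denoise Apply Wiener denoising (default `TRUE`).
#' @param metric Classification metric, `"dtw"` or `"ed"`.
#' @param band_width Optional Sakoe-Chiba band for DTW (`NULL` =
#'   unconstrained).
#' @param rng_seed Seed for all simulation randomness.
#' @param n_subjects,n_classes,n_train,n_live Experiment sizes (defaults
#'   23, 4, 10, 5).
#' @param warp_range,shift_range Live-set temporal mismatch (defaults
#'   `c(0.85, 1.2)` and `c(-0.3, 0.3)` s).
#' @param snr_db Simulated background-noise level (default 20 dB).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_rate_hz = 22050, duration_s = 10,
                            lead_silence_s = 1, intermediate_rate_hz = 1000,
                            envelope_rate_hz = 100, cutoff_hz = 2,
                            wiener = wiener_params(), denoise = TRUE,
                            metric = c("dtw", "ed"), band_width = NULL,
                            rng_seed = 1L, n_subjects = 23, n_classes = 4,
                            n_train = 10, n_live = 5,
                            warp_range = c(0.85, 1.2),
                            shift_range = c(-0.3, 0.3), snr_db = 20) {
  metric <- match.arg(metric)
  if (!(envelope_rate_hz < intermediate_rate_hz &&
        intermediate_rate_hz < sample_rate_hz)) {
    stop_bpi("invalid_argument",
             "need envelope_rate_hz < intermediate_rate_hz < sample_rate_hz")
  }
  if (duration_s <= lead_silence_s) {
    stop_bpi("invalid_argument", "duration_s must exceed lead_silence_s")
  }
  structure(
    list(sample_rate_hz = sample_rate_hz, duration_s = duration_s,
         lead_silence_s = lead_silence_s,
         intermediate_rate_hz = intermediate_rate_hz,
         envelope_rate_hz = envelope_rate_hz, cutoff_hz = cutoff_hz,
         wiener = wiener, denoise = isTRUE(denoise), metric = metric,
         band_width = band_width, rng_seed = as.integer(rng_seed),
         n_subjects = n_subjects, n_classes = n_classes,
         n_train = n_train, n_live = n_live, warp_range = warp_range,
         shift_range = shift_range, snr_db = snr_db),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys override [pipeline_config()] defaults; `wiener.*` keys
#' override [wiener_params()] defaults.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_bpi("io_error", "config not found: %s", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_bpi("invalid_argument", "the 'yaml' package is needed for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  wiener <- do.call(wiener_params, vals$wiener %||% list())
  vals$wiener <- NULL
  do.call(pipeline_config, c(vals, list(wiener = wiener)))
}

#' Process one recording into a normalised breath envelope
#'
#' The shared chain applied identically to training and live audio:
#' optional Wiener denoising, downsampling to the intermediate rate,
#' envelope extraction, and normalisation.
#'
#' @param rec A [raw_recording()].
#' @param config A [pipeline_config()].
#' @param class_label Optional label to attach to the envelope.
#' @return A normalised [breath_envelope()].
#' @export
process_recording <- function(rec, config = pipeline_config(),
                              class_label = NULL) {
  if (config$denoise) rec <- denoise_recording(rec, config$wiener)
  rec <- downsample(rec, config$intermediate_rate_hz)
  env <- extract_envelope(rec, config$cutoff_hz, config$envelope_rate_hz)
  env <- normalize_envelope(env)
  env$class_label <- if (is.null(class_label)) NULL else as.integer(class_label)
  env
}

# pad with zeros / truncate to the configured window, as for real
# acquisitions whose capture stopped early or late
conform_length <- function(rec, config) {
  n_target <- round(config$duration_s * rec$sample_rate_hz)
  n <- length(rec$samples)
  if (n == n_target) return(rec)
  message(sprintf("recording has %d samples; %s to %d", n,
                  if (n < n_target) "zero-padding" else "truncating",
                  n_target))
  s <- if (n < n_target) c(rec$samples, numeric(n_target - n))
       else rec$samples[seq_len(n_target)]
  raw_recording(s, rec$sample_rate_hz, rec$silence_lead_s)
}

#' Offline mode: build a template library from training WAV files
#'
#' Scans `wav_dir` (recursively) for files named
#' `class<k>_rep<j>.wav`, processes each through the shared chain, and
#' builds (optionally persisting) the template library.
#'
#' @param wav_dir Directory of training WAVs.
#' @param vocabulary Class-to-phrase table (default
#'   [default_vocabulary()]).
#' @param config A [pipeline_config()].
#' @param library_path Optional directory to [save_library()] into.
#' @return The [build_library()] result.
#' @export
run_offline_training <- function(wav_dir, vocabulary = default_vocabulary(),
                                 config = pipeline_config(),
                                 library_path = NULL) {
  files <- list.files(wav_dir, pattern = "^class[0-9]+_rep[0-9]+\\.wav$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0) {
    stop_bpi("io_error", "no class<k>_rep<j>.wav files found under %s", wav_dir)
  }
  classes <- as.integer(sub("^class([0-9]+)_.*$", "\\1", basename(files)))
  present <- sort(unique(classes))
  missing <- setdiff(vocabulary$class_id, present)
  if (length(missing) > 0) {
    stop_bpi("vocabulary_mismatch",
             "no training recordings for vocabulary class(es): %s",
             paste(missing, collapse = ", "))
  }
  envs <- vector("list", length(files))
  for (i in seq_along(files)) {
    rec <- read_wav(files[i], silence_lead_s = config$lead_silence_s)
    rec <- conform_length(rec, config)
    envs[[i]] <- process_recording(rec, config, class_label = classes[i])
  }
  lib <- build_library(envs, vocabulary)
  if (!is.null(library_path)) save_library(lib, library_path)
  lib
}

#' Online mode: classify a live recording and emit its phrase
#'
#' Processes the live WAV through the identical chain as training audio,
#' classifies it with the configured metric, prints the phrase, and
#' optionally hands the phrase to an external speech-synthesis command.
#'
#' @param live_wav Path to the live WAV (or a [raw_recording()]).
#' @param library A `template_library` or a path for [load_library()].
#' @param config A [pipeline_config()].
#' @param speech_hook Optional command; invoked as
#'   `speech_hook "<phrase>"`.
#' @param quiet Suppress printing of the phrase.
#' @return The [classify_1nn()] result, invisibly.
#' @export
run_online_classification <- function(live_wav, library,
                                      config = pipeline_config(),
                                      speech_hook = NULL, quiet = FALSE) {
  lib <- if (inherits(library, "template_library")) library
         else load_library(library)
  rec <- if (inherits(live_wav, "raw_recording")) live_wav
         else read_wav(live_wav, silence_lead_s = config$lead_silence_s)
  rec <- conform_length(rec, config)
  env <- process_recording(rec, config)
  res <- classify_1nn(env, lib, metric = config$metric,
                      band_width = config$band_width)
  if (!quiet) {
    cat(sprintf("class %d (%s): %s\n", res$predicted_class,
                res$metric_name, res$phrase))
  }
  if (!is.null(speech_hook)) {
    try(system2(speech_hook, shQuote(res$phrase)), silent = TRUE)
  }
  invisible(res)
}

#' Process a full synthetic subject dataset into envelopes
#'
#' Applies the shared processing chain to every training and live
#' recording of one [generate_subject_dataset()] result.
#'
#' @param ds A `subject_dataset`.
#' @param config A [pipeline_config()].
#' @return A list with `train_envelopes` (flat, labelled),
#'   `live_envelopes`, `live_labels`, `subject_id`, `outlier_flags`.
#' @export
process_dataset <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "subject_dataset"))
  train <- list(); live <- list(); live_labels <- integer(0)
  for (k in seq_len(ds$n_classes)) {
    for (j in seq_len(ds$n_train)) {
      train[[length(train) + 1L]] <-
        process_recording(ds$train_recordings[[k]][[j]], config,
                          class_label = k)
    }
    for (j in seq_len(ds$n_live)) {
      live[[length(live) + 1L]] <-
        process_recording(ds$live_recordings[[k]][[j]], config,
                          class_label = k)
      live_labels <- c(live_labels, k)
    }
  }
  list(train_envelopes = train, live_envelopes = live,
       live_labels = live_labels, subject_id = ds$subject_id,
       outlier_flags = ds$outlier_flags, n_classes = ds$n_classes)
}

# classify one processed subject's live envelopes against its own library
evaluate_processed_subject <- function(proc, metric, band_width = NULL,
                                       vocabulary = NULL) {
  n_classes <- proc$n_classes
  vocab <- vocabulary %||% (if (n_classes == 4) default_vocabulary() else
    data.frame(class_id = seq_len(n_classes),
               label = paste0("Breath_Pattern_", seq_len(n_classes)),
               phrase = paste("Phrase", seq_len(n_classes)),
               stringsAsFactors = FALSE))
  lib <- build_library(proc$train_envelopes, vocab)
  preds <- vapply(proc$live_envelopes, function(e) {
    classify_1nn(e, lib, metric = metric,
                 band_width = band_width)$predicted_class
  }, integer(1))
  subject_evaluation(proc$subject_id, proc$live_labels, preds,
                     class_ids = seq_len(n_classes),
                     outlier_flags = proc$outlier_flags,
                     metric_name = toupper(metric))
}

#' Run the full synthetic classification experiment
#'
#' Generates `n_subjects` synthetic subject datasets, trains a per-subject
#' template library, classifies every live recording with both metrics,
#' aggregates confusion matrices across subjects, and (optionally) writes
#' the evaluation CSVs. With the default protocol (23 subjects, 4 classes,
#' 10 training and 5 live repetitions per class) this produces 40 training
#' patterns per subject and 92 live sets / 460 live classifications per
#' metric.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for `confusion_<metric>.csv`,
#'   `subjects_<metric>.csv` and `comparison.csv`.
#' @param metrics Metrics to run (default both).
#' @param progress Print per-subject progress to stderr.
#' @return A list: `comparison` (see [compare_metrics()]), `counts`
#'   (protocol arithmetic), `datasets` sizes, and the config used.
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = NULL,
                           metrics = c("ed", "dtw"), progress = FALSE) {
  # subjects are generated, processed and classified one at a time so the
  # raw audio of only one subject is ever held in memory
  evals <- stats::setNames(vector("list", length(metrics)), metrics)
  for (s in seq_len(config$n_subjects)) {
    if (progress) message(sprintf("subject %d/%d", s, config$n_subjects))
    ds <- generate_subject_dataset(
      rng_seed = derive_seed(config$rng_seed, s * 1000003),
      n_classes = config$n_classes, n_train = config$n_train,
      n_live = config$n_live, warp_range = config$warp_range,
      shift_range = config$shift_range, snr_db = config$snr_db,
      sample_rate_hz = config$sample_rate_hz,
      duration_s = config$duration_s,
      silence_lead_s = config$lead_silence_s,
      env_rate_hz = config$envelope_rate_hz, subject_id = s)
    proc <- process_dataset(ds, config)
    rm(ds)
    for (m in metrics) {
      evals[[m]][[s]] <- evaluate_processed_subject(
        proc, metric = m, band_width = config$band_width)
    }
  }
  comparison <- comparison_from_evals(evals, metrics)
  counts <- list(
    n_subjects = config$n_subjects,
    n_train_per_subject = config$n_classes * config$n_train,
    n_live_sets = config$n_subjects * config$n_classes,
    n_live_signals = config$n_subjects * config$n_classes * config$n_live)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in metrics) {
      agg <- comparison$aggregates[[m]]
      cm <- agg$cm$counts
      cm_out <- cbind(as.data.frame(cm), total = rowSums(cm))
      cm_out <- rbind(cm_out, total = c(colSums(cm), sum(cm)))
      utils::write.csv(cm_out,
                       file.path(out_dir, sprintf("confusion_%s.csv", m)))
      subj <- do.call(rbind, lapply(agg$subject_scores, function(s)
        data.frame(subject_id = s$subject_id, metric = s$metric_name,
                   percent_correct = s$percent_correct,
                   n_evaluated = s$n_evaluated)))
      utils::write.csv(subj,
                       file.path(out_dir, sprintf("subjects_%s.csv", m)),
                       row.names = FALSE)
    }
    utils::write.csv(comparison$table, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  list(comparison = comparison, counts = counts, config = config)
}
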