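# Training template library: labelled breath-envelope templates arranged
# row-wise (M templates x envelope length, the "40 by [SF x 10]" layout for
# the default protocol) plus the class-to-phrase vocabulary.

#' Default class-to-phrase vocabulary
#'
#' The example four-class vocabulary mapping each trained pattern label to
#' a spoken phrase. In practice phrases are user-defined.
#'
#' @return A data frame with columns `class_id`, `label`, `phrase`.
#' @export
default_vocabulary <- function() {
  data.frame(
    class_id = 1:4,
    label = paste0("Breath_Pattern_", 1:4),
    phrase = c("Hello, good morning",
               "Thank you",
               "My name is ...",
               "May I have a train ticket please?"),
    stringsAsFactors = FALSE
  )
}

validate_vocabulary <- function(vocabulary) {
  need <- c("class_id", "label", "phrase")
  if (!is.data.frame(vocabulary) || !all(need %in% names(vocabulary))) {
    stop_bpi("vocabulary_mismatch",
             "vocabulary must be a data frame with columns class_id, label, phrase")
  }
  if (anyDuplicated(vocabulary$class_id) || anyDuplicated(vocabulary$label)) {
    stop_bpi("vocabulary_mismatch",
             "vocabulary class_ids and labels must be unique")
  }
  if (any(!nzchar(vocabulary$phrase))) {
    stop_bpi("vocabulary_mismatch", "vocabulary phrases must be non-empty")
  }
  vocabulary
}

#' Build a training template library
#'
#' Stacks labelled training envelopes row-wise into an M x L template
#' matrix and attaches the class-to-phrase vocabulary. Every template
#' class must appear in the vocabulary and all envelopes must share one
#' rate and length.
#'
#' @param train_envelopes Either a flat list of [breath_envelope()]s with
#'   `class_label` set, or a list of per-class lists (class taken from the
#'   envelopes).
#' @param vocabulary Data frame with columns `class_id`, `label`, `phrase`
#'   (default [default_vocabulary()]).
#' @return An object of class `template_library` with fields `templates`
#'   (M x L matrix), `class_labels`, `vocabulary`, `env_rate_hz`,
#'   `env_len`.
#' @export
build_library <- function(train_envelopes, vocabulary = default_vocabulary()) {
  vocabulary <- validate_vocabulary(vocabulary)
  if (length(train_envelopes) > 0 &&
      !inherits(train_envelopes[[1]], "breath_envelope")) {
    train_envelopes <- unlist(train_envelopes, recursive = FALSE)
  }
  if (length(train_envelopes) == 0) {
    stop_bpi("invalid_argument", "no training envelopes supplied")
  }
  if (!all(vapply(train_envelopes, inherits, TRUE, "breath_envelope"))) {
    stop_bpi("invalid_argument",
             "train_envelopes must contain breath_envelope objects")
  }
  labels <- vapply(train_envelopes, function(e) {
    if (is.null(e$class_label)) {
      stop_bpi("invalid_argument", "every training envelope needs a class_label")
    }
    e$class_label
  }, integer(1))
  lens <- vapply(train_envelopes, function(e) length(e$values), integer(1))
  rates <- vapply(train_envelopes, function(e) e$rate_hz, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
    stop_bpi("shape_error",
             "training envelopes must share one length and rate")
  }
  missing <- setdiff(unique(labels), vocabulary$class_id)
  if (length(missing) > 0) {
    stop_bpi("vocabulary_mismatch",
             "class(es) %s have no vocabulary entry",
             paste(missing, collapse = ", "))
  }
  templates <- do.call(rbind, lapply(train_envelopes, function(e) e$values))
  structure(
    list(templates = templates, class_labels = labels,
         vocabulary = vocabulary, env_rate_hz = rates[1],
         env_len = lens[1]),
    class = "template_library"
  )
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf(
    "<template_library> %d templates x %d samples @ %g Hz, %d classes\n",
    nrow(x$templates), x$env_len, x$env_rate_hz,
    length(unique(x$class_labels))))
  invisible(x)
}

#' Look up the phrase mapped to a class
#'
#' @param lib A [build_library()] result.
#' @param class_id Integer class identifier.
#' @return The stored phrase, verbatim.
#' @export
phrase_for_class <- function(lib, class_id) {
  stopifnot(inherits(lib, "template_library"))
  i <- match(class_id, lib$vocabulary$class_id)
  if (is.na(i)) {
    stop_bpi("unknown_class", "class %s has no vocabulary entry", class_id)
  }
  lib$vocabulary$phrase[i]
}

#' Persist a template library to disk
#'
#' Writes a `library.json` manifest (vocabulary, rates, template file
#' list) plus one CSV per template envelope (column `value`, with rate,
#' duration and class recorded as comment headers). Values are written at
#' full double precision so [load_library()] round-trips bit-exactly.
#'
#' @param lib A [build_library()] result.
#' @param path Directory to write into (created if needed).
#' @return The manifest path, invisibly.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "template_library"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(lib$templates))
  for (i in seq_len(nrow(lib$templates))) {
    files[i] <- sprintf("template_%03d_class%d.csv", i, lib$class_labels[i])
    con <- file(file.path(path, files[i]), "w")
    writeLines(c(sprintf("# rate_hz: %.17g", lib$env_rate_hz),
                 sprintf("# duration_s: %.17g", lib$env_len / lib$env_rate_hz),
                 sprintf("# class_label: %d", lib$class_labels[i]),
                 "value",
                 sprintf("%.17g", lib$templates[i, ])), con)
    close(con)
  }
  manifest <- list(
    env_rate_hz = lib$env_rate_hz,
    env_len = lib$env_len,
    vocabulary = lib$vocabulary,
    templates = data.frame(class_id = lib$class_labels, file = files,
                           stringsAsFactors = FALSE)
  )
  manifest_path <- file.path(path, "library.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(manifest_path)
}

#' Load a template library from disk
#'
#' @param path The directory written by [save_library()] (or its
#'   `library.json` manifest path).
#' @return A `template_library`, numerically identical to the saved one.
#' @export
load_library <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "library.json")
                   else path
  if (!file.exists(manifest_path)) {
    stop_bpi("format_error", "library manifest not found: %s", manifest_path)
  }
  man <- tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_bpi("format_error", "corrupt library manifest %s: %s",
                             manifest_path, conditionMessage(e))
                  })
  for (field in c("env_rate_hz", "env_len", "vocabulary", "templates")) {
    if (is.null(man[[field]])) {
      stop_bpi("format_error", "manifest field missing: %s", field)
    }
  }
  root <- dirname(manifest_path)
  envs <- vector("list", nrow(man$templates))
  for (i in seq_len(nrow(man$templates))) {
    f <- file.path(root, man$templates$file[i])
    if (!file.exists(f)) {
      stop_bpi("format_error", "template file missing: %s", f)
    }
    lines <- readLines(f)
    vals <- as.numeric(lines[!startsWith(lines, "#")][-1])
    envs[[i]] <- breath_envelope(vals, rate_hz = man$env_rate_hz,
                                 class_label = man$templates$class_id[i])
  }
  build_library(envs, vocabulary = man$vocabulary)
}
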