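# Evaluation machinery: per-subject confusion matrices, correct-
# classification percentages, omission of flagged outlier live sets,
# cross-subject aggregation, and the ED-vs-DTW comparison.

#' Confusion matrix from true and predicted labels
#'
#' @param true_labels,predicted_labels Equal-length label vectors drawn
#'   from `class_ids`.
#' @param class_ids Class identifiers ordering the rows/columns.
#' @param n_omitted_sets Number of omitted live sets to record (metadata).
#' @return An object of class `bp_confusion`: integer `counts` matrix
#'   (true x predicted), `class_ids`, `n_omitted_sets`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_ids = sort(unique(true_labels)),
                             n_omitted_sets = 0L) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_bpi("shape_error", "label sequences must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_ids)
  if (length(bad) > 0) {
    stop_bpi("unknown_label", "label(s) outside class_ids: %s",
             paste(bad, collapse = ", "))
  }
  k <- length(class_ids)
  counts <- matrix(0L, k, k, dimnames = list(true = class_ids,
                                             predicted = class_ids))
  for (idx in seq_along(true_labels)) {
    i <- match(true_labels[idx], class_ids)
    j <- match(predicted_labels[idx], class_ids)
    counts[i, j] <- counts[i, j] + 1L
  }
  structure(list(counts = counts, class_ids = class_ids,
                 n_omitted_sets = as.integer(n_omitted_sets)),
            class = "bp_confusion")
}

#' @export
print.bp_confusion <- function(x, ...) {
  cat("<bp_confusion> true x predicted counts",
      if (x$n_omitted_sets > 0)
        sprintf(" (%d live set(s) omitted)", x$n_omitted_sets) else "",
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-subject classification score from a confusion matrix
#'
#' Percent correct is `100 * trace / total` (the ratio of correct live
#' classifications to all evaluated live patterns, 20 in the default
#' protocol); per-class error rates are `100 * (row sum - diagonal) / row
#' sum`.
#'
#' @param cm A [confusion_matrix()].
#' @param subject_id,metric_name Optional metadata carried in the score.
#' @return An object of class `bp_subject_score` with `percent_correct`,
#'   `per_class_correct`, `per_class_error_pct`, `n_evaluated`.
#' @export
subject_accuracy <- function(cm, subject_id = NA, metric_name = NA) {
  stopifnot(inherits(cm, "bp_confusion"))
  total <- sum(cm$counts)
  if (total == 0) {
    stop_bpi("empty_evaluation", "confusion matrix has no counts")
  }
  correct <- diag(cm$counts)
  row_tot <- rowSums(cm$counts)
  err <- ifelse(row_tot > 0, 100 * (row_tot - correct) / row_tot, NA_real_)
  structure(
    list(subject_id = subject_id, metric_name = metric_name,
         percent_correct = 100 * sum(correct) / total,
         per_class_correct = correct,
         per_class_error_pct = err,
         n_evaluated = total),
    class = "bp_subject_score"
  )
}

#' Bundle one subject's evaluated predictions
#'
#' Carries the raw label sequences plus the per-class outlier flags so
#' that aggregation can omit flagged live sets (all repetitions of one
#' class for one subject) exactly once.
#'
#' @param subject_id Identifier.
#' @param true_labels,predicted_labels Live-set label sequences.
#' @param class_ids Class identifiers.
#' @param outlier_flags Logical vector, one flag per class (`TRUE` =
#'   omit that subject's live set for the class). Default all `FALSE`.
#' @param metric_name Optional metric tag.
#' @return An object of class `bp_subject_eval`.
#' @export
subject_evaluation <- function(subject_id, true_labels, predicted_labels,
                               class_ids = sort(unique(true_labels)),
                               outlier_flags = NULL, metric_name = NA) {
  if (is.null(outlier_flags)) {
    outlier_flags <- rep(FALSE, length(class_ids))
  }
  if (length(outlier_flags) != length(class_ids)) {
    stop_bpi("invalid_argument", "need one outlier flag per class")
  }
  structure(
    list(subject_id = subject_id, true_labels = true_labels,
         predicted_labels = predicted_labels, class_ids = class_ids,
         outlier_flags = outlier_flags, metric_name = metric_name),
    class = "bp_subject_eval"
  )
}

subject_cm <- function(ev, omit_flagged = TRUE) {
  keep <- rep(TRUE, length(ev$true_labels))
  n_omit <- 0L
  if (omit_flagged && any(ev$outlier_flags)) {
    flagged <- ev$class_ids[ev$outlier_flags]
    keep <- !(ev$true_labels %in% flagged)
    n_omit <- sum(ev$outlier_flags)
  }
  confusion_matrix(ev$true_labels[keep], ev$predicted_labels[keep],
                   ev$class_ids, n_omitted_sets = n_omit)
}

#' Aggregate per-subject evaluations into a cumulative confusion matrix
#'
#' Sums the per-subject confusion matrices element-wise, excluding live
#' sets whose outlier flag is set when `omit_flagged = TRUE`. The summary
#' reports both the mean of per-subject percentages and the pooled
#' trace/total percentage (the two readings of an "average rate"), plus
#' per-class cumulative success and error percentages.
#'
#' @param evals List of [subject_evaluation()]s with compatible
#'   `class_ids`.
#' @param omit_flagged Honour the outlier flags (default `TRUE`).
#' @return An object of class `bp_aggregate`: cumulative `cm`
#'   ([confusion_matrix()] with `n_omitted_sets` filled in), data frame
#'   `per_class` (`class_id`, `n`, `correct`, `success_pct`,
#'   `error_pct`), `mean_subject_pct`, `pooled_pct`, `n_omitted_sets`,
#'   `subject_scores`.
#' @export
aggregate_subjects <- function(evals, omit_flagged = TRUE) {
  if (length(evals) == 0) {
    stop_bpi("empty_evaluation", "no subject evaluations supplied")
  }
  class_ids <- evals[[1]]$class_ids
  for (ev in evals) {
    if (!identical(ev$class_ids, class_ids)) {
      stop_bpi("incompatible_subjects",
               "subjects must share one set of class_ids")
    }
  }
  cms <- lapply(evals, subject_cm, omit_flagged = omit_flagged)
  total_counts <- Reduce(`+`, lapply(cms, function(c) c$counts))
  n_omit <- sum(vapply(cms, function(c) c$n_omitted_sets, integer(1)))
  cm <- confusion_matrix(integer(0), integer(0), class_ids,
                         n_omitted_sets = n_omit)
  cm$counts <- total_counts
  # a subject whose every live set is omitted contributes no score
  scored <- which(vapply(cms, function(c) sum(c$counts) > 0, logical(1)))
  scores <- lapply(scored, function(i) {
    subject_accuracy(cms[[i]], subject_id = evals[[i]]$subject_id,
                     metric_name = evals[[i]]$metric_name)
  })
  row_tot <- rowSums(total_counts)
  correct <- diag(total_counts)
  per_class <- data.frame(
    class_id = class_ids, n = as.integer(row_tot),
    correct = as.integer(correct),
    success_pct = ifelse(row_tot > 0, 100 * correct / row_tot, NA_real_),
    error_pct = ifelse(row_tot > 0, 100 * (row_tot - correct) / row_tot,
                       NA_real_))
  structure(
    list(cm = cm, per_class = per_class,
         mean_subject_pct = mean(vapply(scores, function(s)
           s$percent_correct, numeric(1))),
         pooled_pct = 100 * sum(correct) / sum(total_counts),
         n_omitted_sets = n_omit, subject_scores = scores),
    class = "bp_aggregate"
  )
}

#' @export
print.bp_aggregate <- function(x, ...) {
  cat(sprintf(
    "<bp_aggregate> pooled %.1f%% correct (mean per-subject %.1f%%), %d set(s) omitted\n",
    x$pooled_pct, x$mean_subject_pct, x$n_omitted_sets))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Compare ED and DTW 1-NN classification on the same datasets
#'
#' Runs the full processing-and-classification pipeline twice over
#' identical inputs — once per distance metric — and tabulates per-class
#' success rates for both along with their difference. Deterministic
#' given the dataset seeds.
#'
#' @param datasets List of [generate_subject_dataset()] results.
#' @param config A [pipeline_config()].
#' @param metrics Metrics to compare (default `c("ed", "dtw")`).
#' @return A list: `table` (one row per class per metric), `summary`
#'   (mean/pooled accuracy per metric), `difference` (per-class DTW
#'   minus ED success), and the per-metric `aggregates`.
#' @export
compare_metrics <- function(datasets, config = pipeline_config(),
                            metrics = c("ed", "dtw")) {
  if (length(datasets) == 0) {
    stop_bpi("invalid_argument", "no datasets supplied")
  }
  processed <- lapply(datasets, process_dataset, config = config)
  evals <- lapply(metrics, function(m) {
    lapply(processed, evaluate_processed_subject, metric = m,
           band_width = config$band_width)
  })
  names(evals) <- metrics
  comparison_from_evals(evals, metrics)
}

# assemble the comparison tables from per-metric lists of subject
# evaluations (shared by compare_metrics and run_experiment)
comparison_from_evals <- function(evals, metrics) {
  aggregates <- list()
  tabs <- list()
  for (m in metrics) {
    agg <- aggregate_subjects(evals[[m]], omit_flagged = TRUE)
    aggregates[[m]] <- agg
    tabs[[m]] <- cbind(metric = toupper(m), agg$per_class)
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  summary <- data.frame(
    metric = toupper(metrics),
    mean_subject_pct = vapply(metrics, function(m)
      aggregates[[m]]$mean_subject_pct, numeric(1)),
    pooled_pct = vapply(metrics, function(m)
      aggregates[[m]]$pooled_pct, numeric(1)))
  rownames(summary) <- NULL
  difference <- NULL
  if (all(c("ed", "dtw") %in% metrics)) {
    difference <- data.frame(
      class_id = aggregates$dtw$per_class$class_id,
      dtw_minus_ed_pct = aggregates$dtw$per_class$success_pct -
        aggregates$ed$per_class$success_pct)
  }
  list(table = table, summary = summary, difference = difference,
       aggregates = aggregates)
}
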