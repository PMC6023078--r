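test_that("confusion matrices tally labels exactly", {
  cm <- confusion_matrix(rep(1:4, each = 5), rep(1:4, each = 5), 1:4)
  expect_equal(diag(cm$counts), setNames(rep(5L, 4), 1:4))
  expect_equal(rowSums(cm$counts), setNames(rep(5L, 4), 1:4))

  all1 <- confusion_matrix(rep(1:4, each = 5), rep(1L, 20), 1:4)
  expect_equal(unname(colSums(all1$counts)), c(20L, 0L, 0L, 0L))

  cm2 <- confusion_matrix(c(1, 1, 2, 3, 4, 4), c(1, 2, 2, 3, 4, 1), 1:4)
  expect_equal(cm2$counts["1", "1"], 1L)
  expect_equal(cm2$counts["1", "2"], 1L)
  expect_equal(cm2$counts["2", "2"], 1L)
  expect_equal(cm2$counts["3", "3"], 1L)
  expect_equal(cm2$counts["4", "4"], 1L)
  expect_equal(cm2$counts["4", "1"], 1L)
  expect_equal(sum(cm2$counts), 6L)

  expect_error(confusion_matrix(c(1, 5), c(1, 1), 1:4),
               class = "unknown_label")
})

test_that("subject accuracy is the correct/total percentage with class errors", {
  perfect <- confusion_matrix(rep(1:4, each = 5), rep(1:4, each = 5), 1:4)
  expect_equal(subject_accuracy(perfect)$percent_correct, 100)

  # 17 of 20 correct -> 85%
  true <- rep(1:4, each = 5)
  pred <- true; pred[c(2, 8, 14)] <- c(2, 3, 1)
  expect_equal(subject_accuracy(confusion_matrix(true, pred, 1:4))$percent_correct,
               85)

  # diagonal (5,4,5,3) with row sums 5 each
  pred2 <- true
  pred2[6] <- 3                      # class 2: 4 correct
  pred2[16:17] <- c(1, 2)            # class 4: 3 correct
  sc <- subject_accuracy(confusion_matrix(true, pred2, 1:4))
  expect_equal(unname(sc$per_class_correct), c(5L, 4L, 5L, 3L))
  expect_equal(sc$percent_correct, 85)
  expect_equal(unname(sc$per_class_error_pct), c(0, 20, 0, 40))

  empty <- confusion_matrix(integer(0), integer(0), 1:4)
  expect_error(subject_accuracy(empty), class = "empty_evaluation")
})

test_that("aggregation sums matrices, omits flagged sets, and is order-invariant", {
  true <- rep(1:4, each = 5)
  ev_perfect <- function(id, flags = rep(FALSE, 4)) {
    subject_evaluation(id, true, true, 1:4, outlier_flags = flags)
  }
  # two identical diagonal CMs: doubled counts, unchanged accuracy
  agg <- aggregate_subjects(list(ev_perfect(1), ev_perfect(2)))
  expect_equal(diag(agg$cm$counts), setNames(rep(10L, 4), 1:4))
  expect_equal(agg$mean_subject_pct, 100)
  expect_equal(agg$pooled_pct, 100)

  # flagged sets are removed exactly once (5 signals per flagged set)
  agg_f <- aggregate_subjects(list(
    ev_perfect(1, flags = c(TRUE, FALSE, TRUE, FALSE)), ev_perfect(2)))
  expect_equal(agg_f$n_omitted_sets, 2L)
  expect_equal(sum(agg_f$cm$counts), 40L - 2L * 5L)
  expect_equal(unname(rowSums(agg_f$cm$counts)), c(5L, 10L, 5L, 10L))
  # ... and kept when omission is disabled
  agg_k <- aggregate_subjects(list(
    ev_perfect(1, flags = c(TRUE, FALSE, TRUE, FALSE)), ev_perfect(2)),
    omit_flagged = FALSE)
  expect_equal(sum(agg_k$cm$counts), 40L)

  # permutation invariance over randomized subjects
  evs <- lapply(1:6, function(i) {
    pred <- bpinterp:::with_seed(i, sample(1:4, 20, replace = TRUE))
    subject_evaluation(i, true, pred, 1:4)
  })
  a1 <- aggregate_subjects(evs)
  a2 <- aggregate_subjects(rev(evs))
  expect_equal(a1$cm$counts, a2$cm$counts)
  expect_equal(a1$mean_subject_pct, a2$mean_subject_pct)
  expect_equal(a1$per_class, a2$per_class)

  # accuracy + error per class sums to 100
  expect_equal(a1$per_class$success_pct + a1$per_class$error_pct,
               rep(100, 4))

  expect_error(aggregate_subjects(list(
    subject_evaluation(1, true, true, 1:4),
    subject_evaluation(2, rep(1:3, 5), rep(1:3, 5), 1:3))),
    class = "incompatible_subjects")
})

test_that("aggregation matches brute-force recomputation on random cases", {
  for (trial in 1:5) {
    n_subj <- 4
    evs <- lapply(seq_len(n_subj), function(s) {
      seed <- trial * 100 + s
      bpinterp:::with_seed(seed, {
        true <- rep(1:4, each = 3)
        pred <- sample(1:4, 12, replace = TRUE)
        flags <- runif(4) < 0.25
        subject_evaluation(s, true, pred, 1:4, outlier_flags = flags)
      })
    })
    agg <- aggregate_subjects(evs)
    # independent tally
    total <- matrix(0L, 4, 4)
    n_omit <- 0L
    kept_tot <- 0L
    for (ev in evs) {
      keep <- !(ev$true_labels %in% which(ev$outlier_flags))
      total <- total + oracle_confusion(ev$true_labels[keep],
                                        ev$predicted_labels[keep], 1:4)
      n_omit <- n_omit + sum(ev$outlier_flags)
      kept_tot <- kept_tot + sum(keep)
    }
    expect_equal(unname(agg$cm$counts), total)
    expect_equal(agg$n_omitted_sets, n_omit)
    expect_equal(sum(agg$cm$counts), kept_tot)
    expect_equal(agg$pooled_pct, 100 * sum(diag(total)) / kept_tot)
  }
})

test_that("metric comparison runs both pipelines and tabulates per class", {
  ds <- list(quick_subject(41, n_train = 3, n_live = 2,
                           warp_range = c(1, 1), shift_range = c(0, 0),
                           snr_db = 40))
  cfg <- quick_config()
  cmp <- compare_metrics(ds, cfg)
  expect_equal(nrow(cmp$table), 8L)           # 4 classes x 2 metrics
  expect_setequal(unique(cmp$table$metric), c("ED", "DTW"))
  # easy no-warp, high-SNR limit: both metrics are perfect
  expect_equal(cmp$summary$pooled_pct, c(100, 100))
  expect_equal(cmp$difference$dtw_minus_ed_pct, rep(0, 4))
})
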