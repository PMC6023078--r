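# Independent oracles used by the tests. These deliberately avoid the
# package's own dynamic-programming code paths.

# Exhaustively enumerate every monotone, continuous, boundary-anchored
# warp path between series of lengths a and b. Paths are returned as
# vectors of linear indices into an a x b local-cost matrix and cached
# per shape (enumeration is independent of the series values).
.path_cache <- new.env(parent = emptyenv())

all_warp_paths <- function(a, b) {
  key <- paste(a, b)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- list()
  walk <- function(i, j, acc) {
    if (i == a && j == b) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible(NULL))
    }
    if (i < a && j < b) walk(i + 1L, j + 1L, c(acc, j * a + i + 1L))
    if (i < a) walk(i + 1L, j, c(acc, (j - 1L) * a + i + 1L))
    if (j < b) walk(i, j + 1L, c(acc, j * a + i))
  }
  walk(1L, 1L, 1L)
  .path_cache[[key]] <- paths
  paths
}

# brute-force DTW: minimum summed |u_i - v_j| over all enumerated paths
oracle_dtw <- function(u, v) {
  cmat <- abs(outer(u, v, `-`))
  paths <- all_warp_paths(length(u), length(v))
  min(vapply(paths, function(p) sum(cmat[p]), numeric(1)))
}

# brute-force confusion counts by direct tally
oracle_confusion <- function(true, pred, class_ids) {
  k <- length(class_ids)
  m <- matrix(0L, k, k)
  for (t in seq_len(k)) for (p in seq_len(k)) {
    m[t, p] <- sum(true == class_ids[t] & pred == class_ids[p])
  }
  m
}

# small, fast configuration for unit tests that exercise the chain
# end-to-end without needing the full acquisition geometry: a lower audio
# rate and an 8 s window (still roomy enough for four separable events)
quick_config <- function(...) {
  pipeline_config(sample_rate_hz = 8000, duration_s = 8,
                  intermediate_rate_hz = 1000, envelope_rate_hz = 100,
                  ...)
}

quick_subject <- function(seed, ...) {
  generate_subject_dataset(seed, sample_rate_hz = 8000, duration_s = 8,
                           ...)
}

# a small spec with events placed inside the 8 s window
quick_spec <- function(n_events = 2, class_id = 1) {
  centers <- seq(2, 6, length.out = n_events)
  synth_class_spec(class_id, centers,
                   rep(0.6, n_events), rep(0.8, n_events))
}
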