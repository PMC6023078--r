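# Distance computation and 1-nearest-neighbour classification of a live
# breath envelope against the training template library. Two distances are
# supported: plain Euclidean distance on equal-length envelopes, and
# dynamic time warping with local cost |u_i - v_j| (the scalar Euclidean
# distance), which tolerates temporal stretches and shifts.

#' Euclidean distance between two equal-length series
#'
#' `d(U, V) = sqrt(sum_i (u_i - v_i)^2)`. Mismatched lengths are an error:
#' Euclidean matching has no warping, and the processing chain guarantees
#' fixed-length envelopes, so a length mismatch signals a pipeline bug
#' rather than something to resample away.
#'
#' @param u,v Numeric vectors or [breath_envelope()]s of equal length.
#' @return Non-negative distance; zero iff `u == v`.
#' @export
euclidean_distance <- function(u, v) {
  u <- env_values(u); v <- env_values(v)
  if (length(u) != length(v)) {
    stop_bpi("shape_error",
             "Euclidean distance requires equal lengths (%d vs %d)",
             length(u), length(v))
  }
  sqrt(sum((u - v)^2))
}

check_dtw_args <- function(u, v, band_width) {
  if (length(u) == 0 || length(v) == 0) {
    stop_bpi("invalid_input", "DTW requires non-empty series")
  }
  if (!is.null(band_width)) {
    if (band_width < abs(length(u) - length(v))) {
      stop_bpi("invalid_argument",
               "band_width (%d) must be >= |a - b| = %d for a feasible path",
               band_width, abs(length(u) - length(v)))
    }
    as.integer(band_width)
  } else {
    -1L
  }
}

#' Dynamic time warping distance
#'
#' Minimum cumulative local cost over all monotone, continuous,
#' boundary-anchored alignments of `u` and `v`, computed by the dynamic
#' program `D(i,j) = d(u_i, v_j) + min(D(i,j-1), D(i-1,j), D(i-1,j-1))`
#' with `D(1,1) = d(u_1, v_1)`. The local cost is `|u_i - v_j|` by
#' default (`squared = TRUE` switches to the squared-difference variant).
#'
#' @param u,v Numeric vectors or [breath_envelope()]s (lengths may
#'   differ).
#' @param band_width Optional Sakoe-Chiba band half-width in samples
#'   (`|i - j| <= band_width`); must be at least `|length(u) -
#'   length(v)|`. `NULL` (default) leaves the warp unconstrained.
#' @param squared Use squared local cost instead of `|u_i - v_j|`.
#' @return Non-negative distance, symmetric in `u` and `v`; zero for
#'   identical series.
#' @export
dtw_distance <- function(u, v, band_width = NULL, squared = FALSE) {
  u <- env_values(u); v <- env_values(v)
  band <- check_dtw_args(u, v, band_width)
  cpp_dtw_cost(u, v, band, squared)
}

#' Optimal warp path between two series
#'
#' Backtracks the DTW cumulative-cost matrix to the alignment realising
#' [dtw_distance()]. The returned path satisfies the boundary
#' (`(1,1)` to `(a,b)`), monotonicity and continuity constraints, and the
#' sum of local costs along it equals the DTW distance.
#'
#' @inheritParams dtw_distance
#' @return An object of class `warp_path`: integer matrix `pairs`
#'   (K x 2, columns `i`, `j`), path length `K`, and the realised
#'   `distance`.
#' @export
warp_path <- function(u, v, band_width = NULL, squared = FALSE) {
  u <- env_values(u); v <- env_values(v)
  band <- check_dtw_args(u, v, band_width)
  D <- cpp_dtw_matrix(u, v, band, squared)
  a <- length(u); b <- length(v)
  path <- matrix(0L, a + b, 2)
  i <- a; j <- b; k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      # prefer the diagonal on ties
      cand <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      step <- which.min(cand)
      if (step == 1L) { i <- i - 1L; j <- j - 1L }
      else if (step == 2L) i <- i - 1L
      else j <- j - 1L
    }
  }
  pairs <- path[k:1, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, K = nrow(pairs), distance = D[a, b]),
            class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> K = %d, distance = %g\n", x$K, x$distance))
  invisible(x)
}

#' Classify a live envelope by 1-nearest-neighbour template matching
#'
#' Computes the distance from the live envelope to every one of the M
#' training templates (the M x 1 distance vector), selects the smallest,
#' and returns its class together with the vocabulary phrase. Ties are
#' broken by the lowest template index.
#'
#' @param live A [breath_envelope()] (or numeric vector). Under `"ed"`
#'   its length must equal the library's `env_len`; `"dtw"` tolerates
#'   differing lengths.
#' @param lib A [build_library()] result.
#' @param metric `"dtw"` or `"ed"`.
#' @param band_width Optional Sakoe-Chiba band for DTW.
#' @return An object of class `bp_classification`: `predicted_class`,
#'   `distances` (length M), `nearest_template_index`, `metric_name`
#'   (`"DTW"` or `"ED"`), `phrase`.
#' @export
classify_1nn <- function(live, lib, metric = c("dtw", "ed"),
                         band_width = NULL) {
  stopifnot(inherits(lib, "template_library"))
  metric <- match.arg(metric)
  if (nrow(lib$templates) == 0) {
    stop_bpi("empty_library", "template library contains no templates")
  }
  x <- env_values(live)
  m <- nrow(lib$templates)
  if (metric == "ed") {
    if (length(x) != lib$env_len) {
      stop_bpi("shape_error",
               "live envelope length (%d) must equal template length (%d) for ED",
               length(x), lib$env_len)
    }
    distances <- sqrt(colSums((t(lib$templates) - x)^2))
  } else {
    band <- if (is.null(band_width)) -1L
            else check_dtw_args(x, lib$templates[1, ], band_width)
    distances <- vapply(seq_len(m), function(i) {
      cpp_dtw_cost(x, lib$templates[i, ], band, FALSE)
    }, numeric(1))
  }
  nearest <- which.min(distances)  # lowest index wins ties
  cls <- lib$class_labels[nearest]
  structure(
    list(predicted_class = cls, distances = as.numeric(distances),
         nearest_template_index = nearest,
         metric_name = toupper(metric),
         phrase = phrase_for_class(lib, cls)),
    class = "bp_classification"
  )
}

#' @export
print.bp_classification <- function(x, ...) {
  cat(sprintf(
    "<bp_classification> class %d via %s (template %d, distance %.4g)\n  phrase: \"%s\"\n",
    x$predicted_class, x$metric_name, x$nearest_template_index,
    x$distances[x$nearest_template_index], x$phrase))
  invisible(x)
}
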