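# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers/tests can dispatch on the error kind
stop_bpi <- function(code, msg, ...) {
  msg <- sprintf(msg, ...)
  cond <- structure(
    class = c(code, "bpi_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_bpi("invalid_argument", "`%s` must be a single finite number", name)
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator calls do not
#' perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# package-local cache for filter designs keyed by geometry
.bpi_cache <- new.env(parent = emptyenv())

cache_get_or_set <- function(key, value_fn) {
  if (is.null(.bpi_cache[[key]])) .bpi_cache[[key]] <- value_fn()
  .bpi_cache[[key]]
}

# deterministic per-recording substream seeds: one base stream per dataset,
# split by counter, so per-recording reproducibility survives reordering
derive_seed <- function(base, counter) {
  as.integer((as.double(base) %% 2147483629 * 48271 +
                as.double(counter) * 69621) %% 2147483629)
}
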