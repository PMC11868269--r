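# Internal helpers shared across modules.

# Run `expr` under a local RNG seed without disturbing the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("rng seed must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

geom_mean <- function(x) exp(mean(log(x)))

# Sample SD with the n-1 denominator (matches spreadsheet STDEV, used by all
# the original stability tools).
sample_sd <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

abort_cells <- function(msg, cells, call. = FALSE) {
  shown <- utils::head(cells, 10L)
  more <- if (length(cells) > 10L) sprintf(" ... and %d more", length(cells) - 10L) else ""
  stop(msg, ": ", paste(shown, collapse = ", "), more, call. = call.)
}
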