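stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a top-level seed
#'
#' All stochastic operations in the package draw their randomness from one
#' top-level seed; independent substreams (restarts, simulation stages,
#' replicate seeds) are derived deterministically with this helper so that a
#' single `seed` argument makes a whole analysis reproducible.
#'
#' @param seed Integer top-level seed.
#' @param ... Stream labels (character or integer) identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "restart", 3)
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# round half away from zero (the usual "half-up" presentation convention,
# unlike base round()'s banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

check_count <- function(x, name, min = 0) {
  if (!is_count(x) || x < min) {
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  }
  as.integer(x)
}
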