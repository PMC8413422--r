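# Internal helpers shared across modules.

#' Derive a deterministic substream seed for a named stage
#'
#' A single corpus-level seed is expanded into per-stage seeds so that
#' individual stages (ground truth, platform A, platform B, subsampling, ...)
#' can be regenerated independently while remaining jointly reproducible.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  # polynomial rolling hash, kept inside 31-bit range
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003L
  as.integer((abs(as.integer(seed)) + h * 1009L) %% 2147483647L)
}

#' Evaluate an expression under a temporary RNG state
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

# Canonical string form of a condition: compound x concentration x cell line
# x duration. Used as the grouping key throughout.
condition_key <- function(compound, concentration_uM, cell_line, duration_h) {
  paste(compound, format(concentration_uM, trim = TRUE, scientific = FALSE),
        cell_line, duration_h, sep = "|")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
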