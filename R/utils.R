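# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used when scaling colony counts to
#' whole-culture values, where R's default banker's rounding would be
#' surprising for count data.
#'
#' @param x numeric vector.
#' @return `floor(x + 0.5)` for non-negative `x`.
#' @keywords internal
round_half_up <- function(x) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  floor(x + 0.5)
}

# Seed an RNG stream only when the caller asked for reproducibility.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed %% .Machine$integer.max)
    set.seed(seed)
  }
  invisible(NULL)
}

# stop() with a sprintf-style message, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
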