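`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a global seed
#'
#' All stochastic stages derive their own seed deterministically from one
#' global seed, so a pipeline run is reproducible end to end while stages
#' remain independently re-runnable.
#'
#' @param seed integer global seed.
#' @param k integer stream index (one per stage / sub-generator).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(k) * 7919 + 1) %% 2147483647)
}

# round a percentage to the 5%-step visual scoring grid
snap_to_grid <- function(x, step = 5) step * round(x / step)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
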