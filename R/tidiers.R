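# broom-style accessors for the accumulator.

#' Tidy a run accumulator into its per-window statistics
#'
#' @param x a [run_accumulator()].
#' @param cumulative return running totals ([cumulative_stats()]) instead of
#'   per-window values ([window_stats()]).
#' @param ... unused.
#' @return A tibble, one row per elapsed-time window.
#' @export
tidy.run_accumulator <- function(x, cumulative = FALSE, ...) {
  if (cumulative) cumulative_stats(x) else window_stats(x)
}

#' One-row summary of a run accumulator
#'
#' @param x a [run_accumulator()].
#' @param ... unused.
#' @return The [latest_metrics()] snapshot with a `n_rejected` column
#'   appended.
#' @export
glance.run_accumulator <- function(x, ...) {
  dplyr::mutate(latest_metrics(x), n_rejected = sum(x$rejected))
}
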