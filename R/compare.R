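# Multi-run comparison over emitted statistics files. This layer never touches
# raw sequencing summaries: it is a pure function of the five per-run TSVs and
# the registry, mirroring the two-component architecture (the preprocessor
# feeds the presentation layer).

windowed_classes <- c(
  window_index = "integer", t_start = "numeric", n_reads = "integer",
  yield_bases = "numeric", mean_length = "numeric", median_length = "numeric",
  mean_qscore = "numeric", speed = "numeric", low_speed_flag = "logical"
)

emitted_col_classes <- list(
  windowed.tsv = windowed_classes,
  cumulative.tsv = windowed_classes,
  channels.tsv = c(
    channel = "integer", grid_row = "integer", grid_col = "integer",
    n_reads = "integer", yield_bases = "numeric", mean_qscore = "numeric",
    speed = "numeric"
  ),
  quality_time.tsv = c(
    window_index = "integer", t_start = "numeric", q_bin = "integer",
    q_start = "numeric", n_reads = "integer"
  ),
  length_dist.tsv = c(
    bin_index = "integer", bin_start = "numeric", bin_width = "numeric",
    read_count = "integer", base_count = "numeric", percent_bases = "numeric"
  )
)

read_emitted <- function(path, file) {
  classes <- emitted_col_classes[[file]]
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t", fixed = TRUE)[[1]]
  extra <- setdiff(header, names(classes))
  if (length(extra)) {
    warn(paste0(file, ": ignoring unknown column(s): ",
                paste(extra, collapse = ", ")))
  }
  read_tsv_exact(path, classes)
}

#' Load a run's emitted statistics files back into typed tables
#'
#' Reads the five per-run statistics files from `<output_root>/<run_id>/` into
#' a `run_series`. Values round-trip exactly (the emitter writes doubles in
#' shortest-round-trip form). Unknown extra columns are ignored with a
#' warning, so files written by a newer emitter still load.
#'
#' @param output_root the watcher's output directory.
#' @param run_id run identifier (its subdirectory name).
#' @return A `run_series`: list with `run_id` and tibbles `windows`,
#'   `cumulative`, `channels`, `quality_time`, `length_dist`.
#' @export
load_run <- function(output_root, run_id) {
  run_dir <- file.path(output_root, run_id)
  paths <- file.path(run_dir, EMITTED_FILES)
  missing <- EMITTED_FILES[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("run ", run_id, " is missing emitted file(s): ",
                 paste(missing, collapse = ", ")),
          class = "porewatch_missing_file", missing_files = missing)
  }
  tables <- lapply(EMITTED_FILES, function(f) read_emitted(file.path(run_dir, f), f))
  names(tables) <- c("windows", "cumulative", "channels", "quality_time",
                     "length_dist")
  structure(c(list(run_id = run_id), tables), class = "run_series")
}

#' @export
print.run_series <- function(x, ...) {
  cat("<run_series>", x$run_id, "\n")
  cat("  windows:", nrow(x$windows), " channels:", nrow(x$channels),
      " length bins:", nrow(x$length_dist), "\n")
  invisible(x)
}

as_run_list <- function(runs) {
  if (inherits(runs, "run_series")) runs <- list(runs)
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1), "run_series")))
  runs
}

#' Compare a windowed or cumulative metric across runs
#'
#' Long-format, plot-ready table of one metric over elapsed run time for any
#' number of runs. Runs are aligned on elapsed time from each run's own start
#' (never calendar time); shorter runs simply end earlier — no padding or
#' truncation.
#'
#' @param runs a `run_series` or list of them (see [load_run()]).
#' @param metric one of `"yield_bases"`, `"n_reads"`, `"mean_length"`,
#'   `"median_length"`, `"mean_qscore"`, `"speed"`.
#' @param mode `"cumulative"` (running totals from run start) or
#'   `"per_window"`.
#' @return Tibble `(run_id, elapsed_s, value)` sorted by `(run_id, elapsed_s)`.
#' @export
compare_runs <- function(runs, metric = "yield_bases",
                         mode = c("cumulative", "per_window")) {
  runs <- as_run_list(runs)
  mode <- match.arg(mode)
  metric <- match.arg(metric, c("yield_bases", "n_reads", "mean_length",
                                "median_length", "mean_qscore", "speed"))
  rows <- purrr::map(runs, function(r) {
    src <- if (mode == "cumulative") r$cumulative else r$windows
    tibble(run_id = r$run_id, elapsed_s = src$t_start,
           value = as.numeric(src[[metric]]))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$run_id, .data$elapsed_s)
}

#' Cumulative or per-window yield across runs
#'
#' Convenience wrapper around [compare_runs()] for the most-watched metric.
#'
#' @inheritParams compare_runs
#' @return Tibble `(run_id, elapsed_s, value)` with yield in bases.
#' @export
compare_yield <- function(runs, mode = c("cumulative", "per_window")) {
  compare_runs(runs, metric = "yield_bases", mode = mode)
}

#' Compare read-length distributions across runs
#'
#' Long-format table of the length histogram of each run, as read counts, base
#' counts, or each bin's percent of the run's total bases (the view that
#' compares library shapes independently of absolute yield; per-run rows then
#' sum to 100). All runs must have been emitted with the same length bin
#' width.
#'
#' @param runs a `run_series` or list of them.
#' @param mode `"reads"`, `"bases"` or `"percent_bases"`.
#' @return Tibble `(run_id, bin_start, value)` sorted by `(run_id, bin_start)`.
#' @export
compare_length_dist <- function(runs, mode = c("reads", "bases", "percent_bases")) {
  runs <- as_run_list(runs)
  mode <- match.arg(mode)
  widths <- unlist(lapply(runs, function(r) unique(r$length_dist$bin_width)))
  if (length(unique(widths)) > 1L) {
    abort(paste0("length histograms use different bin widths: ",
                 paste(sort(unique(widths)), collapse = ", "),
                 "; re-emit with a common --length-bin"),
          class = "porewatch_bin_width_mismatch")
  }
  rows <- purrr::map(runs, function(r) {
    h <- r$length_dist
    value <- switch(mode,
      reads = as.numeric(h$read_count),
      bases = h$base_count,
      percent_bases = 100 * h$base_count / sum(h$base_count)
    )
    tibble(run_id = r$run_id, bin_start = h$bin_start, value = value)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$run_id, .data$bin_start)
}

#' Cross-run overview table
#'
#' One row per run — in progress or finished alike — combining the registry's
#' status and timestamp with each run's final cumulative totals: the
#' "sequencing overview" of a facility's flowcells.
#'
#' @param output_root the watcher's output directory (must contain `runs.tsv`).
#' @param run_ids optional subset of run ids; default is every registry row.
#' @return Tibble sorted by date then run id, with columns `run_id`, `date`,
#'   `status`, `n_reads`, `yield_bases`, `mean_length`, `mean_qscore`,
#'   `mean_speed`.
#' @export
overview_table <- function(output_root, run_ids = NULL) {
  registry <- read_registry(file.path(output_root, "runs.tsv"))
  if (!is.null(run_ids)) registry <- registry[registry$run_id %in% run_ids, ]
  rows <- purrr::pmap(registry, function(run_id, status, last_updated, ...) {
    r <- load_run(output_root, run_id)
    last <- if (nrow(r$cumulative)) r$cumulative[nrow(r$cumulative), ] else
      tibble(n_reads = 0L, yield_bases = 0, mean_length = NA_real_,
             mean_qscore = NA_real_, speed = NA_real_)
    tibble(run_id = run_id, date = last_updated, status = status,
           n_reads = last$n_reads, yield_bases = last$yield_bases,
           mean_length = last$mean_length, mean_qscore = last$mean_qscore,
           mean_speed = last$speed)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(run_id = character(), date = character(), status = character(),
                  n_reads = integer(), yield_bases = double(),
                  mean_length = double(), mean_qscore = double(),
                  mean_speed = double()))
  }
  dplyr::arrange(out, .data$date, .data$run_id)
}
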