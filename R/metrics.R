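# Per-run accumulator and every statistic derived from it.
#
# The accumulator keeps the accepted read records themselves (plus reject
# counters). At facility desk scale this is cheap, and it buys three
# properties the derived statistics must have: exact medians, exact
# order-independence (records are sorted deterministically before any
# floating-point summation), and bit-identical results whether a run was
# processed in one shot or as many small increments.

#' Flowcell channel-grid layouts
#'
#' Maps channels onto a rectangular grid for spatial metric maps. MinION-class
#' devices (MinION, Mk1C, GridION) expose 512 channels, laid out here as 16
#' rows x 32 columns; PromethION-class flowcells expose 3000 channels, 30 rows
#' x 100 columns. The mapping is row-major: 1-based channel `c` sits at row
#' `(c-1) %/% ncol + 1`, column `(c-1) %% ncol + 1`. This is a plotting
#' convention, not the vendor's physical pore map.
#'
#' @param name `"minion"`, `"gridion"`, `"mk1c"` or `"promethion"`.
#' @return A `porewatch_layout` list: `name`, `n_channels`, `n_rows`, `n_cols`.
#' @examples
#' flowcell_layout("promethion")$n_channels
#' @export
flowcell_layout <- function(name = c("minion", "gridion", "mk1c", "promethion")) {
  name <- match.arg(tolower(name[1L]), c("minion", "gridion", "mk1c", "promethion"))
  dims <- switch(name,
    promethion = c(3000L, 30L, 100L),
    c(512L, 16L, 32L)
  )
  structure(
    list(name = name, n_channels = dims[1L], n_rows = dims[2L], n_cols = dims[3L]),
    class = "porewatch_layout"
  )
}

# Row-major grid position of 1-based channels; channels outside the layout get
# NA coordinates (the overflow bucket).
channel_grid_position <- function(channel, layout) {
  ok <- !is.na(channel) & channel >= 1L & channel <= layout$n_channels
  row <- ifelse(ok, (channel - 1L) %/% layout$n_cols + 1L, NA_integer_)
  col <- ifelse(ok, (channel - 1L) %% layout$n_cols + 1L, NA_integer_)
  tibble(grid_row = as.integer(row), grid_col = as.integer(col))
}

#' Elapsed-time window index of a read
#'
#' Reads are binned into fixed, half-open elapsed-time slices
#' `[k*w, (k+1)*w)` by their start time; the default width elsewhere in the
#' package is 600 s (10 minutes).
#'
#' @param start_time seconds since run start (vectorised, >= 0).
#' @param window_width window width in seconds (> 0).
#' @return Integer window indices (0-based).
#' @examples
#' window_index(c(0, 599.999, 600, 1250), 600)
#' @export
window_index <- function(start_time, window_width) {
  check_positive(window_width = window_width)
  stopifnot(all(start_time >= 0, na.rm = TRUE))
  as.integer(floor(start_time / window_width))
}

#' Create an empty per-run accumulator
#'
#' The accumulator is the mergeable per-run state every statistic is derived
#' from: windowed and cumulative series, per-channel tallies, the read-length
#' histogram and the quality-over-time histogram. Feed it records with
#' [acc_update()]; extract statistics with [window_stats()],
#' [cumulative_stats()], [channel_stats()], [length_histogram()],
#' [quality_time_histogram()] and [latest_metrics()].
#'
#' @param window_width elapsed-time slice width in seconds (default 600 s,
#'   i.e. 10 minutes).
#' @param length_bin read-length histogram bin width in bases (default 500).
#' @param q_bin q-score histogram bin width (default 0.5).
#' @param low_speed_threshold translocation speed (bases/second) below which a
#'   window is flagged; the vendor recommends keeping the rate above 300 b/s,
#'   the default.
#' @param pass_q_threshold mean q-score at or above which a read counts as
#'   "pass" when the summary has no `passes_filtering` column (default 7).
#' @param layout a [flowcell_layout()] or a layout name.
#' @return An empty `run_accumulator`.
#' @examples
#' acc <- run_accumulator()
#' latest_metrics(acc)
#' @export
run_accumulator <- function(window_width = 600, length_bin = 500, q_bin = 0.5,
                            low_speed_threshold = 300, pass_q_threshold = 7,
                            layout = flowcell_layout("minion")) {
  check_positive(window_width = window_width, length_bin = length_bin,
                 q_bin = q_bin, low_speed_threshold = low_speed_threshold)
  stopifnot(pass_q_threshold >= 0)
  if (is.character(layout)) layout <- flowcell_layout(layout)
  stopifnot(inherits(layout, "porewatch_layout"))
  structure(
    list(
      config = list(window_width = window_width, length_bin = length_bin,
                    q_bin = q_bin, low_speed_threshold = low_speed_threshold,
                    pass_q_threshold = pass_q_threshold, layout = layout),
      records = empty_records(),
      rejected = zero_rejects()
    ),
    class = "run_accumulator"
  )
}

#' Add read records (and reject counts) to an accumulator
#'
#' Order-independent: records may arrive in any order across any number of
#' calls; every derived statistic is identical to a one-shot batch
#' computation. Records on channels beyond the fixed layout are kept (they
#' land in the per-channel overflow bucket) with a warning.
#'
#' @param acc a [run_accumulator()].
#' @param records tibble of read records as produced by
#'   [parse_summary_records()] / [read_new_records()].
#' @param rejected optional named reject-count vector to add to the
#'   accumulator's tallies.
#' @return The updated accumulator.
#' @export
acc_update <- function(acc, records, rejected = NULL) {
  stopifnot(inherits(acc, "run_accumulator"))
  proto <- empty_records()
  missing_cols <- setdiff(names(proto), names(records))
  if (length(missing_cols)) {
    abort(paste0("records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "porewatch_bad_records")
  }
  records <- records[names(proto)]
  n_over <- sum(records$channel > acc$config$layout$n_channels)
  if (n_over > 0) {
    warn(paste0(n_over, " record(s) on channels beyond the ",
                acc$config$layout$name, " layout (",
                acc$config$layout$n_channels,
                " channels); counted in the overflow bucket"))
  }
  acc$records <- dplyr::bind_rows(acc$records, records)
  if (!is.null(rejected)) {
    acc$rejected[names(rejected)] <- acc$rejected[names(rejected)] + rejected
  }
  acc
}

#' Merge two accumulators for the same run configuration
#'
#' @param a,b accumulators built with identical configuration.
#' @return The merged accumulator.
#' @export
acc_merge <- function(a, b) {
  stopifnot(inherits(a, "run_accumulator"), inherits(b, "run_accumulator"))
  if (!identical(a$config, b$config)) {
    abort("cannot merge accumulators with different configurations",
          class = "porewatch_invalid_config")
  }
  a$records <- dplyr::bind_rows(a$records, b$records)
  a$rejected <- a$rejected + b$rejected
  a
}

# Records sorted deterministically (window/time, then read_id as tiebreak):
# makes floating-point sums independent of arrival order.
sorted_records <- function(acc) {
  dplyr::arrange(acc$records, .data$start_time, .data$read_id)
}

#' Per-window statistics
#'
#' One row per elapsed-time window from 0 through the last observed window,
#' empty windows included (their metrics are `NA` — gaps are meaningful in a
#' monitoring plot). Per window: read count, yield (summed bases), mean and
#' exact median read length, arithmetic mean of the per-read mean q-scores,
#' translocation speed as summed bases over summed dwell time
#' (duration-weighted, so robust to many tiny reads), and a low-speed flag
#' (`speed < low_speed_threshold`).
#'
#' @param acc a [run_accumulator()].
#' @return Tibble with columns `window_index`, `t_start`, `n_reads`,
#'   `yield_bases`, `mean_length`, `median_length`, `mean_qscore`, `speed`,
#'   `low_speed_flag`; zero rows for an empty run.
#' @export
window_stats <- function(acc) {
  stopifnot(inherits(acc, "run_accumulator"))
  w <- acc$config$window_width
  empty <- tibble(
    window_index = integer(), t_start = double(), n_reads = integer(),
    yield_bases = double(), mean_length = double(), median_length = double(),
    mean_qscore = double(), speed = double(), low_speed_flag = logical()
  )
  if (!nrow(acc$records)) return(empty)
  recs <- sorted_records(acc)
  recs$window_index <- window_index(recs$start_time, w)
  per <- recs |>
    dplyr::group_by(.data$window_index) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      yield_bases = sum(.data$sequence_length),
      mean_length = .data$yield_bases / .data$n_reads,
      median_length = median(.data$sequence_length),
      mean_qscore = sum(.data$mean_qscore) / .data$n_reads,
      speed = .data$yield_bases / sum(.data$duration),
      .groups = "drop"
    )
  tibble(window_index = seq.int(0L, max(per$window_index))) |>
    dplyr::left_join(per, by = "window_index") |>
    dplyr::mutate(
      t_start = .data$window_index * w,
      n_reads = dplyr::coalesce(.data$n_reads, 0L),
      yield_bases = dplyr::coalesce(.data$yield_bases, 0),
      low_speed_flag = .data$speed < acc$config$low_speed_threshold
    ) |>
    dplyr::select(dplyr::all_of(names(empty)))
}

#' Cumulative statistics from run start through each window's end
#'
#' Running totals over the same window grid as [window_stats()]. Means are
#' recomputed from running sums (never means of means) and the cumulative
#' median is the exact median of the run-to-date length multiset. Cumulative
#' speed is total bases over total dwell time; the low-speed flag applies to
#' that cumulative speed.
#'
#' @param acc a [run_accumulator()].
#' @return Tibble with the same columns as [window_stats()]; `yield_bases` is
#'   non-decreasing and its last value is the run's total yield.
#' @export
cumulative_stats <- function(acc) {
  stopifnot(inherits(acc, "run_accumulator"))
  ws <- window_stats(acc)
  if (!nrow(ws)) return(ws)
  recs <- sorted_records(acc)
  recs$window_index <- window_index(recs$start_time, acc$config$window_width)

  # per-window duration sums on the full grid, for cumulative speed
  dur <- recs |>
    dplyr::group_by(.data$window_index) |>
    dplyr::summarise(sum_duration = sum(.data$duration), .groups = "drop")
  grid <- dplyr::left_join(ws[, c("window_index", "n_reads", "yield_bases")],
                           dur, by = "window_index") |>
    dplyr::mutate(sum_duration = dplyr::coalesce(.data$sum_duration, 0))

  q <- recs |>
    dplyr::group_by(.data$window_index) |>
    dplyr::summarise(sum_q = sum(.data$mean_qscore), .groups = "drop")
  grid <- dplyr::left_join(grid, q, by = "window_index") |>
    dplyr::mutate(sum_q = dplyr::coalesce(.data$sum_q, 0))

  cum_n   <- cumsum(grid$n_reads)
  cum_len <- cumsum(grid$yield_bases)
  cum_dur <- cumsum(grid$sum_duration)
  cum_q   <- cumsum(grid$sum_q)

  # exact run-to-date medians: lengths in time order, one median per window
  lens <- recs$sequence_length
  counts <- grid$n_reads
  medians <- rep(NA_real_, nrow(grid))
  upto <- cumsum(counts)
  for (i in seq_along(medians)) {
    if (upto[i] > 0) medians[i] <- median(lens[seq_len(upto[i])])
  }

  tibble(
    window_index = grid$window_index,
    t_start = grid$window_index * acc$config$window_width,
    n_reads = as.integer(cum_n),
    yield_bases = cum_len,
    mean_length = ifelse(cum_n > 0, cum_len / cum_n, NA_real_),
    median_length = medians,
    mean_qscore = ifelse(cum_n > 0, cum_q / cum_n, NA_real_),
    speed = ifelse(cum_dur > 0, cum_len / cum_dur, NA_real_),
    low_speed_flag = ifelse(cum_dur > 0,
                            cum_len / cum_dur < acc$config$low_speed_threshold,
                            NA)
  )
}

#' Per-channel statistics on the flowcell grid
#'
#' One row per channel of the configured layout (quiet channels included with
#' zero reads — a silent region of the grid is exactly what a spatial map is
#' for), plus a final overflow row (`channel = NA`) when records arrived on
#' channels beyond the layout, so read/base counts always sum to the run
#' totals.
#'
#' @param acc a [run_accumulator()].
#' @return Tibble with columns `channel`, `grid_row`, `grid_col`, `n_reads`,
#'   `yield_bases`, `mean_qscore`, `speed`.
#' @export
channel_stats <- function(acc) {
  stopifnot(inherits(acc, "run_accumulator"))
  layout <- acc$config$layout
  recs <- sorted_records(acc)
  over <- recs$channel > layout$n_channels
  per <- recs |>
    dplyr::mutate(channel = ifelse(over, NA_integer_, .data$channel)) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      yield_bases = sum(.data$sequence_length),
      mean_qscore = sum(.data$mean_qscore) / .data$n_reads,
      speed = .data$yield_bases / sum(.data$duration),
      .groups = "drop"
    )
  base <- tibble(channel = seq_len(layout$n_channels))
  if (any(is.na(per$channel))) base <- dplyr::bind_rows(base, tibble(channel = NA_integer_))
  out <- base |>
    dplyr::left_join(per, by = "channel") |>
    dplyr::mutate(
      n_reads = dplyr::coalesce(.data$n_reads, 0L),
      yield_bases = dplyr::coalesce(.data$yield_bases, 0)
    )
  out <- dplyr::bind_cols(out, channel_grid_position(out$channel, layout))
  dplyr::select(out, "channel", "grid_row", "grid_col", "n_reads",
                "yield_bases", "mean_qscore", "speed")
}

#' Read-length histogram (reads and bases per length bin)
#'
#' Read length `L` lands in bin `floor(L / bin_width)`; each bin tracks both
#' how many reads it holds and how many bases those reads contribute — the
#' base view is what reveals whether a library's yield sits in long or short
#' fragments. Only populated bins are returned.
#'
#' @param acc a [run_accumulator()].
#' @param bin_width bin width in bases; defaults to the accumulator's
#'   configured `length_bin`.
#' @return Tibble with columns `bin_index`, `bin_start`, `bin_width`,
#'   `read_count`, `base_count`.
#' @export
length_histogram <- function(acc, bin_width = NULL) {
  stopifnot(inherits(acc, "run_accumulator"))
  bin_width <- bin_width %||% acc$config$length_bin
  check_positive(bin_width = bin_width)
  recs <- sorted_records(acc)
  if (!nrow(recs)) {
    return(tibble(bin_index = integer(), bin_start = double(),
                  bin_width = double(), read_count = integer(),
                  base_count = double()))
  }
  recs |>
    dplyr::mutate(bin_index = as.integer(floor(.data$sequence_length / bin_width))) |>
    dplyr::group_by(.data$bin_index) |>
    dplyr::summarise(read_count = dplyr::n(),
                     base_count = sum(.data$sequence_length),
                     .groups = "drop") |>
    dplyr::mutate(bin_start = .data$bin_index * bin_width,
                  bin_width = bin_width) |>
    dplyr::arrange(.data$bin_index) |>
    dplyr::select("bin_index", "bin_start", "bin_width", "read_count", "base_count")
}

#' Percent-of-bases view of a length histogram
#'
#' Adds `percent_bases`: each bin's share of the run's total bases, in percent
#' (rows sum to 100). Comparing runs on this view removes the difference in
#' absolute yield and leaves only the shape of the length distribution.
#'
#' @param hist a [length_histogram()] result with at least one base.
#' @return The histogram with a `percent_bases` column appended.
#' @export
percent_base_distribution <- function(hist) {
  total <- sum(hist$base_count)
  if (!is.finite(total) || total <= 0) {
    abort("cannot compute a percent-of-bases distribution for a run with zero bases",
          class = "porewatch_empty_run")
  }
  dplyr::mutate(hist, percent_bases = 100 * .data$base_count / total)
}

#' Read counts on the quality x elapsed-time grid
#'
#' Counts reads per (time window, q-score bin) cell: the heatmap that shows
#' basecall quality drifting over the course of a run. Time bins follow the
#' accumulator's window width; a read with mean q-score `q` lands in q-bin
#' `floor(q / q_bin_width)`. Only nonzero cells are returned; counts sum to
#' the run's total reads.
#'
#' @param acc a [run_accumulator()].
#' @param q_bin_width q-score bin width; defaults to the configured `q_bin`.
#' @return Tibble with columns `window_index`, `t_start`, `q_bin`, `q_start`,
#'   `n_reads`.
#' @export
quality_time_histogram <- function(acc, q_bin_width = NULL) {
  stopifnot(inherits(acc, "run_accumulator"))
  q_bin_width <- q_bin_width %||% acc$config$q_bin
  check_positive(q_bin_width = q_bin_width)
  recs <- sorted_records(acc)
  if (!nrow(recs)) {
    return(tibble(window_index = integer(), t_start = double(),
                  q_bin = integer(), q_start = double(), n_reads = integer()))
  }
  w <- acc$config$window_width
  recs |>
    dplyr::mutate(
      window_index = window_index(.data$start_time, w),
      q_bin = as.integer(floor(.data$mean_qscore / q_bin_width))
    ) |>
    dplyr::count(.data$window_index, .data$q_bin, name = "n_reads") |>
    dplyr::mutate(t_start = .data$window_index * w,
                  q_start = .data$q_bin * q_bin_width) |>
    dplyr::arrange(.data$window_index, .data$q_bin) |>
    dplyr::select("window_index", "t_start", "q_bin", "q_start", "n_reads")
}

#' Classify reads as pass or fail
#'
#' When the summary file carries a `passes_filtering` column, that verdict
#' takes precedence; otherwise a read passes iff its mean q-score is at or
#' above the threshold (inclusive, matching the basecaller's convention; the
#' conventional threshold is 7).
#'
#' @param records tibble of read records (needs `mean_qscore`, and uses
#'   `passes_filtering` where non-`NA`).
#' @param q_threshold fallback q-score threshold (default 7).
#' @return Logical vector, one element per record.
#' @examples
#' classify_pass(tibble::tibble(mean_qscore = c(6.99, 7, 12),
#'                              passes_filtering = c(NA, NA, FALSE)))
#' @export
classify_pass <- function(records, q_threshold = 7) {
  stopifnot(q_threshold >= 0)
  fallback <- records$mean_qscore >= q_threshold
  if ("passes_filtering" %in% names(records)) {
    ifelse(is.na(records$passes_filtering), fallback, records$passes_filtering)
  } else {
    fallback
  }
}

#' Latest-metrics snapshot of a run
#'
#' The one-row summary kept in the flowcell registry: total reads and yield,
#' overall mean length and q-score, the translocation speed of the most recent
#' non-empty window, and elapsed seconds (latest read start time seen). An
#' empty run reports zeros and an `NA` speed.
#'
#' @param acc a [run_accumulator()].
#' @return One-row tibble: `n_reads`, `yield_bases`, `mean_length`,
#'   `mean_qscore`, `last_speed`, `elapsed_s`.
#' @export
latest_metrics <- function(acc) {
  stopifnot(inherits(acc, "run_accumulator"))
  recs <- sorted_records(acc)
  if (!nrow(recs)) {
    return(tibble(n_reads = 0L, yield_bases = 0, mean_length = NA_real_,
                  mean_qscore = NA_real_, last_speed = NA_real_, elapsed_s = 0))
  }
  ws <- window_stats(acc)
  nonempty <- ws[ws$n_reads > 0L, ]
  tibble(
    n_reads = nrow(recs),
    yield_bases = sum(recs$sequence_length),
    mean_length = sum(recs$sequence_length) / nrow(recs),
    mean_qscore = sum(recs$mean_qscore) / nrow(recs),
    last_speed = nonempty$speed[nrow(nonempty)],
    elapsed_s = max(recs$start_time)
  )
}

#' @export
print.run_accumulator <- function(x, ...) {
  lm <- latest_metrics(x)
  cat("<run_accumulator>\n")
  cat("  reads:", lm$n_reads, " yield:", format(lm$yield_bases, big.mark = ","),
      "bases  rejected:", sum(x$rejected), "\n")
  cat("  window:", x$config$window_width, "s  layout:", x$config$layout$name,
      paste0("(", x$config$layout$n_channels, " channels)"), "\n")
  invisible(x)
}
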