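# The periodic incremental engine: pull new records per run, update the
# accumulator, and atomically emit the per-run statistics files plus the
# registry.
#
# Per-run state (checkpoint + accumulator) is persisted under the output root
# so a minute-cadence poll costs only the newly appended lines, and a restart
# resumes exactly where the previous process stopped.

# The five per-run statistics files: four windowed/10-min series plus the
# read-length distribution.
EMITTED_FILES <- c("windowed.tsv", "cumulative.tsv", "channels.tsv",
                   "quality_time.tsv", "length_dist.tsv")

STATE_VERSION <- 1L

#' Watcher/emitter configuration
#'
#' All tunables of the preprocessing engine in one object. Defaults: 600 s
#' (10-minute) windows; 500 b length-histogram bins; 0.5 q-score bins; a 300
#' bases/second low-speed threshold (the vendor's recommended floor for the
#' translocation rate); pass threshold q >= 7; a 60 s poll interval.
#'
#' @param window_width elapsed-time slice width, seconds.
#' @param length_bin read-length histogram bin width, bases.
#' @param q_bin q-score histogram bin width.
#' @param low_speed_threshold window speed (bases/second) below which the
#'   low-speed flag is raised.
#' @param pass_q_threshold fallback pass/fail mean q-score threshold.
#' @param poll_interval seconds between polling cycles of [watch_runs()].
#' @param layout flowcell layout name (see [flowcell_layout()]).
#' @return An `emitter_config` list.
#' @export
emitter_config <- function(window_width = 600, length_bin = 500, q_bin = 0.5,
                           low_speed_threshold = 300, pass_q_threshold = 7,
                           poll_interval = 60, layout = "minion") {
  check_positive(window_width = window_width, length_bin = length_bin,
                 q_bin = q_bin, low_speed_threshold = low_speed_threshold,
                 poll_interval = poll_interval)
  stopifnot(pass_q_threshold >= 0)
  layout <- if (is.character(layout)) flowcell_layout(layout) else layout
  stopifnot(inherits(layout, "porewatch_layout"))
  structure(
    list(window_width = window_width, length_bin = length_bin, q_bin = q_bin,
         low_speed_threshold = low_speed_threshold,
         pass_q_threshold = pass_q_threshold, poll_interval = poll_interval,
         layout = layout),
    class = "emitter_config"
  )
}

accumulator_from_config <- function(cfg) {
  run_accumulator(window_width = cfg$window_width, length_bin = cfg$length_bin,
                  q_bin = cfg$q_bin,
                  low_speed_threshold = cfg$low_speed_threshold,
                  pass_q_threshold = cfg$pass_q_threshold, layout = cfg$layout)
}

config_fingerprint <- function(cfg) {
  list(window_width = cfg$window_width, length_bin = cfg$length_bin,
       q_bin = cfg$q_bin, low_speed_threshold = cfg$low_speed_threshold,
       pass_q_threshold = cfg$pass_q_threshold, layout = cfg$layout$name)
}

# Fingerprints survive a JSON round trip (integer vs double), so compare on a
# canonical character form.
same_fingerprint <- function(a, b) {
  identical(sort(names(a)), sort(names(b))) &&
    identical(vapply(a[sort(names(a))], as.character, character(1)),
              vapply(b[sort(names(b))], as.character, character(1)))
}

# State sidecars live under a hidden .state/ subdirectory, keeping the run's
# visible output directory to exactly the five statistics files.
state_paths <- function(out_dir) {
  list(meta = file.path(out_dir, ".state", "state.json"),
       records = file.path(out_dir, ".state", "records.tsv"))
}

# Persist checkpoint + accumulator. Records go to a TSV (readr's
# shortest-round-trip doubles restore bit-identical values); the JSON metadata
# is renamed into place last and acts as the commit point.
save_run_state <- function(acc, checkpoint, finalized, out_dir) {
  p <- state_paths(out_dir)
  write_tsv_atomic(acc$records, p$records)
  meta <- list(
    version = STATE_VERSION,
    config = config_fingerprint(acc$config),
    rejected = as.list(acc$rejected),
    n_records = nrow(acc$records),
    finalized = finalized,
    latest = as.list(latest_metrics(acc)),
    checkpoint = {
      x <- unclass(checkpoint)
      x$cmap <- cmap_to_list(x$cmap)
      x
    }
  )
  tmp <- tempfile(pattern = ".porewatch-", tmpdir = dirname(p$meta))
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  file.rename(tmp, p$meta)
  invisible(out_dir)
}

# Restore persisted state; NULL means "start fresh" (no state, a different
# configuration, or an inconsistent snapshot).
load_run_state <- function(out_dir, cfg) {
  p <- state_paths(out_dir)
  if (!file.exists(p$meta) || !file.exists(p$records)) return(NULL)
  meta <- tryCatch(jsonlite::read_json(p$meta, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta) || !identical(as.integer(meta$version), STATE_VERSION)) return(NULL)
  if (!same_fingerprint(meta$config, config_fingerprint(cfg))) return(NULL)
  records <- tryCatch(
    read_tsv_exact(p$records, c(
      read_id = "character", channel = "integer", start_time = "numeric",
      duration = "numeric", sequence_length = "numeric",
      mean_qscore = "numeric", passes_filtering = "logical"
    )),
    error = function(e) NULL
  )
  if (is.null(records) || nrow(records) != meta$n_records) return(NULL)

  acc <- accumulator_from_config(cfg)
  acc$records <- records
  acc$rejected[names(meta$rejected)] <- unlist(meta$rejected)
  cp <- zero_checkpoint()
  cp$byte_offset <- as.numeric(meta$checkpoint$byte_offset)
  cp$lines_consumed <- as.integer(meta$checkpoint$lines_consumed)
  cp$file_size <- as.numeric(meta$checkpoint$file_size)
  cp$first_line <- meta$checkpoint$first_line
  if (!is.null(meta$checkpoint$cmap)) {
    cp$cmap <- cmap_from_list(meta$checkpoint$cmap)
  }
  latest <- lapply(meta$latest, function(v) if (is.null(v)) NA_real_ else v)
  list(acc = acc, checkpoint = cp, finalized = isTRUE(meta$finalized),
       latest = as_tibble(latest))
}

# Emit the five per-run statistics files atomically.
emit_run_files <- function(acc, out_dir) {
  hist <- length_histogram(acc)
  hist <- if (nrow(hist)) percent_base_distribution(hist) else
    dplyr::mutate(hist, percent_bases = double())
  write_tsv_atomic(window_stats(acc), file.path(out_dir, "windowed.tsv"))
  write_tsv_atomic(cumulative_stats(acc), file.path(out_dir, "cumulative.tsv"))
  write_tsv_atomic(channel_stats(acc), file.path(out_dir, "channels.tsv"))
  write_tsv_atomic(quality_time_histogram(acc), file.path(out_dir, "quality_time.tsv"))
  write_tsv_atomic(hist, file.path(out_dir, "length_dist.tsv"))
  invisible(out_dir)
}

#' Process one run incrementally: read new records, emit statistics files
#'
#' Restores the run's persisted state (or starts fresh), reads only the newly
#' appended complete lines of its sequencing summary, updates the accumulator,
#' and rewrites the five per-run statistics files — `windowed.tsv`,
#' `cumulative.tsv`, `channels.tsv`, `quality_time.tsv`, `length_dist.tsv` —
#' each atomically, under `<output_root>/<run_id>/`. A completed run (its
#' `final_summary.txt` present) is processed one final time and skipped on
#' later calls. If the summary file was truncated or replaced, processing
#' restarts from scratch for that run.
#'
#' @param run one discovered run: a one-row tibble or list with `run_id`,
#'   `summary_path`, `status` (as returned by [scan_runs()]).
#' @param output_root directory under which per-run outputs and state live.
#' @param cfg an [emitter_config()].
#' @return Invisibly, a list: `run_id`, `status`, `skipped`, `reset`, `n_new`
#'   (newly accepted records), `latest` (one-row [latest_metrics()] tibble).
#' @export
process_run_once <- function(run, output_root, cfg = emitter_config()) {
  run <- as.list(run)
  out_dir <- file.path(output_root, run$run_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  state <- load_run_state(out_dir, cfg)
  if (!is.null(state) && state$finalized && identical(run$status, "completed")) {
    return(invisible(list(run_id = run$run_id, status = run$status,
                          skipped = TRUE, reset = FALSE, n_new = 0L,
                          latest = state$latest)))
  }
  acc <- if (is.null(state)) accumulator_from_config(cfg) else state$acc
  checkpoint <- if (is.null(state)) NULL else state$checkpoint

  res <- read_new_records(run$summary_path, checkpoint)
  if (res$reset) acc <- accumulator_from_config(cfg)
  acc <- acc_update(acc, res$records, res$rejected)

  emit_run_files(acc, out_dir)
  finalized <- identical(run$status, "completed")
  save_run_state(acc, res$checkpoint, finalized, out_dir)

  invisible(list(run_id = run$run_id, status = run$status, skipped = FALSE,
                 reset = res$reset, n_new = nrow(res$records),
                 latest = latest_metrics(acc)))
}

#' One preprocessing pass over every run under an input root
#'
#' Scans for runs, processes each one incrementally (a failure in one run is
#' logged and does not stop the others), and refreshes the `runs.tsv` registry
#' at the output root.
#'
#' @param input_root monitored directory containing run directories.
#' @param output_root output directory (created if needed).
#' @param cfg an [emitter_config()].
#' @param quiet suppress per-run progress messages.
#' @return The registry tibble (one row per discovered run), invisibly.
#' @export
prepare_runs <- function(input_root, output_root, cfg = emitter_config(),
                         quiet = TRUE) {
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  runs <- scan_runs(input_root)
  rows <- purrr::pmap(runs, function(run_id, run_dir, summary_path, status) {
    res <- tryCatch(
      process_run_once(list(run_id = run_id, summary_path = summary_path,
                            status = status), output_root, cfg),
      error = function(e) {
        warn(paste0("run ", run_id, " failed: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      return(tibble(run_id = run_id, status = status, n_reads = NA_integer_,
                    yield_bases = NA_real_, mean_length = NA_real_,
                    mean_qscore = NA_real_, last_speed = NA_real_))
    }
    if (!quiet) {
      inform(paste0(run_id, " [", status, "] +", res$n_new, " reads",
                    if (res$skipped) " (skipped, finalized)" else ""))
    }
    dplyr::bind_cols(tibble(run_id = run_id, status = status),
                     res$latest[c("n_reads", "yield_bases", "mean_length",
                                  "mean_qscore", "last_speed")])
  })
  registry <- dplyr::bind_rows(rows)
  if (!nrow(registry)) {
    registry <- tibble(run_id = character(), status = character(),
                       n_reads = integer(), yield_bases = double(),
                       mean_length = double(), mean_qscore = double(),
                       last_speed = double())
  }
  write_registry(registry, file.path(output_root, "runs.tsv"))
  invisible(registry)
}

#' Poll an input root and keep per-run statistics fresh
#'
#' Repeats [prepare_runs()] every `poll_interval` seconds: rescans for runs,
#' processes newly appended data, refreshes the registry. Completed runs are
#' processed once more after their `final_summary.txt` appears, then skipped.
#' Interrupting the loop is safe: state is persisted after every run update,
#' so a restart continues where the previous process stopped.
#'
#' @param input_root monitored directory.
#' @param output_root output directory.
#' @param cfg an [emitter_config()]; its `poll_interval` sets the cadence.
#' @param max_cycles stop after this many polling cycles (`Inf` to run until
#'   interrupted).
#' @param quiet suppress progress messages.
#' @return The last registry tibble, invisibly.
#' @export
watch_runs <- function(input_root, output_root, cfg = emitter_config(),
                       max_cycles = Inf, quiet = FALSE) {
  cycle <- 0
  registry <- NULL
  repeat {
    cycle <- cycle + 1
    registry <- prepare_runs(input_root, output_root, cfg, quiet = quiet)
    if (!quiet) {
      inform(paste0("cycle ", cycle, ": ", nrow(registry), " run(s), ",
                    sum(registry$status == "completed"), " completed"))
    }
    if (cycle >= max_cycles) break
    Sys.sleep(cfg$poll_interval)
  }
  invisible(registry)
}
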