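# Run discovery under a monitored input root, and the flowcell registry file.

# Registry column order is fixed: downstream dashboards key on it.
REGISTRY_COLUMNS <- c("run_id", "status", "n_reads", "yield_bases",
                      "mean_length", "mean_qscore", "last_speed", "last_updated")

# Turn a run directory path (relative to the input root) into a stable id.
sanitize_run_id <- function(relpath) {
  if (relpath %in% c(".", "")) return("root")
  id <- gsub("[/\\\\]+", "__", relpath)
  gsub("[^A-Za-z0-9._-]", "_", id)
}

#' Discover sequencing runs under an input root
#'
#' A run is any directory (the root itself included) containing a file whose
#' name starts with `sequencing_summary`; the scan is recursive. A run is
#' `completed` iff its directory also holds a `final_summary.txt` — the marker
#' the instrument writes when the experiment finishes — and `in_progress`
#' otherwise. A directory with only a `final_summary.txt` is not a run (there
#' is nothing to monitor); it is skipped with a warning.
#'
#' @param input_root directory to scan.
#' @return Tibble sorted by `run_id` with columns `run_id`, `run_dir`,
#'   `summary_path`, `status`.
#' @export
scan_runs <- function(input_root) {
  if (!dir.exists(input_root)) {
    abort(paste0("cannot read input directory: ", input_root),
          class = "porewatch_dir_unreadable")
  }
  summaries <- list.files(input_root, pattern = "^sequencing_summary",
                          recursive = TRUE, full.names = FALSE)
  finals <- list.files(input_root, pattern = "^final_summary\\.txt$",
                       recursive = TRUE, full.names = FALSE)
  sum_dirs <- dirname(summaries)
  orphan <- setdiff(dirname(finals), sum_dirs)
  if (length(orphan)) {
    warn(paste0("final_summary.txt without a sequencing summary in: ",
                paste(orphan, collapse = ", "), " (not a run, skipped)"))
  }
  if (!length(summaries)) {
    return(tibble(run_id = character(), run_dir = character(),
                  summary_path = character(), status = character()))
  }
  # one run per directory; with several summary files, take the first by name
  ord <- order(sum_dirs, basename(summaries), method = "radix")
  summaries <- summaries[ord]
  sum_dirs <- sum_dirs[ord]
  keep <- !duplicated(sum_dirs)
  summaries <- summaries[keep]
  sum_dirs <- sum_dirs[keep]

  run_dir <- ifelse(sum_dirs == ".", input_root, file.path(input_root, sum_dirs))
  completed <- file.exists(file.path(run_dir, "final_summary.txt"))
  out <- tibble(
    run_id = vapply(sum_dirs, sanitize_run_id, character(1), USE.NAMES = FALSE),
    run_dir = run_dir,
    summary_path = file.path(input_root, summaries),
    status = ifelse(completed, "completed", "in_progress")
  )
  dplyr::arrange(out, .data$run_id)
}

#' Write the flowcell registry file
#'
#' One TSV listing every discovered run with its status (completed or not) and
#' latest metrics snapshot; written atomically so a dashboard polling it never
#' sees a half-written table.
#'
#' @param registry tibble with columns `run_id`, `status`, `n_reads`,
#'   `yield_bases`, `mean_length`, `mean_qscore`, `last_speed` and optionally
#'   `last_updated` (filled with `last_updated` when absent).
#' @param path destination, conventionally `<output_root>/runs.tsv`.
#' @param last_updated timestamp string used for rows lacking one; defaults to
#'   the current UTC time.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path,
                           last_updated = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                                 tz = "UTC")) {
  if (!"last_updated" %in% names(registry)) {
    registry$last_updated <- rep(last_updated, nrow(registry))
  }
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(registry))
  if (length(missing_cols)) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "porewatch_bad_records")
  }
  write_tsv_atomic(registry[REGISTRY_COLUMNS], path)
}

#' Read a flowcell registry file
#'
#' @param path path to a registry written by [write_registry()].
#' @return Tibble with the registry columns.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path),
          class = "porewatch_missing_file")
  }
  read_tsv_exact(path, c(
    run_id = "character", status = "character", n_reads = "integer",
    yield_bases = "numeric", mean_length = "numeric", mean_qscore = "numeric",
    last_speed = "numeric", last_updated = "character"
  ))
}
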