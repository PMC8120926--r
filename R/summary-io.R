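# Reading guppy sequencing-summary and final-summary files, incrementally.
#
# A sequencing summary is a headered TSV appended by the basecaller while the
# run is in progress. The writer flushes per buffer, not per line, so the file
# routinely ends in a partial line; only newline-terminated lines are ever
# parsed, and a byte-offset checkpoint lets the next poll resume where the
# previous one stopped.

# Known guppy header spellings for each logical column. Column names changed
# across guppy versions ("sequence_length_template" vs "sequence_length");
# the first synonym found wins.
SUMMARY_COLUMN_SYNONYMS <- list(
  read_id         = c("read_id"),
  channel         = c("channel"),
  start_time      = c("start_time"),
  duration        = c("duration"),
  sequence_length = c("sequence_length_template", "sequence_length"),
  mean_qscore     = c("mean_qscore_template", "mean_qscore")
)

SUMMARY_OPTIONAL_SYNONYMS <- list(
  passes_filtering = c("passes_filtering"),
  run_id           = c("run_id")
)

#' Resolve a sequencing-summary header line to a column map
#'
#' Maps the six logical columns every downstream statistic needs (`read_id`,
#' `channel`, `start_time`, `duration`, `sequence_length`, `mean_qscore`) to
#' their positions in this file's header, tolerating the name variants used by
#' different guppy versions (e.g. `sequence_length_template`). Unknown extra
#' columns are ignored; the optional `passes_filtering` and `run_id` columns
#' are resolved when present.
#'
#' @param header_line the first line of a sequencing summary file (character
#'   scalar, tab-separated, without trailing newline).
#' @return A `porewatch_column_map`: a list with `idx` (named integer vector of
#'   1-based positions for the required logical columns), `optional` (same for
#'   optional columns, `NA` when absent) and `n_fields` (total column count of
#'   the header).
#' @examples
#' parse_summary_header(
#'   "read_id\tchannel\tstart_time\tduration\tsequence_length_template\tmean_qscore_template"
#' )
#' @export
parse_summary_header <- function(header_line) {
  stopifnot(is.character(header_line), length(header_line) == 1L)
  fields <- stringi::stri_split_fixed(header_line, "\t")[[1]]
  resolve <- function(synonyms) {
    hit <- which(fields %in% synonyms)
    if (length(hit)) hit[1L] else NA_integer_
  }
  idx <- vapply(SUMMARY_COLUMN_SYNONYMS, resolve, integer(1))
  if (anyNA(idx)) {
    missing <- names(idx)[is.na(idx)]
    abort(
      paste0("summary header is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "porewatch_missing_column",
      missing_columns = missing
    )
  }
  optional <- vapply(SUMMARY_OPTIONAL_SYNONYMS, resolve, integer(1))
  structure(
    list(idx = idx, optional = optional, n_fields = length(fields)),
    class = "porewatch_column_map"
  )
}

# Prototype of the accepted-records table; every reader and accumulator agrees
# on these columns and types.
empty_records <- function() {
  tibble(
    read_id          = character(),
    channel          = integer(),
    start_time       = double(),
    duration         = double(),
    sequence_length  = double(),
    mean_qscore      = double(),
    passes_filtering = logical()
  )
}

REJECT_REASONS <- c("bad_field_count", "non_numeric",
                    "nonpositive_duration", "negative_value")

zero_rejects <- function() setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)

#' Parse sequencing-summary data lines into read records
#'
#' Converts complete (already newline-terminated) non-header lines into typed
#' read records. A malformed line never raises an error: it is rejected with a
#' machine-readable reason so that monitoring survives writer glitches. Reasons
#' are `bad_field_count` (line does not have the header's column count),
#' `non_numeric` (a numeric field fails conversion, including non-integer
#' channel or length), `nonpositive_duration` (duration <= 0) and
#' `negative_value` (negative time/length/q-score or channel < 1).
#'
#' @param lines character vector of data lines (no trailing newlines).
#' @param cmap column map from [parse_summary_header()].
#' @return A list with `records` (tibble of accepted reads: `read_id`,
#'   `channel`, `start_time`, `duration`, `sequence_length`, `mean_qscore`,
#'   `passes_filtering` — `NA` where the file has no such column) and
#'   `rejected` (named integer vector of per-reason reject counts).
#' @examples
#' cmap <- parse_summary_header(
#'   "read_id\tchannel\tstart_time\tduration\tsequence_length\tmean_qscore")
#' parse_summary_records("r1\t5\t12.0\t2.5\t1000\t9.8", cmap)$records
#' @export
parse_summary_records <- function(lines, cmap) {
  stopifnot(inherits(cmap, "porewatch_column_map"))
  rejected <- zero_rejects()
  if (!length(lines)) {
    return(list(records = empty_records(), rejected = rejected))
  }

  n_fields <- stringi::stri_count_fixed(lines, "\t") + 1L
  ok <- n_fields == cmap$n_fields
  rejected[["bad_field_count"]] <- sum(!ok)
  lines <- lines[ok]
  if (!length(lines)) {
    return(list(records = empty_records(), rejected = rejected))
  }

  mat <- stringi::stri_split_fixed(lines, "\t", simplify = TRUE)
  col <- function(i) mat[, i, drop = TRUE]
  num <- function(i) suppressWarnings(as.numeric(col(i)))

  channel    <- num(cmap$idx[["channel"]])
  start_time <- num(cmap$idx[["start_time"]])
  duration   <- num(cmap$idx[["duration"]])
  seq_len    <- num(cmap$idx[["sequence_length"]])
  qscore     <- num(cmap$idx[["mean_qscore"]])

  non_numeric <- is.na(channel) | is.na(start_time) | is.na(duration) |
    is.na(seq_len) | is.na(qscore) |
    (!is.na(channel) & channel != trunc(channel)) |
    (!is.na(seq_len) & seq_len != trunc(seq_len))
  bad_duration <- !non_numeric & duration <= 0
  negative <- !non_numeric & !bad_duration &
    (start_time < 0 | seq_len < 0 | qscore < 0 | channel < 1)

  rejected[["non_numeric"]]          <- sum(non_numeric)
  rejected[["nonpositive_duration"]] <- sum(bad_duration)
  rejected[["negative_value"]]       <- sum(negative)

  keep <- !(non_numeric | bad_duration | negative)
  if (!any(keep)) {
    return(list(records = empty_records(), rejected = rejected))
  }

  pf_idx <- cmap$optional[["passes_filtering"]]
  passes <- if (is.na(pf_idx)) {
    rep(NA, sum(keep))
  } else {
    pf <- toupper(col(pf_idx)[keep])
    ifelse(pf == "TRUE", TRUE, ifelse(pf == "FALSE", FALSE, NA))
  }

  records <- tibble(
    read_id          = col(cmap$idx[["read_id"]])[keep],
    channel          = as.integer(channel[keep]),
    start_time       = start_time[keep],
    duration         = duration[keep],
    sequence_length  = seq_len[keep],
    mean_qscore      = qscore[keep],
    passes_filtering = as.logical(passes)
  )
  list(records = records, rejected = rejected)
}

#' The zero checkpoint: start reading a summary file from the top
#'
#' @return A `porewatch_checkpoint` positioned at byte 0 with no file
#'   signature and no resolved column map.
#' @export
zero_checkpoint <- function() {
  structure(
    list(byte_offset = 0, lines_consumed = 0L, file_size = 0,
         first_line = NULL, cmap = NULL),
    class = "porewatch_checkpoint"
  )
}

# Does the file still start with the remembered first line (followed by a
# newline or EOF)? A changed first line means the file was replaced.
first_line_matches <- function(path, first_line) {
  want <- charToRaw(first_line)
  n <- length(want)
  con <- file(path, open = "rb")
  on.exit(close(con))
  got <- readBin(con, "raw", n = n + 1L)
  if (length(got) < n) return(FALSE)
  if (!identical(got[seq_len(n)], want)) return(FALSE)
  length(got) == n || got[n + 1L] == as.raw(10L)
}

#' Read newly appended complete records from a growing summary file
#'
#' Seeks to the checkpoint's byte offset and consumes only complete,
#' newline-terminated lines; a trailing partial line (the basecaller flushes
#' per buffer, not per line) is left in place for the next call. The header is
#' parsed only when starting from offset 0; the resolved column map rides
#' along inside the checkpoint. If the file's signature (size shrink, or a
#' changed first line) indicates truncation or replacement, processing
#' restarts from offset 0 and the returned checkpoint carries `reset = TRUE`.
#'
#' @param path path to a sequencing summary file.
#' @param checkpoint a `porewatch_checkpoint` previously returned for this
#'   path, or `NULL` / [zero_checkpoint()] to start from the top.
#' @return A list: `records` (tibble of newly accepted reads), `rejected`
#'   (named reject counts for the new lines), `checkpoint` (advanced
#'   checkpoint, carrying the column map), `reset` (`TRUE` if a signature
#'   mismatch forced a restart from offset 0).
#' @seealso [parse_summary_records()] for the per-line semantics,
#'   [write_checkpoint()] to persist checkpoints between processes.
#' @export
read_new_records <- function(path, checkpoint = NULL) {
  if (is.null(checkpoint)) checkpoint <- zero_checkpoint()
  stopifnot(inherits(checkpoint, "porewatch_checkpoint"))
  size <- suppressWarnings(file.size(path))
  if (is.na(size)) {
    abort(paste0("cannot read summary file: ", path),
          class = "porewatch_file_unreadable")
  }

  reset <- FALSE
  if (checkpoint$byte_offset > 0) {
    intact <- size >= checkpoint$file_size &&
      !is.null(checkpoint$first_line) &&
      first_line_matches(path, checkpoint$first_line)
    if (!intact) {
      checkpoint <- zero_checkpoint()
      reset <- TRUE
    }
  }

  n_new <- size - checkpoint$byte_offset
  if (n_new <= 0) {
    checkpoint$file_size <- size
    return(list(records = empty_records(), rejected = zero_rejects(),
                checkpoint = checkpoint, reset = reset))
  }

  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = checkpoint$byte_offset, origin = "start")
  bytes <- readBin(con, "raw", n = n_new)

  newlines <- which(bytes == as.raw(10L))
  if (!length(newlines)) {
    # nothing but a partial line so far
    checkpoint$file_size <- size
    return(list(records = empty_records(), rejected = zero_rejects(),
                checkpoint = checkpoint, reset = reset))
  }
  consumed <- newlines[length(newlines)]
  txt <- rawToChar(bytes[seq_len(consumed - 1L)])  # drop final newline
  lines <- if (consumed == 1L) character() else
    stringi::stri_split_fixed(txt, "\n")[[1]]

  cmap <- checkpoint$cmap
  if (checkpoint$byte_offset == 0) {
    if (!length(lines)) {
      # a lone empty first line cannot be a header; wait for more bytes
      return(list(records = empty_records(), rejected = zero_rejects(),
                  checkpoint = checkpoint, reset = reset))
    }
    cmap <- parse_summary_header(lines[1L])
    checkpoint$first_line <- lines[1L]
    lines <- lines[-1L]
  }

  parsed <- parse_summary_records(lines, cmap)
  checkpoint$byte_offset <- checkpoint$byte_offset + consumed
  checkpoint$lines_consumed <- checkpoint$lines_consumed + length(lines) +
    as.integer(checkpoint$lines_consumed == 0L)
  checkpoint$file_size <- size
  checkpoint$cmap <- cmap

  list(records = parsed$records, rejected = parsed$rejected,
       checkpoint = checkpoint, reset = reset)
}

#' Parse a run's final_summary.txt marker file
#'
#' The instrument writes a small `key=value` file when a run finishes; its
#' presence is what marks an experiment as completed. Lines without `=` are
#' skipped with a warning; on duplicate keys the last value wins.
#'
#' @param path path to `final_summary.txt`.
#' @return Named character vector of key/value pairs (possibly empty — an
#'   empty file still counts as "present" for run status).
#' @export
parse_final_summary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read final summary file: ", path),
          class = "porewatch_file_unreadable")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  has_eq <- grepl("=", lines, fixed = TRUE)
  if (any(!has_eq)) {
    warn(paste0("skipping ", sum(!has_eq), " line(s) without '=' in ", path))
  }
  lines <- lines[has_eq]
  if (!length(lines)) return(setNames(character(), character()))
  eq <- regexpr("=", lines, fixed = TRUE)
  keys <- substr(lines, 1L, eq - 1L)
  vals <- substr(lines, eq + 1L, nchar(lines))
  out <- setNames(vals, keys)
  out[!duplicated(keys, fromLast = TRUE)][unique(keys)]
}

# JSON-safe forms of the column map (named atomic vectors lose their names in
# JSON; objects do not).
cmap_to_list <- function(cmap) {
  if (is.null(cmap)) return(NULL)
  list(idx = as.list(cmap$idx), optional = as.list(cmap$optional),
       n_fields = cmap$n_fields)
}

cmap_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  opt <- vapply(x$optional, function(v) if (is.null(v)) NA_integer_ else
    as.integer(v), integer(1))
  structure(
    list(idx = vapply(x$idx, as.integer, integer(1)),
         optional = opt,
         n_fields = as.integer(x$n_fields)),
    class = "porewatch_column_map"
  )
}

#' Persist or restore a checkpoint as a JSON sidecar
#'
#' @param checkpoint a `porewatch_checkpoint`.
#' @param path JSON file path.
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   returns the checkpoint, or `NULL` when the file does not exist.
#' @export
write_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "porewatch_checkpoint"))
  x <- unclass(checkpoint)
  x$cmap <- cmap_to_list(x$cmap)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".porewatch-", tmpdir = dirname(path))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) return(NULL)
  x <- jsonlite::read_json(path)
  cp <- zero_checkpoint()
  cp$byte_offset <- as.numeric(x$byte_offset)
  cp$lines_consumed <- as.integer(x$lines_consumed)
  cp$file_size <- as.numeric(x$file_size)
  cp$first_line <- x$first_line
  cp$cmap <- cmap_from_list(x$cmap)
  cp
}
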