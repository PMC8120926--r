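# Shared fixtures: tiny summary files and record tables built in code.

DEFAULT_HEADER <- paste("read_id", "channel", "start_time", "duration",
                        "sequence_length_template", "mean_qscore_template",
                        sep = "\t")

summary_line <- function(id, channel, start_time, duration, length, qscore) {
  paste(id, channel, start_time, duration, length, qscore, sep = "\t")
}

write_summary <- function(path, lines, header = DEFAULT_HEADER) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(header, lines), path, sep = "\n")
}

# A records tibble with sensible defaults, recycled to the longest argument.
rec_tbl <- function(start_time = 0, sequence_length = 1000, duration = 2.5,
                    mean_qscore = 10, channel = 1L, read_id = NULL,
                    passes_filtering = NA) {
  n <- max(lengths(list(start_time, sequence_length, duration, mean_qscore,
                        channel)))
  tibble::tibble(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    channel = as.integer(rep_len(channel, n)),
    start_time = as.numeric(rep_len(start_time, n)),
    duration = as.numeric(rep_len(duration, n)),
    sequence_length = as.numeric(rep_len(sequence_length, n)),
    mean_qscore = as.numeric(rep_len(mean_qscore, n)),
    passes_filtering = as.logical(rep_len(passes_filtering, n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accumulator preloaded with records.
acc_with <- function(records, ...) {
  acc_update(run_accumulator(...), records)
}

# Random record table for property-style checks (call under a fixed seed).
random_records <- function(n, max_time = 3000, n_channels = 512) {
  rec_tbl(
    start_time = runif(n, 0, max_time),
    sequence_length = sample(50:5000, n, replace = TRUE),
    duration = runif(n, 0.1, 20),
    mean_qscore = runif(n, 1, 20),
    channel = sample.int(n_channels, n, replace = TRUE),
    read_id = sprintf("rr%05d", seq_len(n))
  )
}

# Bytes of the five emitted statistics files for a run output directory.
emitted_bytes <- function(out_dir) {
  files <- c("windowed.tsv", "cumulative.tsv", "channels.tsv",
             "quality_time.tsv", "length_dist.tsv")
  lapply(stats::setNames(file.path(out_dir, files), files), function(p) {
    readBin(p, "raw", n = file.size(p))
  })
}
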