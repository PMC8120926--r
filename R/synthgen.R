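# Synthetic guppy-style sequencing runs with known ground truth.
#
# Durations are derived from read length and the instantaneous translocation
# speed at the read's start time (never sampled independently), so the speed
# signal the monitor is supposed to detect — exponential decay as reagents are
# consumed, step recovery at each refuel — genuinely exists in the data.
# Ground-truth numeric fields are re-parsed from the formatted file text, so
# ground truth equals exactly what any reader of the file sees.

#' Configuration of a synthetic sequencing run
#'
#' Defaults emulate a refueled long-read run on a 512-channel flowcell: reads
#' arrive homogeneously over 48 h; read lengths are log-normal (median 5 kb,
#' log-sd 1) truncated to \[50, 2e6\] bases; mean q-scores are normal(10, 1.5)
#' truncated to \[1, 30\]; the translocation speed starts at 400 bases/second
#' and decays exponentially at 0.05/hour, resetting to the base speed at each
#' refuel (defaults: 1200, 1650 and 2450 minutes, echoing a typical refueled
#' run). When `q_speed_coupling` is on (default), reads started while the
#' speed is below `q_coupling_threshold` lose `q_coupling_drop` q-score units
#' — the quality dip that accompanies reagent exhaustion.
#'
#' @param seed RNG seed; the generated file is a deterministic function of the
#'   full configuration.
#' @param n_reads number of reads.
#' @param run_duration_s run length in seconds.
#' @param n_channels channels on the flowcell (512 MinION-class, 3000
#'   PromethION-class); assignment is uniform.
#' @param length_meanlog,length_sdlog log-normal read-length parameters.
#' @param length_min,length_max truncation bounds, bases.
#' @param q_mean,q_sd,q_min,q_max truncated-normal mean q-score parameters.
#' @param q_speed_coupling couple q-scores to instantaneous speed?
#' @param q_coupling_threshold speed (b/s) below which quality drops.
#' @param q_coupling_drop q-score units lost below the threshold.
#' @param base_speed initial translocation speed, bases/second.
#' @param decay_per_hour exponential speed-decay rate per hour since the last
#'   refuel (0 for a constant-speed run).
#' @param refuel_times_s times (seconds) at which speed resets to
#'   `base_speed`; must lie within the run duration.
#' @param shuffle_fraction fraction of rows displaced from start-time order
#'   (real summaries are near-sorted, not guaranteed sorted).
#' @param passes_column write a `passes_filtering` column (pass iff q >= 7)?
#' @param write_final_summary write `final_summary.txt` (marking the run
#'   completed)?
#' @return A `synthetic_run_config` list.
#' @export
synthetic_run_config <- function(seed = 1L, n_reads = 10000L,
                                 run_duration_s = 172800,
                                 n_channels = 512L,
                                 length_meanlog = log(5000), length_sdlog = 1,
                                 length_min = 50, length_max = 2e6,
                                 q_mean = 10, q_sd = 1.5, q_min = 1, q_max = 30,
                                 q_speed_coupling = TRUE,
                                 q_coupling_threshold = 300,
                                 q_coupling_drop = 1,
                                 base_speed = 400, decay_per_hour = 0.05,
                                 refuel_times_s = c(1200, 1650, 2450) * 60,
                                 shuffle_fraction = 0,
                                 passes_column = TRUE,
                                 write_final_summary = TRUE) {
  check_positive(n_reads = n_reads, run_duration_s = run_duration_s,
                 n_channels = n_channels, length_sdlog = length_sdlog,
                 length_min = length_min, length_max = length_max,
                 q_sd = q_sd, base_speed = base_speed)
  bad <- !is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
    seed != trunc(seed) || abs(seed) >= 2^31
  if (bad) abort("`seed` must be a 32-bit integer", class = "porewatch_invalid_config")
  if (decay_per_hour < 0) {
    abort("`decay_per_hour` must be >= 0", class = "porewatch_invalid_config")
  }
  if (length_min >= length_max) {
    abort("`length_min` must be below `length_max`", class = "porewatch_invalid_config")
  }
  if (q_min >= q_max) {
    abort("`q_min` must be below `q_max`", class = "porewatch_invalid_config")
  }
  if (shuffle_fraction < 0 || shuffle_fraction > 1) {
    abort("`shuffle_fraction` must be in [0, 1]", class = "porewatch_invalid_config")
  }
  refuel_times_s <- sort(as.numeric(refuel_times_s))
  if (length(refuel_times_s) &&
      (any(refuel_times_s <= 0) || any(refuel_times_s >= run_duration_s))) {
    abort("`refuel_times_s` must lie strictly within the run duration",
          class = "porewatch_invalid_config")
  }
  structure(
    list(seed = as.integer(seed), n_reads = as.integer(n_reads),
         run_duration_s = run_duration_s, n_channels = as.integer(n_channels),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         length_min = length_min, length_max = length_max,
         q_mean = q_mean, q_sd = q_sd, q_min = q_min, q_max = q_max,
         q_speed_coupling = isTRUE(q_speed_coupling),
         q_coupling_threshold = q_coupling_threshold,
         q_coupling_drop = q_coupling_drop,
         base_speed = base_speed, decay_per_hour = decay_per_hour,
         refuel_times_s = refuel_times_s,
         shuffle_fraction = shuffle_fraction,
         passes_column = isTRUE(passes_column),
         write_final_summary = isTRUE(write_final_summary)),
    class = "synthetic_run_config"
  )
}

#' Instantaneous translocation speed of a synthetic run
#'
#' Closed form: `base_speed * exp(-decay_per_hour * h)` where `h` is hours
#' since the most recent refuel (or run start). Useful as the analytic
#' reference when checking recovered window speeds.
#'
#' @param config a [synthetic_run_config()].
#' @param t times in seconds since run start (vectorised).
#' @return Speeds in bases/second.
#' @export
speed_profile <- function(config, t) {
  stopifnot(inherits(config, "synthetic_run_config"))
  anchors <- c(0, config$refuel_times_s)
  last_refuel <- anchors[findInterval(t, anchors)]
  age_h <- (t - last_refuel) / 3600
  config$base_speed * exp(-config$decay_per_hour * age_h)
}

# Inverse-CDF sampling from a truncated distribution: exact truncation, one
# uniform draw per value.
rtrunc <- function(n, q_fun, p_fun, lower, upper, ...) {
  p <- runif(n, p_fun(lower, ...), p_fun(upper, ...))
  q_fun(p, ...)
}

#' Analytic mean and sd of the truncated log-normal length model
#'
#' @param config a [synthetic_run_config()].
#' @return List with `mean` and `sd` of the (pre-rounding) read-length
#'   distribution, in bases.
#' @export
length_model_moments <- function(config) {
  stopifnot(inherits(config, "synthetic_run_config"))
  mu <- config$length_meanlog; s <- config$length_sdlog
  al <- (log(config$length_min) - mu) / s
  be <- (log(config$length_max) - mu) / s
  z <- pnorm(be) - pnorm(al)
  m1 <- exp(mu + s^2 / 2) * (pnorm(be - s) - pnorm(al - s)) / z
  m2 <- exp(2 * mu + 2 * s^2) * (pnorm(be - 2 * s) - pnorm(al - 2 * s)) / z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# Generate the full file content (header + formatted data lines) and the
# matching ground-truth record table.
synth_content <- function(config) {
  n <- config$n_reads
  draws <- local_seed(config$seed, {
    t <- sort(runif(n, 0, config$run_duration_s))
    len <- round(rtrunc(n, qlnorm, plnorm, config$length_min, config$length_max,
                        meanlog = config$length_meanlog,
                        sdlog = config$length_sdlog))
    len <- pmin(pmax(len, config$length_min), config$length_max)
    q <- rtrunc(n, qnorm, pnorm, config$q_min, config$q_max,
                mean = config$q_mean, sd = config$q_sd)
    chan <- sample.int(config$n_channels, n, replace = TRUE)
    ord <- seq_len(n)
    if (config$shuffle_fraction > 0) {
      k <- max(2L, round(config$shuffle_fraction * n))
      idx <- sample.int(n, min(k, n))
      ord[sort(idx)] <- idx[sample.int(length(idx))]
    }
    list(t = t, len = len, q = q, chan = chan, ord = ord)
  })

  speed <- speed_profile(config, draws$t)
  q <- draws$q
  if (config$q_speed_coupling) {
    q <- q - config$q_coupling_drop * (speed < config$q_coupling_threshold)
    q <- pmin(pmax(q, config$q_min), config$q_max)
  }
  dur <- draws$len / speed

  run_hash <- sprintf("synthrun_%08x", bitwAnd(config$seed, 0x7fffffffL))
  read_id <- sprintf("%s-read-%06d", run_hash, seq_len(n))
  t_fmt <- sprintf("%.5f", draws$t)
  dur_fmt <- sprintf("%.5f", dur)
  q_fmt <- sprintf("%.3f", q)
  q_num <- as.numeric(q_fmt)
  passes <- q_num >= 7

  header_cols <- c("read_id", "run_id", "channel", "start_time", "duration",
                   "num_events", "sequence_length_template",
                   "mean_qscore_template")
  fields <- list(read_id, run_hash, draws$chan, t_fmt, dur_fmt,
                 as.integer(draws$len %/% 2L), format(draws$len, scientific = FALSE,
                                                      trim = TRUE), q_fmt)
  if (config$passes_column) {
    header_cols <- c(header_cols, "passes_filtering")
    fields <- c(fields, list(ifelse(passes, "TRUE", "FALSE")))
  }
  lines <- do.call(paste, c(fields, sep = "\t"))[draws$ord]

  records <- tibble(
    read_id = read_id,
    channel = as.integer(draws$chan),
    start_time = as.numeric(t_fmt),
    duration = as.numeric(dur_fmt),
    sequence_length = as.numeric(draws$len),
    mean_qscore = q_num,
    passes_filtering = if (config$passes_column) passes else rep(NA, n)
  )

  list(header = paste(header_cols, collapse = "\t"), lines = lines,
       records = records, run_hash = run_hash)
}

final_summary_lines <- function(config, content) {
  c(paste0("protocol_run_id=", content$run_hash),
    "instrument=synthetic",
    paste0("sample_id=synth_seed_", config$seed),
    paste0("acquisition_run_time=", config$run_duration_s))
}

#' Generate a synthetic sequencing run on disk
#'
#' Writes a guppy-style `sequencing_summary.txt` (headered TSV with the six
#' required columns plus realistic extras) and, unless disabled, a
#' `final_summary.txt` marking the run completed. Byte-identical on repeated
#' calls with the same configuration.
#'
#' @param config a [synthetic_run_config()].
#' @param dir run directory (created if needed).
#' @return A `synthetic_run` list: `summary_path`, `final_summary_path` (`NA`
#'   if not written), ground-truth `records` tibble, `totals` (`n_reads`,
#'   `yield_bases`), `analytic` length-model moments (see
#'   [length_model_moments()]) and the `config`.
#' @export
generate_run <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  content <- synth_content(config)
  summary_path <- file.path(dir, "sequencing_summary.txt")
  writeLines(c(content$header, content$lines), summary_path, sep = "\n")
  final_path <- NA_character_
  if (config$write_final_summary) {
    final_path <- file.path(dir, "final_summary.txt")
    writeLines(final_summary_lines(config, content), final_path, sep = "\n")
  }
  structure(
    list(summary_path = summary_path, final_summary_path = final_path,
         records = content$records,
         totals = list(n_reads = nrow(content$records),
                       yield_bases = sum(content$records$sequence_length)),
         analytic = length_model_moments(config),
         config = config),
    class = "synthetic_run"
  )
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat("<synthetic_run>", basename(dirname(x$summary_path)), "\n")
  cat("  reads:", x$totals$n_reads, " yield:",
      format(x$totals$yield_bases, big.mark = ","), "bases\n")
  cat("  base speed:", x$config$base_speed, "b/s  decay:",
      x$config$decay_per_hour, "/h  refuels:",
      if (length(x$config$refuel_times_s))
        paste(x$config$refuel_times_s / 60, collapse = ", ") else "none",
      "min\n")
  invisible(x)
}

#' Stream a synthetic run as incremental appends
#'
#' Emulates an in-progress run for the watcher: the same bytes
#' [generate_run()] would write are split into `n_chunks` appends at random
#' byte positions, so chunk boundaries routinely fall mid-line — the partial
#' trailing line a real basecaller leaves between buffer flushes, completed by
#' the next append. The final append drops `final_summary.txt` if the
#' configuration asks for one. Advancing the stream to exhaustion yields a
#' file byte-identical to a one-shot [generate_run()].
#'
#' @param config a [synthetic_run_config()].
#' @param dir run directory (created if needed).
#' @param n_chunks number of appends to split the file into.
#' @return A `run_stream`; advance it with [stream_step()], test it with
#'   [stream_done()]. Carries the same ground truth fields as a
#'   `synthetic_run`.
#' @export
stream_run <- function(config, dir, n_chunks = 5L) {
  stopifnot(inherits(config, "synthetic_run_config"), n_chunks >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  content <- synth_content(config)
  bytes <- charToRaw(paste0(paste(c(content$header, content$lines),
                                  collapse = "\n"), "\n"))
  n_cuts <- min(n_chunks - 1L, length(bytes) - 1L)
  cuts <- if (n_cuts > 0) {
    local_seed((config$seed %% 2147483640L) + 7L,
               sort(sample.int(length(bytes) - 1L, n_cuts)))
  } else integer()
  bounds <- c(0L, cuts, length(bytes))
  chunks <- lapply(seq_len(length(bounds) - 1L), function(i) {
    bytes[(bounds[i] + 1L):bounds[i + 1L]]
  })
  env <- new.env(parent = emptyenv())
  env$chunks <- chunks
  env$i <- 0L
  env$summary_path <- file.path(dir, "sequencing_summary.txt")
  env$dir <- dir
  env$config <- config
  env$content <- content
  env$records <- content$records
  env$totals <- list(n_reads = nrow(content$records),
                     yield_bases = sum(content$records$sequence_length))
  if (file.exists(env$summary_path)) unlink(env$summary_path)
  structure(env, class = "run_stream")
}

#' @rdname stream_run
#' @param stream a `run_stream`.
#' @return `stream_step()` appends the next chunk and returns `TRUE`, or
#'   returns `FALSE` when the stream is exhausted; `stream_done()` reports
#'   whether all chunks have been written.
#' @export
stream_step <- function(stream) {
  stopifnot(inherits(stream, "run_stream"))
  if (stream$i >= length(stream$chunks)) return(FALSE)
  stream$i <- stream$i + 1L
  con <- file(stream$summary_path, open = "ab")
  writeBin(stream$chunks[[stream$i]], con)
  close(con)
  if (stream$i == length(stream$chunks) && stream$config$write_final_summary) {
    writeLines(final_summary_lines(stream$config, stream$content),
               file.path(stream$dir, "final_summary.txt"), sep = "\n")
  }
  TRUE
}

#' @rdname stream_run
#' @export
stream_done <- function(stream) {
  stopifnot(inherits(stream, "run_stream"))
  stream$i >= length(stream$chunks)
}
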