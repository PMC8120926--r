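# Header resolution, record validation, and incremental checkpointed reading.

test_that("header columns resolve by name in any order, with guppy synonyms", {
  cmap <- parse_summary_header(DEFAULT_HEADER)
  expect_identical(
    cmap$idx,
    c(read_id = 1L, channel = 2L, start_time = 3L, duration = 4L,
      sequence_length = 5L, mean_qscore = 6L)
  )
  expect_identical(cmap$n_fields, 6L)

  reversed <- paste(rev(strsplit(DEFAULT_HEADER, "\t")[[1]]), collapse = "\t")
  rmap <- parse_summary_header(reversed)
  expect_identical(rmap$idx, setNames(7L - cmap$idx, names(cmap$idx)))

  # bare (non-_template) names and optional columns resolve too
  alt <- "run_id\tread_id\tchannel\tstart_time\tduration\tsequence_length\tmean_qscore\tpasses_filtering"
  amap <- parse_summary_header(alt)
  expect_identical(amap$idx[["sequence_length"]], 6L)
  expect_identical(amap$optional[["passes_filtering"]], 8L)

  # unknown extra columns are ignored
  extra <- paste0(DEFAULT_HEADER, "\tfilename\tnum_events")
  expect_identical(parse_summary_header(extra)$idx, cmap$idx)
})

test_that("a header lacking a required column names it in the error", {
  no_q <- "read_id\tchannel\tstart_time\tduration\tsequence_length_template"
  err <- expect_error(parse_summary_header(no_q),
                      class = "porewatch_missing_column")
  expect_match(conditionMessage(err), "mean_qscore")
  expect_identical(err$missing_columns, "mean_qscore")
})

test_that("record lines parse to typed records; malformed lines are counted, not fatal", {
  cmap <- parse_summary_header(DEFAULT_HEADER)
  good <- "r1\t5\t12.0\t2.5\t1000\t9.8"
  out <- parse_summary_records(good, cmap)
  expect_identical(out$records$channel, 5L)
  expect_identical(out$records$start_time, 12.0)
  expect_identical(out$records$duration, 2.5)
  expect_identical(out$records$sequence_length, 1000)
  expect_identical(out$records$mean_qscore, 9.8)
  expect_identical(sum(out$rejected), 0L)

  lines <- c(
    good,
    "r2\t5\t12.0\t0.0\t1000\t9.8",        # nonpositive duration
    "r3\t5\t12.0\t2.5\t1000",             # 5 fields vs 6 columns
    "r4\t5\tabc\t2.5\t1000\t9.8",         # non-numeric time
    "r5\t5\t-1.0\t2.5\t1000\t9.8",        # negative time
    "r6\t5\t12.0\t2.5\t10.5\t9.8"         # non-integer length
  )
  out <- parse_summary_records(lines, cmap)
  expect_identical(nrow(out$records), 1L)
  expect_identical(out$rejected[["nonpositive_duration"]], 1L)
  expect_identical(out$rejected[["bad_field_count"]], 1L)
  expect_identical(out$rejected[["non_numeric"]], 2L)
  expect_identical(out$rejected[["negative_value"]], 1L)
})

test_that("passes_filtering is parsed when present and NA otherwise", {
  hdr <- paste0(DEFAULT_HEADER, "\tpasses_filtering")
  cmap <- parse_summary_header(hdr)
  out <- parse_summary_records(
    c("r1\t1\t0\t1\t100\t8\tTRUE", "r2\t1\t0\t1\t100\t8\tFALSE"), cmap)
  expect_identical(out$records$passes_filtering, c(TRUE, FALSE))

  out2 <- parse_summary_records("r1\t1\t0\t1\t100\t8",
                                parse_summary_header(DEFAULT_HEADER))
  expect_identical(out2$records$passes_filtering, NA)
})

test_that("a complete file reads in one pass and the checkpoint lands at EOF", {
  path <- withr::local_tempfile(fileext = ".txt")
  lines <- sapply(1:3, function(i) summary_line(paste0("r", i), i, i * 10, 1, 100 * i, 9))
  write_summary(path, lines)
  out <- read_new_records(path)
  expect_identical(nrow(out$records), 3L)
  expect_identical(out$checkpoint$byte_offset, as.numeric(file.size(path)))
  expect_identical(out$checkpoint$lines_consumed, 4L)  # header + 3
  expect_false(out$reset)
})

test_that("a trailing partial line is deferred until its newline arrives", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_summary(path, summary_line("r1", 1, 0, 1, 100, 9))
  out1 <- read_new_records(path)
  offset1 <- out1$checkpoint$byte_offset

  # append a partial line (no newline): nothing new, offset unchanged
  cat("r4\t7\t30.0\t1.0\t50", file = path, append = TRUE)
  out2 <- read_new_records(path, out1$checkpoint)
  expect_identical(nrow(out2$records), 0L)
  expect_identical(out2$checkpoint$byte_offset, offset1)

  # completing the line yields exactly that one record
  cat("\t8.5\n", file = path, append = TRUE)
  out3 <- read_new_records(path, out2$checkpoint)
  expect_identical(nrow(out3$records), 1L)
  expect_identical(out3$records$read_id, "r4")
  expect_identical(out3$records$mean_qscore, 8.5)

  # oracle: incremental reads concatenated equal a one-shot parse
  oneshot <- read_new_records(path)
  expect_equal(dplyr::bind_rows(out1$records, out2$records, out3$records),
               oneshot$records)
})

test_that("truncation or replacement triggers a reset and a clean re-read", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_summary(path, c(summary_line("r1", 1, 0, 1, 100, 9),
                        summary_line("r2", 2, 5, 1, 200, 9)))
  out1 <- read_new_records(path)
  expect_identical(nrow(out1$records), 2L)

  # truncate back to the header only
  write_summary(path, character())
  out2 <- read_new_records(path, out1$checkpoint)
  expect_true(out2$reset)
  expect_identical(nrow(out2$records), 0L)

  # regrow: records re-emitted from scratch
  write_summary(path, summary_line("r9", 3, 1, 1, 400, 10))
  out3 <- read_new_records(path, out2$checkpoint)
  expect_identical(out3$records$read_id, "r9")

  # replacement with a different header (same size class) also resets
  write_summary(path, summary_line("r1", 1, 0, 1, 100, 9),
                header = paste0(DEFAULT_HEADER, "\tx"))
  out4 <- read_new_records(path, out1$checkpoint)
  expect_true(out4$reset)
})

test_that("chunked reads equal a one-shot parse for any growth partition", {
  lines <- sapply(1:40, function(i)
    summary_line(sprintf("r%02d", i), i %% 8 + 1, i * 3.5, 0.5 + i %% 3,
                 50 * i, 5 + (i %% 10) / 2))
  full <- paste0(paste(c(DEFAULT_HEADER, lines), collapse = "\n"), "\n")
  bytes <- charToRaw(full)

  oneshot_path <- withr::local_tempfile(fileext = ".txt")
  writeBin(bytes, oneshot_path)
  oneshot <- read_new_records(oneshot_path)$records
  # independent oracle: a standard TSV reader on the finished file
  oracle <- readr::read_tsv(oneshot_path, show_col_types = FALSE)
  expect_identical(oneshot$start_time, oracle$start_time)
  expect_identical(oneshot$sequence_length, as.numeric(oracle$sequence_length_template))

  set.seed(101)
  for (k in c(1, 2, 5, 9)) {
    path <- tempfile(fileext = ".txt")
    cuts <- sort(sample.int(length(bytes) - 1L, k))
    bounds <- c(0L, cuts, length(bytes))
    cp <- NULL
    got <- list()
    offsets <- numeric()
    for (i in seq_len(length(bounds) - 1L)) {
      con <- file(path, open = "ab")
      writeBin(bytes[(bounds[i] + 1L):bounds[i + 1L]], con)
      close(con)
      res <- read_new_records(path, cp)
      expect_false(res$reset)
      cp <- res$checkpoint
      got[[i]] <- res$records
      offsets <- c(offsets, cp$byte_offset)
    }
    expect_true(all(diff(offsets) >= 0))  # offset monotonicity
    expect_equal(dplyr::bind_rows(got), oneshot)
    unlink(path)
  }
})

test_that("checkpoints survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_summary(path, summary_line("r1", 1, 0, 1, 100, 9))
  out <- read_new_records(path)
  cp_path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(out$checkpoint, cp_path)
  cp <- read_checkpoint(cp_path)
  expect_identical(cp$byte_offset, out$checkpoint$byte_offset)
  expect_identical(cp$first_line, out$checkpoint$first_line)
  expect_identical(cp$cmap$idx, out$checkpoint$cmap$idx)

  # resuming from the restored checkpoint sees only new data
  cat(summary_line("r2", 2, 5, 1, 200, 9), "\n", sep = "", file = path,
      append = TRUE)
  res <- read_new_records(path, cp)
  expect_identical(res$records$read_id, "r2")
  expect_null(read_checkpoint(withr::local_tempfile()))
})

test_that("final_summary parsing tolerates junk lines and empty files", {
  p <- withr::local_tempfile()
  writeLines(c("instrument=PC24B", "sample_id=s1"), p)
  expect_identical(parse_final_summary(p),
                   c(instrument = "PC24B", sample_id = "s1"))

  writeLines(character(), p)
  expect_identical(length(parse_final_summary(p)), 0L)

  writeLines(c("instrument=PC24B", "garbage", "k=v=w"), p)
  expect_warning(fs <- parse_final_summary(p), "without '='")
  expect_identical(fs[["instrument"]], "PC24B")
  expect_identical(fs[["k"]], "v=w")  # split at the first '='

  expect_error(parse_final_summary(file.path(tempdir(), "nope.txt")),
               class = "porewatch_file_unreadable")
})
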