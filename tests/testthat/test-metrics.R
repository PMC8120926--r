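# Windowed, cumulative, per-channel and distributional statistics.

test_that("window binning is half-open with floor semantics", {
  expect_identical(window_index(0.0, 600), 0L)
  expect_identical(window_index(599.999, 600), 0L)
  expect_identical(window_index(600.0, 600), 1L)
  expect_identical(window_index(1250.0, 600), 2L)
  expect_identical(window_index(c(0, 600, 1250), 600), c(0L, 1L, 2L))
})

test_that("window statistics match hand arithmetic", {
  recs <- rec_tbl(start_time = c(10, 20, 30),
                  sequence_length = c(1000, 2000, 3000),
                  duration = c(2.5, 5.0, 7.5),
                  mean_qscore = c(8, 9, 10), channel = 7L)
  acc <- acc_with(recs)
  ws <- window_stats(acc)
  expect_identical(nrow(ws), 1L)
  expect_identical(ws$n_reads, 3L)
  expect_identical(ws$yield_bases, 6000)
  expect_identical(ws$mean_length, 2000)
  expect_identical(ws$median_length, 2000)
  expect_identical(ws$mean_qscore, 9)
  expect_identical(ws$speed, 6000 / 15.0)  # 400 b/s
  expect_false(ws$low_speed_flag)          # threshold 300

  acc500 <- acc_with(recs, low_speed_threshold = 500)
  expect_true(window_stats(acc500)$low_speed_flag)

  # per-channel view of the same three reads
  cs <- channel_stats(acc)
  expect_identical(cs$n_reads[cs$channel == 7L], 3L)
  expect_identical(sum(cs$n_reads), 3L)

  # latest snapshot
  lm <- latest_metrics(acc)
  expect_identical(lm$n_reads, 3L)
  expect_identical(lm$yield_bases, 6000)
  expect_identical(lm$last_speed, 400)
})

test_that("empty accumulators yield empty/zero outputs", {
  acc <- run_accumulator()
  expect_identical(nrow(window_stats(acc)), 0L)
  expect_identical(nrow(cumulative_stats(acc)), 0L)
  expect_identical(nrow(length_histogram(acc)), 0L)
  expect_identical(nrow(quality_time_histogram(acc)), 0L)
  expect_identical(sum(channel_stats(acc)$n_reads), 0L)
  lm <- latest_metrics(acc)
  expect_identical(lm$n_reads, 0L)
  expect_identical(lm$yield_bases, 0)
  expect_true(is.na(lm$last_speed))
  expect_error(percent_base_distribution(length_histogram(acc)),
               class = "porewatch_empty_run")
})

test_that("update order never changes any finalized statistic", {
  set.seed(7)
  recs <- random_records(400, max_time = 4000)
  sorted <- dplyr::arrange(recs, start_time)
  shuffled <- recs[sample.int(nrow(recs)), ]

  a <- acc_with(sorted)
  b <- acc_with(shuffled)
  # and a third built from three unequal batches, merged pairwise
  parts <- split(shuffled, rep(1:3, length.out = nrow(shuffled)))
  c3 <- acc_merge(acc_merge(acc_with(parts[[2]]), acc_with(parts[[1]])),
                  acc_with(parts[[3]]))

  for (other in list(b, c3)) {
    expect_identical(window_stats(a), window_stats(other))
    expect_identical(cumulative_stats(a), cumulative_stats(other))
    expect_identical(channel_stats(a), channel_stats(other))
    expect_identical(length_histogram(a), length_histogram(other))
    expect_identical(quality_time_histogram(a), quality_time_histogram(other))
  }
})

test_that("incremental updates equal one-shot batch computation", {
  set.seed(11)
  recs <- random_records(300, max_time = 2500)
  batch <- acc_with(recs)
  inc <- run_accumulator()
  for (part in split(recs, rep(1:5, length.out = nrow(recs)))) {
    inc <- acc_update(inc, part)
  }
  expect_identical(window_stats(batch), window_stats(inc))
  expect_identical(cumulative_stats(batch), cumulative_stats(inc))
})

test_that("cumulative series are running sums with pooled means and medians", {
  # four windows with yields 100, 50, 0, 25
  recs <- rec_tbl(start_time = c(10, 650, 1900),
                  sequence_length = c(100, 50, 25))
  cum <- cumulative_stats(acc_with(recs))
  expect_identical(cum$yield_bases, c(100, 150, 150, 175))
  expect_true(all(diff(cum$yield_bases) >= 0))

  # pooled mean, not mean of window means: (2x2000 then 2x1000) -> 1500
  recs2 <- rec_tbl(start_time = c(0, 10, 600, 610),
                   sequence_length = c(2000, 2000, 1000, 1000))
  cum2 <- cumulative_stats(acc_with(recs2))
  expect_identical(cum2$mean_length, c(2000, 1500))
  # run-to-date median over the pooled multiset
  expect_identical(cum2$median_length, c(2000, 1500))

  # single window: cumulative equals windowed
  one <- acc_with(rec_tbl(start_time = c(1, 2), sequence_length = c(10, 30)))
  expect_identical(cumulative_stats(one)$yield_bases,
                   window_stats(one)$yield_bases)
})

test_that("empty windows are emitted explicitly with NA metrics", {
  recs <- rec_tbl(start_time = c(10, 1900), sequence_length = c(100, 25))
  ws <- window_stats(acc_with(recs))
  expect_identical(ws$window_index, 0:3)
  expect_identical(ws$t_start, c(0, 600, 1200, 1800))
  expect_identical(ws$n_reads, c(1L, 0L, 0L, 1L))
  expect_identical(ws$yield_bases, c(100, 0, 0, 25))
  expect_true(all(is.na(ws$speed[2:3])))
  expect_true(all(is.na(ws$low_speed_flag[2:3])))
})

test_that("length histogram bins by floor(L/width) and tracks reads and bases", {
  acc <- acc_with(rec_tbl(sequence_length = c(100, 450, 600)))
  h <- length_histogram(acc)
  expect_identical(h$bin_index, c(0L, 1L))
  expect_identical(h$read_count, c(2L, 1L))
  expect_identical(h$base_count, c(550, 600))

  p <- percent_base_distribution(h)
  expect_equal(p$percent_bases, 100 * c(550, 600) / 1150)  # 47.83 / 52.17
  expect_equal(sum(p$percent_bases), 100, tolerance = 1e-12)

  single <- percent_base_distribution(
    length_histogram(acc_with(rec_tbl(sequence_length = 777))))
  expect_identical(single$percent_bases, 100)
})

test_that("quality-time histogram floors q into bins and conserves reads", {
  acc <- acc_with(rec_tbl(mean_qscore = c(6.9, 7.0, 7.4)))
  qt <- quality_time_histogram(acc)
  expect_identical(qt$q_bin, c(13L, 14L))
  expect_identical(qt$n_reads, c(1L, 2L))

  # all reads identical -> a single nonzero cell
  same <- quality_time_histogram(acc_with(rec_tbl(mean_qscore = rep(9.1, 5))))
  expect_identical(nrow(same), 1L)
  expect_identical(same$n_reads, 5L)

  set.seed(3)
  big <- quality_time_histogram(acc_with(random_records(1000)))
  expect_identical(sum(big$n_reads), 1000L)
})

test_that("reads and bases are conserved across all three decompositions", {
  set.seed(23)
  for (n in c(1L, 57L, 800L)) {
    recs <- random_records(n, max_time = 5000)
    acc <- acc_with(recs)
    total_bases <- sum(recs$sequence_length)
    expect_identical(sum(window_stats(acc)$yield_bases), total_bases)
    expect_identical(sum(channel_stats(acc)$yield_bases), total_bases)
    expect_identical(sum(length_histogram(acc)$base_count), total_bases)
    expect_identical(sum(window_stats(acc)$n_reads), n)
    expect_identical(sum(channel_stats(acc)$n_reads), n)
    expect_identical(sum(length_histogram(acc)$read_count), n)
    expect_identical(sum(quality_time_histogram(acc)$n_reads), n)
  }
})

test_that("window speed lies between the per-read speed extremes", {
  set.seed(31)
  recs <- random_records(500, max_time = 6000)
  recs$w <- window_index(recs$start_time, 600)
  ws <- window_stats(acc_with(recs))
  per_read <- split(recs$sequence_length / recs$duration, recs$w)
  for (w in names(per_read)) {
    s <- ws$speed[ws$window_index == as.integer(w)]
    expect_gte(s, min(per_read[[w]]) - 1e-9)
    expect_lte(s, max(per_read[[w]]) + 1e-9)
  }
})

test_that("out-of-layout channels land in the overflow bucket, conserved", {
  recs <- rec_tbl(channel = c(5L, 513L, 600L), sequence_length = c(10, 20, 30))
  expect_warning(acc <- acc_with(recs), "overflow")
  cs <- channel_stats(acc)
  over <- cs[is.na(cs$channel), ]
  expect_identical(over$n_reads, 2L)
  expect_identical(over$yield_bases, 50)
  expect_identical(sum(cs$n_reads), 3L)
  expect_true(is.na(over$grid_row))
})

test_that("pass/fail classification is inclusive at the threshold and the column wins", {
  expect_true(classify_pass(rec_tbl(mean_qscore = 7.0)))
  expect_false(classify_pass(rec_tbl(mean_qscore = 6.99)))
  # explicit verdict beats the threshold rule
  expect_false(classify_pass(rec_tbl(mean_qscore = 12, passes_filtering = FALSE)))
  expect_true(classify_pass(rec_tbl(mean_qscore = 2, passes_filtering = TRUE)))
  # custom threshold
  expect_true(classify_pass(rec_tbl(mean_qscore = 5), q_threshold = 5))
})

test_that("latest metrics track the newest nonempty window", {
  acc <- acc_with(rec_tbl(start_time = 10, sequence_length = 4000, duration = 10))
  expect_identical(latest_metrics(acc)$last_speed, 400)
  acc <- acc_update(acc, rec_tbl(start_time = 1300, sequence_length = 900,
                                 duration = 3, read_id = "later"))
  lm <- latest_metrics(acc)
  expect_identical(lm$last_speed, 300)
  expect_identical(lm$elapsed_s, 1300)
})

test_that("channel grids map row-major for both flowcell classes", {
  minion <- flowcell_layout("minion")
  expect_identical(minion$n_channels, 512L)
  prom <- flowcell_layout("promethion")
  expect_identical(prom$n_channels, 3000L)
  expect_identical(prom$n_rows * prom$n_cols, prom$n_channels)

  cs <- channel_stats(run_accumulator(layout = prom))
  expect_identical(nrow(cs), 3000L)
  # injective mapping over the grid
  expect_false(any(duplicated(cs[, c("grid_row", "grid_col")])))
  expect_identical(cs$grid_row[cs$channel == 101L], 2L)
  expect_identical(cs$grid_col[cs$channel == 101L], 1L)
})

test_that("tidy/glance/autoplot expose the accumulator broom-style", {
  acc <- acc_with(rec_tbl(start_time = c(1, 700), sequence_length = c(100, 200)))
  expect_identical(tidy(acc), window_stats(acc))
  expect_identical(tidy(acc, cumulative = TRUE), cumulative_stats(acc))
  g <- glance(acc)
  expect_identical(g$n_reads, 2L)
  expect_identical(g$n_rejected, 0L)
  expect_s3_class(autoplot(acc), "ggplot")
  expect_s3_class(plot_channel_grid(channel_stats(acc)), "ggplot")
  expect_s3_class(plot_quality_time(quality_time_histogram(acc)), "ggplot")
  expect_s3_class(
    plot_length_dist(percent_base_distribution(length_histogram(acc)),
                     "percent_bases"),
    "ggplot")
})
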