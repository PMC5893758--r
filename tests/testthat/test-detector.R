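# piecewise-constant stream with abrupt level shifts; the short head keeps the
# martingale near 1 when the first shift arrives, so alarms fire at modest
# thresholds
make_jump_stream <- function() {
  x <- c(rep(1, 15), rep(50, 30), rep(1, 30), rep(50, 30), rep(1, 30))
  signal_stream(x, sampling_rate = 512, stream_id = "piecewise")
}

test_that("an unreachable threshold yields no changes but a full trace", {
  s <- gen_null_stream(200, seed = 15)
  fit <- detect_changes(s, lambda = 1e6, seed = 1)
  expect_s3_class(fit, "change_detection")
  expect_equal(nrow(fit$changes), 0)
  expect_equal(nrow(fit$trace), 200 - 5 + 1)
  expect_equal(fit$n_scores, 196)
  expect_true(all(fit$trace$segment == 1L))
  expect_equal(fit$trace$score_index, 0:195)
  expect_equal(fit$trace$decimated_index, 4:199)
})

test_that("detection is deterministic under stream + config + seed", {
  s <- make_jump_stream()
  f1 <- detect_changes(s, lambda = 1.5, seed = 1)
  f2 <- detect_changes(s, lambda = 1.5, seed = 1)
  expect_identical(f1$changes, f2$changes)
  expect_identical(f1$trace, f2$trace)
})

test_that("the anomaly score peaks at the first level shift", {
  fit <- detect_changes(make_jump_stream(), lambda = 1e6, seed = 1)
  # shift at sample 15: first window containing it emits score index 15 - (L-1)
  peak <- fit$trace$score_index[which.max(fit$trace$s)]
  expect_gte(peak, 11)
  expect_lte(peak, 15)
})

test_that("alarms respect the threshold, burn-in spacing and reset the pipeline", {
  fit <- detect_changes(make_jump_stream(), lambda = 1.5, seed = 1)
  expect_gte(nrow(fit$changes), 2)
  expect_true(all(fit$changes$martingale_value >= 1.5))

  # alarms are at least burn_in scores apart (reset spacing invariant)
  expect_true(all(diff(fit$changes$score_index) >= fit$config$burn_in))
  expect_gte(fit$changes$score_index[1] + 1, fit$config$burn_in)

  # immediately after each alarm the residual chain restarts from scratch
  tr <- fit$trace
  for (k in seq_len(nrow(fit$changes))) {
    t_next <- fit$changes$score_index[k] + 1L  # 0-based -> next score
    row <- tr[tr$score_index == t_next, ]
    if (nrow(row) == 1) {
      expect_equal(c(row$e, row$z, row$s), c(0, 0, 0))
      expect_equal(row$segment, k + 1L)
    }
  }
  # segment labels partition the trace at the alarm indices
  expect_equal(max(tr$segment), nrow(fit$changes) + 1L)
  expect_true(all(diff(tr$segment) %in% c(0L, 1L)))
})

test_that("coordinate systems are consistent across decimation", {
  # the same piecewise shape at 10x the raw rate, decimated back down
  x <- c(rep(1, 150), rep(50, 300), rep(1, 300), rep(50, 300), rep(1, 300))
  s <- signal_stream(x, sampling_rate = 512, stream_id = "piecewise-raw")
  fit <- detect_changes(s, lambda = 1.5, decimate = 10, seed = 1)
  ch <- fit$changes
  expect_gte(nrow(ch), 1)
  expect_equal(ch$decimated_index, ch$score_index + (fit$config$L - 1L))
  expect_equal(ch$original_index, ch$decimated_index * 10L)
  expect_equal(fit$config$decimation_factor, 10L)
  # decimated stream is sample-identical to the short fixture
  expect_identical(ch$score_index,
                   detect_changes(make_jump_stream(), lambda = 1.5,
                                  seed = 1)$changes$score_index)
})

test_that("detect_changes validates its inputs", {
  s <- gen_null_stream(50, seed = 1)
  expect_error(detect_changes(s, lambda = 1), "> 1")
  expect_error(detect_changes(gen_null_stream(4, seed = 1), L = 5),
               "too short")
  expect_error(detect_changes(rnorm(100)), "signal_stream")
})

test_that("tidy, glance and print expose the expected structure", {
  fit <- detect_changes(make_jump_stream(), lambda = 1.5, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("stream_id", "score_index", "decimated_index",
                     "original_index", "martingale_value"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_changes, nrow(fit$changes))
  expect_equal(gl$lambda, 1.5)
  expect_equal(gl$max_martingale, max(fit$trace$M))
  expect_output(print(fit), "change_detection")
})

test_that("autoplot returns a ggplot without evaluating errors", {
  fit <- detect_changes(make_jump_stream(), lambda = 1.5, seed = 1)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})

test_that("lambda_sweep evaluates each threshold once with shared seeds", {
  g1 <- gen_concatenated_stream(
    segment_spec(750, "iid-gaussian", noise_sd = 0.1),
    segment_spec(500, "iid-gaussian", mean = 50, noise_sd = 0.1),
    seed = 23, stream_id = "sw1"
  )
  g2 <- gen_concatenated_stream(
    segment_spec(750, "iid-gaussian", noise_sd = 0.1),
    segment_spec(500, "iid-gaussian", mean = 50, noise_sd = 0.1),
    seed = 29, stream_id = "sw2"
  )
  truth <- dplyr::bind_rows(g1$truth, g2$truth)
  grid <- seq(2, 9, by = 0.5)
  sw <- lambda_sweep(list(g1$stream, g2$stream), truth,
                     lambda_grid = grid, tolerance = 20, seed = 1)
  expect_equal(nrow(sw), 15)
  expect_equal(sw$lambda, grid)
  expect_named(sw, c("lambda", "N", "N_g", "n_m",
                     "precision", "recall", "f_score"))
  expect_true(all(sw$N_g == 2))

  expect_error(lambda_sweep(g1$stream, g2$truth), "No ground truth")
  expect_error(lambda_sweep(g1$stream, g1$truth, lambda_grid = numeric(0)),
               "empty")
})
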