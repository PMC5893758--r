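observe <- function(state, q) {
  step <- rpmdetect:::observe_feature(state, q)
  step$state
}

test_that("prediction is the running segment mean", {
  st <- new_anomaly_state()
  expect_error(predict_feature(st), "before the first")
  st <- observe(st, 2)
  expect_equal(predict_feature(st), 2)
  st <- observe(st, 1); st <- observe(st, 3)
  # mean of 2, 1, 3
  expect_equal(predict_feature(st), 2)
  st2 <- new_anomaly_state()
  for (i in 1:100) st2 <- observe(st2, 5.5)
  expect_equal(predict_feature(st2), 5.5)
})

test_that("prediction error is the absolute difference", {
  expect_equal(prediction_error(3, 1), 2)
  expect_equal(prediction_error(4.2, 4.2), 0)
  expect_equal(prediction_error(-1, 2), 3)
  expect_equal(prediction_error(-1, 2), prediction_error(2, -1))
})

test_that("standardization uses prior running statistics with warm-up conventions", {
  # constant error history, matching e_t: zero numerator
  st <- new_anomaly_state()
  for (i in 1:5) st <- standardize_error(st, 1)$state
  expect_equal(standardize_error(st, 1)$z, 0)

  # known statistics: history mean 1, population sd 2 (values -1 and 3)
  st <- new_anomaly_state()
  st <- standardize_error(st, -1)$state
  st <- standardize_error(st, 3)$state
  expect_equal(standardize_error(st, 5)$z, 2)

  # first error after reset: no prior statistics
  expect_equal(standardize_error(new_anomaly_state(), 0.7)$z, 0)
})

test_that("strangeness is the distance to the running residual mean", {
  st <- new_anomaly_state()
  st <- anomaly_score(st, 0)$state
  st <- anomaly_score(st, 0)$state
  expect_equal(anomaly_score(st, 0)$s, 0)

  st <- new_anomaly_state()
  st <- anomaly_score(st, 1)$state
  st <- anomaly_score(st, 2)$state
  expect_equal(anomaly_score(st, 4)$s, 2.5)  # |4 - mean(1, 2)|

  expect_equal(anomaly_score(new_anomaly_state(), 3.3)$s, 0)
})

test_that("score_stream is causal, non-negative and aligned", {
  expect_error(score_stream(numeric(0)), "empty")

  sc <- score_stream(rep(2.5, 40))
  expect_equal(sc$s, rep(0, 40))
  expect_equal(sc$e, rep(0, 40))

  set.seed(41)
  q <- rnorm(120)
  full <- score_stream(q)
  expect_equal(nrow(full), 120)
  expect_true(all(full$s >= 0))
  for (t in c(1, 7, 63)) {
    expect_equal(score_stream(q[seq_len(t)])$s, full$s[seq_len(t)])
  }
})

test_that("a large level jump produces its maximum score at or just after the jump", {
  set.seed(43)
  q <- c(rnorm(80, sd = 0.2), rnorm(40, mean = 8, sd = 0.2))
  sc <- score_stream(q)
  j <- which.max(sc$s)
  expect_gte(j, 81)
  expect_lte(j, 85)
})

test_that("running statistics equal their batch definitions over the segment", {
  set.seed(47)
  for (rep in 1:5) {
    q <- rnorm(sample(20:80, 1))
    sc <- score_stream(q)
    oracle <- batch_scores_oracle(q)
    expect_equal(sc$e, oracle$e, tolerance = 1e-10)
    expect_equal(sc$z, oracle$z, tolerance = 1e-8)
    expect_equal(sc$s, oracle$s, tolerance = 1e-8)
  }
})

test_that("reset restores a fresh state and segment independence", {
  st <- new_anomaly_state()
  for (q in c(1, 4, -2)) st <- observe(st, q)
  expect_equal(reset_anomaly_state(st), new_anomaly_state())

  st2 <- reset_anomaly_state(st)
  st2 <- observe(st2, 9)
  expect_equal(predict_feature(st2), 9)

  # scores on segment B after a reset equal a standalone run on B
  set.seed(53)
  a <- rnorm(30)
  b <- rnorm(25, mean = 2)
  st3 <- new_anomaly_state()
  for (q in a) st3 <- observe(st3, q)
  st3 <- reset_anomaly_state(st3)
  after_reset <- vapply(b, function(q) {
    step <- rpmdetect:::observe_feature(st3, q)
    st3 <<- step$state
    step$s
  }, numeric(1))
  expect_equal(after_reset, score_stream(b)$s)
})

test_that("the batch standardization flag reproduces whole-series statistics", {
  set.seed(59)
  q <- rnorm(50)
  sc <- score_stream(q, standardization = "batch")
  qbar <- cumsum(q) / seq_along(q)
  e <- c(0, abs(q[-1] - qbar[-50]))
  z <- (e - mean(e)) / (stats::sd(e) * sqrt(49 / 50))
  expect_equal(sc$z, z, tolerance = 1e-10)
})
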