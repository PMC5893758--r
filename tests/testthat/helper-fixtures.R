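# shared test helpers: temp signal files and batch (whole-history) oracles

write_signal_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# batch recomputation of the online score chain from its definitions:
# per index t, statistics are recomputed from scratch over the full history,
# independent of the package's running (Welford) accumulators
batch_scores_oracle <- function(q, epsilon = 1e-8) {
  n <- length(q)
  e <- z <- s <- numeric(n)
  for (t in seq_len(n)) {
    e[t] <- if (t == 1) 0 else abs(q[t] - mean(q[seq_len(t - 1)]))
  }
  for (t in seq_len(n)) {
    prior <- e[seq_len(t - 1)]
    sd_prior <- if (length(prior) >= 2) {
      sqrt(mean((prior - mean(prior))^2))
    } else 0
    z[t] <- if (length(prior) == 0 || sd_prior == 0) {
      if (length(prior) >= 2 && e[t] != mean(prior) && sd_prior == 0) {
        (e[t] - mean(prior)) / epsilon
      } else 0
    } else (e[t] - mean(prior)) / max(sd_prior, epsilon)
  }
  for (t in seq_len(n)) {
    s[t] <- if (t == 1) 0 else abs(z[t] - mean(z[seq_len(t - 1)]))
  }
  list(e = e, z = z, s = s)
}

# enumeration oracle for the randomized p-value (direct transcription of the
# counting definition over the pooled scores s_1..s_i)
pvalue_enum_oracle <- function(history, s_i, theta) {
  all_s <- c(history, s_i)
  i <- length(all_s)
  (sum(all_s > s_i) + theta * sum(all_s == s_i)) / i
}

# exhaustive one-to-one assignment oracle: maximum number of detection/truth
# pairs with |d - g| <= tol, over all injective assignments
match_exhaustive_oracle <- function(detected, truth, tol) {
  if (length(detected) == 0 || length(truth) == 0) return(0L)
  best <- 0L
  assign_next <- function(ti, used, count) {
    if (ti > length(truth)) {
      best <<- max(best, count)
      return()
    }
    assign_next(ti + 1L, used, count)  # leave this truth unmatched
    for (j in seq_along(detected)) {
      if (!used[j] && abs(detected[j] - truth[ti]) <= tol) {
        used[j] <- TRUE
        assign_next(ti + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, logical(length(detected)), 0L)
  best
}
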