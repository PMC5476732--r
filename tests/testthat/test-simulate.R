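test_that("generators are bit-identical under a repeated seed", {
  a <- generate_eda(1, 120, 32, seed = 5)
  b <- generate_eda(1, 120, 32, seed = 5)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$scr_onsets, b$truth$scr_onsets)
  c1 <- generate_ecg(70, 30, 20, 60, 100, seed = 5)
  c2 <- generate_ecg(70, 30, 20, 60, 100, seed = 5)
  expect_identical(c1$record$samples, c2$record$samples)
  t1 <- generate_trials(subject_profile(), 4, seed = 5)
  t2 <- generate_trials(subject_profile(), 4, seed = 5)
  expect_identical(trials_to_df(t1$trials), trials_to_df(t2$trials))
  # distinct seeds give distinct draws
  expect_false(identical(a$record$samples,
                         generate_eda(1, 120, 32, seed = 6)$record$samples))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_eda(1, 120, 32, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("zero arousal yields an event-free EDA record", {
  g <- generate_eda(0, 120, 32, seed = 7)
  expect_length(g$truth$scr_onsets, 0)
  expect_error(generate_eda(-1, 120, 32, seed = 1), ">= 0")
  expect_error(generate_eda(1, 60, 32, seed = 1), ">= 120")
})

test_that("SCR counts follow the programmed Poisson mean", {
  arousal <- 1.5; rate <- 4
  counts <- vapply(1:100, function(s)
    length(generate_eda(arousal, 120, 32, seed = s,
                        scr_rate_base = rate)$truth$scr_onsets),
    numeric(1))
  expected <- arousal * rate * 2
  expect_lt(abs(mean(counts) - expected) / expected, 0.15)
})

test_that("the tonic component starts at zero and drifts within bounds", {
  g <- generate_eda(1, 120, 32, seed = 8)
  expect_equal(g$truth$tonic[1], 0)
  expect_lt(max(abs(g$truth$tonic)), 0.6)
})

test_that("degenerate rate modulation gives perfectly regular beats", {
  g <- generate_ecg(75, 0, 0, duration_s = 60, fs = 100, seed = 2,
                    jitter_ms = 0)
  expect_lt(max(abs(g$truth$rr_ms - 60000 / 75)), 1e-9)
  expect_error(generate_ecg(30, 0, 0, 60, 100, seed = 1), "40")
  expect_error(generate_ecg(170, 200, 0, 60, 100, seed = 1),
               "below 250 ms")
})

test_that("trial logs have 200 trials on a 1.5 s pitch with all kinds", {
  out <- generate_trials(subject_profile(), 1, seed = 11)
  expect_length(out$trials, 200)
  df <- trials_to_df(out$trials)
  expect_equal(max(df$onset_s), 199 * 1.5)
  expect_setequal(unique(df$kind), trial_kinds())
  expect_true(all(df$rt_ms[df$responded] <= 1500))
  expect_error(generate_trials(subject_profile(), 14, seed = 1), "1..13")
})

test_that("a null profile produces flat expected reaction times", {
  prof <- subject_profile(learning_gain = 0, fatigue_slope = 0,
                          acc_decline = 0)
  run_means <- vapply(c(1, 5, 9, 13), function(r) {
    rts <- vapply(1:50, function(s) {
      p <- performance_indices(
        generate_trials(prof, r, seed = r * 100 + s)$trials)
      p$Go_RT
    }, numeric(1))
    mean(rts)
  }, numeric(1))
  expect_lt(diff(range(run_means)), 15)  # well inside the noise band
})

test_that("the programmed fatigue decline lowers late-run withhold accuracy", {
  prof <- subject_profile()
  acc_at <- function(run) {
    mean(vapply(1:50, function(s) {
      performance_indices(
        generate_trials(prof, run, seed = run * 1000 + s)$trials
      )$Repeat_NoGo_acc
    }, numeric(1)))
  }
  expect_lt(acc_at(12), acc_at(7))
})

test_that("a cohort is one session per subject-run with exposed truth", {
  co <- generate_cohort(3, 4, "paper_shaped", seed = 3, fs_eda = 32,
                        fs_ecg = 100)
  expect_length(co$sessions, 12)
  ids <- vapply(co$sessions, function(s)
    paste0(s$subject_id, ".", s$run_number), character(1))
  expect_identical(anyDuplicated(ids), 0L)
  expect_length(co$truth$arousal, 4)
  expect_named(co$truth$sessions, ids, ignore.order = TRUE)
  # every session exposes the quantities the pipeline estimates
  st <- co$truth$sessions[[1]]
  expect_true(all(c("eda", "ecg", "trials") %in% names(st)))
  expect_true(length(st$ecg$beat_times_s) > 100)
  expect_error(generate_cohort(1, 4, seed = 1), "at least 2")
})

test_that("the paper-shaped arousal profile declines after run 9", {
  co <- generate_cohort(2, 13, "paper_shaped", seed = 4, fs_eda = 32,
                        fs_ecg = 100)
  a <- co$truth$arousal
  expect_gt(a[1], a[3])              # learning elevation
  expect_equal(a[3:9], rep(1, 7))    # plateau
  expect_true(all(diff(a[9:13]) < 0))
  null_a <- generate_cohort(2, 13, "null", seed = 4, fs_eda = 32,
                            fs_ecg = 100)$truth$arousal
  expect_equal(null_a, rep(1, 13))
})
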