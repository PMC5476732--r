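test_that("signal records validate their construction", {
  expect_error(signal_record(numeric(0), 400), "non-empty")
  expect_error(signal_record(c(1, NA), 400), "missing")
  expect_error(signal_record(1:10, -1), "positive")
  x <- signal_record(sin(1:400 / 10), fs = 400, units = "mV", label = "ecg")
  expect_equal(duration(x), 1)
  expect_equal(time_axis(x)[1], 0)
  expect_equal(length(time_axis(x)), 400)
})

test_that("signal CSV files round-trip losslessly", {
  x <- signal_record(c(1.234567890123, -2.5e-7, 0, 3.14159), fs = 400,
                     units = "uS", label = "eda", t0 = 2.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(x, path)
  y <- read_signal_csv(path)
  expect_identical(y$samples, x$samples)
  expect_identical(y$fs, x$fs)
  expect_identical(y$units, x$units)
  expect_identical(y$t0, x$t0)
})

test_that("signal CSV rejects malformed files with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units=uS", "1.0", "2.0"), path)   # fs_hz missing
  expect_error(read_signal_csv(path), "fs_hz")
  writeLines(c("# fs_hz=400", "# units=uS"), path)  # empty data section
  expect_error(read_signal_csv(path), "empty data")
  writeLines(c("# fs_hz=400", "1.0", "oops", "3.0"), path)
  expect_error(read_signal_csv(path), "line 3")
  expect_error(read_signal_csv(file.path(tempdir(), "nope__.csv")),
               "no such file")
})

test_that("a header-declared rate of 400 Hz gives the declared duration", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs_hz=400", format(sin(1:400))), path)
  x <- read_signal_csv(path)
  expect_equal(duration(x), 1.0)
})

test_that("trial logs round-trip and enforce the trial taxonomy", {
  prof <- subject_profile()
  trials <- generate_trials(prof, run = 5, seed = 42)$trials
  expect_length(trials, 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(trials, path)
  back <- read_trial_log(path)
  expect_equal(trials_to_df(back), trials_to_df(trials))

  df <- trials_to_df(trials)
  df$kind[3] <- "BLUE_TRIAL"
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_trial_log(path), "unknown trial kind")

  df2 <- trials_to_df(trials)
  miss <- which(!df2$responded)[1]
  df2$rt_ms[miss] <- 512           # rt recorded on an unresponded trial
  utils::write.csv(df2, path, row.names = FALSE, na = "")
  expect_error(read_trial_log(path), "absent")
})

test_that("trial invariants reject rt/responded mismatches", {
  expect_error(task_trial(1, "GO", 0, TRUE), "positive rt_ms")
  expect_error(task_trial(1, "GO", 0, FALSE, rt_ms = 400), "absent")
  expect_silent(task_trial(1, "GO", 0, TRUE, rt_ms = 400))
})

test_that("index tables round-trip to 12 significant digits and keep NA empty", {
  tab <- data.frame(subject_id = rep(c("S01", "S02"), each = 2),
                    run_number = rep(1:2, 2))
  set.seed(5)
  for (col in index_columns()) tab[[col]] <- stats::runif(4, 0.1, 900)
  tab$TVSymp[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_table(tab, path)
  raw <- readLines(path)
  expect_length(raw, 5)                      # header + 4 rows
  expect_match(raw[3], ",,", fixed = TRUE)   # NA written as empty cell
  back <- read_index_table(path)
  expect_true(is.na(back$TVSymp[2]))
  for (col in setdiff(index_columns(), "TVSymp"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  expect_error(write_index_table(tab[c(1, 1), ], path), "one row per")
})

test_that("hours awake follow the configured run convention", {
  expect_equal(hours_awake(1:13), 2 * (0:12))
  expect_equal(hours_awake(1:13, "deprivation"), 2 * (1:13))
  s <- run_session("S01", 7,
                   signal_record(rep(1, 500), 4),
                   signal_record(rep(1, 500), 4),
                   list(task_trial(1, "GO", 0, TRUE, 500)))
  expect_equal(s$hours_deprived, 12)
})

test_that("configuration validates bands and rejects unknown fields", {
  cfg <- analysis_config()
  expect_equal(cfg$scr_threshold, 0.05)
  expect_equal(cfg$edasymp_band, c(0.045, 0.25))
  expect_equal(cfg$tvsymp_band, c(0.08, 0.24))
  expect_error(analysis_config(hrv_lf_band = c(0.2, 0.1)), "increasing")
  expect_error(analysis_config(hrv_hf_band = c(0.15, 3)), "Nyquist")
  expect_error(analysis_config(bogus_field = 1), "unknown config")
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "scr_threshold = 0.04",
               "edasymp_band = 0.05, 0.3", "posthoc_method = bonferroni"),
             path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$scr_threshold, 0.04)
  expect_equal(cfg2$edasymp_band, c(0.05, 0.3))
  expect_equal(cfg2$posthoc_method, "bonferroni")
})
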