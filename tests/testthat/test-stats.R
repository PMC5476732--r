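test_that("Friedman statistic equals the closed-form rank formula", {
  m1 <- matrix(c(3, 1, 2, 2, 3, 1, 3, 2, 1, 1, 3, 2), 4, 3, byrow = TRUE)
  m2 <- matrix(c(9, 4, 1, 8, 7, 2, 6, 12, 3, 5, 10, 11), 4, 3,
               byrow = TRUE)
  for (m in list(m1, m2)) {
    f <- friedman_test(m)
    expect_equal(f$statistic, oracle_friedman_stat(m))
    expect_equal(f$statistic,
                 unname(stats::friedman.test(m)$statistic))
    expect_equal(f$p_value,
                 stats::pchisq(f$statistic, ncol(m) - 1,
                               lower.tail = FALSE))
    expect_equal(sum(f$avg_ranks), ncol(m) * (ncol(m) + 1) / 2)
  }
})

test_that("identical columns give a null ordering", {
  m <- matrix(rep(c(5, 7, 9, 2), 3), 4)
  f <- friedman_test(m)
  expect_equal(f$statistic, 0)
  expect_equal(f$p_value, 1)
  expect_equal(friedman_test(m, method = "exact")$p_value, 1)
})

test_that("exact p equals full enumeration of within-row orderings", {
  m <- matrix(c(3, 1, 2, 2, 3, 1, 3, 2, 1, 1, 3, 2), 4, 3, byrow = TRUE)
  fe <- friedman_test(m, method = "exact")
  expect_equal(fe$p_value, oracle_friedman_exact_p(m))
  # with ties
  mt <- matrix(c(1, 1, 2, 3, 2, 1, 2, 2, 2, 1, 3, 2), 4, 3, byrow = TRUE)
  expect_equal(friedman_test(mt, method = "exact")$p_value,
               oracle_friedman_exact_p(mt))
  expect_error(friedman_test(matrix(rnorm(130), 10, 13), method = "exact"),
               "infeasible")
})

test_that("the statistic depends on within-row ranks only", {
  set.seed(21)
  m <- matrix(rnorm(50), 10, 5)
  f0 <- friedman_test(m)
  f_mono <- friedman_test(exp(3 * m))     # strictly monotone transform
  expect_equal(f_mono$statistic, f0$statistic)
  expect_equal(f_mono$avg_ranks, f0$avg_ranks)
})

test_that("exact and asymptotic p-values agree where the chi-square
           approximation has converged", {
  set.seed(1)
  dif <- vapply(1:50, function(i) {
    m <- matrix(rnorm(45), 15, 3)
    abs(friedman_test(m, "exact")$p_value - friedman_test(m)$p_value)
  }, numeric(1))
  expect_lte(mean(dif), 0.05)
})

test_that("inputs are validated", {
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(friedman_test(matrix(1:3, 1)), "at least 2")
})

test_that("post-hoc critical difference matches first principles", {
  f13 <- structure(list(avg_ranks = seq(1, 13), k = 13L, n = 10L),
                   class = "friedman_result")
  ph <- posthoc_ranks(f13, n = 10, alpha = 0.05)
  cd <- stats::qtukey(0.95, 13, Inf) / sqrt(2) * sqrt(13 * 14 / (12 * 10))
  expect_equal(unique(ph$critical_difference), cd)
  expect_equal(nrow(ph), choose(13, 2))
  # the extreme pair separates; adjacent ranks do not
  expect_true(ph$significant[ph$run_a == 1 & ph$run_b == 13])
  expect_false(ph$significant[ph$run_a == 6 & ph$run_b == 7])
  expect_error(posthoc_ranks(f13, n = 1), "at least 2")
})

test_that("a column ranked last by all subjects separates from one ranked first", {
  set.seed(31)
  m <- matrix(rnorm(130, sd = 0.1), 10, 13)
  m[, 4] <- m[, 4] + 10    # always ranked last (highest)
  m[, 9] <- m[, 9] - 10    # always ranked first
  f <- friedman_test(m)
  ph <- posthoc_ranks(f)
  expect_true(ph$significant[ph$run_a == 4 & ph$run_b == 9])
})

test_that("post-hoc significance is monotone in a growing column shift", {
  set.seed(32)
  base <- matrix(rnorm(80), 10, 8)
  n_sig <- vapply(c(0, 1, 2, 4, 8), function(shift) {
    m <- base
    m[, 8] <- m[, 8] + shift
    sum(posthoc_ranks(friedman_test(m))$significant)
  }, numeric(1))
  expect_true(all(diff(n_sig) >= 0))
})

test_that("profile correlation follows the product-moment formula", {
  expect_equal(profile_correlation(1:5, 1:5), 1)
  expect_equal(profile_correlation(1:5, -(1:5)), -1)
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(profile_correlation(a, b), manual)
  expect_error(profile_correlation(1:4, rep(2, 4)), "zero-variance")
  expect_error(profile_correlation(1:3, 1:4), "equal length")
})

test_that("cohort analysis tests each index and skips incomplete columns", {
  set.seed(41)
  tab <- expand.grid(subject_id = sprintf("S%02d", 1:6), run_number = 1:5,
                     stringsAsFactors = FALSE)
  tab$SCL <- rnorm(30, 2)
  tab$NSSCRs <- rnorm(30, 3) - 1.2 * tab$run_number   # strong run effect
  tab$TVSymp <- rnorm(30, 1)
  tab$TVSymp[3] <- NA
  expect_warning(an <- analyze_cohort(tab), "TVSymp")
  expect_setequal(names(an$friedman), c("SCL", "NSSCRs"))
  expect_identical(an$skipped, "TVSymp")
  expect_lt(an$friedman$NSSCRs$p_value, 0.05)
  expect_true("NSSCRs" %in% names(an$posthoc))
  expect_equal(dim(an$profile_cor), c(2L, 2L))

  single <- tab[tab$subject_id == "S01", ]
  expect_error(analyze_cohort(single), "at least 2 subjects")
})
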