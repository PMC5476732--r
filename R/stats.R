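#' Friedman rank test for one-way repeated measures
#'
#' Nonparametric analysis of variance by ranks: values are ranked within
#' each subject (row) across the k runs (columns, ties get average
#' ranks), and the tie-corrected statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 /
#'       (\sum_{ij} r_{ij}^2 - n k (k+1)^2 / 4)}
#' is referred to a chi-square distribution with k-1 degrees of freedom,
#' or to the full within-row permutation distribution when
#' `method = "exact"`.
#'
#' @param data numeric matrix or data.frame, subjects in rows, runs in
#'   columns; no missing cells.
#' @param method `"asymptotic"` (chi-square) or `"exact"`: the p-value is
#'   the fraction of all `(k!)^n` equally likely within-row rank
#'   orderings whose statistic reaches the observed one.  The
#'   distribution is accumulated by dynamic programming over column
#'   rank-sum states, which enumerates the identical distribution
#'   without materializing every table; a feasibility guard still
#'   rejects problems whose state space is too large.
#' @return A `"friedman_result"`: list with `statistic`, `df`, `p_value`,
#'   `avg_ranks` (length k, mean rank per run; they sum to `k(k+1)/2`),
#'   `n`, `k`, `method`.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 1, 1, 3, 2, 1, 2, 3), 4, byrow = TRUE)
#' friedman_test(m)
#' @export
friedman_test <- function(data, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("data must be numeric", call. = FALSE)
  if (anyNA(m)) stop("data must have no missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 runs", call. = FALSE)

  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  D <- sum(r^2) - n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  if (D <= 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- num / D
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }

  if (method == "exact") {
    if ((n * (k - 1) + 1)^(k - 1) > 2e5 || k > 6)
      stop(sprintf(
        "exact method infeasible for n = %d, k = %d: rank-sum state space too large",
        n, k), call. = FALSE)
    if (D <= 0) p <- 1 else p <- friedman_exact_p(r, stat, D)
  }

  structure(list(statistic = stat, df = k - 1, p_value = p,
                 avg_ranks = Rj / n, n = n, k = k, method = method),
            class = "friedman_result")
}

# Exact permutation p-value of the Friedman statistic.  Every row's rank
# vector may be re-ordered in k! equally likely ways; the statistic only
# depends on the column rank sums, so the (k!)^n orderings are folded
# into a dynamic program over the vector of the first k-1 column sums
# (the last is determined by the fixed per-row total).  Counts are exact
# (doubles; the example sizes keep them far below 2^53).
friedman_exact_p <- function(r, stat_obs, D) {
  n <- nrow(r); k <- ncol(r)
  perms <- permutations_of(k)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(rep(0L, k - 1L), collapse = ","), 1, envir = counts)
  for (i in seq_len(n)) {
    # multiset of rank contributions this row can make to columns 1..k-1
    opts <- r[i, ][perms]
    dim(opts) <- dim(perms)
    opts <- opts[, seq_len(k - 1L), drop = FALSE]
    okeys <- apply(opts, 1, paste, collapse = ",")
    otab <- table(okeys)
    ovals <- do.call(rbind, lapply(strsplit(names(otab), ","), as.numeric))
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(counts)) {
      base <- as.numeric(strsplit(key, ",")[[1]])
      cnt <- get(key, envir = counts)
      for (j in seq_len(nrow(ovals))) {
        nk <- paste(base + ovals[j, ], collapse = ",")
        prev <- if (exists(nk, envir = nxt)) get(nk, envir = nxt) else 0
        assign(nk, prev + cnt * as.numeric(otab[j]), envir = nxt)
      }
    }
    counts <- nxt
  }
  total_rank <- n * k * (k + 1) / 2
  hits <- 0; tot <- 0
  for (key in ls(counts)) {
    Rj <- as.numeric(strsplit(key, ",")[[1]])
    Rj <- c(Rj, total_rank - sum(Rj))
    Q <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / D
    cnt <- get(key, envir = counts)
    tot <- tot + cnt
    if (Q >= stat_obs - 1e-12) hits <- hits + cnt
  }
  hits / tot
}

# All k! permutations of 1..k as a (k! x k) matrix, by inserting k into
# every position of each permutation of 1..(k-1).
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (s in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[row, ] <- append(sub[s, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf(
    "<friedman_result> chi2(%d) = %.3f, p = %.4g (%s), n = %d, k = %d\n",
    x$df, x$statistic, x$p_value, x$method, x$n, x$k))
  invisible(x)
}

#' Rank-based post-hoc pairwise comparisons
#'
#' Nemenyi-type comparison on the Friedman average ranks: runs a and b
#' differ when `|avg_rank_a - avg_rank_b|` exceeds the critical
#' difference `CD = q(alpha, k) / sqrt(2) * sqrt(k (k+1) / (12 n))`, with
#' `q` the Studentized-range quantile at infinite df.  A Bonferroni
#' alternative uses a normal quantile at level `alpha / (k (k - 1))` and
#' standard error `sqrt(k (k+1) / (6 n))`.
#'
#' @param result a `"friedman_result"`.
#' @param n number of subjects (defaults to `result$n`).
#' @param alpha significance level (default 0.05).
#' @param method `"nemenyi"` (default) or `"bonferroni"`.
#' @return A `"pairwise_comparisons"` data.frame: one row per unordered
#'   run pair with `run_a`, `run_b`, `rank_diff`, `critical_difference`,
#'   `significant`; attributes `alpha`, `method`.
#' @export
posthoc_ranks <- function(result, n = result$n, alpha = 0.05,
                          method = c("nemenyi", "bonferroni")) {
  stopifnot(inherits(result, "friedman_result"))
  method <- match.arg(method)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  k <- result$k
  cd <- switch(method,
    nemenyi = stats::qtukey(1 - alpha, k, Inf) / sqrt(2) *
      sqrt(k * (k + 1) / (12 * n)),
    bonferroni = stats::qnorm(1 - alpha / (k * (k - 1))) *
      sqrt(k * (k + 1) / (6 * n))
  )
  pairs <- utils::combn(k, 2)
  diffs <- abs(result$avg_ranks[pairs[1, ]] - result$avg_ranks[pairs[2, ]])
  out <- data.frame(run_a = pairs[1, ], run_b = pairs[2, ],
                    rank_diff = diffs, critical_difference = cd,
                    significant = diffs > cd)
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Pearson correlation between two per-run mean profiles
#'
#' @param a,b numeric vectors of equal length (>= 3) of per-run means.
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
profile_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("profiles must have equal length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("profile correlation undefined for a zero-variance profile",
         call. = FALSE)
  stats::cor(a, b)
}

#' Rank analysis of a full cohort index table
#'
#' One Friedman test per index column (subjects as blocks, runs as
#' treatments), post-hoc rank comparisons for the indices whose Friedman
#' p-value falls below `cfg$alpha`, and a Pearson correlation matrix over
#' the per-run mean profiles of all indices.
#'
#' @param table data.frame with columns `subject_id`, `run_number` and
#'   index columns (see [index_columns()]); one row per subject-run.
#' @param cfg an [analysis_config()].
#' @return A `"cohort_analysis"`: list with `friedman` (named list of
#'   `"friedman_result"`), `posthoc` (named list, only indices with
#'   p < alpha), `run_means` (runs x indices matrix), `profile_cor`
#'   (indices x indices correlation matrix), `skipped` (columns with
#'   missing cells), `alpha`.
#' @export
analyze_cohort <- function(table, cfg = analysis_config()) {
  stopifnot(is.data.frame(table))
  need <- c("subject_id", "run_number")
  if (!all(need %in% names(table)))
    stop("table must have subject_id and run_number columns", call. = FALSE)
  idx_cols <- intersect(index_columns(), names(table))
  if (!length(idx_cols)) stop("no index columns found", call. = FALSE)
  subjects <- sort(unique(table$subject_id))
  runs <- sort(unique(table$run_number))
  if (length(subjects) < 2)
    stop("cohort analysis needs at least 2 subjects", call. = FALSE)

  friedman <- list(); posthoc <- list(); skipped <- character(0)
  run_means <- matrix(NA_real_, length(runs), length(idx_cols),
                      dimnames = list(paste0("run", runs), idx_cols))
  for (col in idx_cols) {
    m <- matrix(NA_real_, length(subjects), length(runs),
                dimnames = list(subjects, paste0("run", runs)))
    ii <- match(table$subject_id, subjects)
    jj <- match(table$run_number, runs)
    m[cbind(ii, jj)] <- table[[col]]
    if (anyNA(m)) {
      warning("index '", col, "' skipped: incomplete column", call. = FALSE)
      skipped <- c(skipped, col)
      next
    }
    res <- friedman_test(m)
    friedman[[col]] <- res
    run_means[, col] <- colMeans(m)
    if (res$p_value < cfg$alpha)
      posthoc[[col]] <- posthoc_ranks(res, alpha = cfg$alpha,
                                      method = cfg$posthoc_method)
  }
  kept <- setdiff(idx_cols, skipped)
  profile_cor <- if (length(kept) >= 2)
    stats::cor(run_means[, kept, drop = FALSE]) else NULL
  structure(list(friedman = friedman, posthoc = posthoc,
                 run_means = run_means[, kept, drop = FALSE],
                 profile_cor = profile_cor, skipped = skipped,
                 runs = runs, subjects = subjects, alpha = cfg$alpha),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects x %d runs, alpha = %g\n",
              length(x$subjects), length(x$runs), x$alpha))
  for (nm in names(x$friedman)) {
    f <- x$friedman[[nm]]
    sig <- if (f$p_value < x$alpha) " *" else ""
    cat(sprintf("  %-16s chi2(%d) = %7.3f  p = %.4g%s\n",
                nm, f$df, f$statistic, f$p_value, sig))
  }
  if (length(x$skipped))
    cat("  skipped (incomplete):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Plain-list report of a cohort analysis (for JSON export)
#'
#' @param analysis a `"cohort_analysis"`.
#' @return Nested list mirroring the analysis: per-index statistic, df,
#'   p-value, average ranks, and significant run pairs.
#' @export
analysis_report <- function(analysis) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  per_index <- lapply(names(analysis$friedman), function(nm) {
    f <- analysis$friedman[[nm]]
    ph <- analysis$posthoc[[nm]]
    sig_pairs <- if (!is.null(ph) && any(ph$significant)) {
      sp <- ph[ph$significant, c("run_a", "run_b"), drop = FALSE]
      lapply(seq_len(nrow(sp)), function(i)
        c(analysis$runs[sp$run_a[i]], analysis$runs[sp$run_b[i]]))
    } else list()
    list(index = nm, statistic = f$statistic, df = f$df,
         p_value = f$p_value, avg_ranks = as.numeric(f$avg_ranks),
         significant_run_pairs = sig_pairs)
  })
  names(per_index) <- names(analysis$friedman)
  list(alpha = analysis$alpha,
       n_subjects = length(analysis$subjects),
       runs = analysis$runs,
       indices = per_index,
       profile_correlations = analysis$profile_cor,
       skipped = analysis$skipped)
}
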