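#' Cohort characteristic tables of the emulated multicenter study
#'
#' `cohort_characteristics()` returns the published patient-characteristics
#' contingency tables (rows = category levels, columns = the four
#' hospitals A-D), shipped as a plain-text fixture; `cohort_age_summary()`
#' returns the per-site age summaries (mean, sd, n).
#'
#' @param characteristic Optional name (e.g. `"histological_type"`); if
#'   given, returns that characteristic's counts as an integer matrix,
#'   otherwise a named list of all matrices.
#' @return Integer matrix, list of matrices, or (for `cohort_age_summary()`) a
#'   data frame.
#' @examples
#' cohort_characteristics("metastasis")
#' @export
cohort_characteristics <- function(characteristic = NULL) {
  path <- system.file("extdata", "cohort_characteristics.csv", package = "fedcrt")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_df <- split(df, df$characteristic)
  mats <- lapply(split_df, function(d) {
    m <- as.matrix(d[, c("A", "B", "C", "D")])
    storage.mode(m) <- "integer"
    rownames(m) <- d$row_label
    colnames(m) <- paste0("Hospital", c("A", "B", "C", "D"))
    m
  })
  if (is.null(characteristic)) return(mats)
  if (!characteristic %in% names(mats)) {
    stop(sprintf("unknown characteristic '%s'; available: %s",
                 characteristic, paste(names(mats), collapse = ", ")),
         call. = FALSE)
  }
  mats[[characteristic]]
}

#' @rdname cohort_characteristics
#' @export
cohort_age_summary <- function() {
  path <- system.file("extdata", "cohort_age.csv", package = "fedcrt")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

new_test_result <- function(statistic, df, p_value, method, flags = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         method = method, flags = flags),
    class = "cohort_test_result"
  )
}

#' @export
print.cohort_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (length(x$flags)) cat("  note:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson statistic with no continuity correction, `df = (r-1)(c-1)`,
#' upper-tail chi-square p-value. A flag is attached when any expected
#' count falls below 5 (the usual validity caution).
#'
#' @param counts r x c matrix of nonnegative integer counts (r, c >= 2).
#' @return A `cohort_test_result`.
#' @examples
#' chi_square_test(cohort_characteristics("metastasis"))
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need an r x c table with r, c >= 2", call. = FALSE)
  }
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be nonnegative with a positive total", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  flags <- if (any(ct$expected < 5)) "some expected counts < 5" else NULL
  new_test_result(unname(ct$statistic), unname(ct$parameter),
                  ct$p.value, "Pearson chi-square", flags)
}

#' One-way ANOVA, from raw samples or group summaries
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within`
#' with `df = (k - 1, N - k)`. `groups` may be a list of raw numeric
#' samples, or a data frame / list with `mean`, `sd`, `n` per group
#' (summary mode, using the standard sum-of-squares decomposition
#' `SS_within = sum (n_i - 1) sd_i^2`,
#' `SS_between = sum n_i (mean_i - grand_mean)^2`).
#'
#' @param groups List of numeric vectors, or summaries (see above).
#' @return A `cohort_test_result`.
#' @examples
#' anova_oneway(list(rnorm(10), rnorm(10, 1)))
#' anova_oneway(cohort_age_summary())
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups) ||
      (is.list(groups) && all(c("mean", "sd", "n") %in% names(groups)))) {
    m <- groups$mean; s <- groups$sd; n <- groups$n
    k <- length(m)
    stopifnot(k >= 2L, length(s) == k, length(n) == k, all(n >= 2))
    N <- sum(n)
    grand <- sum(n * m) / N
    ss_b <- sum(n * (m - grand)^2)
    ss_w <- sum((n - 1) * s^2)
  } else {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (any(vapply(groups, length, 1L) < 2L)) {
      stop("each group needs at least 2 values", call. = FALSE)
    }
    allv <- unlist(groups)
    if (stats::sd(allv) == 0) {
      stop("all values identical: ANOVA undefined", call. = FALSE)
    }
    n <- vapply(groups, length, 1L)
    m <- vapply(groups, mean, 1)
    k <- length(groups)
    N <- sum(n)
    grand <- mean(allv)
    ss_b <- sum(n * (m - grand)^2)
    ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  }
  df1 <- k - 1L
  df2 <- N - k
  flags <- NULL
  if (ss_w == 0) {
    if (ss_b == 0) stop("all values identical: ANOVA undefined",
                        call. = FALSE)
    flags <- "zero within-group variance"
    f <- Inf
    p <- 0
  } else {
    f <- (ss_b / df1) / (ss_w / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  new_test_result(f, c(df1, df2), p, "One-way ANOVA", flags)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's. Tables larger than
#' 2 x 2 are rejected with a pointer to [fisher_exact_mc()].
#'
#' @param counts 2 x 2 matrix of nonnegative counts.
#' @return A `cohort_test_result`.
#' @examples
#' fisher_exact(matrix(c(1, 9, 9, 1), 2))
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) {
    stop("fisher_exact() handles 2 x 2 tables only; use fisher_exact_mc() ",
         "for larger tables", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  ft <- stats::fisher.test(counts)
  new_test_result(unname(ft$estimate), NA_integer_, ft$p.value,
                  "Fisher's exact test (2x2)")
}

#' Monte-Carlo Fisher's exact test for r x c tables
#'
#' Seeded Monte-Carlo estimate of the exact p-value for tables larger
#' than 2 x 2 (network-algorithm sampling of tables with fixed margins);
#' flagged as approximate.
#'
#' @param counts r x c matrix of nonnegative counts.
#' @param n_sim Number of simulated tables.
#' @param seed Integer seed.
#' @return A `cohort_test_result`.
#' @export
fisher_exact_mc <- function(counts, n_sim = 10000, seed = 1) {
  counts <- as.matrix(counts)
  ft <- with_seed(seed, {
    stats::fisher.test(counts, simulate.p.value = TRUE, B = n_sim)
  })
  new_test_result(NA_real_, NA_integer_, ft$p.value,
                  sprintf("Fisher's exact test (Monte-Carlo, B = %d)", n_sim),
                  flags = "Monte-Carlo approximation")
}

#' Reproduce the cohort-comparison statistics report
#'
#' Runs the Pearson chi-square test on every categorical characteristic
#' of the shipped cohort table and the summary-mode one-way ANOVA on age,
#' returning one row per characteristic.
#'
#' @return Data frame with `characteristic`, `method`, `statistic`, `df`,
#'   `p_value`.
#' @examples
#' cohort_stats_report()
#' @export
cohort_stats_report <- function() {
  mats <- cohort_characteristics()
  rows <- lapply(names(mats), function(nm) {
    r <- chi_square_test(mats[[nm]])
    data.frame(characteristic = nm, method = r$method,
               statistic = r$statistic, df = paste(r$df, collapse = ","),
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  age <- anova_oneway(cohort_age_summary())
  rows[[length(rows) + 1L]] <- data.frame(
    characteristic = "age", method = age$method, statistic = age$statistic,
    df = paste(age$df, collapse = ","), p_value = age$p_value,
    stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}
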