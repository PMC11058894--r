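#' Ordinary least-squares regression of one method on another
#'
#' Fits `y = beta1 * x + beta0` by least squares and reports the squared
#' Pearson correlation as the determination coefficient.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @return A list of class `ols_fit` with `beta1`, `beta0`, `r_squared`, `n`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (length(x) < 3) abort("at least 3 pairs are required")
  if (stats::sd(x) == 0) abort("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  structure(list(beta1 = unname(b[2]), beta0 = unname(b[1]),
                 r_squared = stats::cor(x, y)^2, n = length(x)),
            class = "ols_fit")
}

#' @export
tidy.ols_fit <- function(x, ...) {
  tibble(beta1 = x$beta1, beta0 = x$beta0, r_squared = x$r_squared, n = x$n)
}

#' Bland-Altman agreement between two paired measurement sets
#'
#' Differences are `d1 - d2`; the limits of agreement are the mean difference
#' plus/minus exactly 2 sample standard deviations (n - 1 denominator). The
#' per-pair percentage difference is the difference divided by the pair mean,
#' `100 * (d1 - d2) / ((d1 + d2) / 2)`, reported as its mean across pairs.
#'
#' @param d1,d2 Numeric vectors of equal length (>= 2).
#' @return A list of class `bland_altman` with `mean_diff`, `loa_low`,
#'   `loa_high`, `mean_pct_diff`, `sd_diff`, `n`, and the per-pair `diffs`
#'   and `means`.
#' @export
bland_altman <- function(d1, d2) {
  if (length(d1) != length(d2)) abort("d1 and d2 lengths differ")
  if (length(d1) < 2) abort("at least 2 pairs are required")
  d <- d1 - d2
  m <- (d1 + d2) / 2
  zero <- which(m == 0)
  if (length(zero) > 0)
    abort(sprintf("pair mean is zero at index %d; percentage difference undefined",
                  zero[1]))
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = md, loa_low = md - 2 * s, loa_high = md + 2 * s,
                 mean_pct_diff = mean(100 * d / m), sd_diff = s,
                 n = length(d), diffs = d, means = m),
            class = "bland_altman")
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, loa_low = x$loa_low, loa_high = x$loa_high,
         mean_pct_diff = x$mean_pct_diff, sd_diff = x$sd_diff, n = x$n)
}

#' Upper-tail standard normal probability
#'
#' `P(Z > z)` for a standard normal `Z`; monotone decreasing, 0.5 at z = 0.
#'
#' @param z Finite numeric.
#' @return The upper-tail probability.
#' @export
normal_upper_tail <- function(z) {
  if (any(!is.finite(z))) abort("z must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Compare two correlation coefficients via Fisher's r-to-z
#'
#' Transforms each correlation with `atanh` and forms the standard-normal
#' statistic. The default, independent-samples form is
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' one-sided (upper tail) p-value. When the two correlations share a variable
#' (e.g. two methods each correlated against the same reference on the same
#' subjects), the dependent-sample comparison of Steiger (method =
#' `"dependent"`) is available: it requires the correlation `r12` between the
#' two non-shared variables and uses the common `n = n1`.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (> 3).
#' @param method `"independent"` (default) or `"dependent"`.
#' @param r12 Correlation between the two compared variables; required for
#'   the dependent method.
#' @return A list of class `correlation_comparison`: `r1`, `r2`, `n1`, `n2`,
#'   `z`, `p_one_sided`, `method`.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2,
                              method = c("independent", "dependent"),
                              r12 = NULL) {
  method <- match.arg(method)
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("correlations must lie inside (-1, 1)")
  if (n1 <= 3 || n2 <= 3) abort("sample sizes must exceed 3")
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (method == "independent") {
    z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r12)) abort("the dependent method needs r12")
    n <- n1
    rbar <- (r1 + r2) / 2
    # Steiger's case of two overlapping dependent correlations
    psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
    cov_term <- psi / ((1 - rbar^2)^2)
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  }
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z = z,
                 p_one_sided = normal_upper_tail(z), method = method),
            class = "correlation_comparison")
}

#' @export
tidy.correlation_comparison <- function(x, ...) {
  tibble(r1 = x$r1, r2 = x$r2, n1 = x$n1, n2 = x$n2, z = x$z,
         p_one_sided = x$p_one_sided, method = x$method)
}

#' Paired Student t test
#'
#' Standard paired t on `d1 - d2`, two-sided p from the t distribution with
#' `n - 1` degrees of freedom.
#'
#' @param d1,d2 Numeric vectors of equal length (>= 2) with non-degenerate
#'   differences.
#' @return A list with `t_stat`, `p_two_sided`, `df`, `n`.
#' @export
paired_t_test <- function(d1, d2) {
  if (length(d1) != length(d2)) abort("d1 and d2 lengths differ")
  if (length(d1) < 2) abort("at least 2 pairs are required")
  if (stats::sd(d1 - d2) == 0)
    abort("zero-variance differences: paired t statistic undefined")
  ht <- stats::t.test(d1, d2, paired = TRUE)
  list(t_stat = unname(ht$statistic), p_two_sided = ht$p.value,
       df = unname(ht$parameter), n = length(d1))
}

#' Categorize association strength from a determination coefficient
#'
#' Bins: weak for R^2 <= 0.25, moderate for 0.25 < R^2 <= 0.5, strong for
#' 0.5 < R^2 <= 0.8, very strong for 0.8 < R^2 <= 1 (upper edges inclusive).
#'
#' @param r_squared Determination coefficient in `[0, 1]`.
#' @return One of `"weak"`, `"moderate"`, `"strong"`, `"very strong"`.
#' @export
categorize_association <- function(r_squared) {
  if (!is.numeric(r_squared) || length(r_squared) != 1 ||
      is.na(r_squared) || r_squared < 0 || r_squared > 1)
    abort("r_squared must be a single value in [0, 1]")
  if (r_squared <= 0.25) "weak"
  else if (r_squared <= 0.5) "moderate"
  else if (r_squared <= 0.8) "strong"
  else "very strong"
}

#' Method-comparison report over a per-subject measurement table
#'
#' For every requested (method, reference) pair and every metric present,
#' computes the full agreement panel: OLS regression (`y = beta1 x + beta0`,
#' with the method as y and the reference as x), determination coefficient
#' and its association category, Bland-Altman mean difference and mean ± 2 SD
#' limits of agreement, mean percentage difference, and the paired t test.
#' Subjects missing either value of a pair are dropped pairwise (with a
#' message).
#'
#' @param table Long-format measurements: columns `subject_id`, `metric`,
#'   `method`, `value` (as produced by [make_paired_measurements()]).
#' @param pairs List of length-2 character vectors `c(method, reference)`,
#'   or strings `"method:reference"`.
#' @param metrics Metrics to report; default all in the table.
#' @return A tibble of class `agreement_report`, one row per pair x metric,
#'   with columns `method`, `reference`, `metric`, `n`, `r_squared`, `beta1`,
#'   `beta0`, `mean_diff`, `loa_low`, `loa_high`, `mean_pct_diff`, `t_stat`,
#'   `t_p`, `category`.
#' @export
run_comparison <- function(table, pairs, metrics = NULL) {
  stopifnot(all(c("subject_id", "metric", "method", "value") %in% names(table)))
  pairs <- lapply(pairs, function(p) {
    if (is.character(p) && length(p) == 1) strsplit(p, ":", fixed = TRUE)[[1]]
    else p
  })
  methods_present <- unique(table$method)
  if (is.null(metrics)) metrics <- unique(table$metric)
  rows <- list()
  for (pr in pairs) {
    if (!all(pr %in% methods_present))
      abort(sprintf("unknown method column in pair %s:%s", pr[1], pr[2]))
    for (met in metrics) {
      wide <- table |>
        dplyr::filter(.data$metric == met, .data$method %in% pr) |>
        tidyr::pivot_wider(id_cols = "subject_id", names_from = "method",
                           values_from = "value")
      y <- wide[[pr[1]]]; x <- wide[[pr[2]]]
      ok <- stats::complete.cases(x, y)
      if (sum(!ok) > 0)
        message(sprintf("%s vs %s / %s: dropped %d incomplete pair(s)",
                        pr[1], pr[2], met, sum(!ok)))
      x <- x[ok]; y <- y[ok]
      if (length(x) < 4)
        abort(sprintf("fewer than 4 complete pairs for %s vs %s / %s",
                      pr[1], pr[2], met))
      fit <- ols_regression(x, y)
      ba <- bland_altman(y, x)
      tt <- if (stats::sd(y - x) == 0) list(t_stat = NA_real_, p_two_sided = NA_real_)
            else paired_t_test(y, x)
      rows[[length(rows) + 1]] <- tibble(
        method = pr[1], reference = pr[2], metric = met, n = length(x),
        r_squared = fit$r_squared, beta1 = fit$beta1, beta0 = fit$beta0,
        mean_diff = ba$mean_diff, loa_low = ba$loa_low, loa_high = ba$loa_high,
        mean_pct_diff = ba$mean_pct_diff,
        t_stat = tt$t_stat, t_p = tt$p_two_sided,
        category = categorize_association(fit$r_squared))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agreement_report", class(out))
  out
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(n_pairs = length(unique(paste(x$method, x$reference))),
         n_metrics = length(unique(x$metric)),
         min_r_squared = min(x$r_squared),
         max_r_squared = max(x$r_squared))
}

#' Write an agreement report as CSV (and optionally JSON)
#'
#' The CSV mirrors the layout of a method-comparison coefficients table:
#' one row per method pair and metric with R^2, beta1, beta0, mean difference
#' and the mean ± 2 SD limits of agreement.
#'
#' @param report An `agreement_report`.
#' @param csv_path Output CSV file.
#' @param json_path Optional output JSON file.
#' @return `csv_path`, invisibly.
#' @export
write_agreement_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(report), json_path, digits = NA)
  invisible(csv_path)
}
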