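# Test-retest Bland-Altman analysis, paired comparisons, correlations, the
# multiple-comparison threshold and the fat-fraction selection rule.

#' Bland-Altman test-retest analysis
#'
#' Mean difference, SD of the differences (n - 1 denominator) and the 95%
#' limits-of-agreement half-width `1.96 * SD`, with the per-pair means and
#' differences for plotting.
#'
#' @param test,retest paired measurements (equal length, n >= 2).
#' @return object of class `bland_altman`: list with `n`, `mean_diff`, `sd_diff`,
#'   `loa_half` (= 1.96 * sd_diff), `loa` (mean +/- half-width), `pair_mean`,
#'   `pair_diff`.
#' @export
bland_altman <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  ok <- is.finite(test) & is.finite(retest)
  test <- test[ok]; retest <- retest[ok]
  n <- length(test)
  if (n < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- test - retest
  sd_d <- stats::sd(d)
  structure(list(n = n, mean_diff = mean(d), sd_diff = sd_d,
                 loa_half = 1.96 * sd_d,
                 loa = mean(d) + c(-1.96, 1.96) * sd_d,
                 pair_mean = (test + retest) / 2, pair_diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: n = %d, mean difference = %.4g, LOA = %.4g +/- %.4g\n",
              x$n, x$mean_diff, x$mean_diff, x$loa_half))
  invisible(x)
}

#' Paired t-test (one- or two-sided)
#'
#' Classical paired t on the differences `a - b`, with p-values from the t
#' distribution.  Zero-variance differences (including `a == b`) return `p = 1`
#' with a warning rather than an error, so degenerate synthetic cases are handled
#' deterministically.
#'
#' @param a,b paired samples (equal length, n >= 2).
#' @param alternative "two.sided", "greater" (mean of `a - b` > 0) or "less".
#' @return list with `t`, `df`, `p`, `mean_diff`, `alternative`.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("paired t-test needs at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero-variance differences; returning p = 1")
    return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = mean(d),
                alternative = alternative))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = unname(ht$estimate), alternative = alternative)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (equal length, n >= 3, non-degenerate).
#' @return list with `r`, `n`, `t`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Pearson correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, n = length(x), t = NA_real_, df = length(x) - 2,
                p = NA_real_))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), n = length(x), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' One-way analysis of variance
#'
#' Classical between/within-group F with equal variances assumed.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 2)) {
    stop("one-way ANOVA needs >= 2 groups with >= 2 observations each")
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / k` for a family of `k` comparisons; reporting marks significance at
#' both the nominal 0.05 and the adjusted level.
#'
#' @param alpha family-wise level.
#' @param k number of comparisons (>= 1).
#' @return adjusted per-comparison threshold.
#' @export
multiple_comparison_threshold <- function(alpha = 0.05, k = 1) {
  stopifnot(k >= 1)
  alpha / k
}

#' Select subjects by ilium fat fraction
#'
#' Retains subjects whose ilium fat fraction is strictly below the limit (40% by
#' default): marrow water signal, and hence ADC, is only reliable at low fat
#' fraction.  Subjects with no ilium fat fraction are excluded with a warning.
#'
#' @param cohort_table data.frame with columns `subject` and `ff_ilium` (one value
#'   per subject, repeated rows allowed).
#' @param ff_limit exclusive upper bound on ilium fat fraction.
#' @return the retained subset of `cohort_table`; excluded subject ids are in
#'   `attr(, "excluded")`.
#' @export
select_subjects <- function(cohort_table, ff_limit = 0.40) {
  stopifnot(is.data.frame(cohort_table),
            all(c("subject", "ff_ilium") %in% names(cohort_table)))
  ff <- tapply(cohort_table$ff_ilium, cohort_table$subject, function(v) v[1])
  missing_ff <- names(ff)[is.na(ff)]
  if (length(missing_ff)) {
    warning("no ilium fat fraction for: ", paste(missing_ff, collapse = ", "),
            "; excluded")
  }
  keep_ids <- names(ff)[!is.na(ff) & ff < ff_limit]
  out <- cohort_table[cohort_table$subject %in% keep_ids, , drop = FALSE]
  attr(out, "excluded") <- setdiff(unique(cohort_table$subject), keep_ids)
  out
}
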