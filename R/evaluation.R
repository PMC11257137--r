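#' Kish effective sample size
#'
#' `(sum w)^2 / sum w^2`: the equal-weight sample size with the same
#' variance as the weighted sample. Equals N for equal weights and shrinks
#' as weights become more variable; ESS/N is the inverse design effect.
#'
#' @param weights Positive numeric vector.
#' @return Effective sample size (scalar, <= length(weights)).
#' @export
kish_ess <- function(weights) {
  stopifnot(length(weights) >= 1L, all(weights > 0))
  sum(weights)^2 / sum(weights^2)
}

#' Wald confidence interval for a weighted proportion
#'
#' `p +/- z * sqrt(p(1-p)/n_eff)`, truncated to `[0, 1]`. For weighted
#' estimates pass the Kish effective sample size as `effective_n` so the
#' interval reflects the variance inflation of unequal weights.
#'
#' @param p Proportion in `[0, 1]`.
#' @param effective_n Effective sample size (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
wald_ci <- function(p, effective_n, level = 0.95) {
  stopifnot(p >= 0, p <= 1, effective_n > 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / effective_n)
  c(max(0, p - half), min(1, p + half))
}

benchmark_table_row <- function(variable, level, n_sample, benchmark_pct,
                                unweighted, unweighted_ci, weighted,
                                weighted_ci) {
  data.frame(variable = variable, level = level, n_sample = n_sample,
             benchmark_pct = benchmark_pct,
             unweighted_pct = unweighted,
             unweighted_ci_lo = unweighted_ci[1], unweighted_ci_hi = unweighted_ci[2],
             diff_unweighted_pct = abs(unweighted - benchmark_pct),
             weighted_pct = weighted,
             weighted_ci_lo = weighted_ci[1], weighted_ci_hi = weighted_ci[2],
             diff_weighted_pct = abs(weighted - benchmark_pct),
             row.names = NULL)
}

#' Build a benchmark-comparison table from microdata and weights
#'
#' For every category of every listed variable: the benchmark percentage,
#' the unweighted and weighted study percentages with Wald 95% CIs (the
#' weighted CI uses the Kish effective sample size), and the absolute
#' percentage-point differences from the benchmark, computed at full
#' precision. Rows follow schema level order.
#'
#' Binary outcome variables may be given as `outcome_benchmarks` (named
#' scalar fractions); their rows report the prevalence of the `"Yes"` level.
#'
#' @param microdata A `microdata` object.
#' @param weights Raked weights (length N); `NULL` for all-ones.
#' @param benchmarks Named list of benchmark proportions per variable
#'   (fraction scale), e.g. `load_packaged_benchmarks()$nhis_2020`.
#' @param variables Demographic variables to tabulate.
#' @param outcome_benchmarks Optional named scalar fractions for binary
#'   outcome columns present in `microdata$data` with levels `"Yes"`/`"No"`.
#' @param level Confidence level for the CIs.
#' @return A `benchmark_table` data frame.
#' @export
build_benchmark_table <- function(microdata, weights, benchmarks, variables,
                                  outcome_benchmarks = NULL, level = 0.95) {
  stopifnot(inherits(microdata, "microdata"))
  n <- n_records(microdata)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("weights length ", length(weights), " != N = ", n, call. = FALSE)
  w1 <- rep(1, n)
  ess <- kish_ess(weights)
  rows <- list()
  for (v in variables) {
    bm <- benchmarks[[v]]
    if (is.null(bm))
      stop("no benchmark for variable '", v, "'", call. = FALSE)
    obs_u <- observed_marginal(microdata, w1, v)
    obs_w <- observed_marginal(microdata, weights, v)
    lv <- names(obs_u)
    if (!all(lv %in% names(bm)))
      stop("LevelMismatch: benchmark for '", v, "' lacks level(s) ",
           paste(setdiff(lv, names(bm)), collapse = ", "), call. = FALSE)
    for (l in lv) {
      nl <- sum(microdata$data[[v]] == l)
      rows[[length(rows) + 1L]] <- benchmark_table_row(
        v, l, nl, bm[[l]] * 100,
        obs_u[[l]] * 100, wald_ci(obs_u[[l]], n, level) * 100,
        obs_w[[l]] * 100, wald_ci(obs_w[[l]], ess, level) * 100)
    }
  }
  for (v in names(outcome_benchmarks)) {
    x <- microdata$data[[v]]
    if (is.null(x))
      stop("outcome column '", v, "' not present in microdata", call. = FALSE)
    pu <- sum(w1[x == "Yes"]) / sum(w1)
    pw <- sum(weights[x == "Yes"]) / sum(weights)
    rows[[length(rows) + 1L]] <- benchmark_table_row(
      v, "Yes", sum(x == "Yes"), outcome_benchmarks[[v]] * 100,
      pu * 100, wald_ci(pu, n, level) * 100,
      pw * 100, wald_ci(pw, ess, level) * 100)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' Benchmark table from published proportions (fixture mode)
#'
#' Rebuilds a benchmark-comparison table directly from published percentage
#' columns, with the absolute-difference columns recomputed at full
#' precision — no respondent-level data needed. This is how the packaged
#' tables are reproduced offline.
#'
#' @param fixture A fixture data frame with columns `variable`, `level`,
#'   `benchmark_pct`, `unweighted_pct`, `weighted_pct` (CI columns carried
#'   through if present), e.g. `load_packaged_benchmarks()$table2a`.
#' @return A `benchmark_table` data frame with recomputed difference
#'   columns.
#' @export
fixture_benchmark_table <- function(fixture) {
  need <- c("variable", "level", "benchmark_pct", "unweighted_pct",
            "weighted_pct")
  miss <- setdiff(need, names(fixture))
  if (length(miss))
    stop("fixture lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- fixture
  if (!"n_sample" %in% names(out)) out$n_sample <- NA_integer_
  for (col in c("unweighted_ci_lo", "unweighted_ci_hi",
                "weighted_ci_lo", "weighted_ci_hi"))
    if (!col %in% names(out)) out[[col]] <- NA_real_
  out$diff_unweighted_pct <- abs(out$unweighted_pct - out$benchmark_pct)
  out$diff_weighted_pct <- abs(out$weighted_pct - out$benchmark_pct)
  out <- out[c("variable", "level", "n_sample", "benchmark_pct",
               "unweighted_pct", "unweighted_ci_lo", "unweighted_ci_hi",
               "diff_unweighted_pct", "weighted_pct", "weighted_ci_lo",
               "weighted_ci_hi", "diff_weighted_pct")]
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' Mean absolute percentage-point difference
#'
#' The summary bias metric: the unweighted arithmetic mean, over category
#' rows, of the absolute percentage-point gap between study estimates and
#' benchmarks. Rows are categories, not variables — a 6-level variable
#' contributes 6 rows to the mean.
#'
#' @param table A `benchmark_table`.
#' @param column `"unweighted"` or `"weighted"` — which difference column
#'   to average.
#' @param rows Optional row subset (logical or integer index).
#' @return Mean absolute difference in percentage points.
#' @export
mean_abs_pp_difference <- function(table, column = c("unweighted", "weighted"),
                                   rows = NULL) {
  column <- match.arg(column)
  col <- paste0("diff_", column, "_pct")
  d <- table[[col]]
  if (!is.null(rows)) d <- d[rows]
  if (length(d) == 0L) stop("EmptySubset: no rows selected", call. = FALSE)
  mean(d)
}

#' Before/after change in the mean percentage difference
#'
#' @param mpd_before Mean absolute percentage-point difference before
#'   weighting (> 0 for a defined relative change).
#' @param mpd_after Mean absolute percentage-point difference after
#'   weighting.
#' @return List with `mpd_before`, `mpd_after`, `absolute_change`
#'   (percentage points) and `relative_change` (percent of the before
#'   value; `NA` when `mpd_before` is 0). Values are full precision; round
#'   only for display.
#' @export
change_metrics <- function(mpd_before, mpd_after) {
  absolute <- mpd_before - mpd_after
  relative <- if (mpd_before > 0) absolute / mpd_before * 100 else NA_real_
  list(mpd_before = mpd_before, mpd_after = mpd_after,
       absolute_change = absolute, relative_change = relative)
}
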