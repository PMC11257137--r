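#' One raking step on a single variable
#'
#' Multiplies each respondent's weight by the ratio of the known (benchmark)
#' proportion to the current weighted study proportion of their category.
#' After the step, the weighted marginal of `variable` equals its target up
#' to floating error — single-variable raking is exact post-stratification.
#'
#' @param microdata A `microdata` object.
#' @param weights Current positive weights, length N.
#' @param variable Variable to adjust on.
#' @param targets A [marginal_targets()] object covering `variable`.
#' @return Adjusted weight vector (not renormalized).
#' @export
rake_step <- function(microdata, weights, variable, targets) {
  tgt <- targets[[variable]]
  if (is.null(tgt))
    stop("no targets for variable '", variable, "'", call. = FALSE)
  obs <- observed_marginal(microdata, weights, variable)
  lv <- names(obs)
  tgt <- tgt[lv]
  empty <- tgt > 0 & obs == 0
  if (any(empty))
    stop("EmptyTargetCell: variable '", variable, "', level '",
         lv[which(empty)[1L]], "' has a positive target but no sample ",
         "support; collapse categories before raking", call. = FALSE)
  zero_target <- tgt <= 0 & obs > 0
  if (any(zero_target))
    stop("variable '", variable, "', level '", lv[which(zero_target)[1L]],
         "' has a zero target but positive sample support; zero-target ",
         "levels are not allowed in raking", call. = FALSE)
  ratio <- ifelse(obs > 0, tgt / obs, 1)
  weights * unname(ratio[match(microdata$data[[variable]], lv)])
}

#' Maximum marginal discrepancy
#'
#' The largest absolute difference, over the listed variables and their
#' levels, between the weighted study proportion and the benchmark target
#' (fraction units). This is the quantity driven below the prespecified
#' tolerance by [rake()].
#'
#' @inheritParams rake_step
#' @param variables Variables to scan.
#' @return Single non-negative number.
#' @export
max_discrepancy <- function(microdata, weights, targets, variables) {
  max(vapply(variables, function(v) {
    obs <- observed_marginal(microdata, weights, v)
    max(abs(obs - targets[[v]][names(obs)]))
  }, numeric(1)))
}

#' Cap extreme weights
#'
#' Truncates weights above `cap * mean(weights)` to that bound and
#' renormalizes to mean 1, repeating until no weight exceeds the cap.
#' Truncation shifts mass, so a single pass is not always enough.
#'
#' @param weights Positive numeric vector.
#' @param cap Ratio bound (> 1), or `NULL`/`Inf` to disable.
#' @param max_passes Safety bound on truncate-renormalize passes.
#' @return Capped weights with mean 1 (input weights are returned unchanged,
#'   up to scale, when nothing exceeds the cap).
#' @export
apply_cap <- function(weights, cap, max_passes = 100L) {
  if (is.null(cap) || !is.finite(cap)) return(weights)
  stopifnot(cap > 1)
  w <- weights / mean(weights)
  for (i in seq_len(max_passes)) {
    over <- w > cap
    if (!any(over)) return(w)
    w[over] <- cap
    w <- w / mean(w)
  }
  if (any(w > cap * (1 + 1e-9)))
    stop("CapInfeasible: capping at ", cap, " did not stabilize; ",
         "the cap is too tight for this weight distribution", call. = FALSE)
  w
}

#' Rake survey weights by iterative proportional fitting
#'
#' Sequentially adjusts respondent weights one variable at a time —
#' multiplying by the ratio of the known proportion to the current weighted
#' study proportion — and repeats full cycles over the raking variables
#' until the weighted marginals for all of them are simultaneously within
#' the prespecified discrepancy tolerance of the benchmarks, or the cycle
#' limit is reached. Convergence is judged on marginals recomputed after
#' the full cycle, never on per-step state.
#'
#' Weights are renormalized to mean 1 after every cycle, so the weighted N
#' equals the sample N. Records sharing the same combination of
#' raking-variable levels always receive weights proportional to their base
#' weights.
#'
#' @param microdata A `microdata` object (complete cases on the raking
#'   variables).
#' @param targets A [marginal_targets()] covering all raking variables.
#' @param config A [raking_config()].
#' @return Object of class `raking_result`: `weights` (mean 1, aligned with
#'   input rows), `converged`, `iterations_used`, `trace` (per-cycle max
#'   discrepancy, fraction units), and `residuals` (per variable, per level
#'   `|weighted proportion - target|` recomputed from the returned weights).
#' @export
rake <- function(microdata, targets, config) {
  stopifnot(inherits(microdata, "microdata"),
            inherits(config, "raking_config"))
  vars <- config$raking_variables
  missing_t <- setdiff(vars, names(targets))
  if (length(missing_t))
    stop("no targets for raking variable(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  missing_s <- setdiff(vars, schema_variables(microdata$schema))
  if (length(missing_s))
    stop("raking variable(s) not in schema: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  for (v in vars) {
    if (anyNA(microdata$data[[v]]))
      stop("variable '", v, "' has missing values; apply ",
           "complete_case_filter() before raking", call. = FALSE)
  }

  w <- microdata$base_weight / mean(microdata$base_weight)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (cycle in seq_len(config$max_iterations)) {
    iter <- cycle
    for (v in vars) w <- rake_step(microdata, w, v, targets)
    w <- w / mean(w)
    if (!is.null(config$weight_cap)) w <- apply_cap(w, config$weight_cap)
    d <- max_discrepancy(microdata, w, targets, vars)
    trace <- c(trace, d)
    if (d <= config$tolerance) {
      converged <- TRUE
      break
    }
  }

  residuals <- lapply(vars, function(v) {
    obs <- observed_marginal(microdata, w, v)
    abs(obs - targets[[v]][names(obs)])
  })
  names(residuals) <- vars

  structure(list(weights = w, converged = converged, iterations_used = iter,
                 trace = trace, residuals = residuals,
                 raking_variables = vars, tolerance = config$tolerance),
            class = "raking_result")
}

#' @export
print.raking_result <- function(x, ...) {
  cat("<raking_result>", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations_used, "cycle(s)\n")
  cat("  variables:", paste(x$raking_variables, collapse = ", "), "\n")
  cat(sprintf("  max residual: %.3g (tolerance %.3g)\n",
              max(unlist(x$residuals)), x$tolerance))
  cat(sprintf("  weight range: [%.3f, %.3f], Kish ESS: %.0f of %d\n",
              min(x$weights), max(x$weights), kish_ess(x$weights),
              length(x$weights)))
  invisible(x)
}

#' Serialize a raking result to JSON
#'
#' Writes weights, convergence flag, trace and residuals; weights stay
#' aligned with the input row order.
#'
#' @param result A `raking_result`.
#' @param path Output file path.
#' @export
write_raking_result <- function(result, path) {
  obj <- list(
    converged = result$converged,
    iterations_used = result$iterations_used,
    tolerance = result$tolerance,
    raking_variables = result$raking_variables,
    trace = result$trace,
    residuals = lapply(result$residuals, as.list),
    weights = result$weights
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
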