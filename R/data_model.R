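# Sentinel used internally for missing categorical responses. Readers map
# refusal/skip tokens to this value; complete_case_filter() drops it.
MISSING_SENTINEL <- NA_character_

#' Define a categorical survey variable
#'
#' A variable schema is the declared set of category labels for one
#' categorical survey variable. Level order is preserved everywhere
#' downstream (table rows, marginal vectors), so it should follow the order
#' in which results are to be reported.
#'
#' @param name Variable identifier (single non-empty string).
#' @param levels Character vector of at least two unique, non-empty
#'   category labels. Order is significant.
#' @return An object of class `variable_schema`.
#' @export
variable_schema <- function(name, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a single non-empty string", call. = FALSE)
  levels <- trimws(as.character(levels))
  if (length(levels) < 2L)
    stop("variable '", name, "' needs at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("variable '", name, "' has duplicated levels", call. = FALSE)
  if (any(!nzchar(levels)) || anyNA(levels))
    stop("variable '", name, "' has empty or NA levels", call. = FALSE)
  structure(list(name = name, levels = levels), class = "variable_schema")
}

#' Build a survey schema from a named list of level vectors
#'
#' @param levels_by_variable Named list; each element is the ordered level
#'   vector of one variable.
#' @return A list of [variable_schema()] objects, class `survey_schema`.
#' @export
survey_schema <- function(levels_by_variable) {
  nms <- names(levels_by_variable)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("all schema variables must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicated variable names in schema", call. = FALSE)
  out <- lapply(nms, function(v) variable_schema(v, levels_by_variable[[v]]))
  names(out) <- nms
  structure(out, class = "survey_schema")
}

schema_variables <- function(schema) names(schema)

schema_levels <- function(schema, variable) {
  if (!variable %in% names(schema))
    stop("variable '", variable, "' not in schema", call. = FALSE)
  schema[[variable]]$levels
}

#' Validate respondent-level categorical microdata
#'
#' Checks every recorded value against its declared schema levels
#' (exact match after whitespace trimming; `NA` is the missing sentinel and
#' always allowed here — use [complete_case_filter()] to drop incomplete
#' respondents) and attaches a positive base weight per record.
#' Rows are never silently dropped.
#'
#' @param records Data frame with one column per schema variable (extra
#'   columns are carried through untouched).
#' @param schema A [survey_schema()].
#' @param base_weight Optional positive numeric vector of length
#'   `nrow(records)`; defaults to 1 for every respondent, the convention for
#'   a non-probability sample with no design weights.
#' @return An object of class `microdata`: list with elements `data`
#'   (data frame), `schema`, and `base_weight`.
#' @export
validate_microdata <- function(records, schema, base_weight = NULL) {
  if (inherits(records, "microdata")) {
    base_weight <- if (is.null(base_weight)) records$base_weight else base_weight
    records <- records$data
  }
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("EmptyInput: `records` must be a non-empty data frame", call. = FALSE)
  if (!inherits(schema, "survey_schema"))
    stop("`schema` must be a survey_schema", call. = FALSE)
  vars <- schema_variables(schema)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("MissingColumn: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  for (v in vars) {
    vals <- trimws(as.character(records[[v]]))
    vals[!nzchar(vals) | is.na(vals)] <- MISSING_SENTINEL
    bad <- !is.na(vals) & !(vals %in% schema_levels(schema, v))
    if (any(bad)) {
      stop("UnknownLevel: variable '", v, "' has value '",
           vals[which(bad)[1L]], "' (row ", which(bad)[1L],
           ") not among declared levels", call. = FALSE)
    }
    records[[v]] <- vals
  }
  n <- nrow(records)
  if (is.null(base_weight)) base_weight <- rep(1, n)
  base_weight <- as.numeric(base_weight)
  if (length(base_weight) != n)
    stop("base_weight length ", length(base_weight), " != N = ", n, call. = FALSE)
  if (anyNA(base_weight) || any(base_weight <= 0))
    stop("NonPositiveWeight: all base weights must be > 0", call. = FALSE)
  structure(list(data = records, schema = schema, base_weight = base_weight),
            class = "microdata")
}

#' @export
print.microdata <- function(x, ...) {
  cat("<microdata> N =", nrow(x$data), "respondents,",
      length(x$schema), "schema variables\n")
  cat("  variables:", paste(schema_variables(x$schema), collapse = ", "), "\n")
  invisible(x)
}

n_records <- function(md) nrow(md$data)

#' Complete-case filter
#'
#' Restricts the microdata to respondents with a non-missing value for every
#' listed variable (complete-case analysis). Row order is preserved.
#'
#' @param microdata A `microdata` object.
#' @param variables Variables that must be complete; defaults to all schema
#'   variables.
#' @return List with `microdata` (the filtered object) and `n_dropped`.
#' @export
complete_case_filter <- function(microdata, variables = NULL) {
  stopifnot(inherits(microdata, "microdata"))
  vars <- if (is.null(variables)) schema_variables(microdata$schema) else variables
  unknown <- setdiff(vars, schema_variables(microdata$schema))
  if (length(unknown))
    stop("variables not in schema: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, n_records(microdata))
  for (v in vars) keep <- keep & !is.na(microdata$data[[v]])
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("AllRecordsDropped: no respondent is complete on ",
         paste(vars, collapse = ", "), call. = FALSE)
  out <- microdata
  out$data <- microdata$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out$base_weight <- microdata$base_weight[keep]
  list(microdata = out, n_dropped = n_dropped)
}

#' Weighted marginal proportions of one variable
#'
#' The "study proportion": for each declared level of `variable`, the share
#' of total weight carried by respondents at that level. Levels absent from
#' the sample get proportion 0. Missing values are an error — filter first.
#'
#' @param microdata A `microdata` object.
#' @param weights Positive numeric vector of length N; defaults to the base
#'   weights.
#' @param variable Variable name.
#' @return Named numeric vector over the schema levels, summing to 1.
#' @export
observed_marginal <- function(microdata, weights = NULL, variable) {
  stopifnot(inherits(microdata, "microdata"))
  if (is.null(weights)) weights <- microdata$base_weight
  n <- n_records(microdata)
  if (length(weights) != n || anyNA(weights) || any(weights <= 0))
    stop("weights must be positive and of length N", call. = FALSE)
  lv <- schema_levels(microdata$schema, variable)
  x <- microdata$data[[variable]]
  if (anyNA(x))
    stop("variable '", variable, "' has missing values; apply ",
         "complete_case_filter() first", call. = FALSE)
  tot <- vapply(lv, function(l) sum(weights[x == l]), numeric(1))
  tot / sum(weights)
}

#' Marginal calibration targets
#'
#' Benchmark ("known") population proportions per variable and level — the
#' constraints raking drives the weighted sample marginals toward. Per
#' variable, proportions must cover exactly the declared levels and sum to 1;
#' sums off by at most `renorm_tol` (rounding of published percentages) are
#' renormalized with a warning, larger deviations are an error.
#'
#' @param targets Named list: per variable, a named numeric vector of level
#'   proportions on the fraction scale.
#' @param schema Optional [survey_schema()] to check level sets against.
#' @param renorm_tol Maximum tolerated deviation of each per-variable sum
#'   from 1 before erroring (default 0.005).
#' @return Object of class `marginal_targets` (validated named list).
#' @export
marginal_targets <- function(targets, schema = NULL, renorm_tol = 0.005) {
  if (!is.list(targets) || is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("`targets` must be a named list of named numeric vectors", call. = FALSE)
  out <- list()
  for (v in names(targets)) {
    p <- targets[[v]]
    if (is.null(names(p)) || !is.numeric(p))
      stop("targets for '", v, "' must be a named numeric vector", call. = FALSE)
    names(p) <- trimws(names(p))
    if (anyDuplicated(names(p)))
      stop("duplicated level in targets for '", v, "'", call. = FALSE)
    if (anyNA(p) || any(p < 0))
      stop("targets for '", v, "' must be non-negative", call. = FALSE)
    s <- sum(p)
    if (abs(s - 1) > renorm_tol)
      stop("SumViolation: targets for '", v, "' sum to ", format(s),
           " (allowed deviation ", renorm_tol, ")", call. = FALSE)
    if (abs(s - 1) > 1e-9) {
      warning("renormalizing targets for '", v, "' (sum was ", format(s), ")",
              call. = FALSE)
      p <- p / s
    }
    if (!is.null(schema)) {
      lv <- schema_levels(schema, v)
      extra <- setdiff(names(p), lv)
      miss <- setdiff(lv, names(p))
      if (length(extra) || length(miss))
        stop("targets for '", v, "' do not match schema levels",
             if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
             if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
             call. = FALSE)
      p <- p[lv]
    }
    out[[v]] <- p
  }
  structure(out, class = "marginal_targets")
}

#' Raking configuration
#'
#' @param raking_variables Ordered character vector of variables to rake on.
#'   Order defines the within-cycle sweep (the converged weights do not
#'   depend on it for feasible problems).
#' @param tolerance Convergence tolerance on the maximum absolute difference
#'   between weighted marginal proportions and targets, fraction units.
#'   Default 2e-4 (0.02 percentage points).
#' @param max_iterations Maximum number of full raking cycles (default 1000).
#' @param weight_cap Optional cap on `weight / mean(weight)` (> 1), applied
#'   once per cycle; `NULL` (default) disables trimming.
#' @return Object of class `raking_config`.
#' @export
raking_config <- function(raking_variables, tolerance = 2e-4,
                          max_iterations = 1000L, weight_cap = NULL) {
  stopifnot(is.character(raking_variables), length(raking_variables) >= 1L)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L)
    stop("max_iterations must be >= 1", call. = FALSE)
  if (!is.null(weight_cap) && (!is.numeric(weight_cap) || weight_cap <= 1))
    stop("weight_cap must be > 1 when set", call. = FALSE)
  structure(list(raking_variables = raking_variables, tolerance = tolerance,
                 max_iterations = max_iterations, weight_cap = weight_cap),
            class = "raking_config")
}
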