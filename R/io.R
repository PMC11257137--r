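# Default tokens treated as missing when reading respondent CSVs; volunteer
# cohort exports commonly use skip/refusal strings rather than empty cells.
DEFAULT_MISSING_TOKENS <- c("", "NA", "PMI: Skip", "PMI: Prefer Not To Answer",
                            "Skip", "Prefer not to answer", "Don't Know")

#' Read respondent-level microdata from CSV
#'
#' Expects a header row and one column per schema variable; an optional
#' weight column supplies base weights. Cells matching `missing_tokens`
#' become the missing sentinel (dropped later by [complete_case_filter()]);
#' everything else must be a declared level.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required).
#' @param schema A [survey_schema()].
#' @param missing_tokens Character vector of cell values to treat as missing.
#' @param weight_column Optional name of the base-weight column.
#' @return A validated `microdata` object.
#' @export
read_microdata_csv <- function(path, schema,
                               missing_tokens = DEFAULT_MISSING_TOKENS,
                               weight_column = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  if (nrow(df) == 0L)
    stop("EmptyInput: no data rows in ", path, call. = FALSE)
  missing_cols <- setdiff(schema_variables(schema), names(df))
  if (length(missing_cols))
    stop("MissingColumn: ", paste(missing_cols, collapse = ", "),
         " absent from ", path, call. = FALSE)
  for (v in schema_variables(schema)) {
    x <- trimws(df[[v]])
    x[x %in% missing_tokens] <- NA_character_
    df[[v]] <- x
  }
  bw <- NULL
  if (!is.null(weight_column)) {
    if (!weight_column %in% names(df))
      stop("MissingColumn: weight column '", weight_column, "'", call. = FALSE)
    bw <- suppressWarnings(as.numeric(df[[weight_column]]))
    if (anyNA(bw))
      stop("MalformedWeight: non-numeric value in column '", weight_column,
           "' (row ", which(is.na(bw))[1L], ")", call. = FALSE)
  }
  validate_microdata(df, schema, base_weight = bw)
}

#' Write microdata to CSV
#'
#' Inverse of [read_microdata_csv()]: one row per respondent, one column per
#' schema variable plus a `.weight` column with the base weights. Missing
#' values are written as empty cells.
#'
#' @param microdata A `microdata` object.
#' @param path Output path.
#' @export
write_microdata_csv <- function(microdata, path) {
  df <- microdata$data[, schema_variables(microdata$schema), drop = FALSE]
  df$.weight <- microdata$base_weight
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read marginal calibration targets
#'
#' Accepts either a JSON object `{variable: {level: proportion}}` or a
#' 3-column CSV `variable,level,proportion`. Values default to the fraction
#' scale; percent-scale files must say so explicitly (a top-level
#' `"scale": "percent"` field in JSON, or `scale = "percent"` here) —
#' undeclared values above 1 are rejected rather than guessed at.
#'
#' @param path File path (`.json` or `.csv` by extension).
#' @param scale `"fraction"` (default) or `"percent"`; for JSON, a `scale`
#'   field in the file takes precedence.
#' @param schema Optional schema to validate level sets against.
#' @return A [marginal_targets()] object.
#' @export
read_targets <- function(path, scale = c("fraction", "percent"), schema = NULL) {
  scale <- match.arg(scale)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$scale)) {
      scale <- match.arg(obj$scale, c("fraction", "percent"))
      obj$scale <- NULL
    }
    raw <- lapply(obj, unlist)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("variable", "level", "proportion")
    if (!all(need %in% names(df)))
      stop("targets CSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    raw <- split(stats::setNames(df$proportion, trimws(df$level)),
                 df$variable)
  }
  vals <- unlist(raw)
  if (scale == "fraction" && any(vals > 1 + 1e-9))
    stop("ScaleAmbiguity: proportion ", format(max(vals)), " exceeds 1 but ",
         "no percent scale was declared", call. = FALSE)
  if (scale == "percent") raw <- lapply(raw, function(p) p / 100)
  marginal_targets(raw, schema = schema)
}

#' Write marginal targets to JSON
#'
#' @param targets A [marginal_targets()] object.
#' @param path Output path.
#' @export
write_targets <- function(targets, path) {
  obj <- c(list(scale = "fraction"), lapply(targets, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a benchmark-comparison table
#'
#' Machine rendering is plain CSV; the human rendering is an aligned text
#' table mirroring the published layout, percentages to 2 decimals, rows in
#' schema order.
#'
#' @param table A `benchmark_table` data frame (see
#'   [build_benchmark_table()]).
#' @param path Output path.
#' @param format `"csv"` or `"text"`.
#' @export
write_benchmark_table <- function(table, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- table
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "n_sample"
    df[num] <- lapply(df[num], function(x) round(x, 2))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    lines <- format_benchmark_table(table)
    writeLines(lines, path)
  }
  invisible(path)
}

format_benchmark_table <- function(table) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  ci <- function(p, lo, hi) ifelse(is.na(p), "",
    sprintf("%.2f (%.2f-%.2f)", p, lo, hi))
  body <- data.frame(
    Characteristic = paste(table$variable, table$level, sep = ": "),
    N = ifelse(is.na(table$n_sample), "", format(table$n_sample)),
    `Benchmark %` = fmt(table$benchmark_pct),
    `Unweighted % (95% CI)` = ci(table$unweighted_pct, table$unweighted_ci_lo,
                                 table$unweighted_ci_hi),
    `Abs diff` = fmt(table$diff_unweighted_pct),
    `Weighted % (95% CI)` = ci(table$weighted_pct, table$weighted_ci_lo,
                               table$weighted_ci_hi),
    `Abs diff ` = fmt(table$diff_weighted_pct),
    check.names = FALSE)
  widths <- pmax(nchar(names(body)),
                 vapply(body, function(c) max(nchar(c), 0L), integer(1)))
  pad <- function(row) paste(mapply(formatC, row, width = widths,
                                    flag = "-"), collapse = "  ")
  c(pad(names(body)), pad(strrep("-", widths)),
    apply(body, 1L, pad))
}
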