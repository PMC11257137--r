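# The 11 demographic raking candidates and the 6 binary outcomes used in the
# packaged benchmark tables. Level order follows the published table rows.

#' Names of the packaged binary outcome variables
#' @export
OUTCOME_VARIABLES <- c("hypertension", "coronary_artery_disease", "diabetes",
                       "alcohol_use", "ever_smoker", "health_insurance")

#' Schema of the 11 packaged demographic variables
#'
#' Age group (6 levels), sex (2), sexual orientation (2), race/ethnicity (5),
#' education (4), annual household income (4), home ownership (3), Census
#' region (4), self-reported health (5), usual place of care (5), and
#' interval since last doctor's visit (3) — the variables available in both
#' the benchmark survey and the volunteer cohort, with the published
#' category definitions.
#'
#' @return A [survey_schema()] covering all 11 variables in table order.
#' @export
demographic_schema <- function() {
  t2a <- read_fixture("table2a_demographics.csv")
  survey_schema(split(t2a$level, factor(t2a$variable, unique(t2a$variable))))
}

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "svyrake")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

props_from <- function(df, col) {
  demo <- df[!df$variable %in% OUTCOME_VARIABLES, ]
  out <- lapply(split(demo, factor(demo$variable, unique(demo$variable))),
                function(d) stats::setNames(d[[col]] / 100, d$level))
  outc <- df[df$variable %in% OUTCOME_VARIABLES, ]
  if (nrow(outc)) out <- c(out, stats::setNames(as.list(outc[[col]] / 100),
                                                outc$variable))
  out
}

#' Load the packaged benchmark fixtures
#'
#' Returns the published benchmark-comparison tables (43 demographic
#' category rows over 11 variables; 6 outcome rows) transcribed at the
#' printed 2-decimal precision, plus convenient proportion lookups on the
#' fraction scale:
#' \describe{
#'   \item{table2a, table2b}{the raw fixture data frames}
#'   \item{nhis_2020}{benchmark proportions; demographic variables map to
#'     named level vectors, outcomes to scalars. Values are the printed
#'     numbers divided by 100, \emph{not} renormalized — use
#'     [nhis_targets()] for raking.}
#'   \item{aou_unweighted, aou_weighted}{published cohort proportions, same
#'     shape, for evaluation-only use.}
#' }
#'
#' @return List as described.
#' @export
load_packaged_benchmarks <- function() {
  t2a <- read_fixture("table2a_demographics.csv")
  t2b <- read_fixture("table2b_outcomes.csv")
  both <- rbind(t2a, t2b)
  list(table2a = t2a, table2b = t2b,
       nhis_2020 = props_from(both, "benchmark_pct"),
       aou_unweighted = props_from(both, "unweighted_pct"),
       aou_weighted = props_from(both, "weighted_pct"))
}

#' Benchmark demographic proportions as raking targets
#'
#' The published benchmark percentages for the demographic variables,
#' validated and (where a printed column sums to 100.1 because of rounding)
#' renormalized into proper [marginal_targets()].
#'
#' @param variables Which variables to include (default all 11).
#' @return A [marginal_targets()] object.
#' @export
nhis_targets <- function(variables = NULL) {
  bm <- load_packaged_benchmarks()$nhis_2020
  demo <- bm[!names(bm) %in% OUTCOME_VARIABLES]
  if (!is.null(variables)) {
    unknown <- setdiff(variables, names(demo))
    if (length(unknown))
      stop("not packaged demographic variables: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    demo <- demo[variables]
  }
  suppressWarnings(marginal_targets(demo, schema = NULL))
}

#' The published raking-variable set
#'
#' The six variables the published analysis actually raked on: age, sex,
#' race/ethnicity, Census region, annual household income, and home
#' ownership.
#' @export
PUBLISHED_RAKING_VARIABLES <- c("age", "sex", "race_ethnicity", "region",
                                "income", "home_ownership")
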