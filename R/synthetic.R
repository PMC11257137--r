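# Synthetic volunteer-cohort generator: a benchmark-distributed population,
# a logistic self-selection model that over/under-recruits demographic
# groups the way large volunteer research cohorts do, and binary health
# outcomes whose log-odds are additive in demographic categories.

#' Configuration for the synthetic cohort generator
#'
#' @param population_targets Named list of marginal proportions (fraction
#'   scale) defining the population's demographic composition; defaults are
#'   supplied by [default_synthetic_config()].
#' @param association Optional dependence between one pair of variables:
#'   `list(variables = c(v1, v2), tilt = matrix)` where `tilt[i, j]` is a
#'   log-linear tilt added to the independence joint of level i of v1 and
#'   level j of v2; the tilted joint is rescaled (iterative proportional
#'   fitting on the probability table) so both marginals still equal their
#'   targets exactly.
#' @param participation `list(intercept, offsets)`: logistic self-selection
#'   model; `offsets` is a named list mapping variable -> named vector of
#'   per-level log-odds offsets.
#' @param outcome_models Named list per outcome:
#'   `list(prevalence, coefficients)` with `coefficients` a named list of
#'   per-level log-odds vectors; the intercept is solved so the closed-form
#'   population prevalence equals `prevalence` exactly.
#' @param n_pop Population size to draw.
#' @param n_sample Number of cohort participants to self-select.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(population_targets, association = NULL,
                             participation, outcome_models = list(),
                             n_pop = 200000L, n_sample = 20000L, seed = 1L) {
  targets <- marginal_targets(population_targets)
  if (!is.null(association)) {
    stopifnot(length(association$variables) == 2L,
              all(association$variables %in% names(targets)),
              is.matrix(association$tilt))
    d <- vapply(association$variables,
                function(v) length(targets[[v]]), integer(1))
    if (!all(dim(association$tilt) == d))
      stop("tilt matrix must be ", d[1], "x", d[2], call. = FALSE)
  }
  stray <- setdiff(names(participation$offsets), names(targets))
  if (length(stray))
    stop("participation offsets reference unknown variable(s): ",
         paste(stray, collapse = ", "), call. = FALSE)
  for (v in names(participation$offsets)) {
    miss <- setdiff(names(targets[[v]]), names(participation$offsets[[v]]))
    if (length(miss))
      stop("participation offsets for '", v, "' miss level(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  n_pop <- as.integer(n_pop); n_sample <- as.integer(n_sample)
  stopifnot(n_sample >= 1L, n_pop >= n_sample)
  structure(list(population_targets = targets, association = association,
                 participation = participation,
                 outcome_models = outcome_models,
                 n_pop = n_pop, n_sample = n_sample, seed = as.integer(seed)),
            class = "synthetic_config")
}

# IPF on a 2-way probability table so its margins match (pA, pB) exactly.
# Used only to impose the configured association while preserving the
# marginal targets; raking of respondent weights lives in rake().
fit_pair_joint <- function(pA, pB, tilt, tol = 1e-12, max_iter = 10000L) {
  joint <- outer(pA, pB) * exp(tilt)
  if (any(!is.finite(joint)) || any(joint < 0))
    stop("InfeasibleAssociation: tilt produces a degenerate joint",
         call. = FALSE)
  joint <- joint / sum(joint)
  for (i in seq_len(max_iter)) {
    joint <- joint * (pA / rowSums(joint))
    joint <- t(t(joint) * (pB / colSums(joint)))
    if (max(abs(rowSums(joint) - pA)) < tol &&
        max(abs(colSums(joint) - pB)) < tol) break
  }
  dimnames(joint) <- list(names(pA), names(pB))
  joint
}

#' Draw a benchmark-distributed population
#'
#' Each variable is drawn independently from its marginal target, except
#' the configured association pair, which is drawn from the tilted joint
#' (whose margins still equal the targets). Reproducible under
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param n_pop Override for the population size.
#' @return A `microdata` object of `n_pop` records.
#' @export
draw_population <- function(config, n_pop = config$n_pop) {
  targets <- config$population_targets
  set.seed(config$seed)
  df <- list()
  pair <- if (!is.null(config$association)) config$association$variables
  for (v in names(targets)) {
    if (!is.null(pair) && v %in% pair) next
    p <- targets[[v]]
    df[[v]] <- sample(names(p), n_pop, replace = TRUE, prob = p)
  }
  if (!is.null(pair)) {
    joint <- fit_pair_joint(targets[[pair[1]]], targets[[pair[2]]],
                            config$association$tilt)
    cells <- sample(length(joint), n_pop, replace = TRUE, prob = as.vector(joint))
    idx <- arrayInd(cells, dim(joint))
    df[[pair[1]]] <- rownames(joint)[idx[, 1]]
    df[[pair[2]]] <- colnames(joint)[idx[, 2]]
  }
  df <- as.data.frame(df[names(targets)], check.names = FALSE,
                      stringsAsFactors = FALSE)
  schema <- survey_schema(lapply(targets, names))
  validate_microdata(df, schema)
}

#' Logistic participation probability
#'
#' `plogis(intercept + sum of per-level offsets)` for each record: the
#' self-selection model. Groups with positive offsets volunteer more often
#' and end up over-represented in the cohort.
#'
#' @param data Data frame of demographic columns (or a `microdata` object).
#' @param participation `list(intercept, offsets)` as in
#'   [synthetic_config()].
#' @return Probability vector in (0, 1).
#' @export
participation_probability <- function(data, participation) {
  if (inherits(data, "microdata")) data <- data$data
  eta <- rep(participation$intercept, nrow(data))
  for (v in names(participation$offsets)) {
    off <- participation$offsets[[v]]
    got <- off[data[[v]]]
    if (anyNA(got))
      stop("participation offsets for '", v, "' do not cover all observed ",
           "levels", call. = FALSE)
    eta <- eta + unname(got)
  }
  pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
}

#' Self-select a study sample from the population
#'
#' Draws exactly `n_sample` records without replacement with selection
#' probability proportional to each record's participation probability,
#' so high-offset groups are over-represented in the sample.
#'
#' @param population `microdata` from [draw_population()].
#' @param participation Participation model (see [synthetic_config()]).
#' @param n_sample Number of participants.
#' @param seed Integer seed.
#' @return A `microdata` object of `n_sample` records.
#' @export
sample_study <- function(population, participation, n_sample, seed) {
  force(participation)
  n <- n_records(population)
  if (n_sample > n)
    stop("InsufficientPopulation: n_sample ", n_sample, " > population ",
         n, call. = FALSE)
  p <- participation_probability(population, participation)
  set.seed(seed)
  idx <- sort(sample.int(n, n_sample, replace = FALSE, prob = p))
  out <- population
  out$data <- population$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$base_weight <- population$base_weight[idx]
  out
}

outcome_linear_predictor <- function(data, model) {
  eta <- rep(model$intercept, nrow(data))
  for (v in names(model$coefficients)) {
    beta <- model$coefficients[[v]]
    got <- beta[data[[v]]]
    if (anyNA(got))
      stop("outcome coefficients for '", v, "' do not cover all observed ",
           "levels", call. = FALSE)
    eta <- eta + unname(got)
  }
  eta
}

#' Generate binary outcome columns
#'
#' Each outcome is drawn Bernoulli with success probability
#' `plogis(intercept + sum of demographic coefficients)` and stored as a
#' `"Yes"`/`"No"` column alongside the demographic variables. Outcome
#' intercepts must already be resolved (see [resolve_outcome_intercepts()]).
#'
#' @param microdata A `microdata` object.
#' @param outcome_models Named list of resolved outcome models.
#' @param seed Integer seed.
#' @return The input `microdata` with one extra column per outcome.
#' @export
generate_outcomes <- function(microdata, outcome_models, seed) {
  # force arguments before touching the RNG: a lazily evaluated microdata
  # promise (itself drawing random numbers) must not run after set.seed()
  out <- microdata
  force(outcome_models)
  set.seed(seed)
  for (o in names(outcome_models)) {
    p <- stats::plogis(outcome_linear_predictor(out$data, outcome_models[[o]]))
    out$data[[o]] <- ifelse(stats::runif(n_records(out)) < p, "Yes", "No")
  }
  out
}

# Joint enumeration of the variables an outcome model touches: product of
# marginals, with the association pair replaced by its tilted joint when
# either member is involved.
enumerate_joint <- function(config, variables) {
  targets <- config$population_targets
  pair <- if (!is.null(config$association)) config$association$variables
  use_pair <- !is.null(pair) && any(pair %in% variables)
  vars <- union(variables, if (use_pair) pair)
  if (length(vars) == 0L)  # intercept-only model: a single trivial cell
    return(list(grid = data.frame(row.names = 1L), prob = 1))
  grid <- expand.grid(lapply(targets[vars], names),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(grid))
  indep <- setdiff(vars, if (use_pair) pair)
  for (v in indep) prob <- prob * unname(targets[[v]][grid[[v]]])
  if (use_pair) {
    joint <- fit_pair_joint(targets[[pair[1]]], targets[[pair[2]]],
                            config$association$tilt)
    prob <- prob * joint[cbind(grid[[pair[1]]], grid[[pair[2]]])]
  }
  list(grid = grid, prob = prob)
}

#' Closed-form population prevalence of an outcome
#'
#' Exact expectation of the outcome model over the population joint
#' distribution (independent marginals plus the configured association) —
#' the ground truth that weighted sample estimates are judged against.
#'
#' @param config A [synthetic_config()] with resolved intercepts.
#' @param outcome Outcome name.
#' @return Prevalence on the fraction scale.
#' @export
population_prevalence <- function(config, outcome) {
  model <- config$outcome_models[[outcome]]
  if (is.null(model)) stop("unknown outcome '", outcome, "'", call. = FALSE)
  ej <- enumerate_joint(config, names(model$coefficients))
  sum(ej$prob * stats::plogis(outcome_linear_predictor(ej$grid, model)))
}

#' Solve outcome intercepts against stated prevalences
#'
#' For each outcome model with a `prevalence` field, finds the intercept at
#' which the closed-form population prevalence equals that value, so the
#' generator's ground truth matches the stated benchmark by construction.
#'
#' @param config A [synthetic_config()].
#' @return The config with `intercept` filled in for every outcome model.
#' @export
resolve_outcome_intercepts <- function(config) {
  for (o in names(config$outcome_models)) {
    model <- config$outcome_models[[o]]
    if (!is.null(model$intercept)) next
    ej <- enumerate_joint(config, names(model$coefficients))
    model$intercept <- 0
    f <- function(a) {
      model$intercept <- a
      sum(ej$prob * stats::plogis(outcome_linear_predictor(ej$grid, model))) -
        model$prevalence
    }
    model$intercept <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
    config$outcome_models[[o]] <- model
  }
  config
}

#' Default synthetic-cohort profile
#'
#' The stated world of the generator: a population with the packaged 2020
#' benchmark demographic composition (11 variables), a mild positive
#' education-by-income association, a logistic self-selection model whose
#' offsets reproduce the documented volunteer-cohort composition biases
#' (older adults, females, non-Hispanic Whites, college graduates,
#' Northeasterners over-represented; young adults, males,
#' Hispanic/Black/Asian adults, Southern residents, the non-college-educated
#' under-represented), and six binary outcomes whose population prevalences
#' equal the packaged benchmark values by construction.
#'
#' @param n_pop Population size (default 200,000).
#' @param n_sample Cohort size (default 20,000; use 100,391 for a
#'   full-scale run).
#' @param seed Integer seed.
#' @return A resolved [synthetic_config()].
#' @export
default_synthetic_config <- function(n_pop = 200000L, n_sample = 20000L,
                                     seed = 1L) {
  targets <- nhis_targets()
  bm <- load_packaged_benchmarks()$nhis_2020

  offsets <- list(
    age = c("18-24" = -1.2, "25-34" = -0.3, "35-44" = -0.2, "45-54" = -0.1,
            "55-64" = 0.3, "65+" = 0.6),
    sex = c(Male = -0.6, Female = 0),
    sexual_orientation = c(Straight = 0, "Bisexual/Gay/Lesbian/Other" = 1.1),
    race_ethnicity = c("Non-Hispanic White" = 0.4, "Non-Hispanic Black" = -0.4,
                       "Non-Hispanic Asian" = -0.55, Hispanic = -0.7,
                       Other = -0.1),
    education = c("Did not graduate high school" = -1.8,
                  "High school graduate" = -1.2, "Some college" = -0.3,
                  "College graduate" = 0.8),
    income = c("Less than $25,000" = 0,
               "$25,000 to less than $35,000" = -0.2,
               "$35,000 to less than $50,000" = -0.2,
               "$50,000 or more" = 0.15),
    home_ownership = c(Own = 0, Rent = 0, "Other living arrangement" = 1.0),
    region = c(Northeast = 0.5, Midwest = 0.3, South = -0.5, West = 0),
    self_reported_health = c(Excellent = -0.55, "Very good" = 0.1,
                             Good = 0.15, Fair = 0.2, Poor = -0.05),
    usual_place_of_care = c("Doctor's office, clinic or health center" = 0.5,
                            "Urgent care or minute clinic" = -0.2,
                            "Hospital emergency room" = -0.3,
                            "Some other place" = -0.15,
                            "Don't have a usual place for care" = -0.85),
    last_visit_interval = c("Less than 1 year" = 1.0,
                            "1 year to less than 2 years" = -1.0,
                            "More than 2 years" = -1.6))

  # Education x income tilt: positive log-linear dependence so raking on
  # income alone cannot fully correct education-driven outcome bias.
  se <- seq(-1, 1, length.out = 4)
  tilt <- 1.2 * outer(se, se)

  mk <- function(prevalence, coefficients)
    list(prevalence = prevalence, coefficients = coefficients)
  age_lv <- names(targets$age)
  edu_lv <- names(targets$education)
  inc_lv <- names(targets$income)
  outcome_models <- list(
    hypertension = mk(bm$hypertension, list(
      age = stats::setNames(c(0, 0.5, 1.0, 1.5, 2.0, 2.6), age_lv),
      sex = c(Male = 0.3, Female = 0),
      race_ethnicity = c("Non-Hispanic White" = 0, "Non-Hispanic Black" = 0.6,
                         "Non-Hispanic Asian" = 0, Hispanic = 0, Other = 0))),
    coronary_artery_disease = mk(bm$coronary_artery_disease, list(
      age = stats::setNames(c(0, 0.3, 0.8, 1.3, 1.9, 2.5), age_lv),
      sex = c(Male = 0.5, Female = 0))),
    diabetes = mk(bm$diabetes, list(
      age = stats::setNames(c(0, 0.4, 0.9, 1.4, 1.8, 2.2), age_lv),
      race_ethnicity = c("Non-Hispanic White" = 0, "Non-Hispanic Black" = 0.5,
                         "Non-Hispanic Asian" = 0.3, Hispanic = 0.5,
                         Other = 0),
      income = stats::setNames(c(0.4, 0.2, 0.1, 0), inc_lv))),
    alcohol_use = mk(bm$alcohol_use, list(
      education = stats::setNames(c(-0.8, -0.4, 0, 0.6), edu_lv),
      age = stats::setNames(c(0.2, 0.3, 0.2, 0.1, 0, -0.3), age_lv),
      income = stats::setNames(c(0, 0.1, 0.2, 0.3), inc_lv))),
    ever_smoker = mk(bm$ever_smoker, list(
      age = stats::setNames(c(-1.0, -0.6, -0.3, 0, 0.3, 0.5), age_lv),
      education = stats::setNames(c(0.8, 0.6, 0.3, -0.6), edu_lv),
      sex = c(Male = 0.3, Female = 0))),
    health_insurance = mk(bm$health_insurance, list(
      age = stats::setNames(c(0, 0, 0.1, 0.2, 0.5, 2.0), age_lv),
      income = stats::setNames(c(-0.8, -0.4, -0.2, 0.6), inc_lv),
      education = stats::setNames(c(0, 0, 0.2, 0.5), edu_lv))))

  cfg <- synthetic_config(
    population_targets = unclass(targets),
    association = list(variables = c("education", "income"), tilt = tilt),
    participation = list(intercept = -2.2, offsets = offsets),
    outcome_models = outcome_models,
    n_pop = n_pop, n_sample = n_sample, seed = seed)
  resolve_outcome_intercepts(cfg)
}

#' Run the full synthetic pipeline
#'
#' Draws the population, self-selects the cohort, and generates outcome
#' columns for both; sub-seeds are derived from `config$seed` so the whole
#' pipeline is reproducible from one integer.
#'
#' @param config A resolved [synthetic_config()].
#' @return List: `population` and `sample` (`microdata` with outcome
#'   columns), `true_prevalence` (closed-form population prevalences,
#'   fraction scale), and `config`.
#' @export
simulate_cohort <- function(config) {
  pop <- draw_population(config)
  smp <- sample_study(pop, config$participation, config$n_sample,
                      seed = config$seed + 1L)
  pop <- generate_outcomes(pop, config$outcome_models,
                           seed = config$seed + 2L)
  smp <- generate_outcomes(smp, config$outcome_models,
                           seed = config$seed + 3L)
  truth <- vapply(names(config$outcome_models),
                  function(o) population_prevalence(config, o), numeric(1))
  list(population = pop, sample = smp, true_prevalence = truth,
       config = config)
}
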