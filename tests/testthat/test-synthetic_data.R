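cfg_small <- small_synthetic_config(seed = 11L)

test_that("draw_population hits its marginal targets within sampling error", {
  pop <- draw_population(cfg_small)
  expect_equal(n_records <- nrow(pop$data), cfg_small$n_pop)
  tg <- cfg_small$population_targets
  n <- cfg_small$n_pop
  for (v in names(tg)) {
    emp <- observed_marginal(pop, NULL, v)
    se <- sqrt(tg[[v]] * (1 - tg[[v]]) / n)
    expect_true(all(abs(emp - tg[[v]]) <= 4 * se + 1e-12),
                info = paste("variable", v))
  }
  # determinism
  pop2 <- draw_population(cfg_small)
  expect_identical(pop$data, pop2$data)
})

test_that("the association tilt induces dependence but preserves margins", {
  pop <- draw_population(cfg_small)
  tab <- table(pop$data$education, pop$data$income)
  # positive dependence: college graduates sit in the top income bracket
  # more often than independence predicts
  p_joint <- tab["College graduate", "$50,000 or more"] / sum(tab)
  p_marg <- (sum(tab["College graduate", ]) / sum(tab)) *
    (sum(tab[, "$50,000 or more"]) / sum(tab))
  expect_gt(p_joint, p_marg * 1.2)
})

test_that("participation_probability is logistic and monotone in offsets", {
  part <- cfg_small$participation
  pop <- draw_population(small_synthetic_config(seed = 2L))
  p <- participation_probability(pop, part)
  expect_true(all(p > 0 & p < 1))
  # zero offsets collapse to the intercept
  flat <- list(intercept = -1, offsets = list())
  expect_equal(unique(participation_probability(pop, flat)),
               stats::plogis(-1))
  # a 65+ record beats an otherwise-identical 18-24 record
  two <- pop$data[c(1, 1), ]
  two$age <- c("65+", "18-24")
  p2 <- participation_probability(two, part)
  expect_gt(p2[1], p2[2])
})

test_that("sample_study over-represents high-offset groups as documented", {
  pop <- draw_population(cfg_small)
  smp <- sample_study(pop, cfg_small$participation, cfg_small$n_sample,
                      seed = 12L)
  tg <- cfg_small$population_targets
  om <- function(v) observed_marginal(smp, NULL, v)
  # direction of every documented composition bias
  expect_gt(om("age")[["65+"]], tg$age[["65+"]])
  expect_lt(om("age")[["18-24"]], tg$age[["18-24"]])
  expect_lt(om("sex")[["Male"]], tg$sex[["Male"]])
  expect_gt(om("sex")[["Female"]], tg$sex[["Female"]])
  expect_gt(om("race_ethnicity")[["Non-Hispanic White"]],
            tg$race_ethnicity[["Non-Hispanic White"]])
  expect_lt(om("race_ethnicity")[["Hispanic"]],
            tg$race_ethnicity[["Hispanic"]])
  expect_lt(om("race_ethnicity")[["Non-Hispanic Black"]],
            tg$race_ethnicity[["Non-Hispanic Black"]])
  expect_lt(om("region")[["South"]], tg$region[["South"]])
  expect_gt(om("region")[["Northeast"]], tg$region[["Northeast"]])
  expect_gt(om("education")[["College graduate"]],
            tg$education[["College graduate"]])
  expect_lt(om("education")[["Did not graduate high school"]],
            tg$education[["Did not graduate high school"]])

  # zero offsets: unbiased subsampling stays near targets
  flat <- list(intercept = -2, offsets = list())
  smp0 <- sample_study(pop, flat, 2000L, seed = 12L)
  emp <- observed_marginal(smp0, NULL, "age")
  se <- sqrt(tg$age * (1 - tg$age) / 2000)
  expect_true(all(abs(emp - tg$age) <= 4 * se))

  # taking the whole population is the identity
  all_smp <- sample_study(pop, flat, cfg_small$n_pop, seed = 1L)
  expect_identical(all_smp$data, pop$data)
  expect_error(sample_study(pop, flat, cfg_small$n_pop + 1L, seed = 1L),
               "InsufficientPopulation")
})

test_that("outcome generation matches its closed-form prevalence", {
  # flat model: prevalence equals the intercept's logistic transform
  cfg <- cfg_small
  cfg$outcome_models <- list(
    flat = list(intercept = stats::qlogis(0.3), coefficients = list()))
  pop <- draw_population(cfg)
  pop <- generate_outcomes(pop, cfg$outcome_models, seed = 5L)
  expect_equal(mean(pop$data$flat == "Yes"), 0.3, tolerance = 0.02)
  expect_equal(population_prevalence(cfg, "flat"), 0.3, tolerance = 1e-12)

  # determinism under a fixed seed
  pop2 <- generate_outcomes(draw_population(cfg), cfg$outcome_models,
                            seed = 5L)
  expect_identical(pop$data$flat, pop2$data$flat)

  # resolved intercepts reproduce the stated prevalences exactly
  for (o in names(cfg_small$outcome_models)) {
    expect_equal(population_prevalence(cfg_small, o),
                 cfg_small$outcome_models[[o]]$prevalence,
                 tolerance = 1e-9, info = o)
  }
  # large-sample empirical prevalence agrees with the closed form
  popn <- generate_outcomes(draw_population(cfg_small),
                            cfg_small$outcome_models, seed = 6L)
  for (o in c("hypertension", "alcohol_use")) {
    expect_equal(mean(popn$data[[o]] == "Yes"),
                 population_prevalence(cfg_small, o), tolerance = 0.02,
                 info = o)
  }
})

test_that("raking the biased sample recovers the generating marginals", {
  sim <- simulate_cohort(cfg_small)
  tg <- marginal_targets(unclass(cfg_small$population_targets))
  res <- rake(sim$sample, tg, raking_config(PUBLISHED_RAKING_VARIABLES))
  expect_true(res$converged)
  expect_lte(max(unlist(res$residuals)), 2e-4)
})

test_that("weighting moves outcome prevalences toward the closed-form truth", {
  sim <- simulate_cohort(cfg_small)
  tg <- marginal_targets(unclass(cfg_small$population_targets))
  res <- rake(sim$sample, tg, raking_config(PUBLISHED_RAKING_VARIABLES))
  truth <- sim$true_prevalence
  smp <- sim$sample
  pu <- vapply(names(truth), function(o) mean(smp$data[[o]] == "Yes"),
               numeric(1))
  pw <- vapply(names(truth), function(o)
    sum(res$weights[smp$data[[o]] == "Yes"]) / sum(res$weights), numeric(1))
  expect_lt(mean(abs(pw - truth)), mean(abs(pu - truth)))
})
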