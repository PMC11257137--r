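test_that("rake_step multiplies by target/observed and hits the target", {
  sch <- survey_schema(list(g = c("A", "B")))
  md <- validate_microdata(data.frame(g = c(rep("A", 6), rep("B", 4))), sch)
  tg <- marginal_targets(list(g = c(A = 0.5, B = 0.5)))

  w1 <- rake_step(md, rep(1, 10), "g", tg)
  expect_equal(unique(w1[md$data$g == "A"]), 0.5 / 0.6)
  expect_equal(unique(w1[md$data$g == "B"]), 0.5 / 0.4)
  expect_equal(observed_marginal(md, w1, "g"), c(A = 0.5, B = 0.5))

  # fixed point: already-matching marginals leave weights unchanged
  tg2 <- marginal_targets(list(g = c(A = 0.6, B = 0.4)))
  expect_equal(rake_step(md, rep(1, 10), "g", tg2), rep(1, 10))

  # positive target with no sample support is a hard error
  md2 <- validate_microdata(data.frame(g = rep("A", 5)), sch)
  expect_error(rake_step(md2, rep(1, 5), "g", tg), "EmptyTargetCell")
})

test_that("max_discrepancy is the max over variables and levels", {
  md <- toy_microdata(n = 50, seed = 1)
  tg <- marginal_targets(list(
    color = observed_marginal(md, NULL, "color"),
    shape = observed_marginal(md, NULL, "shape")))
  expect_equal(max_discrepancy(md, md$base_weight, tg, names(tg)), 0)
  tg$color["Red"] <- tg$color["Red"] + 0.1
  tg$color["Blue"] <- tg$color["Blue"] - 0.1
  expect_equal(max_discrepancy(md, md$base_weight, tg, names(tg)), 0.1,
               tolerance = 1e-12)
})

test_that("apply_cap bounds weight/mean ratio and renormalizes", {
  expect_equal(apply_cap(c(1, 1, 1), 5), c(1, 1, 1))
  w <- apply_cap(c(9, 1, 1, 1), 2)
  expect_equal(mean(w), 1)
  expect_lte(max(w) / mean(w), 2 + 1e-12)
  expect_equal(apply_cap(c(3, 1, 2), NULL), c(3, 1, 2))
  expect_equal(apply_cap(c(3, 1, 2), Inf), c(3, 1, 2))
})

test_that("single-variable rake equals closed-form post-stratification", {
  sch <- survey_schema(list(g = c("A", "B", "C")))
  md <- validate_microdata(
    data.frame(g = c(rep("A", 10), rep("B", 6), rep("C", 4))), sch)
  tg <- marginal_targets(list(g = c(A = 0.3, B = 0.3, C = 0.4)))
  res <- rake(md, tg, raking_config("g", tolerance = 1e-12))
  expect_true(res$converged)
  expect_equal(res$iterations_used, 1L)
  obs <- c(A = 0.5, B = 0.3, C = 0.2)
  expected <- unname((tg$g / obs)[md$data$g])
  expected <- expected / mean(expected)
  expect_equal(res$weights, expected, tolerance = 1e-14)
})

test_that("rake matches the brute-force contingency-table IPF oracle", {
  # deterministic toy case from first principles
  sch <- survey_schema(list(v1 = c("A0", "A1"), v2 = c("B0", "B1")))
  df <- data.frame(v1 = c("A0", "A0", "A0", "A1", "A1"),
                   v2 = c("B0", "B0", "B1", "B0", "B1"))
  md <- validate_microdata(df, sch)
  tg <- marginal_targets(list(v1 = c(A0 = 0.5, A1 = 0.5),
                              v2 = c(B0 = 0.5, B1 = 0.5)))
  cfg <- raking_config(c("v1", "v2"), tolerance = 1e-11,
                       max_iterations = 10000L)
  res <- rake(md, tg, cfg)
  oracle <- bruteforce_ipf_weights(md$data, "v1", "v2", tg$v1, tg$v2)
  expect_true(res$converged)
  expect_equal(res$weights, unname(oracle), tolerance = 1e-8)

  # property: 50 random 2-variable problems
  for (seed in 1:50) {
    prob <- random_two_var_problem(seed)
    res <- rake(prob$microdata, prob$targets, cfg)
    expect_true(res$converged, info = paste("seed", seed))
    oracle <- bruteforce_ipf_weights(prob$microdata$data, "v1", "v2",
                                     prob$targets$v1, prob$targets$v2)
    expect_equal(res$weights, unname(oracle), tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})

test_that("rake invariants: normalization, positivity, honest reporting", {
  prob <- random_two_var_problem(99)
  cfg <- raking_config(c("v1", "v2"), tolerance = 1e-10)
  res <- rake(prob$microdata, prob$targets, cfg)

  expect_equal(mean(res$weights), 1, tolerance = 1e-12)
  expect_true(all(res$weights > 0))
  expect_equal(length(res$trace), res$iterations_used)
  # residuals recomputed from returned weights agree with observed marginals
  for (v in c("v1", "v2")) {
    obs <- observed_marginal(prob$microdata, res$weights, v)
    expect_equal(res$residuals[[v]],
                 abs(obs - prob$targets[[v]][names(obs)]))
    expect_true(all(res$residuals[[v]] <= cfg$tolerance))
  }

  # within-cell equal treatment: same cell -> identical weight (unit base)
  cell <- interaction(prob$microdata$data$v1, prob$microdata$data$v2)
  spread <- tapply(res$weights, cell, function(w) diff(range(w)))
  expect_true(all(spread[!is.na(spread)] < 1e-12))

  # order robustness: reversed sweep converges to the same marginals
  res_rev <- rake(prob$microdata, prob$targets,
                  raking_config(c("v2", "v1"), tolerance = 1e-10))
  expect_equal(res_rev$weights, res$weights, tolerance = 1e-8)
})

test_that("non-convergence is reported, never thrown", {
  prob <- random_two_var_problem(5)
  res <- rake(prob$microdata, prob$targets,
              raking_config(c("v1", "v2"), tolerance = 1e-14,
                            max_iterations = 1L))
  expect_false(res$converged)
  expect_equal(res$iterations_used, 1L)
})

test_that("weight cap is honored during raking", {
  set.seed(21)
  sch <- survey_schema(list(g = c("A", "B")))
  md <- validate_microdata(
    data.frame(g = c(rep("A", 95), rep("B", 5))), sch)
  tg <- marginal_targets(list(g = c(A = 0.5, B = 0.5)))
  res <- rake(md, tg, raking_config("g", weight_cap = 3,
                                    max_iterations = 50L))
  expect_lte(max(res$weights) / mean(res$weights), 3 + 1e-9)
  # uncapped solution would need weight 10 for the rare level
  expect_false(res$converged)
})

test_that("raking result serializes to JSON faithfully", {
  prob <- random_two_var_problem(3)
  res <- rake(prob$microdata, prob$targets, raking_config(c("v1", "v2")))
  path <- withr::local_tempfile(fileext = ".json")
  write_raking_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$weights, res$weights)
  expect_equal(back$converged, res$converged)
  expect_equal(back$iterations_used, res$iterations_used)
})
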