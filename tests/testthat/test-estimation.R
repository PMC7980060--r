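test_that("outcome standardization yields unit weighted SD and scale invariance", {
  cfg <- generator_config(n = 4000)
  co <- assign_design(generate_cohort(cfg, seed = 60), cfg, seed = 60)
  spec <- default_causal_spec(cfg)
  st <- standardize_outcomes(co, spec)
  w <- co$design_weight
  for (oc in spec$outcomes) {
    mu <- sum(w * st[[oc]]) / sum(w)
    sdw <- sqrt(sum(w * (st[[oc]] - mu)^2) / sum(w))
    expect_equal(sdw, 1, tolerance = 1e-10)
  }
  # scaling the input by 10 changes nothing after standardization
  sc <- as.data.frame(co); sc$y1 <- sc$y1 * 10
  st2 <- standardize_outcomes(cohort_table(sc, dictionary(co)), spec)
  expect_equal(st2$y1, st$y1, tolerance = 1e-10)
  # idempotence: an already-standardized outcome passes through unchanged
  st3 <- standardize_outcomes(st, spec)
  expect_equal(st3$y1, st$y1, tolerance = 1e-10)
  zer <- as.data.frame(co); zer$y2 <- 1
  expect_error(standardize_outcomes(cohort_table(zer, dictionary(co)), spec),
               "zero design-weighted SD")
  # x100 display convention
  st4 <- standardize_outcomes(co, spec, scale_factor = 100)
  expect_equal(st4$y1, st$y1 * 100, tolerance = 1e-10)
})

test_that("randomized exposure: weighted estimate equals the unadjusted difference", {
  cfg <- generator_config(n = 5000)
  co <- generate_cohort(cfg, seed = 61)
  spec0 <- causal_spec(exposure = "x", mediator = "m",
                       confounders_pre = character(0),
                       confounders_post = character(0), outcomes = c("y1", "y2"))
  ws <- total_effect_weights(co, spec0)
  est <- estimate_total_effect(co, ws, spec0)
  raw <- mean(co$y1[co$x == 1]) - mean(co$y1[co$x == 0])
  expect_equal(pick(est, "total_effect", "y1")$point, raw, tolerance = 1e-8)
})

test_that("total effect collapses to the CDE when M and L are causally inert", {
  cfg <- generator_config(
    n = 10,
    coef_X_on_L = list(l1 = c(intercept = -0.4, x = 0),
                       l2 = c(intercept = 0, x = 0, sd = 0.5)),
    coef_on_Y = list(y1 = list(x = 0.2,
                               m = c(non_centre = 0, centre = 0),
                               xm = c(non_centre = 0, centre = 0),
                               c = c(c1 = 0.1, c2 = 0.1, c3 = 0.1),
                               l = c(l1 = 0.2, l2 = 0.2), noise_sd = 1))
  )
  tr <- true_estimands(cfg, oracle_n = 1e5)
  expect_equal(tr$y1$total_effect, tr$y1$cde[["parental"]], tolerance = 1e-9)
  expect_equal(tr$y1$total_effect, tr$y1$cde[["centre"]], tolerance = 1e-9)
})

test_that("empty design cells and absent mediator levels raise named errors", {
  cfg <- generator_config(n = 400)
  co <- generate_cohort(cfg, seed = 62)
  spec <- default_causal_spec(cfg)
  d <- as.data.frame(co)
  d$m[d$x == 1 & d$m == "centre"] <- "parental"
  co2 <- cohort_table(d, dictionary(co))
  ws <- cde_weights(co2, spec)
  expect_error(fit_msm_cde(co2, ws, spec), "x=1/m=centre")
})

test_that("run_question equals manual stage-by-stage invocation", {
  cfg <- generator_config(n = 4000)
  co <- assign_design(generate_cohort(cfg, seed = 63), cfg, seed = 63)
  spec <- default_causal_spec(cfg)
  des <- design_spec()
  q1 <- run_question(co, spec, 1, design = des)
  # manual: respondents -> standardize -> weights -> combine -> estimate
  r <- respondents(co)
  st <- standardize_outcomes(r, spec)
  ws <- combine_weights(ate_weights(st, spec), des, st)
  manual <- estimate_ate(st, ws, spec, des)
  expect_equal(q1$point, manual$point, tolerance = 1e-12)
  expect_equal(q1$se, manual$se, tolerance = 1e-12)
  # questions 2 and 3 share the identical total-effect stage
  q2 <- run_question(co, spec, 2, design = des)
  q3 <- run_question(co, spec, 3, design = des)
  te2 <- q2[q2$estimand == "total_effect", c("point", "se")]
  te3 <- q3[q3$estimand == "total_effect", c("point", "se")]
  expect_equal(te2, te3, tolerance = 1e-12)
  expect_setequal(q1$outcome[q1$estimand == "ate_mediator"],
                  rep(spec$outcomes, each = 2))
  expect_identical(unique(q2$scenario[q2$estimand == "cde"]), "centre")
  expect_identical(unique(q3$scenario[q3$estimand == "cde"]), "parental")
})

test_that("effect tables satisfy their CI contract", {
  cfg <- generator_config(n = 3000)
  co <- generate_cohort(cfg, seed = 64)
  spec <- default_causal_spec(cfg)
  est <- estimate_ate(co, ate_weights(co, spec), spec)
  expect_true(all(est$ci_low <= est$point & est$point <= est$ci_high))
  expect_equal(est$ci_high - est$point, qnorm(0.975) * est$se, tolerance = 1e-10)
  expect_equal(nrow(est), 2 * length(spec$outcomes))
})
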