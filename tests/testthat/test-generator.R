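test_that("generation is deterministic given a seed", {
  cfg <- generator_config(n = 100)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  d <- assign_design(a, cfg, seed = 42)
  expect_identical(d, assign_design(b, cfg, seed = 42))
  m1 <- apply_missingness(d, cfg, seed = 42)
  expect_identical(m1, apply_missingness(d, cfg, seed = 42))
})

test_that("null config gives exposure independent of confounders at its prevalence", {
  cfg <- generator_config(
    n = 40000, exposure_prevalence = 0.5,
    coef_C_on_X = c(c1 = 0, c2 = 0, c3 = 0)
  )
  expect_equal(cfg$exposure_intercept, 0, tolerance = 1e-10)
  co <- generate_cohort(cfg, seed = 3)
  expect_equal(mean(co$x), 0.5, tolerance = 0.01)
  expect_lt(abs(cor(co$x, co$c1)), 0.015)
  expect_lt(abs(cor(co$x, co$c3)), 0.015)
})

test_that("invalid configs fail naming the offending field", {
  expect_error(generator_config(n = 0), "`n`")
  expect_error(generator_config(missing_rate = 1.2), "`missing_rate`")
  cfg <- generator_config(n = 10)
  cfg$coef_on_Y$y1$noise_sd <- -1
  expect_error(validate_generator_config(cfg), "noise_sd")
  cfg2 <- generator_config(n = 10)
  cfg2$stratum_oversample <- c(1, 2)
  expect_error(validate_generator_config(cfg2), "stratum_oversample")
})

test_that("closed-form estimand identities hold", {
  # no interaction row: CDE identical across mediator levels (outcome y2)
  cfg <- generator_config(n = 10)
  tr <- true_estimands(cfg, oracle_n = 1e4)
  expect_equal(unname(diff(range(tr$y2$cde))), 0, tolerance = 1e-12)
  # no X->L path: CDE(m) = coef_X + interaction[m] exactly
  cfg2 <- generator_config(
    n = 10,
    coef_X_on_L = list(l1 = c(intercept = -0.4, x = 0),
                       l2 = c(intercept = 0, x = 0, sd = 0.5))
  )
  tr2 <- true_estimands(cfg2, oracle_n = 1e4)
  b <- cfg2$coef_on_Y$y1
  expect_equal(tr2$y1$cde[["parental"]], b$x, tolerance = 1e-12)
  expect_equal(tr2$y1$cde[["centre"]], b$x + b$xm[["centre"]], tolerance = 1e-12)
})

test_that("discrete-config estimands match exhaustive enumeration", {
  cfg <- discrete_config()
  tr <- true_estimands(cfg)
  expect_equal(tr$y1$ate[["non_centre"]], oracle_ate(cfg, "y1", "non_centre"),
               tolerance = 1e-10)
  expect_equal(tr$y1$ate[["centre"]], oracle_ate(cfg, "y1", "centre"),
               tolerance = 1e-10)
  expect_equal(tr$y1$total_effect, oracle_te(cfg, "y1"), tolerance = 1e-10)
  for (lv in c("parental", "non_centre", "centre")) {
    expect_equal(tr$y1$cde[[lv]], oracle_cde(cfg, "y1", lv), tolerance = 1e-10)
  }
})

test_that("missingness is MAR, calibrated, and never touches exposure/design", {
  cfg <- generator_config(n = 14376)
  co <- assign_design(generate_cohort(cfg, seed = 21), cfg, seed = 21)
  expect_identical(apply_missingness(co, generator_config(n = 14376, missing_rate = 0),
                                     seed = 21), co)
  masked <- apply_missingness(co, cfg, seed = 21)
  expect_false(anyNA(masked$x))
  expect_false(anyNA(masked$stratum))
  expect_false(anyNA(masked$design_weight))
  # observed fraction within 2 SE of the 5% target per maskable column
  se2 <- 2 * sqrt(0.05 * 0.95 / nrow(masked))
  for (col in c("m", "c1", "c3", "l1", "y1", "y2")) {
    expect_lt(abs(mean(is.na(masked[[col]])) - 0.05), se2 + 1e-12)
  }
  # MAR contract: given the always-observed predictor X, missingness is
  # independent of the underlying value
  big <- generate_cohort(generator_config(n = 30000), seed = 22)
  bigm <- apply_missingness(big, generator_config(n = 30000), seed = 22)
  miss <- as.numeric(is.na(bigm$y1))
  fit <- glm(miss ~ big$y1 + big$x, family = binomial())
  z <- coef(summary(fit))["big$y1", "z value"]
  expect_lt(abs(z), 3)
  bad <- generator_config(n = 100)
  bad$missing_rate <- 1
  expect_error(apply_missingness(generate_cohort(bad, seed = 1), bad), "missing_rate")
})

test_that("survey design behaves as declared", {
  cfg <- generator_config(n = 20000)
  co <- generate_cohort(cfg, seed = 31)
  de <- assign_design(co, cfg, seed = 31)
  expect_equal(mean(de$design_weight), 1, tolerance = 1e-6)
  # cluster nesting
  expect_silent(cohort_table(as.data.frame(de), dictionary(de)))
  # degenerate design: one stratum, flat weights, no attrition -> SRS
  flat <- generator_config(n = 5000, n_strata = 1, clusters_per_stratum = 10,
                           stratum_pop_shares = 1, stratum_oversample = 1,
                           stratum_tilt = 0, attrition_model = NULL)
  co2 <- assign_design(generate_cohort(flat, seed = 32), flat, seed = 32)
  expect_true(all(co2$responded == 1))
  expect_equal(sd(co2$design_weight), 0, tolerance = 1e-12)
  w_mean <- sum(co2$design_weight * co2$y1) / sum(co2$design_weight)
  expect_equal(w_mean, mean(co2$y1), tolerance = 1e-12)
  # two strata, 2:1 oversampling: weighted shares recover population shares
  two <- generator_config(n = 40000, n_strata = 2, clusters_per_stratum = 20,
                          stratum_pop_shares = c(0.5, 0.5),
                          stratum_oversample = c(1, 2),
                          stratum_tilt = c(0, 0), attrition_model = NULL)
  co3 <- assign_design(generate_cohort(two, seed = 33), two, seed = 33)
  raw_share <- mean(co3$stratum == 1)
  w_share <- sum(co3$design_weight[co3$stratum == 1]) / sum(co3$design_weight)
  expect_equal(raw_share, 1 / 3, tolerance = 0.02)   # oversampled draw
  expect_equal(w_share, 0.5, tolerance = 0.02)       # weights undo it
  bad <- generator_config(n = 100)
  bad$n_strata <- 0L
  expect_error(assign_design(co, bad), "n_strata")
})

test_that("default cohort hits the childcare marginals it is calibrated to", {
  cfg <- generator_config()  # n = 14,376
  co <- generate_cohort(cfg, seed = cfg$seed)
  shares <- as.numeric(table(co$m) / nrow(co))
  expect_lt(max(abs(shares - c(0.396, 0.330, 0.274))), 0.015)
})
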