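toy_spec <- function(cpre = c("c1", "c2"), cpost = "l1") {
  causal_spec(exposure = "x", mediator = "m",
              confounders_pre = cpre, confounders_post = cpost,
              outcomes = "y1")
}

test_that("intercept-only exposure model returns the sample prevalence", {
  cfg <- discrete_config()
  co <- generate_cohort(cfg, seed = 50)
  spec <- causal_spec(exposure = "x", mediator = "m",
                      confounders_pre = character(0),
                      confounders_post = "l1", outcomes = "y1")
  fit <- fit_exposure_model(co, spec)
  expect_equal(unname(fit$fitted[, "1"]), rep(mean(co$x), nrow(co)),
               tolerance = 1e-8)
})

test_that("saturated exposure model recovers cell proportions (toy counts)", {
  d <- data.frame(c1 = rep(c(1, 0), each = 10),
                  x = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)),
                  m = factor(rep(c("parental", "non_centre", "centre"), length.out = 20),
                             levels = c("parental", "non_centre", "centre")),
                  y1 = rnorm(20))
  dict <- list(x = list(role = "exposure", type = "binary"),
               c1 = list(role = "confounder_pre", type = "binary"),
               m = list(role = "mediator", type = "categorical",
                        levels = c("parental", "non_centre", "centre"),
                        reference = "parental"),
               y1 = list(role = "outcome", type = "continuous"))
  co <- cohort_table(d, dict)
  spec <- causal_spec(exposure = "x", mediator = "m",
                      confounders_pre = "c1", confounders_post = character(0),
                      outcomes = "y1")
  fit <- fit_exposure_model(co, spec)
  expect_equal(unname(fit$fitted[d$c1 == 1, "1"][1]), 0.8, tolerance = 1e-8)
  expect_equal(unname(fit$fitted[d$c1 == 0, "1"][1]), 0.2, tolerance = 1e-8)
})

test_that("marginal mediator model returns observed shares", {
  cfg <- generator_config(n = 2000)
  co <- generate_cohort(cfg, seed = 51)
  fit <- fit_mediator_model(co, default_causal_spec(cfg), "marginal")
  shares <- as.numeric(table(co$m) / nrow(co))
  expect_equal(unname(fit$fitted[1, ]), shares, tolerance = 1e-8)
  expect_lt(max(abs(rowSums(fit$fitted) - 1)), 1e-12)
})

test_that("no confounding makes every stabilized weight 1", {
  cfg <- generator_config(n = 1000)
  co <- generate_cohort(cfg, seed = 52)
  spec <- default_causal_spec(cfg)
  ws <- ate_weights(co, spec, denominator_formula = ~ 1)
  expect_lt(max(abs(ws$analysis_weight - 1)), 1e-8)
  spec0 <- causal_spec(exposure = "x", mediator = "m",
                       confounders_pre = character(0),
                       confounders_post = character(0), outcomes = "y1")
  ws_te <- total_effect_weights(co, spec0)
  expect_lt(max(abs(ws_te$analysis_weight - 1)), 1e-8)
})

test_that("product contract and component ledger hold for CDE weights", {
  cfg <- generator_config(n = 3000)
  co <- assign_design(generate_cohort(cfg, seed = 53), cfg, seed = 53)
  co <- respondents(co)
  spec <- default_causal_spec(cfg)
  ws <- cde_weights(co, spec)
  expect_equal(ws$analysis_weight,
               ws$components$exposure_ipw * ws$components$mediator_ipw,
               tolerance = 1e-12)
  wsd <- combine_weights(ws, design_spec(), co)
  expect_equal(wsd$analysis_weight, Reduce(`*`, wsd$components), tolerance = 1e-12)
  expect_error(combine_weights(wsd, design_spec(), co), "already combined")
})

test_that("total-effect weights ignore post-exposure confounders entirely", {
  cfg <- generator_config(n = 2000)
  co <- generate_cohort(cfg, seed = 54)
  spec <- default_causal_spec(cfg)
  ws1 <- total_effect_weights(co, spec)
  perm <- as.data.frame(co)
  set.seed(1); perm$l1 <- sample(perm$l1); perm$l2 <- sample(perm$l2)
  co2 <- cohort_table(perm, dictionary(co))
  ws2 <- total_effect_weights(co2, spec)
  expect_identical(ws1$analysis_weight, ws2$analysis_weight)
})

test_that("weight construction never reads outcome columns", {
  cfg <- generator_config(n = 2000)
  co <- generate_cohort(cfg, seed = 55)
  spec <- default_causal_spec(cfg)
  scr <- as.data.frame(co)
  set.seed(2); scr$y1 <- rnorm(nrow(scr)); scr$y2 <- rnorm(nrow(scr))
  co2 <- cohort_table(scr, dictionary(co))
  for (f in list(ate_weights, total_effect_weights, cde_weights)) {
    expect_identical(f(co, spec)$analysis_weight, f(co2, spec)$analysis_weight)
  }
})

test_that("weight truncation winsorizes at the stated percentiles", {
  ws <- structure(list(analysis_weight = c(1, 1, 1, 1, 100),
                       components = list(mediator_ipw = c(1, 1, 1, 1, 100)),
                       estimand = "ate_mediator", truncation = "none"),
                  class = "weight_set")
  expect_identical(truncate_weights(ws, 0, 100)$analysis_weight,
                   ws$analysis_weight)
  tr <- truncate_weights(ws, 0, 80)
  expect_equal(max(tr$analysis_weight),
               quantile(c(1, 1, 1, 1, 100), 0.8, names = FALSE))
  flat <- ws; flat$analysis_weight <- rep(2, 5)
  expect_equal(truncate_weights(flat, 10, 90)$analysis_weight, rep(2, 5))
  expect_error(truncate_weights(ws, 60, 40), "percentiles")
})

test_that("stabilized weight means sit near 1 within treatment groups", {
  cfg <- generator_config(n = 20000)
  co <- generate_cohort(cfg, seed = 56)
  spec <- default_causal_spec(cfg)
  ws <- ate_weights(co, spec)
  gm <- tapply(ws$analysis_weight, co$m, mean)
  expect_lt(max(abs(gm - 1)), 0.02)
  expect_equal(mean(ws$analysis_weight), 1, tolerance = 0.01)
})

test_that("balance report trivials: uniform weights and constant columns", {
  cfg <- generator_config(n = 1500)
  co <- generate_cohort(cfg, seed = 57)
  spec <- default_causal_spec(cfg)
  uni <- structure(list(analysis_weight = rep(1, nrow(co)),
                        components = list(mediator_ipw = rep(1, nrow(co))),
                        estimand = "ate_mediator", truncation = "none"),
                   class = "weight_set")
  rep1 <- balance_report(co, uni, spec)
  expect_equal(rep1$smd_after, rep1$smd_before, tolerance = 1e-12)
  const <- as.data.frame(co); const$c2 <- 1
  co2 <- cohort_table(const, dictionary(co))
  rep2 <- balance_report(co2, uni, spec)
  c2rows <- rep2[rep2$confounder == "c2", ]
  expect_true(all(c2rows$smd_before == 0 & c2rows$zero_sd))
})

test_that("correct weights balance confounders on the population table", {
  cfg <- discrete_config()
  pt <- population_table(cfg)
  spec <- causal_spec(exposure = "x", mediator = "m",
                      confounders_pre = c("c1", "c2"), confounders_post = "l1",
                      outcomes = "y1")
  ws <- combine_weights(
    ate_weights(pt, spec, denominator_formula = SAT$mediator),
    population_design(), pt)
  w <- ws$analysis_weight
  wm <- function(v, g) sum(w[pt$m == g] * v[pt$m == g]) / sum(w[pt$m == g])
  for (v in list(pt$c1, pt$c2, pt$l1, pt$x)) {
    means <- vapply(c("parental", "non_centre", "centre"), function(g) wm(v, g),
                    numeric(1))
    expect_lt(max(abs(means - means[1])), 1e-8)
  }
  br <- balance_report(pt, ws, spec)
  expect_lt(max(abs(br$smd_after)), 1e-8)
})
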