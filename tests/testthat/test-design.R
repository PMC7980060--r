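test_that("degenerate clustering reduces to the heteroskedasticity-robust sandwich", {
  set.seed(70)
  n <- 500
  d <- data.frame(x = rbinom(n, 1, 0.5), z = rnorm(n))
  d$y <- 0.5 * d$x + d$z * 0.3 + rnorm(n) * (1 + d$x)  # heteroskedastic
  w <- runif(n, 0.5, 2)
  fit <- msm_fit(y ~ x + z, d, weights = w,
                 cluster = seq_len(n), stratum = rep(1L, n))
  # textbook sandwich computed directly: bread' (sum s s' * n/(n-1)) bread
  X <- model.matrix(~ x + z, d)
  e <- d$y - X %*% solve(crossprod(X, X * w), crossprod(X, d$y * w))
  S <- X * (w * drop(e))
  bread <- solve(crossprod(X, X * w))
  V_ref <- bread %*% (crossprod(S) * n / (n - 1)) %*% bread
  expect_lt(max(abs(sqrt(diag(fit$vcov)) - sqrt(diag(V_ref)))), 1e-8)
  expect_equal(fit$df, n - 1)
})

test_that("cluster-robust covariance is symmetric PSD with survey df", {
  cfg <- generator_config(n = 3000)
  co <- assign_design(generate_cohort(cfg, seed = 71), cfg, seed = 71)
  fit <- msm_fit(y1 ~ x * m, as.data.frame(co), weights = co$design_weight,
                 cluster = co$cluster, stratum = co$stratum)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12)
  n_cl <- length(unique(co$cluster))
  n_st <- length(unique(co$stratum))
  expect_identical(fit$df, n_cl - n_st)
})

test_that("a stratum with a single cluster is refused", {
  d <- data.frame(y = rnorm(20), x = rbinom(20, 1, 0.5))
  expect_error(
    msm_fit(y ~ x, d, weights = rep(1, 20),
            cluster = c(rep(c("a", "b"), length.out = 19), "z"),
            stratum = c(rep(1L, 19), 2L)),
    "fewer than 2 clusters")
})

test_that("duplicating every cluster leaves point estimates unchanged", {
  cfg <- generator_config(n = 1000)
  co <- assign_design(generate_cohort(cfg, seed = 72), cfg, seed = 72)
  d <- as.data.frame(co)
  fit1 <- msm_fit(y1 ~ x, d, weights = d$design_weight,
                  cluster = d$cluster, stratum = d$stratum)
  d2 <- rbind(d, d)
  d2$cluster <- c(d$cluster, paste0(d$cluster, "_copy"))
  fit2 <- msm_fit(y1 ~ x, d2, weights = d2$design_weight,
                  cluster = d2$cluster, stratum = d2$stratum)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-10)
})

test_that("design weights undo deliberate oversampling of a subgroup", {
  cfg <- generator_config(n = 30000, attrition_model = NULL)
  full <- generate_cohort(cfg, seed = 73)
  truth <- mean(full$y1[full$x == 1]) - mean(full$y1[full$x == 0])
  # include disadvantaged children (c1 = 1) with probability 1, others 0.4
  set.seed(74)
  incl_p <- ifelse(full$c1 == 1, 1, 0.4)
  keep <- runif(nrow(full)) < incl_p
  d <- as.data.frame(full)[keep, ]
  d$design_weight <- 1 / incl_p[keep]
  d$stratum <- 1L
  d$cluster <- seq_len(nrow(d))
  dict <- dictionary(full)
  dict$design_weight <- list(role = "design_weight", type = "continuous")
  dict$stratum <- list(role = "stratum", type = "categorical", levels = "1")
  dict$cluster <- list(role = "cluster", type = "categorical",
                       levels = as.character(seq_len(nrow(d))))
  sub <- cohort_table(d, dict)
  # population mean: unweighted subsample estimate is pulled toward the
  # oversampled disadvantaged stratum; weighting recovers it
  mu_truth <- mean(full$y1)
  expect_gt(abs(mean(d$y1) - mu_truth), 0.03)
  expect_lt(abs(sum(d$design_weight * d$y1) / sum(d$design_weight) - mu_truth),
            0.015)
  spec0 <- causal_spec(exposure = "x", mediator = "m",
                       confounders_pre = character(0),
                       confounders_post = character(0), outcomes = "y1")
  ws <- combine_weights(total_effect_weights(sub, spec0), design_spec(), sub)
  est <- estimate_total_effect(sub, ws, spec0, design_spec())
  expect_lt(abs(pick(est, "total_effect", "y1")$point - truth), 0.03)
})

test_that("flat design weights rescale analysis weights by a constant", {
  cfg <- generator_config(n = 800, n_strata = 1, clusters_per_stratum = 5,
                          stratum_pop_shares = 1, stratum_oversample = 1,
                          stratum_tilt = 0, attrition_model = NULL)
  co <- assign_design(generate_cohort(cfg, seed = 75), cfg, seed = 75)
  spec <- default_causal_spec(cfg)
  ws <- ate_weights(co, spec)
  wsd <- combine_weights(ws, design_spec(), co)
  ratio <- wsd$analysis_weight / ws$analysis_weight
  expect_lt(diff(range(ratio)), 1e-12)
})
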