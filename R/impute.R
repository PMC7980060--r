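#' Configure multiple imputation by chained equations
#'
#' @param m Number of imputed datasets (default 25, matching the
#'   motivating analysis; at least 2 for pooling).
#' @param iterations Chained-equation sweeps per dataset (default 10).
#' @param seed Seed; the whole run is deterministic given it.
#' @param pmm_k Donor-pool size for predictive mean matching.
#' @param method_by_type Imputation model per variable type:
#'   binary -> Bayesian logistic draw, categorical -> multinomial draw,
#'   continuous -> predictive mean matching (`"pmm"`, default) or a
#'   normal linear draw (`"norm"`).
#' @export
imputation_config <- function(m = 25L, iterations = 10L, seed = 1L,
                              pmm_k = 5L,
                              method_by_type = c(binary = "logistic",
                                                 categorical = "multinomial",
                                                 continuous = "pmm")) {
  stopifnot(m >= 2, iterations >= 1, pmm_k >= 1)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 seed = as.integer(seed), pmm_k = as.integer(pmm_k),
                 method_by_type = method_by_type),
            class = "imputation_config")
}

impute_predictors <- function(cohort, target) {
  rl <- roles(cohort)
  keep <- names(rl)[rl %in% c("exposure", "mediator", "confounder_pre",
                              "confounder_post", "outcome", "design_weight")]
  setdiff(keep, target)
}

draw_coef <- function(beta, V) {
  V <- (V + t(V)) / 2
  drop(MASS::mvrnorm(1, mu = beta, Sigma = V))
}

impute_binary <- function(d, target, preds, miss) {
  f <- stats::as.formula(paste(target, "~", paste(preds, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = d, family = stats::binomial()))
  if (!fit$converged) stop("logistic model did not converge")
  bstar <- draw_coef(stats::coef(fit), stats::vcov(fit))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                           d[miss, , drop = FALSE], xlev = fit$xlevels)
  p <- stats::plogis(drop(X %*% bstar))
  stats::rbinom(sum(miss), 1, p)
}

impute_categorical <- function(d, target, preds, miss) {
  f <- stats::as.formula(paste(target, "~", paste(preds, collapse = " + ")))
  fit <- multinom_fit(f, d, penalty = 1e-4)
  if (is.null(fit$vcov)) stop("multinomial covariance unavailable")
  bstar <- matrix(draw_coef(as.vector(fit$coef), fit$vcov),
                  nrow(fit$coef), ncol(fit$coef))
  fit$coef <- bstar
  P <- predict(fit, d[miss, , drop = FALSE])
  u <- stats::runif(nrow(P))
  cs <- t(apply(P, 1, cumsum))
  idx <- 1L + rowSums(u > cs[, -ncol(cs), drop = FALSE])
  fit$levels[idx]
}

impute_continuous <- function(d, target, preds, miss, method, k) {
  f <- stats::as.formula(paste(target, "~", paste(preds, collapse = " + ")))
  obs <- !miss
  fit <- stats::lm(f, data = d[obs, , drop = FALSE])
  X_obs <- stats::model.matrix(fit)
  res <- stats::residuals(fit)
  df_res <- fit$df.residual
  sigma2_star <- sum(res^2) / stats::rchisq(1, df_res)
  XtXinv <- chol2inv(chol(crossprod(X_obs)))
  bstar <- draw_coef(stats::coef(fit), sigma2_star * XtXinv)
  X_mis <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                               d[miss, , drop = FALSE], xlev = fit$xlevels)
  if (method == "norm") {
    return(drop(X_mis %*% bstar) + stats::rnorm(sum(miss), sd = sqrt(sigma2_star)))
  }
  # type-1 predictive mean matching: observed predictions under the ML
  # coefficients, missing predictions under the posterior draw; donors
  # found by a window search over the sorted observed predictions
  yhat_obs <- drop(X_obs %*% stats::coef(fit))
  yhat_mis <- drop(X_mis %*% bstar)
  y_obs <- d[[target]][obs]
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]; yv <- y_obs[ord]
  n_obs <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  vapply(seq_along(yhat_mis), function(i) {
    win <- max(1L, pos[i] - k):min(n_obs, pos[i] + k)
    donors <- win[order(abs(ys[win] - yhat_mis[i]))[seq_len(min(k, length(win)))]]
    yv[sample(donors, 1)]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed cohorts.  Every analysis variable (exposure,
#' mediator, confounders, outcomes) enters each conditional model, with
#' the design weight as an additional predictor (not as a fitting
#' weight).  Columns are visited in dictionary order on every sweep;
#' observed cells are never altered; the whole run is deterministic
#' given `cfg$seed`.
#'
#' @param cohort A [cohort_table()] with missing values.
#' @param cfg An [imputation_config()].
#' @return List of `m` completed `cohort_table`s (class `imputed_cohorts`).
#' @export
impute <- function(cohort, cfg = imputation_config()) {
  d0 <- as.data.frame(cohort)
  dict <- dictionary(cohort)
  targets <- names(dict)[vapply(names(dict), function(cn) anyNA(d0[[cn]]), logical(1))]
  for (cn in targets) {
    if (mean(is.na(d0[[cn]])) > 0.95) {
      stop("column `", cn, "` is more than 95% missing; refusing to impute",
           call. = FALSE)
    }
  }
  if (length(targets) == 0) {
    out <- replicate(cfg$m, cohort, simplify = FALSE)
    class(out) <- "imputed_cohorts"
    return(out)
  }
  # categorical columns as factors with declared levels for model.matrix
  for (cn in names(dict)) {
    if (identical(dict[[cn]]$type, "categorical") && !is.null(dict[[cn]]$levels)) {
      d0[[cn]] <- factor(d0[[cn]], levels = dict[[cn]]$levels)
    }
  }
  miss_idx <- lapply(targets, function(cn) which(is.na(d0[[cn]])))
  names(miss_idx) <- targets
  set.seed(cfg$seed)
  completed <- vector("list", cfg$m)
  for (imp in seq_len(cfg$m)) {
    d <- d0
    for (cn in targets) {  # random draws from the observed margin
      obs <- d[[cn]][!is.na(d[[cn]])]
      d[[cn]][miss_idx[[cn]]] <- sample(obs, length(miss_idx[[cn]]), replace = TRUE)
    }
    for (it in seq_len(cfg$iterations)) {
      for (cn in targets) {
        preds <- impute_predictors(cohort, cn)
        miss <- seq_len(nrow(d)) %in% miss_idx[[cn]]
        type <- dict[[cn]]$type
        method <- cfg$method_by_type[[type]] %||% type
        vals <- tryCatch(
          switch(type,
                 binary = impute_binary(d, cn, preds, miss),
                 categorical = impute_categorical(d, cn, preds, miss),
                 continuous = impute_continuous(d, cn, preds, miss,
                                                method, cfg$pmm_k)),
          error = function(e) {
            stop("imputation model for `", cn, "` failed at iteration ", it,
                 " (imputation ", imp, "): ", conditionMessage(e),
                 call. = FALSE)
          })
        if (type == "categorical") {
          d[[cn]][miss] <- factor(vals, levels = dict[[cn]]$levels)
        } else {
          d[[cn]][miss] <- vals
        }
      }
    }
    completed[[imp]] <- cohort_table(d, dict)
  }
  class(completed) <- "imputed_cohorts"
  completed
}

#' Pool per-imputation effect estimates by Rubin's rules
#'
#' Point estimate: mean across imputations.  Within variance W: mean of
#' squared SEs.  Between variance B: variance of points.  Total
#' T = W + (1 + 1/m) B.  Degrees of freedom use the Barnard--Rubin
#' small-sample adjustment against the complete-data (design) degrees of
#' freedom carried by each estimate; confidence intervals use the
#' t-quantile on those df.
#'
#' @param estimates List of `effect_tbl`s (one per imputation) sharing
#'   an identical estimand x contrast x scenario x outcome grid.
#' @return A `pooled_tbl` data.frame with point, se, W, B, T, df,
#'   riv (relative increase in variance), fmi (fraction of missing
#'   information) and 95% CI per row.
#' @export
pool <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 2)
  m <- length(estimates)
  key <- function(e) paste(e$estimand, e$contrast, e$scenario, e$outcome, sep = "|")
  k0 <- key(estimates[[1]])
  for (e in estimates[-1]) {
    if (!identical(key(e), k0)) {
      stop("per-imputation estimate grids differ; cannot pool", call. = FALSE)
    }
  }
  pts <- sapply(estimates, function(e) e$point)
  ses <- sapply(estimates, function(e) e$se)
  if (is.null(dim(pts))) { pts <- matrix(pts, nrow = 1); ses <- matrix(ses, nrow = 1) }
  point <- rowMeans(pts)
  W <- rowMeans(ses^2)
  B <- apply(pts, 1, stats::var)
  Tv <- W + (1 + 1 / m) * B
  riv <- (1 + 1 / m) * B / W
  lambda <- (1 + 1 / m) * B / Tv
  df_old <- (m - 1) / pmax(lambda, 1e-12)^2
  nu_com <- estimates[[1]]$df %||% rep(Inf, length(point))
  nu_com[!is.finite(nu_com)] <- 1e6
  df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
  df <- 1 / (1 / df_old + 1 / df_obs)
  se <- sqrt(Tv)
  tq <- stats::qt(0.975, df)
  base <- estimates[[1]]
  out <- data.frame(estimand = base$estimand, contrast = base$contrast,
                    scenario = base$scenario, outcome = base$outcome,
                    point = point, se = se, W = W, B = B, T = Tv,
                    df = df, riv = riv, fmi = lambda,
                    ci_low = point - tq * se, ci_high = point + tq * se,
                    m = m, row.names = NULL)
  class(out) <- c("pooled_tbl", "data.frame")
  out
}

#' @export
print.pooled_tbl <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  for (cl in c("point", "se", "ci_low", "ci_high", "fmi")) {
    y[[cl]] <- round(y[[cl]], digits)
  }
  cat("pooled estimates over m =", x$m[1], "imputations\n")
  print(y[, c("estimand", "contrast", "scenario", "outcome",
              "point", "se", "ci_low", "ci_high", "fmi")])
  invisible(x)
}
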