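#' Configure the synthetic cohort generator
#'
#' The generator draws cohorts with the causal structure used throughout
#' the package: pre-exposure confounders C (two binary, one continuous),
#' a binary social exposure X (index category analogous to low parental
#' education, prevalence 0.54), post-exposure confounders L influenced by
#' X (one binary, one continuous), a three-level childcare mediator M
#' (parental / non-centre / centre, marginals calibrated to
#' 39.6/33.0/27.4%), and continuous outcomes with exposure-by-mediator
#' interaction.  Outcomes are calibrated to unit marginal SD so that the
#' structural coefficients read directly as SD-unit effects.
#'
#' Default outcome `y1` behaves like an externalising-symptom score: the
#' exposure raises it with controlled direct effect 0.15 SD when the
#' mediator is fixed at parental care and 0.02 SD when fixed at
#' centre-based care (the exposure-by-mediator interaction attenuates the
#' exposure effect under universal centre-based care).  Outcome `y2`
#' behaves like a school-readiness score with a +0.10 SD centre-care
#' effect and no direct exposure effect.
#'
#' @param n Number of children (default 14376, the analytic sample size
#'   the defaults are calibrated for).
#' @param seed Integer seed recorded in the config; all stochastic
#'   operations also accept an explicit seed.
#' @param exposure_prevalence Target marginal P(X = 1); the exposure
#'   intercept is solved exactly at config time.
#' @param coef_C_on_X Named log-odds of C columns on X.
#' @param c_prevalence Prevalences of the binary confounders c1, c2.
#' @param continuous If `FALSE`, drop the continuous confounders c3 and
#'   l2 entirely (used for fully discrete enumeration oracles).
#' @param coef_X_on_L List of coefficient blocks for the L equations
#'   (`l1`: logistic intercept + x; `l2`: linear intercept + x + sd).
#' @param coef_on_M Multinomial-logit blocks (reference `parental`) for
#'   the `non_centre` and `centre` contrasts; names index the predictors.
#' @param coef_on_Y Per-outcome list with elements `x`, `m`, `xm`
#'   (exposure-by-mediator interaction, row x = 1; the x = 0 row and the
#'   parental column are identically zero), `c`, `l`, `noise_sd`.
#' @param missing_rate Per-column masking probability for
#'   [apply_missingness()].
#' @param missing_coef Log-odds of always-observed predictors (x) in the
#'   missingness model; the intercept is solved so the mean rate matches
#'   `missing_rate` (missing-at-random by construction).
#' @param n_strata,clusters_per_stratum Survey design shape.
#' @param stratum_pop_shares Population share of each stratum.
#' @param stratum_oversample Relative inclusion probability per stratum
#'   (oversampling of disadvantaged strata).
#' @param stratum_tilt Log-odds tilt of stratum membership on c1, so
#'   strata correlate with disadvantage.
#' @param attrition_model Coefficients (intercept, x, c1) of the
#'   follow-up response propensity, or `NULL` for no attrition.  The
#'   inverse response probability folds into the design weight.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n = 14376,
                             seed = 20210312L,
                             exposure_prevalence = 0.54,
                             coef_C_on_X = c(c1 = 0.6, c2 = 0.4, c3 = 0.3),
                             c_prevalence = c(c1 = 0.4, c2 = 0.3),
                             continuous = TRUE,
                             coef_X_on_L = list(
                               l1 = c(intercept = -0.4, x = 0.5),
                               l2 = c(intercept = 0, x = 0.3, sd = 0.5)
                             ),
                             coef_on_M = list(
                               non_centre = c(intercept = CAL$m_intercepts[["non_centre"]],
                                              x = -0.25, c1 = 0.20, c2 = 0.15,
                                              c3 = 0.15, l1 = 0.25, l2 = 0.20),
                               centre = c(intercept = CAL$m_intercepts[["centre"]],
                                          x = -0.45, c1 = 0.30, c2 = 0.20,
                                          c3 = 0.20, l1 = 0.35, l2 = 0.25)
                             ),
                             coef_on_Y = list(
                               y1 = list(x = CAL$y1_x,
                                         m = c(non_centre = -0.05, centre = -0.08),
                                         xm = c(non_centre = -0.07, centre = -0.13),
                                         c = c(c1 = 0.15, c2 = 0.10, c3 = 0.10),
                                         l = c(l1 = 0.15, l2 = 0.20),
                                         noise_sd = CAL$noise_sd[["y1"]]),
                               y2 = list(x = 0,
                                         m = c(non_centre = 0.04, centre = 0.10),
                                         xm = c(non_centre = 0, centre = 0),
                                         c = c(c1 = -0.12, c2 = -0.08, c3 = 0.12),
                                         l = c(l1 = -0.10, l2 = -0.15),
                                         noise_sd = CAL$noise_sd[["y2"]])
                             ),
                             missing_rate = 0.05,
                             missing_coef = c(x = 0.5),
                             n_strata = 4L,
                             clusters_per_stratum = 100L,
                             stratum_pop_shares = rep(0.25, 4),
                             stratum_oversample = c(1, 1.5, 1.5, 2),
                             stratum_tilt = c(0, 0.2, 0.2, 0.4),
                             attrition_model = c(intercept = 1.53, x = -0.4, c1 = -0.3)) {
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed),
         exposure_prevalence = exposure_prevalence,
         coef_C_on_X = coef_C_on_X, c_prevalence = c_prevalence,
         continuous = isTRUE(continuous),
         coef_X_on_L = coef_X_on_L, coef_on_M = coef_on_M,
         coef_on_Y = coef_on_Y,
         missing_rate = missing_rate, missing_coef = missing_coef,
         n_strata = as.integer(n_strata),
         clusters_per_stratum = as.integer(clusters_per_stratum),
         stratum_pop_shares = stratum_pop_shares,
         stratum_oversample = stratum_oversample,
         stratum_tilt = stratum_tilt,
         attrition_model = attrition_model),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg$exposure_intercept <- calibrate_exposure_intercept(cfg)
  cfg
}

# frozen calibration constants (see the methods vignette): mediator-model
# intercepts hitting the 39.6/33.0/27.4% marginals at the default
# coefficients; noise SDs giving unit marginal outcome SD; y1 direct
# effect such that CDE(parental) = 0.15 given the X->L->Y contribution.
CAL <- list(
  m_intercepts = c(non_centre = -0.30897, centre = -0.50932),
  y1_x = 0.07144997,
  noise_sd = c(y1 = 0.98007, y2 = 0.98526)
)

validate_generator_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid generator config: field `", field, "` ", why, call. = FALSE)
  }
  if (!is.finite(cfg$n) || cfg$n < 1) fail("n", "must be >= 1")
  for (f in c("exposure_prevalence", "missing_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must be a probability in [0, 1]")
  }
  if (!setequal(names(cfg$coef_on_M), c("non_centre", "centre"))) {
    fail("coef_on_M", "must have blocks `non_centre` and `centre` (reference parental)")
  }
  for (oc in names(cfg$coef_on_Y)) {
    blk <- cfg$coef_on_Y[[oc]]
    if (!is.finite(blk$noise_sd) || blk$noise_sd <= 0) {
      fail(paste0("coef_on_Y$", oc, "$noise_sd"), "must be > 0")
    }
    if (!all(c("non_centre", "centre") %in% names(blk$xm))) {
      fail(paste0("coef_on_Y$", oc, "$xm"),
           "must name the non-reference mediator levels")
    }
  }
  if (cfg$n_strata < 1) fail("n_strata", "must be >= 1")
  if (cfg$clusters_per_stratum < 1) fail("clusters_per_stratum", "must be >= 1")
  for (f in c("stratum_pop_shares", "stratum_oversample", "stratum_tilt")) {
    if (length(cfg[[f]]) != cfg$n_strata) {
      fail(f, sprintf("must have length n_strata = %d", cfg$n_strata))
    }
  }
  if (any(cfg$c_prevalence < 0 | cfg$c_prevalence > 1)) {
    fail("c_prevalence", "must be probabilities")
  }
  invisible(cfg)
}

# Solve the exposure intercept so that E_C[ P(X=1|C) ] equals the target
# prevalence; expectation over the binary C cells is exact, over the
# continuous confounder by adaptive quadrature.
calibrate_exposure_intercept <- function(cfg) {
  b <- cfg$coef_C_on_X
  p1 <- cfg$c_prevalence[["c1"]]; p2 <- cfg$c_prevalence[["c2"]]
  cells <- expand.grid(c1 = 0:1, c2 = 0:1)
  cellp <- ifelse(cells$c1 == 1, p1, 1 - p1) * ifelse(cells$c2 == 1, p2, 1 - p2)
  marg <- function(a0) {
    per_cell <- vapply(seq_len(nrow(cells)), function(i) {
      eta0 <- a0 + b[["c1"]] * cells$c1[i] + b[["c2"]] * cells$c2[i]
      if (cfg$continuous && b[["c3"]] != 0) {
        stats::integrate(function(z) stats::plogis(eta0 + b[["c3"]] * z) * stats::dnorm(z),
                         -Inf, Inf, rel.tol = 1e-12)$value
      } else {
        stats::plogis(eta0)
      }
    }, numeric(1))
    sum(cellp * per_cell)
  }
  stats::uniroot(function(a0) marg(a0) - cfg$exposure_prevalence,
                 c(-30, 30), tol = 1e-12)$root
}

role_dictionary <- function(cfg) {
  dict <- list(
    x = list(role = "exposure", type = "binary"),
    m = list(role = "mediator", type = "categorical",
             levels = c("parental", "non_centre", "centre"),
             reference = "parental"),
    c1 = list(role = "confounder_pre", type = "binary"),
    c2 = list(role = "confounder_pre", type = "binary")
  )
  if (cfg$continuous) dict$c3 <- list(role = "confounder_pre", type = "continuous")
  dict$l1 <- list(role = "confounder_post", type = "binary")
  if (cfg$continuous) dict$l2 <- list(role = "confounder_post", type = "continuous")
  for (oc in names(cfg$coef_on_Y)) {
    dict[[oc]] <- list(role = "outcome", type = "continuous")
  }
  dict
}

# linear predictors of the two mediator contrasts for given columns
mediator_eta <- function(cfg, df) {
  sapply(c("non_centre", "centre"), function(k) {
    b <- cfg$coef_on_M[[k]]
    eta <- b[["intercept"]] + b[["x"]] * df$x + b[["c1"]] * df$c1 + b[["c2"]] * df$c2 +
      b[["l1"]] * df$l1
    if (cfg$continuous) eta <- eta + b[["c3"]] * df$c3 + b[["l2"]] * df$l2
    eta
  })
}

mediator_probs_from_eta <- function(eta) {
  denom <- 1 + exp(eta[, 1]) + exp(eta[, 2])
  cbind(parental = 1 / denom,
        non_centre = exp(eta[, 1]) / denom,
        centre = exp(eta[, 2]) / denom)
}

# structural outcome mean for outcome `oc` at mediator level columns m_*
outcome_mean <- function(cfg, oc, df, m) {
  blk <- cfg$coef_on_Y[[oc]]
  mu <- blk$x * df$x +
    blk$c[["c1"]] * df$c1 + blk$c[["c2"]] * df$c2 +
    blk$l[["l1"]] * df$l1
  if (cfg$continuous) mu <- mu + blk$c[["c3"]] * df$c3 + blk$l[["l2"]] * df$l2
  mnc <- as.numeric(m == "non_centre"); mc <- as.numeric(m == "centre")
  mu + blk$m[["non_centre"]] * mnc + blk$m[["centre"]] * mc +
    df$x * (blk$xm[["non_centre"]] * mnc + blk$xm[["centre"]] * mc)
}

#' Generate a complete synthetic cohort
#'
#' Draws C, then X | C (logistic), L | X, M | X, C, L (multinomial
#' logistic with reference parental), and each outcome as its structural
#' mean plus Gaussian noise.  Deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Overrides `config$seed`.
#' @return A [cohort_table()] without missingness or design columns.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  n <- config$n
  df <- data.frame(
    c1 = stats::rbinom(n, 1, config$c_prevalence[["c1"]]),
    c2 = stats::rbinom(n, 1, config$c_prevalence[["c2"]])
  )
  if (config$continuous) df$c3 <- stats::rnorm(n)
  bx <- config$coef_C_on_X
  eta_x <- config$exposure_intercept + bx[["c1"]] * df$c1 + bx[["c2"]] * df$c2
  if (config$continuous) eta_x <- eta_x + bx[["c3"]] * df$c3
  df$x <- stats::rbinom(n, 1, stats::plogis(eta_x))
  bl1 <- config$coef_X_on_L$l1
  df$l1 <- stats::rbinom(n, 1, stats::plogis(bl1[["intercept"]] + bl1[["x"]] * df$x))
  if (config$continuous) {
    bl2 <- config$coef_X_on_L$l2
    df$l2 <- bl2[["intercept"]] + bl2[["x"]] * df$x + stats::rnorm(n, sd = bl2[["sd"]])
  }
  pm <- mediator_probs_from_eta(mediator_eta(config, df))
  u <- stats::runif(n)
  lev <- c("parental", "non_centre", "centre")
  idx <- 1L + (u > pm[, 1]) + (u > pm[, 1] + pm[, 2])
  df$m <- factor(lev[idx], levels = lev)
  for (oc in names(config$coef_on_Y)) {
    df[[oc]] <- outcome_mean(config, oc, df, df$m) +
      stats::rnorm(n, sd = config$coef_on_Y[[oc]]$noise_sd)
  }
  ord <- c("x", "m", intersect(c("c1", "c2", "c3", "l1", "l2"), names(df)),
           names(config$coef_on_Y))
  cohort_table(df[, ord], role_dictionary(config))
}

#' Attach a stratified--clustered survey design with attrition weights
#'
#' Strata membership correlates with the disadvantage indicator c1
#' (`stratum_tilt`), with relative inclusion probabilities
#' `stratum_oversample`, so the base design weight is the inverse
#' oversampling factor.  Children are sorted into contiguous clusters
#' (primary sampling units) by the continuous confounder within each
#' stratum, mimicking geographic sorting, which induces intra-cluster
#' correlation in covariates and outcomes.  A follow-up response
#' indicator is drawn from `attrition_model` and its inverse probability
#' is folded into the design weight, which is then scaled to mean 1.
#'
#' @param cohort A complete [cohort_table()].
#' @param config A [generator_config()].
#' @param seed Overrides `config$seed` (offset internally so design
#'   draws are independent of cohort draws).
#' @return The cohort with `stratum`, `cluster`, `design_weight` and
#'   `responded` columns added.
#' @export
assign_design <- function(cohort, config, seed = config$seed) {
  validate_generator_config(config)
  if (config$n_strata < 1) stop("n_strata must be >= 1", call. = FALSE)
  set.seed(seed + 1L)
  n <- nrow(cohort)
  H <- config$n_strata
  base <- config$stratum_pop_shares * config$stratum_oversample
  logit_tilt <- outer(cohort$c1, config$stratum_tilt)      # n x H
  pr <- sweep(exp(logit_tilt), 2, base, `*`)
  pr <- pr / rowSums(pr)
  u <- stats::runif(n)
  if (H == 1) {
    stratum <- rep(1L, n)
  } else {
    cum <- t(apply(pr, 1, cumsum))
    stratum <- as.integer(1L + rowSums(u > cum[, -H, drop = FALSE]))
  }

  cluster <- character(n)
  sortkey <- if ("c3" %in% names(cohort)) cohort$c3 else stats::runif(n)
  for (h in seq_len(H)) {
    idx <- which(stratum == h)
    ranks <- rank(sortkey[idx], ties.method = "first")
    J <- min(config$clusters_per_stratum, length(idx))
    cl <- ceiling(ranks / (length(idx) / J))
    cluster[idx] <- sprintf("s%d_c%03d", h, cl)
  }

  w <- 1 / config$stratum_oversample[stratum]
  responded <- rep(1L, n)
  if (!is.null(config$attrition_model)) {
    am <- config$attrition_model
    p_resp <- stats::plogis(am[["intercept"]] + am[["x"]] * cohort$x +
                              am[["c1"]] * cohort$c1)
    responded <- stats::rbinom(n, 1, p_resp)
    w <- w / p_resp
  }
  w <- w / mean(w)

  out <- as.data.frame(cohort)
  out$stratum <- stratum
  out$cluster <- cluster
  out$design_weight <- w
  out$responded <- responded
  dict <- dictionary(cohort)
  dict$stratum <- list(role = "stratum", type = "categorical",
                       levels = as.character(seq_len(H)))
  dict$cluster <- list(role = "cluster", type = "categorical",
                       levels = sort(unique(cluster)))
  dict$design_weight <- list(role = "design_weight", type = "continuous")
  dict$responded <- list(role = "auxiliary", type = "binary")
  cohort_table(out, dict)
}

#' Mask values missing-at-random
#'
#' Masks the mediator, confounders and outcomes with a per-column
#' missingness probability that depends only on the always-observed
#' exposure (logistic model; intercept solved so that the mean
#' probability equals `missing_rate`).  Exposure and design columns are
#' never masked, so missingness is MAR given observed data.
#'
#' @param cohort A [cohort_table()].
#' @param config A [generator_config()].
#' @param seed Overrides `config$seed`.
#' @export
apply_missingness <- function(cohort, config, seed = config$seed) {
  rate <- config$missing_rate
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  set.seed(seed + 2L)
  rl <- roles(cohort)
  maskable <- names(rl)[rl %in% c("mediator", "confounder_pre",
                                  "confounder_post", "outcome")]
  slope <- config$missing_coef[["x"]]
  eta_part <- slope * cohort$x
  t0 <- stats::uniroot(function(t) mean(stats::plogis(t + eta_part)) - rate,
                       c(-30, 10), tol = 1e-12)$root
  p <- stats::plogis(t0 + eta_part)
  out <- as.data.frame(cohort)
  for (col in maskable) {
    out[[col]][stats::runif(nrow(out)) < p] <- NA
  }
  cohort_table(out, dictionary(cohort))
}

#' Exact marginal exposure prevalence implied by a generator config
#' @param config A [generator_config()].
#' @keywords internal
marginal_exposure_prob <- function(config) {
  b <- config$coef_C_on_X
  p1 <- config$c_prevalence[["c1"]]; p2 <- config$c_prevalence[["c2"]]
  cells <- expand.grid(c1 = 0:1, c2 = 0:1)
  cellp <- ifelse(cells$c1 == 1, p1, 1 - p1) * ifelse(cells$c2 == 1, p2, 1 - p2)
  per_cell <- vapply(seq_len(nrow(cells)), function(i) {
    eta0 <- config$exposure_intercept + b[["c1"]] * cells$c1[i] + b[["c2"]] * cells$c2[i]
    if (config$continuous && b[["c3"]] != 0) {
      stats::integrate(function(z) stats::plogis(eta0 + b[["c3"]] * z) * stats::dnorm(z),
                       -Inf, Inf, rel.tol = 1e-12)$value
    } else {
      stats::plogis(eta0)
    }
  }, numeric(1))
  sum(cellp * per_cell)
}

#' Ground-truth estimands implied by a generator configuration
#'
#' Computes, per outcome, the average treatment effect of each
#' non-reference mediator level versus parental care, the total effect of
#' the exposure, and the controlled direct effect CDE(m) of the exposure
#' at every mediator level.  CDE(m) is closed form: the direct
#' coefficient, plus the interaction term for level m, plus the
#' contribution of the open X->L->Y pathway (which a controlled direct
#' effect deliberately retains).  The ATE of the mediator is closed form
#' given the exact marginal exposure prevalence.  The total effect is
#' computed by exhaustive enumeration for discrete configs and otherwise
#' by a large-population Monte Carlo evaluation with common random
#' numbers across the two exposure arms.
#'
#' @param config A [generator_config()].
#' @param oracle_n Monte Carlo population size (default 1e6).
#' @param seed Seed for the Monte Carlo arm (default `config$seed`).
#' @return Object of class `true_estimands`: per outcome a list with
#'   `ate` (non_centre, centre), `total_effect`, and `cde` (parental,
#'   non_centre, centre), all in outcome units (SD units for the default
#'   unit-variance outcomes).
#' @export
true_estimands <- function(config, oracle_n = 1e6, seed = config$seed) {
  validate_generator_config(config)
  px <- marginal_exposure_prob(config)
  bl1 <- config$coef_X_on_L$l1
  dl1 <- stats::plogis(bl1[["intercept"]] + bl1[["x"]]) -
    stats::plogis(bl1[["intercept"]])
  dl2 <- if (config$continuous) config$coef_X_on_L$l2[["x"]] else 0

  res <- list()
  for (oc in names(config$coef_on_Y)) {
    blk <- config$coef_on_Y[[oc]]
    delta_L <- blk$l[["l1"]] * dl1 + if (config$continuous) blk$l[["l2"]] * dl2 else 0
    cde <- c(parental = blk$x + delta_L,
             non_centre = blk$x + blk$xm[["non_centre"]] + delta_L,
             centre = blk$x + blk$xm[["centre"]] + delta_L)
    ate <- c(non_centre = blk$m[["non_centre"]] + px * blk$xm[["non_centre"]],
             centre = blk$m[["centre"]] + px * blk$xm[["centre"]])
    res[[oc]] <- list(ate = ate, cde = cde)
  }

  te <- if (config$continuous) {
    total_effect_mc(config, oracle_n, seed)
  } else {
    total_effect_enum(config)
  }
  for (oc in names(res)) res[[oc]]$total_effect <- te[[oc]]
  structure(res, class = "true_estimands")
}

# E[Y | do(x)] averaged over C and L|x, with the mediator mixed
# analytically over its conditional distribution; common random numbers
# across arms.
total_effect_mc <- function(config, oracle_n, seed) {
  set.seed(seed %% .Machine$integer.max)
  n <- oracle_n
  df0 <- data.frame(c1 = stats::rbinom(n, 1, config$c_prevalence[["c1"]]),
                    c2 = stats::rbinom(n, 1, config$c_prevalence[["c2"]]),
                    c3 = stats::rnorm(n))
  u_l1 <- stats::runif(n)
  eps_l2 <- stats::rnorm(n, sd = config$coef_X_on_L$l2[["sd"]])
  arm <- function(xval) {
    d <- df0
    d$x <- xval
    bl1 <- config$coef_X_on_L$l1
    d$l1 <- as.numeric(u_l1 < stats::plogis(bl1[["intercept"]] + bl1[["x"]] * xval))
    bl2 <- config$coef_X_on_L$l2
    d$l2 <- bl2[["intercept"]] + bl2[["x"]] * xval + eps_l2
    pm <- mediator_probs_from_eta(mediator_eta(config, d))
    sapply(names(config$coef_on_Y), function(oc) {
      mu <- pm[, "parental"] * outcome_mean(config, oc, d, "parental") +
        pm[, "non_centre"] * outcome_mean(config, oc, d, "non_centre") +
        pm[, "centre"] * outcome_mean(config, oc, d, "centre")
      mean(mu)
    })
  }
  as.list(arm(1) - arm(0))
}

# exact enumeration over the discrete support (no c3/l2)
total_effect_enum <- function(config) {
  cells <- expand.grid(c1 = 0:1, c2 = 0:1, l1 = 0:1)
  p1 <- config$c_prevalence[["c1"]]; p2 <- config$c_prevalence[["c2"]]
  pc <- ifelse(cells$c1 == 1, p1, 1 - p1) * ifelse(cells$c2 == 1, p2, 1 - p2)
  bl1 <- config$coef_X_on_L$l1
  out <- stats::setNames(vector("list", length(config$coef_on_Y)),
                         names(config$coef_on_Y))
  ey <- function(xval) {
    d <- cells; d$x <- xval
    pl <- stats::plogis(bl1[["intercept"]] + bl1[["x"]] * xval)
    wl <- ifelse(cells$l1 == 1, pl, 1 - pl)
    pm <- mediator_probs_from_eta(mediator_eta(config, d))
    sapply(names(config$coef_on_Y), function(oc) {
      mu <- pm[, "parental"] * outcome_mean(config, oc, d, "parental") +
        pm[, "non_centre"] * outcome_mean(config, oc, d, "non_centre") +
        pm[, "centre"] * outcome_mean(config, oc, d, "centre")
      sum(pc * wl * mu)
    })
  }
  as.list(ey(1) - ey(0))
}

#' @export
print.true_estimands <- function(x, ...) {
  cat("true estimands (outcome units)\n")
  for (oc in names(x)) {
    e <- x[[oc]]
    cat(sprintf("  %s: ATE nc %+0.4f, centre %+0.4f | TE %+0.4f | CDE par %+0.4f, nc %+0.4f, centre %+0.4f\n",
                oc, e$ate[["non_centre"]], e$ate[["centre"]], e$total_effect,
                e$cde[["parental"]], e$cde[["non_centre"]], e$cde[["centre"]]))
  }
  invisible(x)
}

#' Serialize true estimands to JSON
#' @param x A `true_estimands` object.
#' @param path Output path.
#' @export
write_true_estimands <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Enumerate a discrete generator as a population table
#'
#' For configs with `continuous = FALSE` the full joint support of
#' (c1, c2, x, l1, m) is finite.  This returns one row per cell with the
#' exact cell probability in `design_weight` and each outcome set to its
#' structural mean, so weighted estimators applied to the table with
#' saturated models behave as if fit to the infinite population
#' (sampling noise excluded by construction).
#'
#' @param config A discrete [generator_config()].
#' @return A [cohort_table()] with cell probabilities as design weights.
#' @export
population_table <- function(config) {
  if (config$continuous) {
    stop("population_table requires a discrete config (continuous = FALSE)",
         call. = FALSE)
  }
  lev <- c("parental", "non_centre", "centre")
  cells <- expand.grid(c1 = 0:1, c2 = 0:1, x = 0:1, l1 = 0:1,
                       m = factor(lev, levels = lev))
  p1 <- config$c_prevalence[["c1"]]; p2 <- config$c_prevalence[["c2"]]
  pr <- ifelse(cells$c1 == 1, p1, 1 - p1) * ifelse(cells$c2 == 1, p2, 1 - p2)
  eta_x <- config$exposure_intercept +
    config$coef_C_on_X[["c1"]] * cells$c1 + config$coef_C_on_X[["c2"]] * cells$c2
  pr <- pr * ifelse(cells$x == 1, stats::plogis(eta_x), 1 - stats::plogis(eta_x))
  bl1 <- config$coef_X_on_L$l1
  pl1 <- stats::plogis(bl1[["intercept"]] + bl1[["x"]] * cells$x)
  pr <- pr * ifelse(cells$l1 == 1, pl1, 1 - pl1)
  pm <- mediator_probs_from_eta(mediator_eta(config, cells))
  pr <- pr * pm[cbind(seq_len(nrow(cells)), as.integer(cells$m))]
  out <- cells
  for (oc in names(config$coef_on_Y)) {
    out[[oc]] <- outcome_mean(config, oc, cells, cells$m)
  }
  out$design_weight <- pr
  dict <- role_dictionary(config)
  dict$design_weight <- list(role = "design_weight", type = "continuous")
  cohort_table(out, dict)
}
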