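#' Weighted marginal structural model fits
#'
#' `msm_fit` fits a weighted least-squares outcome model (the marginal
#' structural model) and carries everything needed for design-based
#' inference: the model matrix, weights, residuals, cluster and stratum
#' identifiers, and a cluster-robust covariance.  It is the single
#' model object behind all three estimands.
#'
#' @param formula Outcome-model formula (e.g. `y ~ x * m`).
#' @param data data.frame holding the columns.
#' @param weights Analysis weights (stabilized IPW x design).
#' @param cluster,stratum Optional design identifiers for the sandwich
#'   variance; defaults give independent observations.
#' @param variance `"linearized"` or `"cluster_bootstrap"`.
#' @param bootstrap_replicates,seed Bootstrap controls.
#' @return Object of class `msm_fit`.
#' @export
msm_fit <- function(formula, data, weights, cluster = NULL, stratum = NULL,
                    variance = c("linearized", "cluster_bootstrap"),
                    bootstrap_replicates = 500L, seed = 1L) {
  variance <- match.arg(variance)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  stopifnot(length(weights) == nrow(X), all(is.finite(weights)), all(weights > 0))
  ft <- stats::lm.wfit(X, y, weights)
  if (any(is.na(ft$coefficients))) {
    bad <- names(ft$coefficients)[is.na(ft$coefficients)]
    stop("outcome model is rank deficient (empty design cell?): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- structure(list(coefficients = ft$coefficients, X = X, y = y,
                        weights = weights,
                        residuals = y - drop(X %*% ft$coefficients),
                        cluster = cluster, stratum = stratum,
                        formula = formula, variance_method = variance),
                   class = "msm_fit")
  fit$vcov <- if (variance == "linearized") {
    robust_variance(fit)
  } else {
    cluster_bootstrap(fit, replicates = bootstrap_replicates, seed = seed)
  }
  fit$df <- attr(fit$vcov, "df")
  fit
}

#' @export
coef.msm_fit <- function(object, ...) object$coefficients

#' @export
vcov.msm_fit <- function(object, ...) object$vcov

#' @export
print.msm_fit <- function(x, ...) {
  cat("weighted MSM:", deparse(x$formula), "\n")
  cat("  n =", nrow(x$X), "| variance:", x$variance_method,
      "| df =", x$df, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.msm_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               z = object$coefficients / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)))
  structure(list(call = object$formula, coefficients = tab, df = object$df),
            class = "summary.msm_fit")
}

#' @export
print.summary.msm_fit <- function(x, ...) {
  cat("weighted MSM:", deparse(x$call), " (design df =", x$df, ")\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
confint.msm_fit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- paste(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Standardize outcome columns to design-weighted SD units
#'
#' Divides each outcome by its design-weighted standard deviation
#' (centring on the weighted mean by default), so all effects read in SD
#' units; `scale_factor = 100` reproduces the convention of reporting
#' SD-unit differences multiplied by 100.
#'
#' @param cohort A [cohort_table()].
#' @param spec A [causal_spec()].
#' @param center Subtract the weighted mean (default TRUE).
#' @param scale_factor 1 (SD units) or 100 (SD x 100 display units).
#' @export
standardize_outcomes <- function(cohort, spec, center = TRUE, scale_factor = 1) {
  dw <- design_weights_of(cohort)
  out <- as.data.frame(cohort)
  for (oc in spec$outcomes) {
    v <- out[[oc]]
    ok <- !is.na(v)
    mu <- sum(dw[ok] * v[ok]) / sum(dw[ok])
    sd_w <- sqrt(sum(dw[ok] * (v[ok] - mu)^2) / sum(dw[ok]))
    if (!is.finite(sd_w) || sd_w <= 0) {
      stop("outcome `", oc, "` has zero design-weighted SD", call. = FALSE)
    }
    out[[oc]] <- scale_factor * (v - if (center) mu else 0) / sd_w
  }
  cohort_table(out, dictionary(cohort))
}

effect_row <- function(estimand, contrast, scenario, outcome, point, se, df,
                       n_effective, scale_factor = 1) {
  z <- stats::qnorm(0.975)
  data.frame(estimand = estimand, contrast = contrast, scenario = scenario,
             outcome = outcome, point = point, se = se,
             ci_low = point - z * se, ci_high = point + z * se,
             df = df, n_effective = n_effective, scale_factor = scale_factor,
             row.names = NULL)
}

as_effect_tbl <- function(rows) {
  out <- do.call(rbind, rows)
  class(out) <- c("effect_tbl", "data.frame")
  out
}

#' @export
print.effect_tbl <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- intersect(c("point", "se", "ci_low", "ci_high"), names(y))
  for (cl in num) y[[cl]] <- round(y[[cl]], digits)
  show <- intersect(c("estimand", "contrast", "scenario", "outcome", num),
                    names(y))
  print(y[, show])
  invisible(x)
}

n_effective <- function(w) sum(w)^2 / sum(w^2)

msm_from_cohort <- function(rhs, outcome, cohort, ws, design, ...) {
  dc <- design_columns(as.data.frame(cohort), design)
  d <- as.data.frame(cohort)
  f <- stats::as.formula(paste(outcome, "~", rhs))
  msm_fit(f, d, weights = ws$analysis_weight,
          cluster = dc$cluster, stratum = dc$stratum, ...)
}

check_levels_present <- function(cohort, spec) {
  m <- as.data.frame(cohort)[[spec$mediator]]
  missing_lv <- setdiff(spec$mediator_levels, unique(as.character(m)))
  if (length(missing_lv) > 0) {
    stop("mediator level(s) empty: ", paste(missing_lv, collapse = ", "),
         call. = FALSE)
  }
}

#' Average treatment effects of the childcare mediator
#'
#' Weighted least-squares fit of each outcome on mediator indicators
#' (reference parental) under mediator-ATE weights, with cluster-robust
#' standard errors: the marginal effect of centre and non-centre care
#' versus parental care had childcare been randomized.
#'
#' @param cohort A [cohort_table()] (complete data).
#' @param ws A `weight_set` with estimand `ate_mediator` (design weights
#'   already combined via [combine_weights()] where applicable).
#' @param spec A [causal_spec()].
#' @param design Optional [design_spec()] for the sandwich variance.
#' @param ... Passed to [msm_fit()] (e.g. `variance`).
#' @return An `effect_tbl` with one row per outcome x contrast.
#' @export
estimate_ate <- function(cohort, ws, spec, design = NULL, ...) {
  stopifnot(identical(ws$estimand, "ate_mediator"))
  check_levels_present(cohort, spec)
  d <- as.data.frame(cohort)
  d[[spec$mediator]] <- factor(d[[spec$mediator]], levels = spec$mediator_levels)
  non_ref <- setdiff(spec$mediator_levels, spec$mediator_reference)
  rows <- list()
  for (oc in spec$outcomes) {
    dc <- design_columns(d, design)
    fit <- msm_fit(stats::as.formula(paste(oc, "~", spec$mediator)), d,
                   weights = ws$analysis_weight,
                   cluster = dc$cluster, stratum = dc$stratum, ...)
    for (lv in non_ref) {
      nm <- paste0(spec$mediator, lv)
      rows[[length(rows) + 1]] <- effect_row(
        "ate_mediator", paste(lv, "vs", spec$mediator_reference), "n/a", oc,
        fit$coefficients[[nm]], sqrt(fit$vcov[nm, nm]), fit$df,
        n_effective(ws$analysis_weight))
    }
  }
  as_effect_tbl(rows)
}

#' Total effect of the exposure
#'
#' Weighted fit of each outcome on the exposure indicator under
#' total-effect weights (pre-exposure confounders only): the effect of
#' the exposure through every pathway, childcare included.
#'
#' @inheritParams estimate_ate
#' @export
estimate_total_effect <- function(cohort, ws, spec, design = NULL, ...) {
  stopifnot(identical(ws$estimand, "total_effect"))
  d <- as.data.frame(cohort)
  rows <- list()
  for (oc in spec$outcomes) {
    dc <- design_columns(d, design)
    fit <- msm_fit(stats::as.formula(paste(oc, "~", spec$exposure)), d,
                   weights = ws$analysis_weight,
                   cluster = dc$cluster, stratum = dc$stratum, ...)
    nm <- spec$exposure
    rows[[length(rows) + 1]] <- effect_row(
      "total_effect", "1 vs 0", "n/a", oc,
      fit$coefficients[[nm]], sqrt(fit$vcov[nm, nm]), fit$df,
      n_effective(ws$analysis_weight))
  }
  as_effect_tbl(rows)
}

#' Controlled direct effects from a weighted marginal structural model
#'
#' Fits Y ~ X + M + X:M under product (exposure x mediator) weights and
#' reads off CDE(m) = beta_X + beta_{X:m} (the interaction with the
#' reference level being zero) for each requested scenario level:
#' scenario 1 fixes childcare at centre-based care for everyone,
#' scenario 2 at parental care only.  Variances use the full
#' cluster-robust coefficient covariance.
#'
#' @inheritParams estimate_ate
#' @param scenarios Mediator levels to report (default
#'   `spec$scenario_levels`).
#' @export
fit_msm_cde <- function(cohort, ws, spec, design = NULL,
                        scenarios = spec$scenario_levels, ...) {
  stopifnot(identical(ws$estimand, "cde"))
  check_levels_present(cohort, spec)
  d <- as.data.frame(cohort)
  d[[spec$mediator]] <- factor(d[[spec$mediator]], levels = spec$mediator_levels)
  cells <- table(d[[spec$exposure]], d[[spec$mediator]])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty exposure-by-mediator cell(s): ",
         paste(sprintf("x=%s/m=%s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (oc in spec$outcomes) {
    dc <- design_columns(d, design)
    fit <- msm_fit(stats::as.formula(
      paste(oc, "~", spec$exposure, "*", spec$mediator)), d,
      weights = ws$analysis_weight,
      cluster = dc$cluster, stratum = dc$stratum, ...)
    cf <- fit$coefficients; V <- fit$vcov
    for (lv in scenarios) {
      a <- stats::setNames(numeric(length(cf)), names(cf))
      a[spec$exposure] <- 1
      if (lv != spec$mediator_reference) {
        nm_int <- paste0(spec$exposure, ":", spec$mediator, lv)
        a[nm_int] <- 1
      }
      point <- sum(a * cf)
      se <- sqrt(drop(t(a) %*% V %*% a))
      rows[[length(rows) + 1]] <- effect_row(
        "cde", "1 vs 0", lv, oc, point, se, fit$df,
        n_effective(ws$analysis_weight))
    }
  }
  as_effect_tbl(rows)
}

#' Run one research question end to end on complete data
#'
#' Question 1: average treatment effects of childcare on every outcome.
#' Question 2: total effects of the exposure plus controlled direct
#' effects under universal centre-based care (scenario 1).  Question 3:
#' total effects plus controlled direct effects under parental-only care
#' (scenario 2).
#'
#' @param cohort Complete [cohort_table()].
#' @param spec A [causal_spec()].
#' @param question 1, 2 or 3.
#' @param design Optional [design_spec()]; when given, design weights
#'   are combined into the analysis weights and the sandwich variance
#'   honours strata and clusters.
#' @param standardize Standardize outcomes to weighted SD units first.
#' @param scale_factor Passed to [standardize_outcomes()].
#' @param ... Passed to the weight constructors (e.g. `penalty`).
#' @return An `effect_tbl`; attribute `weight_summary` carries weight
#'   diagnostics per stage.
#' @export
run_question <- function(cohort, spec, question, design = NULL,
                         standardize = TRUE, scale_factor = 1, ...) {
  stopifnot(question %in% 1:3)
  cohort <- respondents(cohort)
  if (standardize) {
    cohort <- standardize_outcomes(cohort, spec, scale_factor = scale_factor)
  }
  fold <- function(ws) if (is.null(design)) ws else combine_weights(ws, design, cohort)
  diagnostics <- list()
  if (question == 1) {
    ws <- fold(ate_weights(cohort, spec, ...))
    diagnostics$ate <- weight_summary(ws, as.data.frame(cohort)[[spec$mediator]])
    out <- estimate_ate(cohort, ws, spec, design)
  } else {
    ws_te <- fold(total_effect_weights(cohort, spec, ...))
    diagnostics$total_effect <-
      weight_summary(ws_te, as.data.frame(cohort)[[spec$exposure]])
    te <- estimate_total_effect(cohort, ws_te, spec, design)
    ws_cde <- fold(cde_weights(cohort, spec, ...))
    diagnostics$cde <- weight_summary(ws_cde, as.data.frame(cohort)[[spec$exposure]])
    scen <- if (question == 2) "centre" else "parental"
    cde <- fit_msm_cde(cohort, ws_cde, spec, design, scenarios = scen)
    out <- as_effect_tbl(list(te, cde))
  }
  out$scale_factor <- scale_factor
  attr(out, "weight_summary") <- diagnostics
  out
}
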