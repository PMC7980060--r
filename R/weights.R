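#' Stabilized inverse-probability weight sets
#'
#' A `weight_set` carries one analysis weight per person together with
#' its named components (`exposure_ipw`, `mediator_ipw`, `design`), the
#' estimand it targets (`ate_mediator`, `total_effect`, `cde`), and any
#' truncation applied.  The analysis weight is always the elementwise
#' product of the components (before truncation).
#'
#' @name weight_set
NULL

new_weight_set <- function(components, estimand, truncation = "none") {
  w <- Reduce(`*`, components)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be strictly positive and finite", call. = FALSE)
  }
  structure(list(analysis_weight = w,
                 components = components,
                 estimand = estimand,
                 truncation = truncation),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set [", x$estimand, "], n =", length(x$analysis_weight), "\n")
  cat("  components:", paste(names(x$components), collapse = " x "), "\n")
  q <- stats::quantile(x$analysis_weight, c(0, 0.5, 0.99, 1))
  cat(sprintf("  analysis weight: mean %.3f, median %.3f, p99 %.3f, max %.3f\n",
              mean(x$analysis_weight), q[2], q[3], q[4]))
  if (!identical(x$truncation, "none")) {
    cat("  truncated at:", paste(signif(unlist(x$truncation), 4), collapse = " - "), "\n")
  }
  invisible(x)
}

design_weights_of <- function(cohort) {
  dw <- columns_with_role(cohort, "design_weight")
  if (length(dw) == 1) cohort[[dw]] else rep(1, nrow(cohort))
}

#' Fit the exposure propensity model P(X = 1 | C)
#'
#' Main-effects logistic regression of the binary exposure on the
#' pre-exposure confounders, fitted with design weights when the cohort
#' carries them.  Post-exposure confounders never enter.
#'
#' @param cohort A [cohort_table()] with complete C columns.
#' @param spec A [causal_spec()].
#' @param formula Optional RHS override (e.g. `~ c1 * c2` for a
#'   saturated model); default is main effects of `confounders_pre`.
#' @param penalty Optional ridge penalty passed to the fitter, for
#'   separated data (default 0: plain ML, failing loudly on separation).
#' @return A `multinom_fit` with two levels (`0`, `1`); its `fitted`
#'   matrix columns are P(X = 0 | C), P(X = 1 | C).
#' @export
fit_exposure_model <- function(cohort, spec, formula = NULL, penalty = 0) {
  rhs <- if (is.null(formula)) {
    if (length(spec$confounders_pre) == 0) "1" else
      paste(spec$confounders_pre, collapse = " + ")
  } else {
    paste(deparse(formula[[length(formula)]]), collapse = "")
  }
  f <- stats::as.formula(paste0("factor(", spec$exposure, ") ~ ", rhs))
  multinom_fit(f, as.data.frame(cohort), weights = design_weights_of(cohort),
               reference = "0", penalty = penalty)
}

#' Fit a mediator model for the three-level childcare variable
#'
#' Multinomial logistic regression with reference level `parental`.
#' `conditioning = "full"` uses X plus the full confounder set
#' \{C, L\} (weight denominators); `"marginal_given_X"` uses X only
#' (stabilization numerator for controlled-direct-effect weights);
#' `"marginal"` is intercept-only (stabilization numerator for
#' mediator-ATE weights).
#'
#' @inheritParams fit_exposure_model
#' @param conditioning One of `"full"`, `"marginal_given_X"`,
#'   `"marginal"`.
#' @export
fit_mediator_model <- function(cohort, spec,
                               conditioning = c("full", "marginal_given_X", "marginal"),
                               formula = NULL, penalty = 0) {
  conditioning <- match.arg(conditioning)
  rhs <- if (!is.null(formula)) {
    paste(deparse(formula[[length(formula)]]), collapse = "")
  } else {
    switch(conditioning,
           full = {
             tr <- c(spec$exposure, spec$confounders_pre, spec$confounders_post)
             if (length(tr) == 0) "1" else paste(tr, collapse = " + ")
           },
           marginal_given_X = spec$exposure,
           marginal = "1")
  }
  f <- stats::as.formula(paste0(spec$mediator, " ~ ", rhs))
  d <- as.data.frame(cohort)
  d[[spec$mediator]] <- factor(d[[spec$mediator]], levels = spec$mediator_levels)
  multinom_fit(f, d, weights = design_weights_of(cohort),
               reference = spec$mediator_reference, penalty = penalty)
}

prob_of_observed <- function(P, observed) {
  p <- P[cbind(seq_along(observed), match(as.character(observed), colnames(P)))]
  if (any(p <= 0 | !is.finite(p))) {
    stop("fitted assignment probabilities must be strictly positive",
         call. = FALSE)
  }
  p
}

#' Stabilized weights for the mediator average treatment effect
#'
#' w_i = P(M = m_i) / P(M = m_i | X, C, L): the marginal mediator
#' distribution over the fully conditional one, so the weighted sample
#' behaves as if childcare had been randomized.
#'
#' @inheritParams fit_exposure_model
#' @param numerator `"marginal"` (default) or `"conditional_on_X"`.
#' @param denominator_formula,penalty Passed to the denominator model.
#' @export
ate_weights <- function(cohort, spec, numerator = c("marginal", "conditional_on_X"),
                        denominator_formula = NULL, penalty = 0) {
  numerator <- match.arg(numerator)
  m_obs <- as.data.frame(cohort)[[spec$mediator]]
  num_fit <- fit_mediator_model(cohort, spec,
                                if (numerator == "marginal") "marginal" else "marginal_given_X",
                                penalty = penalty)
  den_fit <- fit_mediator_model(cohort, spec, "full",
                                formula = denominator_formula, penalty = penalty)
  w <- prob_of_observed(num_fit$fitted, m_obs) /
    prob_of_observed(den_fit$fitted, m_obs)
  new_weight_set(list(mediator_ipw = w), "ate_mediator")
}

#' Stabilized weights for the total effect of the exposure
#'
#' w_i = P(X = x_i) / P(X = x_i | C).  Post-exposure confounders are
#' deliberately excluded: effects flowing through them are part of the
#' total effect.
#'
#' @inheritParams fit_exposure_model
#' @param denominator_formula Optional RHS override for the denominator.
#' @export
total_effect_weights <- function(cohort, spec, denominator_formula = NULL,
                                 penalty = 0) {
  x_obs <- as.data.frame(cohort)[[spec$exposure]]
  den_fit <- fit_exposure_model(cohort, spec, formula = denominator_formula,
                                penalty = penalty)
  dw <- design_weights_of(cohort)
  p1 <- sum(dw * x_obs) / sum(dw)
  num <- ifelse(x_obs == 1, p1, 1 - p1)
  w <- num / prob_of_observed(den_fit$fitted, x_obs)
  new_weight_set(list(exposure_ipw = w), "total_effect")
}

#' Product weights for controlled direct effects
#'
#' w_i = P(X = x_i) / P(X = x_i | C) times
#' P(M = m_i | X) / P(M = m_i | X, C, L).  The exposure factor mimics
#' randomization of X given C; the mediator factor mimics randomization
#' of M given X, leaving the X -> L -> Y pathway open as a controlled
#' direct effect requires.  Components are stored separately.
#'
#' @inheritParams fit_exposure_model
#' @param exposure_formula,mediator_formula Optional RHS overrides for
#'   the two denominator models.
#' @export
cde_weights <- function(cohort, spec, exposure_formula = NULL,
                        mediator_formula = NULL, penalty = 0) {
  d <- as.data.frame(cohort)
  x_obs <- d[[spec$exposure]]
  m_obs <- d[[spec$mediator]]
  xfit <- fit_exposure_model(cohort, spec, formula = exposure_formula,
                             penalty = penalty)
  dw <- design_weights_of(cohort)
  p1 <- sum(dw * x_obs) / sum(dw)
  w_x <- ifelse(x_obs == 1, p1, 1 - p1) / prob_of_observed(xfit$fitted, x_obs)
  m_num <- fit_mediator_model(cohort, spec, "marginal_given_X", penalty = penalty)
  m_den <- fit_mediator_model(cohort, spec, "full", formula = mediator_formula,
                              penalty = penalty)
  w_m <- prob_of_observed(m_num$fitted, m_obs) /
    prob_of_observed(m_den$fitted, m_obs)
  new_weight_set(list(exposure_ipw = w_x, mediator_ipw = w_m), "cde")
}

#' Winsorize analysis weights at percentiles
#'
#' Default analyses apply no truncation; this is an explicit,
#' provenance-recorded option for heavy-tailed weights.
#'
#' @param ws A `weight_set`.
#' @param lower_pct,upper_pct Percentile bounds in [0, 50) and (50, 100].
#' @export
truncate_weights <- function(ws, lower_pct = 0, upper_pct = 100) {
  if (!(lower_pct >= 0 && lower_pct < 50) || !(upper_pct > 50 && upper_pct <= 100)) {
    stop("truncation percentiles must satisfy 0 <= lower < 50 < upper <= 100",
         call. = FALSE)
  }
  w <- ws$analysis_weight
  lo <- stats::quantile(w, lower_pct / 100, names = FALSE)
  hi <- stats::quantile(w, upper_pct / 100, names = FALSE)
  ws$analysis_weight <- pmin(pmax(w, lo), hi)
  ws$truncation <- list(lower_pct = lower_pct, upper_pct = upper_pct,
                        lower = lo, upper = hi)
  ws
}

#' Summary statistics of analysis weights by treatment group
#'
#' @param ws A `weight_set`.
#' @param group Grouping vector (e.g. the mediator column).
#' @return data.frame with mean, max and 99th percentile per group.
#' @export
weight_summary <- function(ws, group) {
  sp <- split(ws$analysis_weight, group)
  data.frame(group = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             p99 = vapply(sp, function(v) stats::quantile(v, 0.99, names = FALSE),
                          numeric(1)),
             max = vapply(sp, max, numeric(1)),
             row.names = NULL)
}
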