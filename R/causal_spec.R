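#' Declare the causal structure of an analysis
#'
#' A `causal_spec` names the exposure X (binary social exposure such as
#' low parental education or lone parenthood), the three-level childcare
#' mediator M, the pre-exposure confounders C (common causes of X, M and
#' Y), the post-exposure confounders L (mediator--outcome confounders
#' possibly affected by X), and the outcome columns Y.  The distinction
#' between C and L drives every adjustment set: total effects adjust C
#' only, mediator average-treatment-effect weights condition on
#' \{X, C, L\}, and controlled-direct-effect weights combine an exposure
#' weight (C) with a mediator weight (X in the numerator; X, C, L in the
#' denominator) so that the X->L->Y pathway stays inside the estimate.
#'
#' @param exposure Name of the binary exposure column (values 0/1; 1 is
#'   the index category, e.g. low parental education).
#' @param mediator Name of the mediator column.
#' @param mediator_levels Character vector of the three childcare levels.
#' @param mediator_reference Reference level (default `"parental"`).
#' @param confounders_pre Character vector of C column names.
#' @param confounders_post Character vector of L column names.
#' @param outcomes Character vector of outcome column names.
#' @param scenario_levels Mediator levels at which controlled direct
#'   effects are reported: scenario 1 sets everyone to `"centre"`
#'   (universal take-up), scenario 2 to `"parental"` (care at home only).
#' @return Object of class `causal_spec`.
#' @export
causal_spec <- function(exposure,
                        mediator,
                        mediator_levels = c("parental", "non_centre", "centre"),
                        mediator_reference = "parental",
                        confounders_pre = character(0),
                        confounders_post = character(0),
                        outcomes,
                        scenario_levels = c("centre", "parental")) {
  stopifnot(is.character(exposure), length(exposure) == 1,
            is.character(mediator), length(mediator) == 1,
            length(mediator_levels) == 3)
  if (!mediator_reference %in% mediator_levels) {
    stop("mediator reference `", mediator_reference,
         "` is not among the declared levels", call. = FALSE)
  }
  if (length(intersect(confounders_pre, confounders_post)) > 0) {
    stop("pre- and post-exposure confounder sets overlap: ",
         paste(intersect(confounders_pre, confounders_post), collapse = ", "),
         call. = FALSE)
  }
  core <- c(exposure, mediator, outcomes)
  clash <- intersect(core, c(confounders_pre, confounders_post))
  if (length(clash) > 0) {
    stop("column(s) ", paste(clash, collapse = ", "),
         " cannot be both confounder and exposure/mediator/outcome",
         call. = FALSE)
  }
  bad <- setdiff(scenario_levels, mediator_levels)
  if (length(bad) > 0) {
    stop("scenario level(s) not among mediator levels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(exposure = exposure, mediator = mediator,
         mediator_levels = mediator_levels,
         mediator_reference = mediator_reference,
         confounders_pre = confounders_pre,
         confounders_post = confounders_post,
         outcomes = outcomes,
         scenario_levels = scenario_levels),
    class = "causal_spec"
  )
}

#' @export
print.causal_spec <- function(x, ...) {
  cat("causal_spec\n")
  cat("  exposure (X):        ", x$exposure, "\n")
  cat("  mediator (M):        ", x$mediator, " [",
      paste(x$mediator_levels, collapse = " / "),
      "; ref ", x$mediator_reference, "]\n", sep = "")
  cat("  pre-exposure C:      ", paste(x$confounders_pre, collapse = ", "), "\n")
  cat("  post-exposure L:     ", paste(x$confounders_post, collapse = ", "), "\n")
  cat("  outcomes (Y):        ", paste(x$outcomes, collapse = ", "), "\n")
  cat("  CDE scenarios:       ", paste(x$scenario_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Default causal spec for the synthetic cohort
#'
#' Matches the columns produced by [generate_cohort()] under the default
#' generator configuration.
#'
#' @param config A [generator_config()]; used to decide whether the
#'   continuous confounders are present.
#' @export
default_causal_spec <- function(config = generator_config()) {
  cpre <- c("c1", "c2"); cpost <- "l1"
  if (isTRUE(config$continuous)) {
    cpre <- c(cpre, "c3"); cpost <- c(cpost, "l2")
  }
  causal_spec(
    exposure = "x", mediator = "m",
    confounders_pre = cpre, confounders_post = cpost,
    outcomes = names(config$coef_on_Y)
  )
}
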