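#' Covariate balance diagnostics for a weight set
#'
#' For each confounder and each pairwise treatment contrast, the
#' standardized mean difference (SMD): weighted mean difference divided
#' by the pooled *unweighted* SD (so before/after values share a
#' denominator).  Binary columns enter as 0/1 indicators and categorical
#' columns are expanded to level indicators.  For product
#' (controlled-direct-effect) weights, mediator contrasts are also
#' reported within exposure strata -- the check that exposed residual
#' imbalance among lone parents in the motivating analysis.
#'
#' @param cohort A [cohort_table()].
#' @param ws A `weight_set` (design weights combined where applicable).
#' @param spec A [causal_spec()].
#' @param threshold Reporting convention for flagged imbalance
#'   (|SMD| above it); 0.1 by default.
#' @return A `balance_report` data.frame with columns `confounder`,
#'   `treatment`, `contrast`, `stratum`, `smd_before`, `smd_after`,
#'   `zero_sd` plus a `weight_summary` attribute.
#' @export
balance_report <- function(cohort, ws, spec, threshold = 0.1) {
  d <- as.data.frame(cohort)
  w_after <- ws$analysis_weight
  stopifnot(all(is.finite(w_after)))
  dict <- dictionary(cohort)

  expand_cols <- function(cols) {
    out <- list()
    for (cn in cols) {
      e <- dict[[cn]] %||% list(type = if (is.numeric(d[[cn]])) "continuous" else "categorical")
      if (identical(e$type, "categorical")) {
        lv <- e$levels %||% levels(factor(d[[cn]]))
        for (l in lv) out[[paste0(cn, "=", l)]] <- as.numeric(as.character(d[[cn]]) == l)
      } else {
        out[[cn]] <- as.numeric(d[[cn]])
      }
    }
    out
  }

  smd <- function(v, g, a, b, w) {
    ia <- g == a; ib <- g == b
    sd_pool <- sqrt((stats::var(v[ia]) + stats::var(v[ib])) / 2)
    if (!is.finite(sd_pool) || sd_pool == 0) return(c(0, TRUE))
    ma <- sum(w[ia] * v[ia]) / sum(w[ia])
    mb <- sum(w[ib] * v[ib]) / sum(w[ib])
    c((ma - mb) / sd_pool, FALSE)
  }

  contrasts_for <- function(treatment_col, covariate_cols, strata = NULL) {
    g <- as.character(d[[treatment_col]])
    lv <- if (treatment_col == spec$mediator) spec$mediator_levels else sort(unique(g))
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    covs <- expand_cols(covariate_cols)
    rows <- list()
    strata_def <- list(overall = rep(TRUE, nrow(d)))
    if (!is.null(strata)) {
      for (s in sort(unique(as.character(d[[strata]])))) {
        strata_def[[paste0(strata, "=", s)]] <- as.character(d[[strata]]) == s
      }
    }
    for (sn in names(strata_def)) {
      keep <- strata_def[[sn]]
      for (pr in pairs) {
        for (cv in names(covs)) {
          before <- smd(covs[[cv]][keep], g[keep], pr[1], pr[2], rep(1, sum(keep)))
          after <- smd(covs[[cv]][keep], g[keep], pr[1], pr[2], w_after[keep])
          rows[[length(rows) + 1]] <- data.frame(
            confounder = cv, treatment = treatment_col,
            contrast = paste(pr[1], "vs", pr[2]), stratum = sn,
            smd_before = before[1], smd_after = after[1],
            zero_sd = as.logical(before[2]))
        }
      }
    }
    rows
  }

  rows <- switch(ws$estimand,
    ate_mediator = contrasts_for(spec$mediator,
                                 c(spec$exposure, spec$confounders_pre,
                                   spec$confounders_post)),
    total_effect = contrasts_for(spec$exposure, spec$confounders_pre),
    cde = c(contrasts_for(spec$exposure, spec$confounders_pre),
            contrasts_for(spec$mediator,
                          c(spec$confounders_pre, spec$confounders_post),
                          strata = spec$exposure)),
    stop("unknown estimand label: ", ws$estimand)
  )
  out <- do.call(rbind, rows)
  class(out) <- c("balance_report", "data.frame")
  attr(out, "threshold") <- threshold
  tr_col <- if (ws$estimand == "ate_mediator") spec$mediator else spec$exposure
  attr(out, "weight_summary") <- weight_summary(ws, d[[tr_col]])
  out
}

#' @export
print.balance_report <- function(x, ...) {
  thr <- attr(x, "threshold") %||% 0.1
  cat("balance report (", nrow(x), "confounder x contrast rows )\n")
  cat(sprintf("  max |SMD| before: %.3f  after: %.3f\n",
              max(abs(x$smd_before)), max(abs(x$smd_after))))
  bad <- x[abs(x$smd_after) > thr & x$stratum == "overall", , drop = FALSE]
  if (nrow(bad) > 0) {
    cat("  residual imbalance (|SMD| >", thr, "):\n")
    print(bad[, c("confounder", "treatment", "contrast", "smd_after")])
  } else {
    cat("  no overall |SMD| exceeds", thr, "after weighting\n")
  }
  invisible(x)
}

#' Serialize a balance report
#'
#' Long-format CSV (confounder, contrast, stage, smd) plus a JSON weight
#' summary block.
#'
#' @param x A `balance_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_balance_report <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    long <- rbind(
      data.frame(confounder = x$confounder, treatment = x$treatment,
                 contrast = x$contrast, stratum = x$stratum,
                 stage = "before", smd = x$smd_before),
      data.frame(confounder = x$confounder, treatment = x$treatment,
                 contrast = x$contrast, stratum = x$stratum,
                 stage = "after", smd = x$smd_after)
    )
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(attr(x, "weight_summary"), json_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(x)
}
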