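#' Declare the survey design
#'
#' @param stratum_col,cluster_col,weight_col Column names of the design
#'   stratum, primary sampling unit, and design/attrition weight; any may
#'   be `NULL` for designs without that feature.
#' @param variance_method `"linearized"` (stratified cluster sandwich,
#'   the default) or `"cluster_bootstrap"`.
#' @param bootstrap_replicates Resamples when bootstrapping (default 500).
#' @export
design_spec <- function(stratum_col = "stratum", cluster_col = "cluster",
                        weight_col = "design_weight",
                        variance_method = c("linearized", "cluster_bootstrap"),
                        bootstrap_replicates = 500L) {
  variance_method <- match.arg(variance_method)
  structure(list(stratum_col = stratum_col, cluster_col = cluster_col,
                 weight_col = weight_col, variance_method = variance_method,
                 bootstrap_replicates = as.integer(bootstrap_replicates)),
            class = "design_spec")
}

design_columns <- function(cohort, design) {
  n <- nrow(cohort)
  get <- function(col, default) {
    if (is.null(col) || !col %in% names(cohort)) default else cohort[[col]]
  }
  if (!is.null(design)) {
    for (col in c(design$stratum_col, design$cluster_col, design$weight_col)) {
      if (!is.null(col) && !col %in% names(cohort)) {
        stop("design column `", col, "` not found in cohort", call. = FALSE)
      }
    }
  }
  list(
    stratum = if (is.null(design)) rep(1L, n) else get(design$stratum_col, rep(1L, n)),
    cluster = if (is.null(design)) seq_len(n) else get(design$cluster_col, seq_len(n)),
    weight  = if (is.null(design)) rep(1, n) else {
      w <- get(design$weight_col, rep(1, n))
      if (any(w <= 0 | !is.finite(w))) {
        stop("design weights must be positive and finite", call. = FALSE)
      }
      w
    }
  )
}

#' Fold design weights into an analysis weight set
#'
#' Multiplies the inverse-probability analysis weight by the
#' design/attrition weight and records the component, so downstream
#' estimation and balance checks honour the complex sampling design.
#'
#' @param ws A `weight_set`.
#' @param design A [design_spec()].
#' @param cohort The cohort the weights belong to.
#' @export
combine_weights <- function(ws, design, cohort) {
  dc <- design_columns(cohort, design)
  if ("design" %in% names(ws$components)) {
    stop("design weights already combined into this weight set", call. = FALSE)
  }
  ws$components$design <- dc$weight
  ws$analysis_weight <- ws$analysis_weight * dc$weight
  ws
}

#' Stratified cluster-robust (linearized) covariance
#'
#' Sandwich covariance for a weighted least-squares fit: per-person
#' scores `w_i x_i e_i` are summed within primary sampling units,
#' centred within design strata, and combined with the usual
#' `g_h / (g_h - 1)` small-sample factor per stratum.  With one stratum
#' and each person their own cluster this reduces to the ordinary
#' heteroskedasticity-robust sandwich (scaled n/(n-1)).  Degrees of
#' freedom follow the survey convention: clusters minus strata.
#'
#' @param fit An [msm_fit] (or any list with elements `X`, `weights`,
#'   `residuals`).
#' @param cluster,stratum Vectors identifying PSU and stratum per row;
#'   default to those stored in the fit.
#' @return Covariance matrix with attribute `df`.
#' @export
robust_variance <- function(fit, cluster = NULL, stratum = NULL) {
  X <- fit$X; w <- fit$weights; e <- fit$residuals
  cluster <- cluster %||% fit$cluster %||% seq_len(nrow(X))
  stratum <- stratum %||% fit$stratum %||% rep(1L, nrow(X))
  scores <- X * (w * e)
  cl_strat <- unique(data.frame(cl = as.character(cluster), st = as.character(stratum)))
  sc <- rowsum(scores, group = as.character(cluster), reorder = FALSE)
  st_of_cl <- cl_strat$st[match(rownames(sc), cl_strat$cl)]
  meat <- matrix(0, ncol(X), ncol(X))
  G <- 0L
  for (h in unique(st_of_cl)) {
    rows <- which(st_of_cl == h)
    g <- length(rows)
    if (g < 2) {
      stop("stratum `", h, "` has fewer than 2 clusters; ",
           "variance is not identified", call. = FALSE)
    }
    S <- sc[rows, , drop = FALSE]
    S <- sweep(S, 2, colMeans(S))
    meat <- meat + crossprod(S) * g / (g - 1)
    G <- G + g
  }
  bread <- solve(crossprod(X, X * w))
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  attr(V, "df") <- G - length(unique(st_of_cl))
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Cluster bootstrap covariance for a weighted least-squares fit
#'
#' Resamples primary sampling units with replacement within strata and
#' refits; offered as a cross-check on the linearized variance.
#'
#' @inheritParams robust_variance
#' @param replicates Number of bootstrap resamples.
#' @param seed Seed for resampling.
#' @export
cluster_bootstrap <- function(fit, replicates = 500L, seed = 1L,
                              cluster = NULL, stratum = NULL) {
  X <- fit$X; w <- fit$weights; y <- fit$y
  cluster <- as.character(cluster %||% fit$cluster %||% seq_len(nrow(X)))
  stratum <- as.character(stratum %||% fit$stratum %||% rep(1L, nrow(X)))
  set.seed(seed)
  idx_by_cl <- split(seq_len(nrow(X)), cluster)
  st_of_cl <- vapply(idx_by_cl, function(ix) stratum[ix[1]], character(1))
  cls_by_st <- split(names(idx_by_cl), st_of_cl)
  B <- matrix(NA_real_, replicates, ncol(X))
  for (b in seq_len(replicates)) {
    take <- unlist(lapply(cls_by_st, function(cls) {
      sel <- sample(cls, length(cls), replace = TRUE)
      unlist(idx_by_cl[sel], use.names = FALSE)
    }), use.names = FALSE)
    cf <- tryCatch(stats::lm.wfit(X[take, , drop = FALSE], y[take], w[take])$coefficients,
                   error = function(e) rep(NA_real_, ncol(X)))
    B[b, ] <- cf
  }
  V <- stats::cov(B, use = "complete.obs")
  dimnames(V) <- list(colnames(X), colnames(X))
  attr(V, "df") <- length(idx_by_cl) - length(cls_by_st)
  V
}
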