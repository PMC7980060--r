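#' Weighted multinomial logistic regression
#'
#' Maximum-likelihood multinomial logit by Newton--Raphson, with case
#' weights and an optional ridge penalty for separated data.  Used for
#' the three-level childcare mediator models; written in-package because
#' the estimation stack here deliberately carries no dependency beyond
#' base R and `MASS`.
#'
#' @param formula Model formula; the response must be a factor.
#' @param data data.frame.
#' @param weights Optional nonnegative case weights.
#' @param reference Reference level (default: first factor level).
#' @param penalty Ridge penalty on non-intercept coefficients (default 0,
#'   i.e. plain maximum likelihood).
#' @param maxit,tol Newton iteration controls.
#' @return Object of class `multinom_fit` with elements `coef`
#'   (predictors x non-reference levels), `levels`, `fitted`
#'   (n x K probability matrix), `vcov` (inverse negative Hessian of the
#'   stacked coefficient vector), `converged`.
#' @export
multinom_fit <- function(formula, data, weights = NULL, reference = NULL,
                         penalty = 0, maxit = 100L, tol = 1e-10) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  if (!is.null(reference)) {
    if (!reference %in% levels(y)) {
      stop("reference level `", reference, "` not present", call. = FALSE)
    }
    y <- stats::relevel(y, ref = reference)
  }
  lev <- levels(y)
  present <- lev %in% unique(as.character(y))
  if (!all(present)) {
    stop("mediator level(s) absent from data: ",
         paste(lev[!present], collapse = ", "), call. = FALSE)
  }
  K <- length(lev)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0))

  Yind <- matrix(0, n, K - 1)
  for (k in 2:K) Yind[, k - 1] <- as.numeric(y == lev[k])
  B <- matrix(0, p, K - 1)
  pen <- rep(penalty, p)
  pen[colnames(X) == "(Intercept)"] <- 0

  probs <- function(B) {
    eta <- X %*% B
    em <- exp(eta - apply(cbind(0, eta), 1, max))
    e0 <- exp(-apply(cbind(0, eta), 1, max))
    denom <- e0 + rowSums(em)
    cbind(e0 / denom, em / denom)
  }

  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- probs(B)
    G <- matrix(0, p, K - 1)
    for (k in 2:K) {
      G[, k - 1] <- crossprod(X, w * (Yind[, k - 1] - P[, k])) - pen * B[, k - 1]
    }
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in 2:K) {
      for (l in k:K) {
        wkl <- w * P[, k] * ((k == l) - P[, l])
        blk <- -crossprod(X, X * wkl)
        ri <- (k - 2) * p + seq_len(p); ci <- (l - 2) * p + seq_len(p)
        H[ri, ci] <- blk
        if (l != k) H[ci, ri] <- t(blk)
      }
    }
    diag(H) <- diag(H) - rep(pen, K - 1)
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) {
      stop("multinomial Hessian is singular; consider a ridge `penalty`",
           call. = FALSE)
    }
    B <- B - matrix(step, p, K - 1)
    if (max(abs(G)) < tol || max(abs(step)) < tol) { converged <- TRUE; break }
    if (max(abs(B)) > 30) {
      stop("multinomial fit diverging (|coef| > 30): data may be separated; ",
           "set a ridge `penalty` to stabilise", call. = FALSE)
    }
  }
  if (!converged) {
    stop("multinomial fit did not converge in ", maxit, " iterations",
         call. = FALSE)
  }
  P <- probs(B)
  colnames(P) <- lev
  rownames(B) <- colnames(X)
  colnames(B) <- lev[-1]
  vc <- tryCatch(solve(-H), error = function(e) NULL)
  structure(list(coef = B, levels = lev, fitted = P, vcov = vc,
                 terms = attr(mf, "terms"), xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 converged = converged, penalty = penalty),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("multinomial logit (reference:", x$levels[1], ")\n")
  print(t(x$coef))
  invisible(x)
}

#' @export
coef.multinom_fit <- function(object, ...) object$coef

#' Predicted class probabilities from a multinomial fit
#' @param object A `multinom_fit`.
#' @param newdata Optional data.frame; defaults to fitted values.
#' @param ... Unused.
#' @export
predict.multinom_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                           xlev = object$xlevels)
  eta <- X %*% object$coef
  m <- apply(cbind(0, eta), 1, max)
  em <- exp(eta - m); e0 <- exp(-m)
  denom <- e0 + rowSums(em)
  P <- cbind(e0 / denom, em / denom)
  colnames(P) <- object$levels
  P
}
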