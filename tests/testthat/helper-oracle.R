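# Independent brute-force oracles for fully discrete generator configs.
# These enumerate the joint support (c1, c2, x, l1, m) directly from the
# structural coefficient blocks -- a code path deliberately separate from
# the package's own closed forms, population_table() and IPW estimators.

oracle_cells <- function(cfg) {
  stopifnot(!cfg$continuous)
  cells <- expand.grid(c1 = 0:1, c2 = 0:1, x = 0:1, l1 = 0:1,
                       m = c("parental", "non_centre", "centre"),
                       stringsAsFactors = FALSE)
  p1 <- cfg$c_prevalence[["c1"]]; p2 <- cfg$c_prevalence[["c2"]]
  pr_c <- ifelse(cells$c1 == 1, p1, 1 - p1) * ifelse(cells$c2 == 1, p2, 1 - p2)
  bx <- cfg$coef_C_on_X
  px1 <- plogis(cfg$exposure_intercept + bx[["c1"]] * cells$c1 + bx[["c2"]] * cells$c2)
  pr_x <- ifelse(cells$x == 1, px1, 1 - px1)
  bl <- cfg$coef_X_on_L$l1
  pl1 <- plogis(bl[["intercept"]] + bl[["x"]] * cells$x)
  pr_l <- ifelse(cells$l1 == 1, pl1, 1 - pl1)
  pm <- oracle_m_probs(cfg, cells)
  pr_m <- pm[cbind(seq_len(nrow(cells)),
                   match(cells$m, c("parental", "non_centre", "centre")))]
  cells$prob <- pr_c * pr_x * pr_l * pr_m
  cells
}

oracle_m_probs <- function(cfg, d) {
  eta <- sapply(c("non_centre", "centre"), function(k) {
    b <- cfg$coef_on_M[[k]]
    b[["intercept"]] + b[["x"]] * d$x + b[["c1"]] * d$c1 + b[["c2"]] * d$c2 +
      b[["l1"]] * d$l1
  })
  den <- 1 + exp(eta[, 1]) + exp(eta[, 2])
  cbind(1 / den, exp(eta[, 1]) / den, exp(eta[, 2]) / den)
}

oracle_mu <- function(cfg, oc, d, m) {
  b <- cfg$coef_on_Y[[oc]]
  b$x * d$x + b$c[["c1"]] * d$c1 + b$c[["c2"]] * d$c2 + b$l[["l1"]] * d$l1 +
    b$m[["non_centre"]] * (m == "non_centre") + b$m[["centre"]] * (m == "centre") +
    d$x * (b$xm[["non_centre"]] * (m == "non_centre") +
             b$xm[["centre"]] * (m == "centre"))
}

# g-formula ATE of mediator level `lv` vs parental: average the
# structural contrast over the joint (c, x, l) distribution
oracle_ate <- function(cfg, oc, lv) {
  cells <- oracle_cells(cfg)
  base <- cells[cells$m == "parental", ]  # one row per (c, x, l) cell
  w <- tapply(cells$prob, list(cells$c1, cells$c2, cells$x, cells$l1), sum)
  pr <- w[cbind(base$c1 + 1, base$c2 + 1, base$x + 1, base$l1 + 1)]
  sum(pr * (oracle_mu(cfg, oc, base, lv) - oracle_mu(cfg, oc, base, "parental")))
}

# g-formula total effect: E[Y | do(x = 1)] - E[Y | do(x = 0)], with L and
# M following their conditional laws under each arm
oracle_te <- function(cfg, oc) {
  grid <- expand.grid(c1 = 0:1, c2 = 0:1, l1 = 0:1)
  p1 <- cfg$c_prevalence[["c1"]]; p2 <- cfg$c_prevalence[["c2"]]
  pc <- ifelse(grid$c1 == 1, p1, 1 - p1) * ifelse(grid$c2 == 1, p2, 1 - p2)
  bl <- cfg$coef_X_on_L$l1
  ey <- function(xv) {
    d <- grid; d$x <- xv
    pl <- plogis(bl[["intercept"]] + bl[["x"]] * xv)
    wl <- ifelse(grid$l1 == 1, pl, 1 - pl)
    pm <- oracle_m_probs(cfg, d)
    mu <- pm[, 1] * oracle_mu(cfg, oc, d, "parental") +
      pm[, 2] * oracle_mu(cfg, oc, d, "non_centre") +
      pm[, 3] * oracle_mu(cfg, oc, d, "centre")
    sum(pc * wl * mu)
  }
  ey(1) - ey(0)
}

# g-formula CDE(m): contrast in x with the mediator held at `lv`,
# averaging L over its law under each exposure arm (X->L->Y stays open)
oracle_cde <- function(cfg, oc, lv) {
  grid <- expand.grid(c1 = 0:1, c2 = 0:1, l1 = 0:1)
  p1 <- cfg$c_prevalence[["c1"]]; p2 <- cfg$c_prevalence[["c2"]]
  pc <- ifelse(grid$c1 == 1, p1, 1 - p1) * ifelse(grid$c2 == 1, p2, 1 - p2)
  bl <- cfg$coef_X_on_L$l1
  arm <- function(xv) {
    d <- grid; d$x <- xv
    pl <- plogis(bl[["intercept"]] + bl[["x"]] * xv)
    wl <- ifelse(grid$l1 == 1, pl, 1 - pl)
    sum(pc * wl * oracle_mu(cfg, oc, d, lv))
  }
  arm(1) - arm(0)
}

# a small discrete config with every structural path active
discrete_config <- function(...) {
  generator_config(
    n = 500, continuous = FALSE,
    coef_C_on_X = c(c1 = 0.8, c2 = -0.5, c3 = 0),
    exposure_prevalence = 0.5,
    coef_X_on_L = list(l1 = c(intercept = -0.3, x = 0.7),
                       l2 = c(intercept = 0, x = 0, sd = 1)),
    coef_on_M = list(
      non_centre = c(intercept = 0.1, x = -0.4, c1 = 0.5, c2 = 0.3,
                     c3 = 0, l1 = 0.4, l2 = 0),
      centre = c(intercept = -0.2, x = -0.6, c1 = 0.7, c2 = 0.2,
                 c3 = 0, l1 = 0.5, l2 = 0)
    ),
    coef_on_Y = list(
      y1 = list(x = 0.2, m = c(non_centre = -0.1, centre = -0.15),
                xm = c(non_centre = -0.05, centre = -0.12),
                c = c(c1 = 0.3, c2 = -0.2, c3 = 0),
                l = c(l1 = 0.25, l2 = 0), noise_sd = 0.5)
    ),
    ...
  )
}

# saturated-model formulas for the discrete config
SAT <- list(
  exposure = ~ c1 * c2,
  mediator = ~ x * c1 * c2 * l1,
  te_denominator = ~ c1 * c2
)

population_design <- function() {
  design_spec(stratum_col = NULL, cluster_col = NULL,
              weight_col = "design_weight")
}

default_design <- function() design_spec()

pick <- function(tab, estimand, outcome, scenario = NULL, contrast = NULL) {
  i <- tab$estimand == estimand & tab$outcome == outcome
  if (!is.null(scenario)) i <- i & tab$scenario == scenario
  if (!is.null(contrast)) i <- i & tab$contrast == contrast
  stopifnot(sum(i) == 1)
  tab[i, , drop = FALSE]
}
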