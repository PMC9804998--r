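# Regression and testing toolkit: robust linear and power-law fits
# (Tukey bisquare M-estimation), the gamma log-link GLM of gm,25 on
# anatomical traits with McFadden's pseudo-R2, Dunn's test of multiple
# comparisons, and the n >= 12 reporting gate.

BISQUARE_C <- 4.685

# M-estimation needs a positive residual scale; on (near-)exact data the
# MAD collapses and rlm spins without converging, so perfect fits are
# short-circuited to ordinary least squares with unit weights.
rlm_or_exact <- function(xv, yv) {
  ols <- lm(yv ~ xv)
  if (max(abs(resid(ols))) <= 1e-10 * max(abs(yv), 1)) {
    ols$w <- rep(1, length(yv))
    attr(ols, "exact") <- TRUE
    return(ols)
  }
  MASS::rlm(yv ~ xv, psi = MASS::psi.bisquare, c = BISQUARE_C,
            maxit = 50, acc = 1e-8)
}

#' Robust linear regression (Tukey bisquare M-estimation)
#'
#' Iteratively reweighted least squares with the Tukey bisquare psi
#' function (tuning constant 4.685, 95% Gaussian efficiency), run to a
#' relative coefficient tolerance of 1e-8 or 50 iterations. The reported
#' R-squared is the robust weighted variant
#' \eqn{1 - \sum w r^2 / \sum w (y - \bar y_w)^2} with the final IRLS
#' weights; the slope p-value comes from its robust standard error
#' (normal reference). Pairs with a missing value in either variable are
#' dropped (pairwise-complete analysis).
#'
#' @param data Tibble containing the two variables.
#' @param x,y Column names (tidy-eval).
#' @param n_min Reporting gate: results with fewer than `n_min` pairs are
#'   marked `reported = FALSE` (default 12).
#' @return Object of class `robust_fit`: `form = "linear"`,
#'   `coefficients` (intercept, slope), `r2`, `pvalue` (slope), `n`,
#'   `reported`, and the underlying `rlm` fit.
#' @export
robust_linear_fit <- function(data, x, y, n_min = 12) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 finite pairs")
  if (sd(xv) == 0) abort("x is constant: no slope is identifiable")

  fit <- rlm_or_exact(xv, yv)
  cf <- coef(fit)
  w <- fit$w
  r <- resid(fit)
  ybar_w <- sum(w * yv) / sum(w)
  r2 <- 1 - sum(w * r^2) / sum(w * (yv - ybar_w)^2)
  se <- if (isTRUE(attr(fit, "exact"))) 0 else sqrt(diag(vcov(fit)))[2]
  pval <- if (se == 0) 0 else 2 * pnorm(-abs(cf[2] / se))

  structure(
    list(form = "linear",
         coefficients = c(intercept = unname(cf[1]), slope = unname(cf[2])),
         r2 = r2, pvalue = unname(pval), n = length(xv),
         reported = length(xv) >= n_min, n_min = n_min, fit = fit),
    class = "robust_fit"
  )
}

#' Robust power-law regression y = a x^b
#'
#' Robust nonlinear fit on the original scale: IRLS with Tukey bisquare
#' weights around a nonlinear least-squares step, started from a robust
#' linear fit of log(y) on log(x). The residual scale per iteration is the
#' MAD of the weighted-fit residuals; iteration stops at a relative
#' coefficient change below 1e-8 or 50 iterations.
#'
#' @param data Tibble containing the two variables.
#' @param x,y Column names (tidy-eval); both variables must be positive.
#' @param n_min Reporting gate (default 12).
#' @return Object of class `robust_fit` with `form = "power"` and
#'   `coefficients` (a, b).
#' @export
robust_power_fit <- function(data, x, y, n_min = 12) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 5) abort("need at least 5 finite pairs")
  if (any(xv <= 0) || any(yv <= 0)) abort("power fit requires x > 0 and y > 0")

  start_fit <- rlm_or_exact(log(xv), log(yv))
  theta <- c(a = exp(unname(coef(start_fit)[1])), b = unname(coef(start_fit)[2]))

  w <- rep(1, length(xv))
  converged <- FALSE
  for (it in seq_len(50)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yv ~ a * xv^b, start = as.list(theta), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      abort(paste0("robust power fit failed at IRLS iteration ", it, ": ",
                   conditionMessage(fit)))
    }
    new_theta <- coef(fit)
    r <- yv - new_theta["a"] * xv^new_theta["b"]
    s <- mad(r, center = 0)
    if (s == 0) { theta <- new_theta; w <- rep(1, length(xv)); converged <- TRUE; break }
    u <- r / (BISQUARE_C * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) abort("robust power fit degenerate: all weights zero")
    delta <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-10))
    theta <- new_theta
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    warn("robust power fit reached the iteration cap (50) before the 1e-8 tolerance")
  }

  fitted_y <- theta["a"] * xv^theta["b"]
  r <- yv - fitted_y
  ybar_w <- sum(w * yv) / sum(w)
  r2 <- 1 - sum(w * r^2) / sum(w * (yv - ybar_w)^2)
  # exponent p-value from the final weighted nls step
  sm <- summary(fit)
  pval <- 2 * pnorm(-abs(sm$coefficients["b", "t value"]))

  structure(
    list(form = "power",
         coefficients = c(a = unname(theta["a"]), b = unname(theta["b"])),
         r2 = r2, pvalue = unname(pval), n = length(xv),
         reported = length(xv) >= n_min, n_min = n_min, fit = fit,
         weights = w),
    class = "robust_fit"
  )
}

#' Apply the minimum-sample reporting gate
#'
#' Relationships are only tested and reported when the number of
#' measurements reaches the gate (12 by default); this sets the `reported`
#' flag accordingly without touching the fit itself.
#'
#' @param result A `robust_fit` (or any list with an `n` field).
#' @param n_min Gate threshold (default 12).
#' @return The result with `reported = (n >= n_min)` and `n_min` updated.
#' @export
gate_significance <- function(result, n_min = 12) {
  result$reported <- result$n >= n_min
  result$n_min <- n_min
  result
}

#' @export
print.robust_fit <- function(x, ...) {
  lab <- if (x$form == "linear") c("intercept", "slope") else c("a", "b")
  cat(sprintf("Robust %s fit (Tukey bisquare, c = %.3f)\n", x$form, BISQUARE_C))
  cat(sprintf("  %s = %.5g   %s = %.5g\n", lab[1], x$coefficients[1],
              lab[2], x$coefficients[2]))
  cat(sprintf("  robust R2 = %.3f   p = %.3g   n = %d   reported: %s\n",
              x$r2, x$pvalue, x$n, x$reported))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.robust_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname glance
#' @export
glance.robust_fit <- function(x, ...) {
  tibble(r.squared = x$r2, p.value = x$pvalue, nobs = x$n,
         reported = x$reported)
}

#' Gamma GLM of gm,25 on anatomical traits (log link)
#'
#' gm data are right-skewed (gamma-distributed rather than normal), so gm
#' is modelled as \eqn{\log E[g_{m,25}] = \beta_0 + \beta_1 S_c + \beta_2
#' T_{cw}} with a gamma error distribution. Coefficients are reported on
#' the exponential scale — the model is equivalent to
#' \eqn{g_{m,25} = e^{\beta_0} (e^{\beta_1})^{S_c} (e^{\beta_2})^{T_{cw}}},
#' so a one-unit increase in a covariate multiplies the expected gm by
#' \eqn{e^{\beta}}. Wald 95% confidence intervals (link scale,
#' exponentiated) use the Pearson-chi-squared dispersion estimate; the fit
#' quality is McFadden's pseudo-R2 against the intercept-only gamma GLM.
#'
#' @param data Tibble with the response and covariates; complete cases are
#'   used.
#' @param formula Model formula, default `gm_25 ~ Sc + Tcw`.
#' @param n_min Minimum number of complete cases (default 10).
#' @return Object of class `gm_glm`: exp-scale coefficient table, pseudo
#'   R2, counts, and the underlying `glm` fits.
#' @export
fit_gamma_glm <- function(data, formula = gm_25 ~ Sc + Tcw, n_min = 10) {
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("column(s) not in data: ", paste(missing_vars, collapse = ", ")))
  }
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(d) < n_min) {
    abort(paste0("need at least ", n_min, " complete cases; got ", nrow(d)))
  }
  response <- vars[1]
  if (any(d[[response]] <= 0)) abort("response must be strictly positive for a gamma GLM")
  for (v in vars[-1]) {
    if (sd(d[[v]]) == 0) {
      abort(paste0("covariate '", v, "' is constant: coefficient not identifiable"))
    }
  }

  full <- glm(formula, data = d, family = Gamma(link = "log"))
  null <- glm(stats::reformulate("1", response = response), data = d,
              family = Gamma(link = "log"))
  ll_full <- as.numeric(logLik(full))
  ll_null <- as.numeric(logLik(null))
  # a (near-)deterministic response sends the gamma likelihood to infinity
  pseudo_r2 <- if (is.finite(ll_full) && is.finite(ll_null)) {
    mcfadden_r2(ll_full, ll_null)
  } else NA_real_

  sm <- summary(full)  # Pearson chi-squared dispersion by default
  est <- coef(full)
  se <- sm$coefficients[, "Std. Error"]
  zcrit <- qnorm(0.975)
  coefs <- tibble(
    term = names(est),
    estimate = exp(unname(est)),
    conf.low = exp(unname(est) - zcrit * unname(se)),
    conf.high = exp(unname(est) + zcrit * unname(se)),
    p.value = unname(sm$coefficients[, "Pr(>|t|)"])
  )

  n_studies <- if ("study_id" %in% names(data)) {
    dplyr::n_distinct(data$study_id[complete.cases(data[vars])])
  } else NA_integer_

  structure(
    list(coefficients = coefs, pseudo_r2 = pseudo_r2,
         n_measurements = nrow(d), n_studies = n_studies,
         formula = formula, fit = full, null_fit = null,
         dispersion = sm$dispersion),
    class = "gm_glm"
  )
}

#' McFadden's pseudo R-squared
#'
#' \eqn{R^2 = 1 - \ln L(M_{full}) / \ln L(M_{null})} for nested
#' likelihood-fitted models.
#'
#' @param loglik_full Log-likelihood of the full model.
#' @param loglik_null Log-likelihood of the intercept-only model; must be
#'   non-zero and no greater than `loglik_full`.
#' @return Dimensionless value in \eqn{[0, 1)} for negative
#'   log-likelihoods.
#' @export
mcfadden_r2 <- function(loglik_full, loglik_null) {
  if (loglik_null == 0) abort("null log-likelihood is zero: ratio undefined")
  if (loglik_full < loglik_null - 1e-8) {
    abort("full model log-likelihood below the null's: models are not nested as assumed")
  }
  1 - loglik_full / loglik_null
}

#' @export
print.gm_glm <- function(x, ...) {
  cat("Gamma GLM (log link): ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d measurements", x$n_measurements))
  if (!is.na(x$n_studies)) cat(sprintf(" from %d studies", x$n_studies))
  cat(sprintf("; McFadden pseudo-R2 = %.3f\n", x$pseudo_r2))
  print(x$coefficients)
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.gm_glm <- function(x, ...) x$coefficients

#' @rdname glance
#' @export
glance.gm_glm <- function(x, ...) {
  tibble(pseudo.r.squared = x$pseudo_r2, nobs = x$n_measurements,
         n.studies = x$n_studies, dispersion = x$dispersion)
}

#' Dunn's test of multiple comparisons
#'
#' Rank-based pairwise z statistics with tie correction, following a
#' Kruskal-Wallis layout: with overall ranks \eqn{R}, groups i and j are
#' compared by
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' where \eqn{T = \sum (t^3 - t) / (12 (N - 1))} sums over tie groups.
#' Two-sided p-values are adjusted across all pairs (Holm by default).
#'
#' @param data Tibble with the value and grouping columns.
#' @param value,group Column names (tidy-eval).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @param alpha Significance level for the `significant` flag (0.05).
#' @return Tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p.value`, `p.adjusted`, `significant`. Groups with no non-missing
#'   values are dropped with a warning.
#' @export
dunn_test <- function(data, value, group, p_adjust = "holm", alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  all_groups <- unique(g[!is.na(g)])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  counts <- table(g)
  empty <- setdiff(all_groups, names(counts)[counts > 0])
  if (length(empty) > 0) warn(paste0("dropping all-missing group(s): ",
                                     paste(empty, collapse = ", ")))
  groups <- names(counts)
  if (length(groups) < 2) abort("need at least 2 groups with data")
  if (any(counts < 2)) {
    abort(paste0("every group needs n >= 2; too small: ",
                 paste(groups[counts < 2], collapse = ", ")))
  }

  N <- length(v)
  r <- rank(v)  # midranks for ties
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)

  pairs <- utils::combn(groups, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) *
                    (1 / counts[[g1]] + 1 / counts[[g2]]))
    z <- if (sigma == 0) 0 else (rbar[[g1]] - rbar[[g2]]) / sigma
    tibble(group1 = g1, group2 = g2, z = z,
           p.value = 2 * pnorm(-abs(z)))
  }) |> list_rbind()
  res$p.adjusted <- p.adjust(res$p.value, method = p_adjust)
  res$significant <- res$p.adjusted < alpha
  res
}
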