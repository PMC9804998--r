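# Relative photosynthetic limitation by mesophyll conductance: the Lm
# statistic, the exponential limitation curve Lm = a exp(-b gm), and
# PFT-level limitation ranges over the interquartile gm range.

#' Relative photosynthetic limitation imposed by mesophyll conductance
#'
#' \eqn{L_m = (A_{np} - A_n)/A_{np} \times 100}, where \eqn{A_n} is net
#' photosynthesis as measured and \eqn{A_{np}} is net photosynthesis at
#' \eqn{C_c = C_i}, i.e. with infinite mesophyll conductance and stomata
#' as measured. \eqn{L_m} quantifies by how much photosynthesis could be
#' enhanced if the mesophyll posed no diffusive resistance.
#'
#' @param An Measured net photosynthesis, umol m-2 s-1 (vectorised).
#' @param Anp Net photosynthesis at Cc = Ci, umol m-2 s-1; must be
#'   positive.
#' @return Limitation in percent; in \eqn{[0, 100)} when
#'   \eqn{0 \le A_n \le A_{np}}. An > Anp yields a negative value and a
#'   warning (physically it means the reported Anp is inconsistent).
#' @export
compute_lm <- function(An, Anp) {
  if (any(Anp <= 0, na.rm = TRUE)) abort("Anp must be positive")
  neg <- !is.na(An) & !is.na(Anp) & An > Anp
  if (any(neg)) {
    warn(paste0(sum(neg), " record(s) have An > Anp; their Lm is negative"))
  }
  (Anp - An) / Anp * 100
}

#' Fit the exponential limitation curve Lm = a exp(-b gm)
#'
#' Direct nonlinear least squares on the original scale (no
#' log-linearisation of the loss), with start values from a linear fit of
#' log(Lm) on gm over the Lm > 0 pairs and a small restart grid if the
#' optimiser fails. The decay rate is stored positive with the minus sign
#' in the model. A percentile bootstrap (case resampling) provides the 95%
#' confidence band; point exclusion is an explicit row-id list supplied by
#' the caller, never automatic.
#'
#' @param data Tibble containing the gm and Lm columns.
#' @param gm,lm Column names (tidy-eval) holding gm (mol m-2 s-1, > 0) and
#'   Lm (%). Defaults `gm_25` and `Lm`.
#' @param exclude Optional integer row numbers (of `data`) to exclude from
#'   the regression; they are kept in the returned object's
#'   `excluded_points`.
#' @param bootstrap Number of bootstrap resamples for the confidence band
#'   (default 1000); 0 disables the band.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `limitation_fit`: list with `a`, `b`, `r2`,
#'   `n`, `data` (pairs used), `excluded_points`, `boot` (tibble of
#'   resampled (a, b)), `seed`.
#' @export
fit_limitation_curve <- function(data, gm = gm_25, lm = Lm, exclude = NULL,
                                 bootstrap = 1000, seed = 1L) {
  gm_v <- dplyr::pull(data, {{ gm }})
  lm_v <- dplyr::pull(data, {{ lm }})
  keep <- seq_along(gm_v)
  if (!is.null(exclude)) keep <- setdiff(keep, exclude)
  keep <- keep[!is.na(gm_v[keep]) & !is.na(lm_v[keep])]
  x <- gm_v[keep]; y <- lm_v[keep]
  if (length(x) < 5) abort("need at least 5 (gm, Lm) pairs after exclusion")
  if (any(x <= 0)) abort("gm must be positive")

  est <- fit_exp_decay(x, y)

  fitted_y <- est["a"] * exp(-est["b"] * x)
  r2 <- 1 - sum((y - fitted_y)^2) / sum((y - mean(y))^2)

  boot <- NULL
  if (bootstrap > 0) {
    boot <- withr::with_seed(seed, {
      res <- matrix(NA_real_, bootstrap, 2)
      for (i in seq_len(bootstrap)) {
        idx <- sample.int(length(x), replace = TRUE)
        est_i <- tryCatch(fit_exp_decay(x[idx], y[idx]), error = function(e) NULL)
        if (!is.null(est_i)) res[i, ] <- est_i
      }
      tibble(a = res[, 1], b = res[, 2]) |> dplyr::filter(!is.na(a))
    })
  }

  structure(
    list(a = unname(est["a"]), b = unname(est["b"]), r2 = r2,
         n = length(x), data = tibble(gm = x, Lm = y),
         excluded_points = exclude %||% integer(0),
         boot = boot, seed = seed),
    class = "limitation_fit"
  )
}

# Nonlinear least squares for y = a exp(-b x) with linearised start values
# and a restart grid. Shared by the main fit and the bootstrap.
fit_exp_decay <- function(x, y) {
  pos <- y > 0
  start <- if (sum(pos) >= 3) {
    lf <- lm(log(y[pos]) ~ x[pos])
    c(a = exp(unname(coef(lf)[1])), b = -unname(coef(lf)[2]))
  } else {
    c(a = max(y), b = 1)
  }
  starts <- list(start,
                 c(a = max(y), b = 1),
                 c(a = max(y), b = 5),
                 c(a = mean(y[y > 0], na.rm = TRUE) * 2, b = 0.5))
  last_err <- NULL
  for (s in starts) {
    if (!all(is.finite(s))) next
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * x), start = as.list(s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (!inherits(fit, "error")) {
      cf <- coef(fit)
      return(c(a = unname(cf["a"]), b = unname(cf["b"])))
    }
    last_err <- fit
  }
  abort(paste0("limitation-curve fit failed to converge after restart grid: ",
               conditionMessage(last_err)))
}

#' Construct a limitation fit from known coefficients
#'
#' Builds a `limitation_fit` object directly from curve coefficients
#' (e.g. published values), so [predict_lm()] and the range machinery can
#' be used without the underlying pairs. No confidence band is attached.
#'
#' @param a Amplitude, percent (limitation as gm tends to 0).
#' @param b Decay rate, mol-1 m2 s (stored positive).
#' @return A `limitation_fit` object with `r2`, `n` and `boot` empty.
#' @export
limitation_fit <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(
    list(a = a, b = b, r2 = NA_real_, n = 0L,
         data = tibble(gm = numeric(), Lm = numeric()),
         excluded_points = integer(0), boot = NULL, seed = NA_integer_),
    class = "limitation_fit"
  )
}

#' Predict Lm from a fitted limitation curve
#'
#' Evaluates \eqn{a e^{-b g_m}}; with `interval = "confidence"` and a
#' bootstrap band available, percentile 2.5/97.5% bounds of the resampled
#' curves are attached.
#'
#' @param gm Conductance values at which to predict, mol m-2 s-1 (>= 0).
#' @param fit A `limitation_fit`.
#' @param interval `"none"` (default) or `"confidence"`.
#' @param level Confidence level for the bootstrap band.
#' @return With `interval = "none"`, a numeric vector of Lm (%). Otherwise
#'   a tibble with columns `gm`, `fit`, `lwr`, `upr`.
#' @export
predict_lm <- function(gm, fit, interval = c("none", "confidence"),
                       level = 0.95) {
  stopifnot(inherits(fit, "limitation_fit"))
  interval <- match.arg(interval)
  if (any(gm < 0)) abort("gm must be non-negative")
  est <- fit$a * exp(-fit$b * gm)
  if (interval == "none") return(est)
  if (is.null(fit$boot) || nrow(fit$boot) == 0) {
    warn("no bootstrap band available; returning point predictions")
    return(tibble(gm = gm, fit = est, lwr = est, upr = est))
  }
  alpha <- (1 - level) / 2
  bands <- vapply(gm, function(g) {
    curves <- fit$boot$a * exp(-fit$boot$b * g)
    quantile(curves, c(alpha, 1 - alpha), names = FALSE)
  }, numeric(2))
  tibble(gm = gm, fit = est, lwr = bands[1, ], upr = bands[2, ])
}

#' @export
predict.limitation_fit <- function(object, newdata, ...) {
  gm <- if (is.data.frame(newdata)) newdata$gm else newdata
  predict_lm(gm, object, ...)
}

#' Per-PFT limitation ranges over the typical gm range
#'
#' For each PFT with at least `min_n` values, evaluates the limitation
#' curve's confidence band over the PFT's interquartile gm range: the low
#' end is the lower confidence bound at the 75th gm percentile (high gm,
#' low limitation) and the high end the upper bound at the 25th percentile
#' — the widest defensible reading of combining a confidence band with a
#' typical range. With `rule = "point"` the point prediction is used at
#' both quartiles instead.
#'
#' @param data Tibble with gm and PFT columns.
#' @param fit A `limitation_fit` with a bootstrap band (point predictions
#'   with a warning otherwise).
#' @param gm,pft Column names (tidy-eval); defaults `gm_25` and `pft`.
#' @param min_n Minimum per-PFT sample size (default 4).
#' @param rule `"band"` (default) or `"point"`.
#' @return Tibble with one row per PFT: `pft`, `n`, `gm_q1`, `gm_q3`,
#'   `low`, `high` (integer percent).
#' @export
pft_limitation_ranges <- function(data, fit, gm = gm_25, pft = pft,
                                  min_n = 4, rule = c("band", "point")) {
  rule <- match.arg(rule)
  if (rule == "band" && (is.null(fit$boot) || nrow(fit$boot) == 0)) {
    warn("fit has no confidence band; using point predictions")
    rule <- "point"
  }
  data |>
    dplyr::rename(.gm = {{ gm }}, .pft = {{ pft }}) |>
    filter(!is.na(.data$.gm), !is.na(.data$.pft), .data$.pft != "other") |>
    group_by(.data$.pft) |>
    filter(n() >= min_n) |>
    summarise(
      n = n(),
      gm_q1 = quantile(.data$.gm, 0.25, type = 7, names = FALSE),
      gm_q3 = quantile(.data$.gm, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    ) |>
    mutate(
      low = if (rule == "band") {
        map_dbl(.data$gm_q3, function(g) predict_lm(g, fit, "confidence")$lwr)
      } else {
        predict_lm(.data$gm_q3, fit)
      },
      high = if (rule == "band") {
        map_dbl(.data$gm_q1, function(g) predict_lm(g, fit, "confidence")$upr)
      } else {
        predict_lm(.data$gm_q1, fit)
      },
      low = round(.data$low), high = round(.data$high)
    ) |>
    dplyr::rename(pft = ".pft")
}

#' @export
print.limitation_fit <- function(x, ...) {
  cat("Limitation curve: Lm = a exp(-b gm)\n")
  cat(sprintf("  a = %.3f %%   b = %.3f mol-1 m2 s   R2 = %s   n = %d\n",
              x$a, x$b, ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)), x$n))
  if (!is.null(x$boot)) cat("  bootstrap band:", nrow(x$boot), "resamples\n")
  invisible(x)
}

#' @rdname tidy
#' @param x A `limitation_fit`.
#' @param ... Unused.
#' @export
tidy.limitation_fit <- function(x, ...) {
  ci <- if (!is.null(x$boot) && nrow(x$boot) > 0) {
    tibble(
      conf.low = c(quantile(x$boot$a, 0.025, names = FALSE),
                   quantile(x$boot$b, 0.025, names = FALSE)),
      conf.high = c(quantile(x$boot$a, 0.975, names = FALSE),
                    quantile(x$boot$b, 0.975, names = FALSE))
    )
  } else {
    tibble(conf.low = c(NA_real_, NA_real_), conf.high = c(NA_real_, NA_real_))
  }
  dplyr::bind_cols(
    tibble(term = c("a", "b"), estimate = c(x$a, x$b)), ci
  )
}

#' @rdname glance
#' @param x A `limitation_fit`.
#' @param ... Unused.
#' @export
glance.limitation_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n,
         n.excluded = length(x$excluded_points),
         n.boot = if (is.null(x$boot)) 0L else nrow(x$boot))
}

#' Plot a fitted limitation curve
#'
#' Scatter of the (gm, Lm) pairs used in the fit, the fitted exponential
#' curve, and (when available) the bootstrap confidence ribbon.
#'
#' @param object A `limitation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.limitation_fit <- function(object, ...) {
  grid <- tibble(gm = seq(max(1e-3, min(object$data$gm, na.rm = TRUE) * 0.5),
                          max(object$data$gm, 1), length.out = 200))
  pred <- predict_lm(grid$gm, object,
                     interval = if (!is.null(object$boot)) "confidence" else "none")
  if (!is.data.frame(pred)) pred <- tibble(gm = grid$gm, fit = pred,
                                           lwr = pred, upr = pred)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$gm, y = .data$Lm)) +
    ggplot2::geom_point(alpha = 0.5)
  if (!is.null(object$boot)) {
    p <- p + ggplot2::geom_ribbon(
      data = pred, ggplot2::aes(x = .data$gm, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line(data = pred, ggplot2::aes(x = .data$gm, y = .data$fit),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::labs(x = expression(g[m] ~ (mol ~ m^-2 ~ s^-1)),
                  y = expression(L[m] ~ ("%")))
}
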