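test_that("robust linear fit matches exact data and resists gross outliers", {
  d <- tibble::tibble(x = seq_len(20), y = 2 * seq_len(20) + 1)
  fit <- robust_linear_fit(d, x, y)
  expect_equal(unname(fit$coefficients["slope"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["intercept"]), 1, tolerance = 1e-7)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  d_out <- d
  d_out$y[20] <- d_out$y[20] + 100  # high-leverage gross outlier
  rob <- robust_linear_fit(d_out, x, y)
  ols <- lm(y ~ x, data = d_out)
  expect_lt(abs(rob$coefficients["slope"] - 2), 0.05)
  expect_gt(abs(coef(ols)[2] - 2), 0.5)

  expect_error(robust_linear_fit(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "constant")
})

test_that("robust fits agree with least squares on clean Gaussian data", {
  set.seed(21)
  x <- runif(60, 0, 10)
  y <- 1.5 + 0.8 * x + rnorm(60, 0, 0.5)
  d <- tibble::tibble(x = x, y = y)
  rob <- robust_linear_fit(d, x, y)
  ols <- lm(y ~ x)
  se <- summary(ols)$coefficients[2, 2]
  expect_lt(abs(rob$coefficients["slope"] - coef(ols)[2]), 2 * se)
})

test_that("robust power fit recovers y = a x^b and resists contamination", {
  set.seed(5)
  x <- runif(40, 0.5, 10)
  d <- tibble::tibble(x = x, y = 3 * x^0.5)
  fit <- robust_power_fit(d, x, y)
  expect_equal(unname(fit$coefficients["a"]), 3, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["b"]), 0.5, tolerance = 1e-6)

  # 10% contamination
  d_c <- d
  idx <- sample(40, 4)
  d_c$y[idx] <- d_c$y[idx] * 5
  fit_c <- robust_power_fit(d_c, x, y)
  expect_lt(abs(fit_c$coefficients["b"] - 0.5), 0.05)
  # the non-robust fit is visibly pulled
  nls_c <- nls(y ~ a * x^b, data = d_c, start = list(a = 3, b = 0.5))
  expect_gt(abs(coef(nls_c)["a"] - 3), 4 * abs(fit_c$coefficients["a"] - 3) + 0.01)

  expect_error(robust_power_fit(tibble::tibble(x = c(-1, 2, 3, 4, 5),
                                               y = c(1, 2, 3, 4, 5)), x, y),
               "x > 0")
})

test_that("constant-An drawdown against gm has a power exponent of -1", {
  set.seed(8)
  gm <- runif(50, 0.05, 1)
  d <- tibble::tibble(gm = gm, drawdown = 20 / gm)
  fit <- robust_power_fit(d, gm, drawdown)
  expect_equal(unname(fit$coefficients["b"]), -1, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["a"]), 20, tolerance = 1e-5)
})

test_that("the n >= 12 reporting gate flags small samples", {
  d <- tibble::tibble(x = seq_len(10), y = 2 * seq_len(10) + rnorm(10, 0, 0.1))
  fit <- robust_linear_fit(d, x, y)
  expect_false(fit$reported)
  d12 <- tibble::tibble(x = seq_len(12), y = seq_len(12))
  expect_true(robust_linear_fit(d12, x, y)$reported)
  big <- gate_significance(list(n = 1000))
  expect_true(big$reported)
  expect_false(gate_significance(list(n = 11))$reported)
  expect_true(gate_significance(list(n = 12))$reported)
  # threshold configurable
  expect_true(gate_significance(list(n = 10), n_min = 10)$reported)
})

test_that("gamma GLM recovers a noise-free log-linear mean exactly", {
  set.seed(1)
  n <- 60
  d <- tibble::tibble(
    Sc = runif(n, 5, 40),
    Tcw = runif(n, 0.05, 0.6),
    study_id = rep(c("a", "b", "c"), length.out = n)
  )
  d$gm_25 <- 0.128 * 1.050^d$Sc * 0.096^d$Tcw
  # the deterministic response sends the gamma likelihood to infinity,
  # which the fit reports as an NA pseudo-R2
  fit <- suppressWarnings(fit_gamma_glm(d))
  expect_equal(fit$coefficients$estimate,
               c(0.128, 1.050, 0.096), tolerance = 1e-8)
  expect_equal(fit$n_measurements, n)
  expect_equal(fit$n_studies, 3)
  # model identity on the exp scale holds for fitted values
  eb <- fit$coefficients$estimate
  mu_hat <- eb[1] * eb[2]^d$Sc * eb[3]^d$Tcw
  expect_equal(unname(fitted(fit$fit)), mu_hat, tolerance = 1e-9)
})

test_that("gamma GLM reports exp-scale Wald intervals and errors on degenerate input", {
  set.seed(2)
  n <- 80
  d <- tibble::tibble(Sc = runif(n, 5, 40), Tcw = runif(n, 0.05, 0.6))
  mu <- 0.128 * 1.050^d$Sc * 0.096^d$Tcw
  d$gm_25 <- rgamma(n, shape = 5, rate = 5 / mu)
  fit <- fit_gamma_glm(d)
  expect_true(all(fit$coefficients$estimate > 0))
  expect_true(all(fit$coefficients$conf.low < fit$coefficients$estimate))
  expect_true(all(fit$coefficients$conf.high > fit$coefficients$estimate))

  d_const <- d; d_const$Tcw <- 0.3
  expect_error(fit_gamma_glm(d_const), "Tcw")
  expect_error(fit_gamma_glm(d[1:5, ]), "complete cases")
  d_neg <- d; d_neg$gm_25[1] <- -1
  expect_error(fit_gamma_glm(d_neg), "positive")
})

test_that("McFadden pseudo-R2 is the likelihood ratio complement", {
  expect_equal(mcfadden_r2(-100, -100), 0)
  expect_equal(mcfadden_r2(-50, -100), 0.5)
  expect_error(mcfadden_r2(-50, 0), "zero")
  expect_error(mcfadden_r2(-120, -100), "nested")

  # a stronger mean structure yields a higher pseudo-R2; the response is
  # expressed in mmol so both log-likelihoods are negative, the regime in
  # which the McFadden ratio is interpretable
  set.seed(4)
  n <- 150
  Sc <- runif(n, 5, 40); Tcw <- runif(n, 0.05, 0.6)
  mu <- 1000 * 0.128 * 1.050^Sc * 0.096^Tcw
  weak <- tibble::tibble(Sc, Tcw, gm_25 = rgamma(n, 1.2, rate = 1.2 / mu))
  strong <- tibble::tibble(Sc, Tcw, gm_25 = rgamma(n, 4, rate = 4 / mu))
  r2w <- fit_gamma_glm(weak)$pseudo_r2
  r2s <- fit_gamma_glm(strong)$pseudo_r2
  expect_gt(r2s, r2w)
  expect_gt(r2w, 0)
  expect_lt(r2s, 1)
})

test_that("GLM estimation is unbiased to first order over replicates", {
  reps <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    n <- 150
    Sc <- runif(n, 5, 40); Tcw <- runif(n, 0.05, 0.6)
    mu <- 0.128 * 1.050^Sc * 0.096^Tcw
    d <- tibble::tibble(Sc, Tcw, gm_25 = rgamma(n, 5, rate = 5 / mu))
    fit_gamma_glm(d)$coefficients$estimate[2]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 1.050) / 1.050, 0.005)
})

test_that("Dunn's test matches hand-computed rank statistics", {
  # identical groups: no separation
  d_eq <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  r_eq <- dunn_test(d_eq, v, g)
  expect_equal(r_eq$z, 0)
  expect_equal(r_eq$p.value, 1)

  # maximal separation: z equals the brute-force Dunn statistic
  d2 <- tibble::tibble(v = c(1:5, 101:105), g = rep(c("lo", "hi"), each = 5))
  r2 <- dunn_test(d2, v, g)
  N <- 10
  rbar_lo <- mean(rank(d2$v)[d2$g == "lo"])
  rbar_hi <- mean(rank(d2$v)[d2$g == "hi"])
  z_hand <- (rbar_hi - rbar_lo) / sqrt(N * (N + 1) / 12 * (1 / 5 + 1 / 5))
  expect_equal(abs(r2$z), abs(z_hand))
  expect_true(r2$significant)

  # tie correction: brute-force oracle with midranks and tie term
  set.seed(77)
  v <- sample(rep(1:6, 4))
  g <- rep(c("a", "b", "c"), each = 8)
  d3 <- tibble::tibble(v = v, g = g)
  r3 <- dunn_test(d3, v, g)
  rk <- rank(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (length(v) - 1))
  for (k in seq_len(nrow(r3))) {
    i <- r3$group1[k]; j <- r3$group2[k]
    z_oracle <- (mean(rk[g == i]) - mean(rk[g == j])) /
      sqrt((length(v) * (length(v) + 1) / 12 - tie_term) * (1 / 8 + 1 / 8))
    expect_equal(r3$z[k], z_oracle)
  }
})

test_that("two-group tie-free Dunn z equals the Wilcoxon normal approximation", {
  set.seed(12)
  x <- rnorm(9); y <- rnorm(7) + 1
  d <- tibble::tibble(v = c(x, y), g = rep(c("x", "y"), c(9, 7)))
  z_dunn <- dunn_test(d, v, g)$z
  # Mann-Whitney U normal approximation without continuity correction
  W <- sum(rank(c(x, y))[1:9]) - 9 * 10 / 2
  mu_W <- 9 * 7 / 2
  sd_W <- sqrt(9 * 7 * (9 + 7 + 1) / 12)
  expect_equal(abs(z_dunn), abs((W - mu_W) / sd_W), tolerance = 1e-12)
})

test_that("distinct synthetic PFT distributions separate in all pairwise tests", {
  set.seed(31)
  d <- tibble::tibble(
    v = c(rgamma(60, 5, rate = 5 / 0.08), rgamma(60, 5, rate = 5 / 0.2),
          rgamma(60, 5, rate = 5 / 0.45)),
    g = rep(c("fern", "evergreen_angiosperm", "C3_annual_herb"), each = 60)
  )
  r <- dunn_test(d, v, g)
  expect_true(all(r$significant))
  # Holm adjustment never lowers a p-value
  expect_true(all(r$p.adjusted >= r$p.value - 1e-15))
})

test_that("groups with no data are dropped with a warning", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, NA, NA),
                      g = c("a", "a", "b", "b", "c", "c"))
  expect_warning(r <- dunn_test(d, v, g), "all-missing")
  expect_equal(nrow(r), 1)
  expect_error(dunn_test(tibble::tibble(v = 1:3, g = c("a", "a", "a")), v, g),
               "2 groups")
})
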