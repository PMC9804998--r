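test_that("measurement filters classify by the published thresholds and never error", {
  base <- tibble::tibble(
    T_meas = c(14, 25, 25, 25, 25, NA, 36, 25),
    PPFD = c(1500, 200, 1500, 1500, NA, 1500, 1500, 1500),
    CO2_meas = c(400, 400, 600, 400, 400, 400, 250, 400),
    An = c(20, 20, 20, 30, 20, 20, 20, 20),
    gm = c(0.2, 0.2, 0.2, 0.05, 0.2, 0.2, 0.2, 0.2)
  )
  rep <- apply_measurement_filters(base)
  expect_s3_class(rep, "filter_report")
  expect_equal(rep$n_input, 8)
  # row 1: temperature low; row 2: irradiance; row 3: CO2 high; row 4:
  # drawdown 600; row 5: missing PPFD retained; row 6: missing T excluded;
  # row 7 trips temperature high AND CO2 low (counted once in retention);
  # row 8 is fully clean
  expect_equal(rep$n_retained, 2)
  counts <- setNames(rep$report$n_excluded, rep$report$criterion)
  expect_equal(counts[["temperature"]], 3)
  expect_equal(counts[["irradiance"]], 1)
  expect_equal(counts[["co2"]], 2)
  expect_equal(counts[["drawdown"]], 1)
  # multi-criterion rows carry every reason
  expect_true(any(grepl("temperature;co2", rep$excluded$.reasons)))
  # retention arithmetic: input = retained + unique excluded rows
  expect_equal(rep$n_input, rep$n_retained + nrow(rep$excluded))
  # missing PPFD logged, not excluded
  expect_equal(rep$missing_log$n_missing_retained[
    rep$missing_log$criterion == "irradiance"], 1)
})

test_that("filters are idempotent on their own retained set", {
  d <- derive_gas_exchange(generate_cohort(cohort_config(
    violation_rates = list(temperature = 0.05, irradiance = 0.05,
                           co2 = 0.05, drawdown = 0.05), seed = 11)))
  rep1 <- apply_measurement_filters(d)
  rep2 <- apply_measurement_filters(rep1$retained)
  expect_equal(rep2$n_retained, rep2$n_input)
  expect_equal(sum(rep2$report$n_excluded), 0)
})

test_that("outlier step 1 applies growth-form extreme thresholds before the IQR step", {
  vals <- c(0.2, 0.25, 0.3, 0.35, 2.5)
  res <- detect_outliers(vals, pft = rep("C3_annual_herb", 5),
                         growth_form = rep("herbaceous", 5))
  expect_equal(res$flag_extreme, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # woody threshold is 1 mol m-2 s-1
  res_w <- detect_outliers(c(0.2, 0.3, 0.25, 1.2), rep("evergreen_angiosperm", 4),
                           rep("woody", 4))
  expect_equal(sum(res_w$flag_extreme), 1)
  # ferns (neither herbaceous nor woody label) use the woody threshold
  res_f <- detect_outliers(c(0.1, 0.12, 0.15, 1.2), rep("fern", 4),
                           rep("fern", 4))
  expect_equal(sum(res_f$flag_extreme), 1)
})

test_that("IQR fences on the log scale match the brute-force oracle", {
  g <- c(0.10, 0.12, 0.15, 0.20, 0.22, 0.25, 0.90)
  res <- detect_outliers(g, rep("C3_annual_herb", 7), rep("herbaceous", 7))
  expect_equal(res$flag_iqr, brute_force_iqr_flags(g))
  expect_true(res$flag_iqr[7])

  # all-equal group: IQR = 0, fences collapse onto the data, no flags
  res_eq <- detect_outliers(rep(0.2, 4), rep("fern", 4), rep("woody", 4))
  expect_false(any(res_eq$flag_iqr))

  # random groups, including ties after rounding
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    g <- round(rlnorm(n, log(0.2), 0.8), sample(2:4, 1))
    g <- pmin(g, 0.99)  # keep below step-1 threshold so all enter step 2
    res <- detect_outliers(g, rep("p", n), rep("woody", n))
    expect_equal(res$flag_iqr, brute_force_iqr_flags(g))
  }
})

test_that("outlier flags are invariant to order and to uniform rescaling", {
  set.seed(9)
  g <- rlnorm(30, log(0.2), 0.7)
  g <- pmin(g, 0.95)
  res <- detect_outliers(g, rep("p", 30), rep("woody", 30))
  perm <- sample(30)
  res_p <- detect_outliers(g[perm], rep("p", 30), rep("woody", 30))
  expect_equal(res_p$flag_iqr, res$flag_iqr[perm])
  # rescaling shifts log values and fences identically (scale kept below
  # the step-1 threshold so step 1 does not interfere)
  res_s <- detect_outliers(g * 0.5, rep("p", 30), rep("woody", 30))
  expect_equal(res_s$flag_iqr, res$flag_iqr)
})

test_that("small groups skip the IQR step with a log", {
  expect_message(
    res <- detect_outliers(c(0.1, 0.2, 0.9), rep("fern", 3), rep("woody", 3)),
    "skipped"
  )
  expect_false(any(res$flag_iqr))
  expect_equal(attr(res, "skipped_groups"), "fern")
})

test_that("multi-method reconciliation follows the supersede/mean rules", {
  # curve fitting + one other: the other method wins
  expect_equal(as.numeric(reconcile_gm(c("curve_fitting", "isotope"), c(0.20, 0.30))), 0.30)
  # two non-curve-fitting methods: arithmetic mean
  expect_equal(as.numeric(reconcile_gm(c("isotope", "fluorescence"), c(0.20, 0.30))), 0.25)
  # single entry: identity
  expect_equal(as.numeric(reconcile_gm("fluorescence", 0.22)), 0.22)
  # out-of-rule case: 2 non-CF + CF -> mean of non-CF, logged
  v <- reconcile_gm(c("curve_fitting", "isotope", "fluorescence"), c(0.1, 0.2, 0.4))
  expect_equal(as.numeric(v), 0.3)
  expect_true(attr(v, "out_of_rule_case"))
  expect_error(reconcile_gm(c("isotope", "isotope"), c(0.1, 0.2)), "distinct")
})

test_that("table-level reconciliation collapses plant sets to one row", {
  d <- tibble::tibble(
    study_id = c("s1", "s1", "s2"),
    species = c("a", "a", "b"),
    method = c("curve_fitting", "isotope", "fluorescence"),
    gm_value = c(0.2, 0.3, 0.22),
    An = c(18, 20, 15)
  )
  r <- reconcile_methods(d)
  expect_equal(nrow(r), 2)
  s1 <- r[r$study_id == "s1", ]
  expect_equal(s1$gm_value, 0.3)
  expect_equal(s1$An, 20)  # averaged over the rows actually used
  expect_equal(s1$method, "isotope")
})

test_that("planted violations are recovered with perfect precision and recall", {
  rates <- list(temperature = 0.05, irradiance = 0.05, co2 = 0.05,
                drawdown = 0.05, extreme = 0.03)
  d <- derive_gas_exchange(generate_cohort(cohort_config(violation_rates = rates,
                                                         seed = 303)))
  d$.row <- seq_len(nrow(d))
  rep <- apply_measurement_filters(d)

  for (crit in c("temperature", "irradiance", "co2", "drawdown")) {
    planted <- d$.row[d$planted_violation %in% crit]
    flagged <- rep$excluded$.row[grepl(crit, rep$excluded$.reasons)]
    expect_equal(sort(flagged), sort(planted), label = crit)
  }

  # extreme gm violations are caught by outlier step 1
  kept <- rep$retained
  out <- detect_outliers(kept$gm_25, kept$pft, kept$growth_form)
  planted_extreme <- kept$planted_violation %in% "extreme"
  expect_equal(out$flag_extreme, planted_extreme)
})
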