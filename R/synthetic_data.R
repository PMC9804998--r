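# Synthetic data: a minimal Rubisco-limited leaf gas-exchange simulator
# (supply-demand coupling) and a cohort generator producing datasets with
# the statistical structure the analysis assumes, including controllable
# planted filter violations.

#' Configuration for the leaf gas-exchange simulator
#'
#' A Rubisco-limited demand curve
#' \eqn{A = V_{cmax}(C_c - \Gamma^*)/(C_c + K_m) - R_d} coupled with the
#' diffusive supply chain \eqn{C_c = C_a - A (1/g_{s,c} + 1/g_m)}.
#' Defaults are standard 25 degC constants; the analysis never depends on
#' them, only on the coupling identities.
#'
#' @param Vcmax Maximum carboxylation rate, umol m-2 s-1.
#' @param Rd Day respiration, umol m-2 s-1.
#' @param gamma_star CO2 compensation point without Rd, umol mol-1.
#' @param Km Effective Michaelis constant of Rubisco, umol mol-1.
#' @param gs_c Stomatal conductance to CO2, mol m-2 s-1.
#' @param gm Mesophyll conductance, mol m-2 s-1; `Inf` allowed.
#' @param Ca Ambient CO2 concentration, umol mol-1; must exceed
#'   `gamma_star`.
#' @return A list of class `leaf_sim_config`.
#' @export
leaf_sim_config <- function(Vcmax = 80, Rd = 1, gamma_star = 42.75,
                            Km = 717, gs_c = 0.25, gm = 0.2, Ca = 400) {
  vals <- c(Vcmax = Vcmax, Rd = Rd, gamma_star = gamma_star, Km = Km,
            gs_c = gs_c, Ca = Ca)
  if (any(vals <= 0) || gm <= 0) abort("all simulator parameters must be positive")
  if (Ca <= gamma_star) abort("Ca must exceed gamma_star")
  structure(list(Vcmax = Vcmax, Rd = Rd, gamma_star = gamma_star, Km = Km,
                 gs_c = gs_c, gm = gm, Ca = Ca),
            class = "leaf_sim_config")
}

# Net photosynthesis for total diffusive resistance r = 1/gs + 1/gm.
# Substituting the supply chain Cc = Ca - A r into the demand curve gives
# the quadratic r A^2 - (Ca + Km + (Vcmax - Rd) r) A
#               + Vcmax (Ca - gamma_star) - Rd (Ca + Km) = 0;
# the physical root is the smaller one (the larger puts Cc below the
# compensation point or negative).
solve_An <- function(cfg, r) {
  with(cfg, {
    if (r == 0) {
      # no diffusive resistance: Cc = Ca exactly
      return(Vcmax * (Ca - gamma_star) / (Ca + Km) - Rd)
    }
    qa <- r
    qb <- -(Ca + Km + (Vcmax - Rd) * r)
    qc <- Vcmax * (Ca - gamma_star) - Rd * (Ca + Km)
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) {
      abort(paste0("no physical root: supply cannot meet demand (Vcmax=", Vcmax,
                   ", gs_c=", gs_c, ", gm=", gm, ", Ca=", Ca, ")"))
    }
    A <- (-qb - sqrt(disc)) / (2 * qa)  # smaller root
    Cc <- Ca - A * r
    if (!(Cc > 0 && Cc < Ca)) {
      A_alt <- (-qb + sqrt(disc)) / (2 * qa)
      Cc_alt <- Ca - A_alt * r
      if (Cc_alt > 0 && Cc_alt < Ca) { A <- A_alt } else {
        abort("no root with Cc in (0, Ca): configuration is unphysical")
      }
    }
    A
  })
}

#' Simulate steady-state leaf gas exchange
#'
#' Solves the Rubisco-limited demand curve jointly with the CO2 supply
#' chain (closed-form quadratic, physical root with \eqn{C_c \in (0,
#' C_a)}). \eqn{A_{np}} — photosynthesis at \eqn{C_c = C_i} — is solved
#' identically with the mesophyll term removed (\eqn{1/g_m = 0}), i.e.
#' infinite mesophyll conductance with stomata as measured, and the
#' limitation follows from [compute_lm()].
#'
#' @param config A [leaf_sim_config()].
#' @return One-row tibble: `An`, `Ci`, `Cc`, `Anp`, `Lm`.
#' @export
simulate_leaf <- function(config) {
  stopifnot(inherits(config, "leaf_sim_config"))
  r_full <- 1 / config$gs_c + if (is.finite(config$gm)) 1 / config$gm else 0
  An <- solve_An(config, r_full)
  Ci <- config$Ca - An / config$gs_c
  Cc <- Ci - if (is.finite(config$gm)) An / config$gm else 0
  Anp <- solve_An(config, 1 / config$gs_c)
  Lm <- compute_lm(An, Anp)
  tibble(An = An, Ci = Ci, Cc = Cc, Anp = Anp, Lm = Lm)
}

#' Configuration for a synthetic measurement cohort
#'
#' Describes the PFT-stratified structure of a synthetic dataset: per-PFT
#' sample sizes, the log-linear trait link for gm,25
#' (\eqn{E[g_{m,25}] = e^{\beta_0} (e^{\beta_1})^{S_c}
#' (e^{\beta_2})^{T_{cw}}}) with multiplicative gamma noise, trait ranges,
#' the mix of measurement methods, and the fraction of rows that will be
#' planted to violate each quality filter.
#'
#' @param pfts Tibble with one row per PFT: `pft`, `n`, `growth_form`
#'   (`herbaceous`/`woody`), `exp_beta0`, `exp_beta1`, `exp_beta2`
#'   (exp-scale GLM coefficients), `gamma_shape` (gm noise shape),
#'   `Sc_min`, `Sc_max`, `Tcw_min`, `Tcw_max`. The default is a single
#'   pooled stratum with exp-scale coefficients (0.128, 1.050, 0.096),
#'   gamma shape 5, Sc in (5, 40) m2 m-2 and Tcw in (0.05, 0.6) um.
#' @param methods_prob Named probabilities for method assignment.
#' @param violation_rates Named list of fractions per filter criterion
#'   (`temperature`, `irradiance`, `co2`, `drawdown`, `extreme`); all 0 by
#'   default.
#' @param frac_25C Fraction of records measured at exactly 25 degC (the
#'   rest draw from (18, 32) degC).
#' @param Ca Ambient CO2 during measurement, umol mol-1.
#' @param tresponse [tresponse_params()] used to back-transform gm,25 to
#'   the measurement temperature.
#' @param seed Integer seed; generation is fully reproducible under it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(pfts = NULL,
                          methods_prob = c(isotope = 0.4, fluorescence = 0.4,
                                           curve_fitting = 0.2),
                          violation_rates = list(),
                          frac_25C = 0.7, Ca = 400,
                          tresponse = tresponse_params("tobacco"),
                          seed = 1L) {
  if (is.null(pfts)) {
    pfts <- tibble(
      pft = c("C3_annual_herb", "C3_perennial_herb", "deciduous_angiosperm",
              "evergreen_angiosperm", "evergreen_gymnosperm", "fern"),
      n = c(60, 50, 45, 45, 40, 25),
      growth_form = c("herbaceous", "herbaceous", "woody", "woody", "woody",
                      "woody"),
      exp_beta0 = 0.128, exp_beta1 = 1.050, exp_beta2 = 0.096,
      gamma_shape = 5,
      Sc_min = c(12, 10, 8, 6, 5, 5),
      Sc_max = c(40, 35, 30, 28, 25, 20),
      Tcw_min = c(0.05, 0.08, 0.10, 0.15, 0.20, 0.25),
      Tcw_max = c(0.30, 0.35, 0.40, 0.50, 0.60, 0.60)
    )
  }
  rates <- list(temperature = 0, irradiance = 0, co2 = 0, drawdown = 0,
                extreme = 0)
  rates[names(violation_rates)] <- violation_rates
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    abort("violation rates must lie in [0, 1]")
  }
  if (any(pfts$n < 1)) abort("each PFT needs n >= 1")
  structure(list(pfts = pfts, methods_prob = methods_prob,
                 violation_rates = rates, frac_25C = frac_25C, Ca = Ca,
                 tresponse = tresponse, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic measurement cohort
#'
#' Per PFT: draws traits uniformly over the configured ranges, sets the
#' expected gm,25 through the log-linear trait link, adds multiplicative
#' gamma noise (mean preserved), back-transforms gm,25 to the measurement
#' temperature via the inverse temperature scaling, and derives An, Ci,
#' Cc, Anp and Lm from the leaf simulator with photosynthetic capacity
#' and stomatal conductance co-varying with gm (as observed across
#' species, keeping CO2 drawdowns in the physically typical range).
#' Methods and study identifiers are assigned at random. Output follows
#' the canonical CSV schema; generator ground truth is carried in
#' `true_gm_25` and `true_mu` columns.
#'
#' @param config A [cohort_config()].
#' @return Tibble of records; violations configured in
#'   `config$violation_rates` are planted by [inject_violations()] and
#'   labelled in `planted_violation`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- withr::with_seed(config$seed, {
    rows <- purrr::pmap(config$pfts, function(pft, n, growth_form, exp_beta0,
                                              exp_beta1, exp_beta2, gamma_shape,
                                              Sc_min, Sc_max, Tcw_min, Tcw_max, ...) {
      Sc <- runif(n, Sc_min, Sc_max)
      Tcw <- runif(n, Tcw_min, Tcw_max)
      mu <- exp_beta0 * exp_beta1^Sc * exp_beta2^Tcw
      gm_25 <- rgamma(n, shape = gamma_shape, rate = gamma_shape / mu)
      T_meas <- ifelse(runif(n) < config$frac_25C, 25, runif(n, 18, 32))
      f <- temperature_scaling_factor(T_meas, config$tresponse)
      gm_T <- gm_25 * f
      # capacity and stomata co-vary with gm so that the CO2 drawdown
      # stays in the physically typical range
      Vcmax <- pmin(150, pmax(10, 400 * gm_25 *
                                exp(rnorm(n, 0, 0.15))))
      gs_c <- pmax(0.02, 1.3 * gm_T * exp(rnorm(n, 0, 0.2)))
      gas <- purrr::map(seq_len(n), function(i) {
        simulate_leaf(leaf_sim_config(
          Vcmax = Vcmax[i], Rd = 0.015 * Vcmax[i], gs_c = gs_c[i],
          gm = gm_T[i], Ca = config$Ca
        ))
      }) |> list_rbind()
      n_studies <- max(1L, round(n / 6))
      tibble(
        study_id = paste0(pft, "_study_", sample.int(n_studies, n, replace = TRUE)),
        species = paste0("synthetic_", pft, "_sp", seq_len(n)),
        pft = pft,
        growth_form = growth_form,
        gm_value = gm_T,
        gm_units = "mol_m2_s",
        method = sample(names(config$methods_prob), n, replace = TRUE,
                        prob = config$methods_prob),
        T_meas = T_meas,
        PPFD = runif(n, 1000, 2000),
        CO2_meas = config$Ca,
        pressure = 100,
        elevation = NA_real_,
        already_standardised = FALSE,
        An = gas$An, gs_c = gs_c, Ci = gas$Ci, Ca = config$Ca,
        Anp = gas$Anp,
        Sc = Sc, Tcw = Tcw,
        N_area = pmax(0.4, 1.2 + 1.5 * gm_25 + rnorm(n, 0, 0.3)),
        K_area = pmax(0.1, 0.5 + 0.8 * gm_25 + rnorm(n, 0, 0.2)),
        true_gm_25 = gm_25,
        true_mu = mu,
        true_Lm = gas$Lm
      )
    })
    dplyr::bind_rows(rows)
  })
  seed2 <- (config$seed * 7919L + 13L) %% .Machine$integer.max
  inject_violations(out, config$violation_rates, seed = seed2)
}

#' Plant labelled filter violations into a cohort
#'
#' Randomly selects disjoint row sets and modifies each to violate exactly
#' one named criterion: temperature set to 10 degC, irradiance to 200
#' umol m-2 s-1, CO2 to 600 umol mol-1, gm lowered so the drawdown An/gm
#' exceeds 300 umol mol-1, or gm,25 inflated past the extreme-value
#' threshold for the row's growth form. Ground truth is stored in the
#' `planted_violation` column (`NA` for clean rows).
#'
#' @param data Cohort tibble (canonical schema).
#' @param rates Named list of fractions per criterion (`temperature`,
#'   `irradiance`, `co2`, `drawdown`, `extreme`).
#' @param seed Integer seed.
#' @return The tibble with planted rows modified and labelled. A rate that
#'   rounds to zero planted rows triggers a warning.
#' @export
inject_violations <- function(data, rates, seed = 1L) {
  rates_full <- list(temperature = 0, irradiance = 0, co2 = 0, drawdown = 0,
                     extreme = 0)
  rates_full[names(rates)] <- rates
  data$planted_violation <- NA_character_
  n <- nrow(data)
  if (all(unlist(rates_full) == 0)) return(data)

  withr::with_seed(seed, {
    available <- seq_len(n)
    for (crit in names(rates_full)) {
      rate <- rates_full[[crit]]
      if (rate == 0) next
      k <- round(rate * n)
      if (k < 1) {
        warn(paste0("rate ", rate, " for criterion '", crit,
                    "' yields zero planted rows at n = ", n))
        next
      }
      if (k > length(available)) {
        abort("violation rates too high: not enough unplanted rows left")
      }
      pick <- sample(available, k)
      available <- setdiff(available, pick)
      data$planted_violation[pick] <- crit
      if (crit == "temperature") {
        data$T_meas[pick] <- 10
      } else if (crit == "irradiance") {
        data$PPFD[pick] <- 200
      } else if (crit == "co2") {
        data$CO2_meas[pick] <- 600
      } else if (crit == "drawdown") {
        # lower gm so An/gm lands past the 300 umol mol-1 bound
        data$gm_value[pick] <- data$An[pick] / 400
      } else if (crit == "extreme") {
        thr <- ifelse(!is.na(data$growth_form[pick]) &
                        data$growth_form[pick] == "herbaceous", 2, 1)
        data$gm_value[pick] <- thr * 1.25
        data$T_meas[pick] <- 25
        # keep the drawdown in range so the row violates only this criterion
        data$An[pick] <- data$gm_value[pick] * 100
        if ("true_gm_25" %in% names(data)) data$true_gm_25[pick] <- NA_real_
      }
    }
  })
  data
}
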