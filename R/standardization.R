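# Temperature standardisation of gm to 25 degC and Fick's-law derived
# quantities (Cc, CO2 drawdown, Cc:Ca).

R_GAS <- 8.314  # J mol-1 K-1

#' Load a temperature-response parameter set
#'
#' Parameter sets for the temperature scaling of mesophyll conductance are
#' shipped as a versioned YAML file. Two responses are provided: `tobacco`,
#' a peaked Arrhenius function measured on *Nicotiana tabacum* (the
#' default standardisation), and `arabidopsis`, a weaker non-peaked
#' Arrhenius response used to characterise the uncertainty tied to the
#' choice of response function.
#'
#' @param name `"tobacco"` or `"arabidopsis"`, or any name present in
#'   `file`.
#' @param file Optional path to a YAML parameter file; defaults to the one
#'   shipped with the package.
#' @return An object of class `tresponse_params`: list with `name`,
#'   `family` (`peaked_arrhenius`, `arrhenius` or `polynomial`), `params`
#'   (named numeric), `T_ref` (25).
#' @export
tresponse_params <- function(name = c("tobacco", "arabidopsis"), file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "tresponse.yaml", package = "mesolim")
  }
  all <- yaml::read_yaml(file)
  name <- if (length(name) > 1) name[1] else name
  if (!name %in% names(all)) {
    abort(paste0("no temperature response named '", name, "' in ", file))
  }
  entry <- all[[name]]
  out <- list(
    name = name,
    family = entry$family,
    params = unlist(entry$params),
    T_ref = entry$T_ref %||% 25
  )
  class(out) <- "tresponse_params"
  validate_tresponse(out)
  out
}

validate_tresponse <- function(p) {
  needed <- switch(p$family,
    peaked_arrhenius = c("c", "Ha", "Hd", "S"),
    arrhenius = "Ea",
    polynomial = NULL,
    abort(paste0("unknown temperature-response family: ", p$family))
  )
  if (p$family == "polynomial") {
    if (length(p$params) < 1) abort("polynomial family needs at least one coefficient")
  } else if (!all(needed %in% names(p$params))) {
    abort(paste0("temperature response '", p$name, "' (", p$family,
                 ") is missing parameter(s): ",
                 paste(setdiff(needed, names(p$params)), collapse = ", ")))
  }
  invisible(p)
}

# Unnormalised scaling function; the public factor divides by this at T_ref.
tresponse_raw <- function(T_c, p) {
  Tk <- T_c + 273.15
  pa <- p$params
  switch(p$family,
    peaked_arrhenius =
      exp(pa[["c"]] - pa[["Ha"]] / (R_GAS * Tk)) /
        (1 + exp((pa[["S"]] * Tk - pa[["Hd"]]) / (R_GAS * Tk))),
    arrhenius =
      exp(pa[["Ea"]] * (Tk - 298.15) / (R_GAS * 298.15 * Tk)),
    polynomial = {
      # coefficients in increasing power of (T - T_ref)
      dT <- T_c - (p$T_ref %||% 25)
      Reduce(`+`, Map(function(coef, k) coef * dT^k,
                      unname(pa), seq_along(pa) - 1))
    }
  )
}

#' Temperature scaling factor for mesophyll conductance
#'
#' Evaluates the chosen temperature response, renormalised so that
#' \eqn{f(25) = 1} exactly. gm measured at temperature T is divided by this
#' factor to obtain gm at 25 degrees C.
#'
#' @param T_c Leaf temperature in degrees C (vectorised); must lie in
#'   (0, 50).
#' @param params A [tresponse_params()] object.
#' @return Dimensionless positive factor, 1 at 25 degrees C.
#' @export
temperature_scaling_factor <- function(T_c, params) {
  stopifnot(inherits(params, "tresponse_params"))
  validate_tresponse(params)
  if (any(T_c <= 0 | T_c >= 50, na.rm = TRUE)) {
    abort("temperature out of supported range (0, 50) degC")
  }
  tresponse_raw(T_c, params) / tresponse_raw(params$T_ref %||% 25, params)
}

#' Standardise gm to 25 degrees C
#'
#' Divides gm by the temperature scaling factor at the measurement
#' temperature. Records whose source already reports gm at 25 degrees C
#' (flag `already_standardised`) pass through unchanged; the value at the
#' original temperature is meant to be retained alongside (see
#' [derive_gas_exchange()]).
#'
#' @param gm Conductance in mol m-2 s-1 (vectorised); must be positive.
#' @param T_c Measurement temperature, degrees C.
#' @param params A [tresponse_params()] object.
#' @param already_standardised Logical (recycled): bypass scaling.
#' @return gm at 25 degrees C, mol m-2 s-1.
#' @export
standardize_gm_to_25 <- function(gm, T_c, params, already_standardised = FALSE) {
  if (any(gm <= 0, na.rm = TRUE)) abort("gm must be positive")
  n <- length(gm)
  already <- rep_len(already_standardised, n)
  already[is.na(already)] <- FALSE
  T_c <- rep_len(T_c, n)
  out <- gm
  idx <- which(!already & !is.na(T_c))
  if (length(idx) > 0) {
    out[idx] <- gm[idx] / temperature_scaling_factor(T_c[idx], params)
  }
  out
}

#' Chloroplast CO2 concentration and drawdown from Fick's first law
#'
#' With \eqn{g_m = A_n / (C_i - C_c)}, the CO2 drawdown from the
#' intercellular airspaces to the chloroplast stroma is
#' \eqn{C_i - C_c = A_n / g_m}.
#'
#' @param An Net photosynthesis, umol m-2 s-1 (vectorised).
#' @param Ci Intercellular CO2 concentration, umol mol-1.
#' @param gm Mesophyll conductance, mol m-2 s-1; must be strictly positive.
#' @return Tibble with columns `Cc`, `drawdown` and `flag_negative_An`
#'   (TRUE where An <= 0 puts Cc at or above Ci).
#' @export
compute_cc <- function(An, Ci, gm) {
  if (any(gm == 0, na.rm = TRUE)) abort("gm = 0: drawdown undefined")
  drawdown <- An / gm
  tibble(
    Cc = Ci - drawdown,
    drawdown = drawdown,
    flag_negative_An = !is.na(An) & An <= 0
  )
}

#' Add standardised gm and Fick's-law quantities to a record table
#'
#' Data-frame verb combining [standardize_units()],
#' [standardize_gm_to_25()] and [compute_cc()]: adds `gm` (mol m-2 s-1 at
#' the measurement temperature, pressure-standardised), `gm_25`, `Cc`,
#' `drawdown`, `Cc_over_Ca` and `Ci_over_Ca`. gm at the original
#' temperature is retained in `gm` so analyses pairing gm with other
#' measurements made at the same temperature remain possible.
#'
#' @param data Tibble of records in the canonical schema (see
#'   [gm_column_dictionary()]).
#' @param tresponse A [tresponse_params()] object, or a name passed to
#'   [tresponse_params()].
#' @return The input tibble with derived columns appended.
#' @export
derive_gas_exchange <- function(data, tresponse = "tobacco") {
  if (is.character(tresponse)) tresponse <- tresponse_params(tresponse)
  pres <- if ("pressure" %in% names(data)) data$pressure else NULL
  elev <- if ("elevation" %in% names(data)) data$elevation else NULL
  already <- if ("already_standardised" %in% names(data)) {
    dplyr::coalesce(data$already_standardised, FALSE)
  } else FALSE
  gm <- standardize_units(data$gm_value, data$gm_units, pres, elev)
  ok <- !is.na(gm) & gm > 0
  gm_25 <- rep(NA_real_, nrow(data))
  T_meas <- if ("T_meas" %in% names(data)) data$T_meas else rep(NA_real_, nrow(data))
  gm_25[ok] <- standardize_gm_to_25(gm[ok], T_meas[ok], tresponse,
                                    rep_len(already, nrow(data))[ok])
  cc <- compute_cc(data$An, data$Ci, ifelse(ok, gm, NA_real_))
  data |>
    mutate(
      gm = gm,
      gm_25 = gm_25,
      Cc = cc$Cc,
      drawdown = cc$drawdown,
      Cc_over_Ca = .data$Cc / .data$Ca,
      Ci_over_Ca = .data$Ci / .data$Ca
    )
}
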