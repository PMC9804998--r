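# Record schema, CSV ingest, unit conversion to mol m-2 s-1 at 100 kPa,
# and plant-functional-type assignment.

#' Canonical column dictionary for gas-exchange records
#'
#' One row per recognised column of the flat dataset: name, class, units and
#' whether the column is mandatory at ingest. The same table is shipped as a
#' machine-readable schema at
#' `system.file("extdata", "column_dictionary.csv", package = "mesolim")`.
#'
#' @return A tibble with columns `column`, `class`, `units`, `mandatory`,
#'   `description`.
#' @export
gm_column_dictionary <- function() {
  tibble::tribble(
    ~column, ~class, ~units, ~mandatory, ~description,
    "study_id", "character", "", TRUE, "opaque identifier of the source study",
    "species", "character", "", FALSE, "species name as reported",
    "pft", "character", "", TRUE, "plant functional type label",
    "growth_form", "character", "", FALSE, "herbaceous or woody (extreme-value thresholds)",
    "gm_value", "numeric", "see gm_units", TRUE, "mesophyll conductance as reported",
    "gm_units", "character", "", TRUE, "one of mol_m2_s, mol_m2_s_bar, umol_m2_s_Pa",
    "method", "character", "", FALSE, "isotope, fluorescence, curve_fitting or other",
    "T_meas", "numeric", "degC", FALSE, "leaf temperature during measurement",
    "PPFD", "numeric", "umol m-2 s-1", FALSE, "measurement irradiance",
    "CO2_meas", "numeric", "umol mol-1", FALSE, "measurement CO2 concentration",
    "pressure", "numeric", "kPa", FALSE, "atmospheric pressure, if reported",
    "elevation", "numeric", "m", FALSE, "site elevation, if pressure missing",
    "already_standardised", "logical", "", FALSE, "gm reported at 25 degC in the source",
    "An", "numeric", "umol m-2 s-1", FALSE, "light-saturated net photosynthesis",
    "gs_c", "numeric", "mol m-2 s-1", FALSE, "stomatal conductance to CO2",
    "Ci", "numeric", "umol mol-1", FALSE, "intercellular CO2 concentration",
    "Ca", "numeric", "umol mol-1", FALSE, "ambient CO2 concentration",
    "Anp", "numeric", "umol m-2 s-1", FALSE, "net photosynthesis at Cc = Ci",
    "Sc", "numeric", "m2 m-2", FALSE, "chloroplast surface area exposed to airspaces per leaf area",
    "Sm", "numeric", "m2 m-2", FALSE, "mesophyll surface area exposed to airspaces per leaf area",
    "Tcw", "numeric", "um", FALSE, "mesophyll cell-wall thickness",
    "LMA", "numeric", "g m-2", FALSE, "leaf dry mass per area",
    "leaf_thickness", "numeric", "um", FALSE, "leaf thickness",
    "density", "numeric", "g cm-3", FALSE, "leaf density",
    "porosity", "numeric", "fraction", FALSE, "mesophyll porosity",
    "N_area", "numeric", "g m-2", FALSE, "leaf nitrogen content per area",
    "K_area", "numeric", "g m-2", FALSE, "leaf potassium content per area",
    "rubisco", "numeric", "g m-2", FALSE, "Rubisco content per area",
    "Vcmax_Cc", "numeric", "umol m-2 s-1", FALSE, "maximum carboxylation rate on a Cc basis",
    "stomatal_density", "numeric", "mm-2", FALSE, "stomatal density",
    "stomatal_length", "numeric", "um", FALSE, "stomatal length"
  )
}

#' Recognised unit systems for reported mesophyll conductance
#' @return Character vector of unit codes.
#' @export
gm_unit_levels <- function() c("mol_m2_s", "mol_m2_s_bar", "umol_m2_s_Pa")

#' Plant functional type labels carried by the pipeline
#' @return Character vector of PFT labels; `other` collects groups excluded
#'   from PFT-level statistics (CAM, C4, semideciduous, deciduous
#'   gymnosperms, fern allies, mosses).
#' @export
pft_levels <- function() {
  c("fern", "evergreen_gymnosperm", "evergreen_angiosperm",
    "deciduous_angiosperm", "C3_perennial_herb", "C3_annual_herb", "other")
}

#' Read a gas-exchange dataset from CSV
#'
#' Reads a flat CSV of per-study leaf records into the canonical schema.
#' Column names can be remapped through `schema`; unparseable cells in
#' optional numeric columns become `NA` and are listed in the parse log
#' rather than raising errors. Rows with non-positive `gm_value` are
#' retained but flagged.
#'
#' @param path Path to a CSV file (UTF-8, comma separated, `.` decimal,
#'   header row required).
#' @param schema Optional named character vector mapping file column names
#'   to canonical names, e.g. `c(gm = "gm_value")` renames column `gm`.
#' @return A tibble of records with attributes `parse_log` (tibble of
#'   coerced cells: row, column, original value) and `row_flags` (tibble of
#'   row-level validation flags). Row count equals the file's data rows.
#' @export
read_gas_exchange <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      abort("`schema` must be a fully named character vector: c(file_col = \"canonical_col\")")
    }
    idx <- match(names(schema), names(raw))
    if (anyNA(idx)) {
      abort(paste0("schema refers to absent column(s): ",
                   paste(names(schema)[is.na(idx)], collapse = ", ")))
    }
    names(raw)[idx] <- unname(schema)
  }
  dict <- gm_column_dictionary()
  mandatory <- dict$column[dict$mandatory]
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mandatory column(s) missing: ", paste(missing_cols, collapse = ", ")),
          class = "mesolim_schema_error")
  }

  parse_log <- list()
  out <- raw
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    if (!col %in% names(out)) next
    cls <- dict$class[i]
    if (cls == "numeric") {
      parsed <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(!is.na(out[[col]]) & is.na(parsed))
      if (length(bad) > 0) {
        parse_log[[length(parse_log) + 1L]] <- tibble(
          row = bad, column = col, original = out[[col]][bad]
        )
      }
      out[[col]] <- parsed
    } else if (cls == "logical") {
      parsed <- suppressWarnings(as.logical(out[[col]]))
      bad <- which(!is.na(out[[col]]) & is.na(parsed))
      if (length(bad) > 0) {
        parse_log[[length(parse_log) + 1L]] <- tibble(
          row = bad, column = col, original = out[[col]][bad]
        )
      }
      out[[col]] <- parsed
    }
  }
  parse_log <- if (length(parse_log) > 0) dplyr::bind_rows(parse_log) else
    tibble(row = integer(), column = character(), original = character())

  flags <- tibble(row = integer(), flag = character())
  nonpos <- which(!is.na(out$gm_value) & out$gm_value <= 0)
  if (length(nonpos) > 0) {
    flags <- dplyr::bind_rows(flags, tibble(row = nonpos, flag = "nonpositive_gm"))
  }
  unknown_units <- which(!is.na(out$gm_units) & !out$gm_units %in% gm_unit_levels())
  if (length(unknown_units) > 0) {
    flags <- dplyr::bind_rows(flags, tibble(row = unknown_units, flag = "unknown_gm_units"))
  }

  out <- as_tibble(out)
  attr(out, "parse_log") <- parse_log
  attr(out, "row_flags") <- flags
  out
}

#' Write a gas-exchange dataset to CSV
#'
#' Inverse of [read_gas_exchange()]; a read-write-read round trip preserves
#' all non-coerced fields exactly.
#'
#' @param data Tibble of records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Convert site elevation to mean atmospheric pressure
#'
#' International barometric formula
#' \eqn{P = 101.325 (1 - 2.25577\times 10^{-5} z)^{5.25588}} kPa.
#'
#' @param elevation_m Elevation above sea level in metres.
#' @return Pressure in kPa.
#' @export
elevation_to_pressure <- function(elevation_m) {
  101.325 * (1 - 2.25577e-5 * elevation_m)^5.25588
}

#' Standardise reported gm to mol m-2 s-1 at 100 kPa
#'
#' Pressure-normalised (liquid-phase equivalent) units are converted to a
#' molar-flux basis at the reported atmospheric pressure:
#' \eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}} Pa\eqn{^{-1}} \eqn{\times 0.1
#' \rightarrow} mol m\eqn{^{-2}} s\eqn{^{-1}} bar\eqn{^{-1}}, then
#' \eqn{\times P}(bar). When neither pressure nor elevation is available,
#' 100 kPa (= 1 bar) is assumed. Values already in mol m\eqn{^{-2}}
#' s\eqn{^{-1}} pass through unchanged.
#'
#' @param gm_value Reported conductance (vectorised).
#' @param gm_units One of [gm_unit_levels()] (recycled).
#' @param pressure_kPa Optional atmospheric pressure, kPa.
#' @param elevation_m Optional elevation, m (used when pressure is missing).
#' @return gm in mol m-2 s-1 at the measurement pressure (100 kPa assumed
#'   when unreported).
#' @export
standardize_units <- function(gm_value, gm_units, pressure_kPa = NULL,
                              elevation_m = NULL) {
  n <- length(gm_value)
  gm_units <- rep_len(gm_units, n)
  bad_units <- stats::na.omit(setdiff(unique(gm_units), gm_unit_levels()))
  if (length(bad_units) > 0) {
    abort(paste0("unknown gm units: ", paste(bad_units, collapse = ", ")))
  }
  pressure_kPa <- if (is.null(pressure_kPa)) rep(NA_real_, n) else rep_len(pressure_kPa, n)
  elevation_m <- if (is.null(elevation_m)) rep(NA_real_, n) else rep_len(elevation_m, n)
  if (any(pressure_kPa <= 0, na.rm = TRUE)) {
    abort("atmospheric pressure must be positive")
  }
  p <- ifelse(!is.na(pressure_kPa), pressure_kPa,
              ifelse(!is.na(elevation_m), elevation_to_pressure(elevation_m), 100))
  p_bar <- p / 100  # 100 kPa = 1 bar
  out <- gm_value
  is_pa <- !is.na(gm_units) & gm_units == "umol_m2_s_Pa"
  is_bar <- !is.na(gm_units) & gm_units == "mol_m2_s_bar"
  out[is_pa] <- gm_value[is_pa] * 0.1 * p_bar[is_pa]
  out[is_bar] <- gm_value[is_bar] * p_bar[is_bar]
  out
}

#' Convert water-vapour stomatal conductance to a CO2 basis
#'
#' Divides by the ratio of diffusivities of water vapour and CO2 in air
#' (1.6).
#'
#' @param gs_w Stomatal conductance to water vapour, mol m-2 s-1.
#' @return Stomatal conductance to CO2, mol m-2 s-1.
#' @export
gs_water_to_co2 <- function(gs_w) gs_w / 1.6

#' Assign a plant functional type from lineage and habit
#'
#' Deterministic mapping from evolutionary lineage, growth habit and leaf
#' longevity to the PFT labels used throughout the package. Herbaceous
#' covers both forbs and grasses; biennial herbs are grouped with annuals.
#' CAM and C4 plants, semideciduous angiosperms, deciduous gymnosperms,
#' fern allies and mosses map to `other` and are carried but excluded from
#' PFT-level statistics.
#'
#' @param lineage One of `angiosperm`, `gymnosperm`, `fern`, `fern_ally`,
#'   `moss` (vectorised).
#' @param growth_habit One of `woody`, `herbaceous_forb`,
#'   `herbaceous_grass`, `nonvascular`.
#' @param leaf_longevity One of `evergreen`, `deciduous`, `semideciduous`,
#'   `perennial`, `annual`, `biennial`; `NA` allowed where irrelevant
#'   (mosses, fern allies).
#' @param pathway Photosynthetic pathway: `C3` (default), `C4` or `CAM`.
#' @param overrides Optional tibble with columns `lineage`, `growth_habit`,
#'   `leaf_longevity`, `pathway`, `pft`; exact matches take precedence over
#'   the built-in rules, so species with unusual metadata can be classified
#'   by configuration rather than code.
#' @return Character vector of PFT labels, one per input.
#' @export
assign_pft <- function(lineage, growth_habit, leaf_longevity,
                       pathway = "C3", overrides = NULL) {
  n <- max(length(lineage), length(growth_habit), length(leaf_longevity),
           length(pathway))
  lineage <- rep_len(as.character(lineage), n)
  growth_habit <- rep_len(as.character(growth_habit), n)
  leaf_longevity <- rep_len(as.character(leaf_longevity), n)
  pathway <- rep_len(as.character(pathway), n)

  herb <- c("herbaceous_forb", "herbaceous_grass")
  annualish <- c("annual", "biennial")

  conflict <- (lineage %in% c("fern", "fern_ally", "moss") &
                 leaf_longevity %in% annualish) |
    (growth_habit == "nonvascular" & lineage != "moss") |
    (growth_habit == "woody" & leaf_longevity %in% annualish)
  conflict[is.na(conflict)] <- FALSE
  if (any(conflict)) {
    i <- which(conflict)[1]
    abort(paste0("contradictory PFT attributes at position ", i, ": lineage=",
                 lineage[i], ", growth_habit=", growth_habit[i],
                 ", leaf_longevity=", leaf_longevity[i]))
  }

  classify_one <- function(lin, hab, lon, pw) {
    if (!is.null(overrides) && nrow(overrides) > 0) {
      hit <- overrides$lineage == lin & overrides$growth_habit == hab &
        (is.na(overrides$leaf_longevity) & is.na(lon) |
           !is.na(overrides$leaf_longevity) & !is.na(lon) &
           overrides$leaf_longevity == lon) &
        overrides$pathway == pw
      hit[is.na(hit)] <- FALSE
      if (any(hit)) return(overrides$pft[which(hit)[1]])
    }
    if (!is.na(pw) && pw %in% c("C4", "CAM")) return("other")
    if (is.na(lin)) return("other")
    if (lin %in% c("moss", "fern_ally")) return("other")
    if (lin == "fern") return("fern")
    if (lin == "gymnosperm") {
      if (!is.na(lon) && lon == "evergreen") return("evergreen_gymnosperm")
      return("other")  # deciduous/semideciduous gymnosperms excluded
    }
    if (lin == "angiosperm") {
      if (!is.na(hab) && hab == "woody") {
        if (is.na(lon)) return("other")
        if (lon == "evergreen") return("evergreen_angiosperm")
        if (lon == "deciduous") return("deciduous_angiosperm")
        return("other")  # semideciduous
      }
      if (!is.na(hab) && hab %in% herb) {
        if (!is.na(lon) && lon %in% annualish) return("C3_annual_herb")
        if (!is.na(lon) && lon == "perennial") return("C3_perennial_herb")
        return("other")
      }
    }
    "other"
  }
  vapply(seq_len(n), function(i) {
    classify_one(lineage[i], growth_habit[i], leaf_longevity[i], pathway[i])
  }, character(1))
}
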