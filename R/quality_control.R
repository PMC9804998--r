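# Measurement-condition filters, the two-step PFT-specific outlier screen,
# and reconciliation of multi-method gm measurements.

#' Default quality-control thresholds
#'
#' The measurement-condition filters and outlier rules applied to the
#' compiled dataset. All values can be overridden, but the defaults are the
#' analysis conditions: leaf temperature within 15--35 degC (missing
#' temperature excludes), irradiance at least 300 umol m-2 s-1, measurement
#' CO2 within 300--500 umol mol-1, CO2 drawdown An/gm within 10--300
#' umol mol-1, extreme gm values above 2 (herbaceous) or 1 (woody)
#' mol m-2 s-1, and log-scale Tukey fences at 1.5 IQR per PFT.
#'
#' @param T_min,T_max Temperature window, degC.
#' @param PPFD_min Minimum irradiance, umol m-2 s-1.
#' @param CO2_min,CO2_max Measurement CO2 window, umol mol-1.
#' @param drawdown_min,drawdown_max CO2 drawdown window, umol mol-1.
#' @param extreme_herbaceous,extreme_woody Step-1 extreme-value thresholds,
#'   mol m-2 s-1. Groups that are neither herbaceous nor woody (ferns,
#'   mosses) use the woody threshold: their gm range is low.
#' @param iqr_k Fence multiplier for the step-2 interquartile screen.
#' @param iqr_min_n Minimum group size for step 2; smaller PFT groups are
#'   skipped and logged.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(T_min = 15, T_max = 35, PPFD_min = 300,
                          CO2_min = 300, CO2_max = 500,
                          drawdown_min = 10, drawdown_max = 300,
                          extreme_herbaceous = 2, extreme_woody = 1,
                          iqr_k = 1.5, iqr_min_n = 4) {
  list(T_min = T_min, T_max = T_max, PPFD_min = PPFD_min,
       CO2_min = CO2_min, CO2_max = CO2_max,
       drawdown_min = drawdown_min, drawdown_max = drawdown_max,
       extreme_herbaceous = extreme_herbaceous, extreme_woody = extreme_woody,
       iqr_k = iqr_k, iqr_min_n = iqr_min_n)
}

#' Apply measurement-condition filters
#'
#' Classifies each record against the deterministic exclusion criteria:
#' (1) measurement temperature below `T_min`, above `T_max` or not
#' reported; (2) irradiance below `PPFD_min`; (3) measurement CO2 outside
#' (`CO2_min`, `CO2_max`); (4) CO2 drawdown An/gm outside
#' (`drawdown_min`, `drawdown_max`). Missing irradiance or CO2 does not
#' exclude (only missing temperature does); such rows are retained and
#' listed in the report's `missing_log`. Filters never raise errors: they
#' classify.
#'
#' @param data Tibble with columns `T_meas`, `PPFD`, `CO2_meas` and either
#'   `drawdown` or both `An` and `gm` (pressure-standardised,
#'   mol m-2 s-1).
#' @param thresholds A [qc_thresholds()] list.
#' @return An object of class `filter_report`: list with `retained`
#'   (tibble), `excluded` (tibble with `.reasons`, a semicolon-separated
#'   list of every criterion a row trips), `report` (per-criterion
#'   exclusion counts), `n_input`, `n_retained`, and `missing_log`.
#' @export
apply_measurement_filters <- function(data, thresholds = qc_thresholds()) {
  th <- thresholds
  n <- nrow(data)
  get <- function(col) if (col %in% names(data)) data[[col]] else rep(NA_real_, n)

  T_meas <- get("T_meas")
  PPFD <- get("PPFD")
  CO2 <- get("CO2_meas")
  drawdown <- if ("drawdown" %in% names(data)) data$drawdown else get("An") / get("gm")

  fails <- list(
    temperature = is.na(T_meas) | T_meas < th$T_min | T_meas > th$T_max,
    irradiance = !is.na(PPFD) & PPFD < th$PPFD_min,
    co2 = !is.na(CO2) & (CO2 < th$CO2_min | CO2 > th$CO2_max),
    drawdown = !is.na(drawdown) &
      (drawdown > th$drawdown_max | drawdown < th$drawdown_min)
  )
  fail_mat <- do.call(cbind, fails)
  any_fail <- rowSums(fail_mat) > 0

  reasons <- apply(fail_mat, 1, function(r) paste(names(fails)[r], collapse = ";"))
  excluded <- data[any_fail, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$.reasons <- reasons[any_fail]
  else excluded$.reasons <- character(0)

  missing_log <- tibble(
    criterion = c("irradiance", "co2"),
    n_missing_retained = c(sum(is.na(PPFD) & !any_fail), sum(is.na(CO2) & !any_fail))
  )

  out <- list(
    retained = as_tibble(data[!any_fail, , drop = FALSE]),
    excluded = as_tibble(excluded),
    report = tibble(criterion = names(fails), n_excluded = colSums(fail_mat)),
    n_input = n,
    n_retained = sum(!any_fail),
    missing_log = missing_log,
    thresholds = th
  )
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Measurement-condition filter report\n")
  cat("  input rows:    ", x$n_input, "\n")
  cat("  retained rows: ", x$n_retained, "\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  excluded by %-12s %d\n", paste0(x$report$criterion[i], ":"),
                x$report$n_excluded[i]))
  }
  invisible(x)
}

#' Two-step PFT-specific outlier detection for gm,25
#'
#' Step 1 flags extreme values above 2 mol m-2 s-1 (herbaceous) or
#' 1 mol m-2 s-1 (woody and other growth forms). Step 2 log-transforms the
#' survivors and, separately within each PFT, flags values below
#' Q1 - 1.5 IQR or above Q3 + 1.5 IQR (quartiles by linear interpolation,
#' type 7). The steps are applied strictly in order: step-1 flags never
#' enter the step-2 quartile computation. Groups smaller than `iqr_min_n`
#' skip step 2 (logged in the `skipped_groups` attribute).
#'
#' @param gm_25 Positive conductance values, mol m-2 s-1.
#' @param pft PFT label per value (step-2 grouping).
#' @param growth_form `"herbaceous"` or `"woody"` per value; anything else
#'   uses the woody threshold.
#' @param thresholds A [qc_thresholds()] list.
#' @return Tibble with columns `gm_25`, `pft`, `growth_form`,
#'   `flag_extreme`, `flag_iqr`, `outlier` (either flag); attribute
#'   `skipped_groups` lists PFTs too small for step 2.
#' @export
detect_outliers <- function(gm_25, pft, growth_form, thresholds = qc_thresholds()) {
  th <- thresholds
  if (any(gm_25 <= 0, na.rm = TRUE)) abort("gm_25 must be positive")
  n <- length(gm_25)
  pft <- rep_len(as.character(pft), n)
  growth_form <- rep_len(as.character(growth_form), n)

  limit <- ifelse(!is.na(growth_form) & growth_form == "herbaceous",
                  th$extreme_herbaceous, th$extreme_woody)
  flag_extreme <- !is.na(gm_25) & gm_25 > limit

  flag_iqr <- rep(FALSE, n)
  skipped <- character(0)
  for (g in unique(pft[!is.na(gm_25) & !flag_extreme])) {
    idx <- which(pft == g & !flag_extreme & !is.na(gm_25))
    if (length(idx) < th$iqr_min_n) {
      skipped <- c(skipped, g)
      next
    }
    lg <- log(gm_25[idx])
    q <- quantile(lg, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flag_iqr[idx] <- lg < q[1] - th$iqr_k * iqr | lg > q[2] + th$iqr_k * iqr
  }
  if (length(skipped) > 0) {
    inform(paste0("IQR outlier step skipped for group(s) with n < ",
                  th$iqr_min_n, ": ", paste(skipped, collapse = ", ")))
  }
  out <- tibble(gm_25 = gm_25, pft = pft, growth_form = growth_form,
                flag_extreme = flag_extreme, flag_iqr = flag_iqr,
                outlier = flag_extreme | flag_iqr)
  attr(out, "skipped_groups") <- skipped
  out
}

#' Reconcile gm measured with several methods on one set of plants
#'
#' When gm for a set of plants was estimated with the curve-fitting method
#' plus exactly one other method, the other method's value is used; two
#' non-curve-fitting methods are averaged; a single entry is returned as
#' is. Beyond those cases (three or more methods), the mean of the
#' non-curve-fitting values is used and the case is logged.
#'
#' @param methods Character vector of distinct method labels
#'   (`curve_fitting`, `isotope`, `fluorescence`, `other`).
#' @param gm Conductance per method, same length.
#' @return Single reconciled gm value; attribute `out_of_rule_case` is
#'   TRUE when more than two non-curve-fitting methods were combined.
#' @export
reconcile_gm <- function(methods, gm) {
  stopifnot(length(methods) == length(gm), length(gm) >= 1)
  if (anyDuplicated(methods)) abort("methods must be distinct within a plant set")
  non_cf <- methods != "curve_fitting"
  beyond <- FALSE
  val <- if (length(gm) == 1) {
    gm
  } else if (sum(non_cf) == 0) {
    mean(gm)  # several curve-fitting variants: average
  } else if (sum(non_cf) == 1) {
    gm[non_cf]  # curve fitting superseded by the second method
  } else {
    beyond <- sum(non_cf) > 2 || any(!non_cf)
    mean(gm[non_cf])
  }
  attr(val, "out_of_rule_case") <- beyond
  val
}

#' Reconcile multi-method measurements across a record table
#'
#' Groups records by plant set (default: `study_id` x `species`) and
#' collapses each group to one row with [reconcile_gm()] applied to
#' `gm_value`; other numeric columns are averaged over the rows whose
#' method was used, and the `method` column records which method(s)
#' contributed.
#'
#' @param data Tibble with at least `method` and `gm_value`.
#' @param group_vars Character vector of grouping columns.
#' @return Tibble with one row per plant set.
#' @export
reconcile_methods <- function(data, group_vars = c("study_id", "species")) {
  group_vars <- intersect(group_vars, names(data))
  if (length(group_vars) == 0) abort("no grouping columns present")
  data |>
    group_by(across(dplyr::all_of(group_vars))) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1) return(d)
      val <- reconcile_gm(d$method, d$gm_value)
      non_cf <- d$method != "curve_fitting"
      used <- if (nrow(d) > 1 && sum(non_cf) >= 1) which(non_cf) else seq_len(nrow(d))
      out <- d[1, , drop = FALSE]
      num <- vapply(d, is.numeric, logical(1))
      out[1, num] <- as.list(colMeans(d[used, num, drop = FALSE], na.rm = TRUE))
      out$gm_value <- as.numeric(val)
      out$method <- paste(sort(d$method[used]), collapse = "+")
      out
    }) |>
    ungroup()
}
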