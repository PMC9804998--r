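# Pipeline orchestration: ingest -> standardise -> quality control ->
# limitation curve and trait statistics, with serialised result tables and
# a run manifest.

#' Pipeline run configuration
#'
#' @param input Path to a CSV in the canonical schema, or a tibble of
#'   records already in memory.
#' @param schema Optional column mapping passed to [read_gas_exchange()].
#' @param tresponse Temperature response name or [tresponse_params()]
#'   object (default `"tobacco"`).
#' @param thresholds [qc_thresholds()] list.
#' @param reconcile Collapse multi-method plant sets with
#'   [reconcile_methods()] before analysis (default TRUE).
#' @param exclude_ids Row ids excluded from the limitation-curve fit.
#' @param bootstrap Bootstrap resamples for the limitation confidence band.
#' @param analyses Character subset of `c("limitation", "glm", "dunn")`.
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, schema = NULL, tresponse = "tobacco",
                       thresholds = qc_thresholds(), reconcile = TRUE,
                       exclude_ids = NULL, bootstrap = 1000,
                       analyses = c("limitation", "glm", "dunn"),
                       seed = 1L) {
  if (is.character(input) && !file.exists(input)) {
    abort(paste0("input path not resolvable: ", input))
  }
  structure(list(input = input, schema = schema, tresponse = tresponse,
                 thresholds = thresholds, reconcile = reconcile,
                 exclude_ids = exclude_ids, bootstrap = bootstrap,
                 analyses = analyses, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in fixed order: ingest (if `input` is a path), unit and
#' pressure standardisation plus temperature standardisation to 25 degC,
#' measurement-condition filters, two-step outlier detection,
#' multi-method reconciliation, then the requested analyses: the
#' exponential limitation curve on records with both gm,25 and Lm
#' (Lm computed from An and Anp where available), the gamma GLM of gm,25
#' on Sc and Tcw, and Dunn's test of gm,25 medians across PFTs. Any stage
#' error aborts with the stage name attached.
#'
#' @param config A [run_config()].
#' @return Object of class `mesolim_run`: list with `records` (analysis
#'   set), `filter` (the `filter_report`), `outliers`, `limitation`,
#'   `glm`, `dunn`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }

  records <- stage("ingest", {
    if (is.character(config$input)) {
      read_gas_exchange(config$input, schema = config$schema)
    } else as_tibble(config$input)
  })

  records <- stage("standardize", derive_gas_exchange(records, config$tresponse))

  filt <- stage("qc_filters", apply_measurement_filters(records, config$thresholds))
  kept <- filt$retained

  out_flags <- stage("qc_outliers", {
    gf <- if ("growth_form" %in% names(kept)) kept$growth_form else
      ifelse(kept$pft %in% c("C3_annual_herb", "C3_perennial_herb"),
             "herbaceous", "woody")
    detect_outliers(kept$gm_25, kept$pft, gf, config$thresholds)
  })
  analysis_set <- kept[!out_flags$outlier, , drop = FALSE]

  if (config$reconcile) {
    analysis_set <- stage("reconcile", {
      n0 <- nrow(analysis_set)
      res <- reconcile_methods(analysis_set)
      attr(res, "n_collapsed") <- n0 - nrow(res)
      res
    })
    # reconciliation averages raw gm; refresh derived columns
    analysis_set <- stage("standardize",
                          derive_gas_exchange(
                            select(analysis_set, -dplyr::any_of(
                              c("gm", "gm_25", "Cc", "drawdown",
                                "Cc_over_Ca", "Ci_over_Ca"))),
                            config$tresponse))
  }

  limitation <- NULL
  if ("limitation" %in% config$analyses) {
    limitation <- stage("limitation", {
      d <- analysis_set |>
        filter(!is.na(.data$gm_25), !is.na(.data$An), !is.na(.data$Anp),
               .data$Anp > 0) |>
        mutate(Lm = compute_lm(.data$An, .data$Anp))
      if (nrow(d) >= 5) {
        fit_limitation_curve(d, gm = gm_25, lm = Lm,
                             exclude = config$exclude_ids,
                             bootstrap = config$bootstrap, seed = config$seed)
      } else NULL
    })
  }

  glm_fit <- NULL
  if ("glm" %in% config$analyses &&
      all(c("Sc", "Tcw") %in% names(analysis_set))) {
    glm_fit <- stage("glm", {
      ok <- complete.cases(analysis_set[c("gm_25", "Sc", "Tcw")])
      if (sum(ok) >= 10) fit_gamma_glm(analysis_set) else NULL
    })
  }

  dunn <- NULL
  if ("dunn" %in% config$analyses) {
    dunn <- stage("dunn", {
      d <- filter(analysis_set, .data$pft != "other", !is.na(.data$gm_25))
      if (dplyr::n_distinct(d$pft) >= 2 && all(table(d$pft) >= 2)) {
        dunn_test(d, gm_25, pft)
      } else NULL
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mesolim")),
    seed = config$seed,
    tresponse = if (is.character(config$tresponse)) config$tresponse else
      config$tresponse$name,
    thresholds = config$thresholds,
    config_hash = rlang::hash(config[setdiff(names(config), "input")]),
    n_input = filt$n_input,
    n_retained_filters = filt$n_retained,
    n_outliers = sum(out_flags$outlier),
    n_analysis = nrow(analysis_set),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  structure(list(records = analysis_set, filter = filt, outliers = out_flags,
                 limitation = limitation, glm = glm_fit, dunn = dunn,
                 manifest = manifest),
            class = "mesolim_run")
}

#' Serialise a pipeline run to a result bundle
#'
#' Writes `qc_report.json` (per-criterion exclusion counts and outlier
#' totals), `limitation_fit.json`, `glm_table.csv`, `dunn_table.csv`,
#' `records.csv` and `manifest.json` into `dir`. Components not computed
#' in the run are skipped.
#'
#' @param run A `mesolim_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_bundle <- function(run, dir) {
  stopifnot(inherits(run, "mesolim_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(n_input = run$filter$n_input,
         n_retained = run$filter$n_retained,
         n_excluded_by = setNames(as.list(run$filter$report$n_excluded),
                                  run$filter$report$criterion),
         n_outliers_extreme = sum(run$outliers$flag_extreme),
         n_outliers_iqr = sum(run$outliers$flag_iqr)),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(run$limitation)) {
    jsonlite::write_json(
      list(a = run$limitation$a, b = run$limitation$b,
           r2 = run$limitation$r2, n = run$limitation$n,
           excluded_points = run$limitation$excluded_points),
      file.path(dir, "limitation_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$glm)) {
    readr::write_csv(tidy(run$glm), file.path(dir, "glm_table.csv"),
                     progress = FALSE)
  }
  if (!is.null(run$dunn)) {
    readr::write_csv(run$dunn, file.path(dir, "dunn_table.csv"),
                     progress = FALSE)
  }
  readr::write_csv(run$records, file.path(dir, "records.csv"), progress = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.mesolim_run <- function(x, ...) {
  cat("mesolim pipeline run\n")
  cat("  analysis rows:", x$manifest$n_analysis,
      "(", x$manifest$n_input, "in,", x$manifest$n_input - x$manifest$n_retained_filters,
      "filtered,", x$manifest$n_outliers, "outliers )\n")
  if (!is.null(x$limitation)) print(x$limitation)
  if (!is.null(x$glm)) print(x$glm)
  invisible(x)
}

#' Violin-style plot of gm,25 by plant functional type
#'
#' @param data Tibble with `gm_25` and `pft`.
#' @return A ggplot object (log-scaled y).
#' @export
plot_gm_by_pft <- function(data) {
  d <- filter(data, !is.na(.data$gm_25), .data$pft != "other")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pft, y = .data$gm_25)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression(g[m25] ~ (mol ~ m^-2 ~ s^-1))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
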