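# Fixtures built in code: a small raw-record table and CSV writers.

make_records <- function() {
  tibble::tibble(
    study_id = c("s1", "s1", "s2"),
    species = c("Triticum aestivum", "Quercus ilex", "Picea abies"),
    pft = c("C3_annual_herb", "evergreen_angiosperm", "evergreen_gymnosperm"),
    growth_form = c("herbaceous", "woody", "woody"),
    gm_value = c(0.30, 0.12, 0.08),
    gm_units = c("mol_m2_s", "mol_m2_s_bar", "umol_m2_s_Pa"),
    method = c("isotope", "fluorescence", "curve_fitting"),
    T_meas = c(25, 28, 22),
    PPFD = c(1500, 1200, 1000),
    CO2_meas = c(400, 400, 400),
    pressure = c(100, NA, NA),
    elevation = c(NA, 500, NA),
    already_standardised = c(FALSE, FALSE, FALSE),
    An = c(24, 10, 6),
    gs_c = c(0.4, 0.15, 0.1),
    Ci = c(290, 260, 270),
    Ca = c(400, 400, 400),
    Anp = c(30, 13, 8),
    Sc = c(25, 12, 8),
    Tcw = c(0.12, 0.30, 0.40)
  )
}

write_records_csv <- function(data = make_records(), path = tempfile(fileext = ".csv")) {
  readr::write_csv(data, path, na = "")
  path
}

# Independent brute-force oracle for the log-scale IQR fence screen:
# type-7 quartiles computed from first principles, each value checked
# against the fences one by one.
brute_force_iqr_flags <- function(values, k = 1.5) {
  lg <- log(values)
  n <- length(lg)
  s <- sort(lg)
  q_type7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- q_type7(0.25); q3 <- q_type7(0.75)
  iqr <- q3 - q1
  vapply(lg, function(v) v < q1 - k * iqr || v > q3 + k * iqr, logical(1))
}
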