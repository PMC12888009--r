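#' Read / write the pipeline's CSV tables
#'
#' All tables use the same dialect: comma separator, '.' decimal, UTF-8,
#' mandatory header. Readers validate the required columns and report
#' the offending file in errors; writers emit values at full precision
#' so a write-then-read round trip is the identity.
#'
#' @param path file path.
#' @return The validated data.frame.
#' @name venomics_io
NULL

.read_csv <- function(path, cols, what) {
  if (!file.exists(path)) .fail("%s file not found: %s", what, path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) .fail("cannot read %s '%s': %s", what,
                                           path, conditionMessage(e)))
  if (nrow(df) == 0) .fail("%s '%s' contains no rows", what, path)
  .check_columns(df, cols, sprintf("%s '%s'", what, path))
  df
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname venomics_io
#' @export
read_peak_table <- function(path)
  .read_csv(path, c("fraction_id", "retention_time_min", "area", "family"),
            "peak table")

#' @param peaks peak table data.frame.
#' @rdname venomics_io
#' @export
write_peak_table <- function(peaks, path) .write_csv(peaks, path)

#' @rdname venomics_io
#' @export
read_antivenomics_table <- function(path)
  .read_csv(path, c("toxin_id", "venom_amount_ug", "retained_area",
                    "nonretained_area"), "antivenomics table")

#' @param series antivenomics dose-series data.frame.
#' @rdname venomics_io
#' @export
write_antivenomics_table <- function(series, path) .write_csv(series, path)

#' @rdname venomics_io
#' @export
read_dose_table <- function(path)
  .read_csv(path, c("dose", "n_subjects", "n_responders"), "dose table")

#' @param table dose-response data.frame.
#' @rdname venomics_io
#' @export
write_dose_table <- function(table, path) .write_csv(table, path)

#' @rdname venomics_io
#' @export
read_mhd_table <- function(path)
  .read_csv(path, c("dose_ug", "area_cm2"), "MHD table")

#' Composition analysis chain
#'
#' Reads (or accepts) a peak table, computes family-level mass
#' percentages, converts them to molar percentages with the registry
#' masses, and reports the SVMPi:(PI+PIII)-SVMP molar ratio and the
#' compositional pattern. The result is deterministic.
#'
#' @param peaks path to a peak-table CSV or an equivalent data.frame.
#' @param species label carried into the report.
#' @param config analysis configuration, see [venomics_config()].
#' @param out optional path; when given, the report is also written as
#'   JSON.
#' @return List of class `composition_report` with `species`,
#'   `mass_percent`, `molar_percent`, `unassigned_percent`,
#'   `svmpi_svmp_ratio`, `pattern`.
#' @export
run_chain_composition <- function(peaks, species = "venom",
                                  config = venomics_config(), out = NULL) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  mass <- relative_abundance(peaks)
  unassigned <- if ("unassigned" %in% names(mass))
    mass[["unassigned"]] else 0
  mass <- mass[setdiff(names(mass), "unassigned")]
  masses <- unlist(config$families)
  known <- intersect(names(mass), names(masses))
  comp <- venom_composition(species, mass[known],
                            data.frame(family = names(masses),
                                       mass_da = unname(masses)))
  ratio <- if ("SVMPi" %in% comp$families &&
               any(c("PI-SVMP", "PIII-SVMP") %in% comp$families))
    molar_ratio(comp, "SVMPi", c("PI-SVMP", "PIII-SVMP")) else NA_real_
  rep <- structure(list(
    species = species,
    mass_percent = mass,
    molar_percent = comp$molar_percent,
    unassigned_percent = unassigned,
    svmpi_svmp_ratio = ratio,
    pattern = classify_dichotomy(comp, config$dichotomy)
  ), class = "composition_report")
  if (!is.null(out)) .write_report_json(rep, out)
  rep
}

#' Antivenom characterization chain
#'
#' Ties the antivenomics and neutralization stages together: runs the
#' 3GA binding analysis on an immunocapture dose series, fits the
#' neutralization dose-response by probit to get the ED50, and derives
#' potency, percentage of neutralizing antibodies and vials per bite.
#'
#' @param series antivenomics CSV path or data.frame
#'   (see [read_antivenomics_table()]).
#' @param dose_table neutralization dose table CSV path or data.frame,
#'   doses in mg venom / g antivenom.
#' @param toxin_shares named numeric vector of proteome shares (%).
#' @param venom_yield_mg average venom yield of a bite (mg), optional.
#' @param config analysis configuration.
#' @param out optional path for a JSON report.
#' @return List of class `antivenom_report` combining the
#'   [analyze_binding_series()] output with the [potency_report()]
#'   fields.
#' @export
run_chain_antivenom <- function(series, dose_table, toxin_shares,
                                venom_yield_mg = NA,
                                config = venomics_config(), out = NULL) {
  if (is.character(series)) series <- read_antivenomics_table(series)
  if (is.character(dose_table)) dose_table <- read_dose_table(dose_table)
  binding <- analyze_binding_series(series, toxin_shares, config)
  fit <- probit_fit(dose_table)
  pot <- potency_report(fit$median, binding$maxbind_mg_g, venom_yield_mg,
                        ed50_ci = fit$ci95, config = config)
  rep <- structure(c(list(binding = binding, probit = fit), pot),
                   class = "antivenom_report")
  if (!is.null(out)) .write_report_json(rep, out)
  rep
}

# serialize a report to JSON (classes dropped; numbers at full precision)
.write_report_json <- function(rep, path) {
  jsonlite::write_json(rapply(unclass(rep), unclass, how = "replace"),
                       path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
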