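#' Default analysis configuration
#'
#' Central place for the constants the analysis chains use: the
#' toxin-family molecular-mass registry, the antivenom constants
#' (7 mg F(ab')2 per immunoaffinity column, 46.45 g F(ab')2 per litre of
#' antivenom, 0.4645 g F(ab')2 per 10 mL vial), the lethality challenge
#' of 5 LD50s used in neutralization assays, the compositional-pattern
#' thresholds, and the decimal precisions used when rendering reports
#' against published tables.
#'
#' @return A list of class `venomics_config`.
#' @export
venomics_config <- function() {
  structure(list(
    families = as.list(family_masses()),
    antivenom = list(mass_on_column_mg = 7,
                     fab2_g_per_L = 46.45,
                     fab2_g_per_vial = 0.4645),
    challenge_n = 5,
    dichotomy = list(k49_negligible = 0.05,
                     ratio_high = 1.5,
                     ratio_low = 0.67,
                     piii_low = 0.3),
    rounding = list(molar = 3, capacity = 2, potency = 1, vials = 1)
  ), class = "venomics_config")
}

.validate_config <- function(cfg) {
  bad <- character(0)
  fams <- unlist(cfg$families)
  if (!is.numeric(fams) || any(fams <= 0)) bad <- c(bad, "families")
  for (k in c("mass_on_column_mg", "fab2_g_per_L", "fab2_g_per_vial")) {
    v <- cfg$antivenom[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      bad <- c(bad, paste0("antivenom$", k))
  }
  if (!is.numeric(cfg$challenge_n) || cfg$challenge_n <= 1)
    bad <- c(bad, "challenge_n")
  for (k in c("k49_negligible", "ratio_high", "ratio_low", "piii_low")) {
    v <- cfg$dichotomy[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      bad <- c(bad, paste0("dichotomy$", k))
  }
  if (length(bad))
    .fail("invalid configuration value(s): %s", paste(bad, collapse = ", "))
  cfg
}

#' Load an analysis configuration from JSON
#'
#' Reads a JSON configuration file and merges it over the defaults of
#' [venomics_config()]: an empty file yields the full defaults, known
#' keys override them, unknown top-level keys produce a warning (not an
#' error) and are kept. Values are schema-checked; offending keys are
#' named in the error.
#'
#' @param path path to a JSON file.
#' @return A validated `venomics_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .fail("configuration file not found: %s", path)
  user <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                   error = function(e)
                     .fail("cannot parse '%s' as JSON: %s", path,
                           conditionMessage(e)))
  if (is.null(user)) user <- list()
  if (!is.list(user)) .fail("configuration root must be a JSON object")
  cfg <- venomics_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("unknown configuration key(s) kept as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  merged <- utils::modifyList(unclass(cfg), user)
  .validate_config(structure(merged, class = "venomics_config"))
}
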