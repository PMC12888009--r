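#' Percentage of a toxin fraction retained on the antivenom column
#'
#' The immunoretention of one RP-HPLC toxin fraction, computed from the
#' chromatographic areas of the material recovered in the retained (Ri)
#' and nonretained (NRi) immunoaffinity fractions:
#' `%Ri = 100 * Ri / (Ri + NRi)`.
#'
#' @param retained,nonretained chromatographic areas (>= 0, not both 0).
#' @return Retained percentage in \[0, 100\]. Vectorized.
#' @export
retained_fraction <- function(retained, nonretained) {
  .check_numeric(retained, "retained", 0)
  .check_numeric(nonretained, "nonretained", 0)
  tot <- retained + nonretained
  if (any(tot <= 0)) .fail("Ri + NRi must be > 0")
  100 * retained / tot
}

#' Subtract nonspecific (control-column) retention
#'
#' Corrects a retained percentage for the nonspecific signal observed on
#' a mock or naive-IgG control column by simple subtraction, floored at
#' zero.
#'
#' @param percent_retained,control_retained percentages in \[0, 100\].
#' @return Corrected retained percentage. Vectorized.
#' @export
control_correct <- function(percent_retained, control_retained) {
  .check_numeric(percent_retained, "percent_retained", 0)
  .check_numeric(control_retained, "control_retained", 0)
  if (any(percent_retained > 100) || any(control_retained > 100))
    .fail("percentages must lie in [0, 100]")
  pmax(0, percent_retained - control_retained)
}

#' Mass of one toxin immunocaptured at one venom dose
#'
#' `captured = (%Ri/100) * (toxin share of the proteome/100) * venom dose`,
#' in the units of `venom_amount` (micrograms throughout the package).
#'
#' @param percent_retained retained percentage of the toxin (\[0, 100\]).
#' @param toxin_share the toxin's share of the venom proteome (%).
#' @param venom_amount total venom incubated on the column (ug).
#' @return Captured toxin mass (ug). Vectorized.
#' @export
immunocaptured_mass <- function(percent_retained, toxin_share, venom_amount) {
  .check_numeric(percent_retained, "percent_retained", 0)
  .check_numeric(toxin_share, "toxin_share", 0)
  .check_numeric(venom_amount, "venom_amount", 0)
  if (any(percent_retained > 100) || any(toxin_share > 100))
    .fail("percentages must lie in [0, 100]")
  (percent_retained / 100) * (toxin_share / 100) * venom_amount
}

#' Saturation maximum of an immunocapture dose series
#'
#' Fits captured mass versus venom dose with a least-squares quadratic
#' `y = a x^2 + b x + c` and, when the parabola opens downward with its
#' vertex inside `(0, 2 * max(dose)]`, reports the vertex value as the
#' modeled binding maximum. Outside that supported domain, or when the
#' curve shows no saturation (`a >= 0`), the largest observed captured
#' mass is reported instead and the series is flagged unsaturated.
#'
#' @param venom_amount venom doses (ug), at least 3 distinct values.
#' @param captured captured toxin mass at each dose (ug).
#' @return List with `max_ug` (modeled maximum, >= 0), `raw_max_ug`
#'   (largest observed), `saturated` (logical), `vertex_x` (dose at the
#'   modeled maximum, NA when unsaturated) and `coefficients` (c, b, a).
#' @examples
#' x <- 0:3
#' fit_saturation(x, -x^2 + 4 * x)   # vertex at x = 2, maximum 4
#' @export
fit_saturation <- function(venom_amount, captured) {
  .check_numeric(venom_amount, "venom_amount", 0)
  .check_numeric(captured, "captured", 0)
  if (length(venom_amount) != length(captured))
    .fail("'venom_amount' and 'captured' must have the same length")
  if (length(unique(venom_amount)) < 3)
    .fail("saturation fit needs at least 3 distinct venom amounts")
  raw_max <- max(captured)
  if (diff(range(captured)) == 0) {
    return(list(max_ug = raw_max, raw_max_ug = raw_max, saturated = TRUE,
                vertex_x = NA_real_,
                coefficients = c(raw_max, 0, 0)))
  }
  fit <- stats::lm(captured ~ venom_amount + I(venom_amount^2))
  cf <- unname(stats::coef(fit))          # c, b, a
  a <- cf[3]; b <- cf[2]; cc <- cf[1]
  if (a < 0) {
    vx <- -b / (2 * a)
    if (vx > 0 && vx <= 2 * max(venom_amount)) {
      return(list(max_ug = max(a * vx^2 + b * vx + cc, 0),
                  raw_max_ug = raw_max, saturated = TRUE, vertex_x = vx,
                  coefficients = cf))
    }
  }
  list(max_ug = raw_max, raw_max_ug = raw_max, saturated = FALSE,
       vertex_x = NA_real_, coefficients = cf)
}

#' Antivenom maximal venom-binding capacity
#'
#' The sum of the per-toxin saturation maxima, expressed per gram of
#' immobilized antivenom: `sum(maxima ug) / antivenom mg` is numerically
#' mg venom per g antivenom.
#'
#' @param per_toxin_max_ug numeric vector of per-toxin maxima (ug).
#' @param antivenom_mg antivenom mass on the column (mg, > 0;
#'   the study design uses 7 mg).
#' @return MaxBind in mg venom / g antivenom.
#' @export
max_binding_capacity <- function(per_toxin_max_ug, antivenom_mg = 7) {
  if (length(per_toxin_max_ug)) {
    .check_numeric(per_toxin_max_ug, "per_toxin_max_ug", 0)
  }
  .check_numeric(antivenom_mg, "antivenom_mg", 0, strict_min = TRUE)
  sum(per_toxin_max_ug) / antivenom_mg
}

#' Convert binding capacity to per-volume and per-vial units
#'
#' @param max_bind MaxBind in mg venom / g antivenom.
#' @param fab2_g_per_L antivenom F(ab')2 concentration (g/L).
#' @param fab2_g_per_vial grams of F(ab')2 per vial.
#' @return List with `mg_per_ml` (mg venom bound per mL antivenom) and
#'   `mg_per_vial` (mg venom bound per vial).
#' @examples
#' capacity_units(165.67, 46.45, 0.4645)  # 7.70 mg/mL
#' @export
capacity_units <- function(max_bind, fab2_g_per_L = 46.45,
                           fab2_g_per_vial = 0.4645) {
  .check_numeric(max_bind, "max_bind", 0)
  .check_numeric(fab2_g_per_L, "fab2_g_per_L", 0, strict_min = TRUE)
  .check_numeric(fab2_g_per_vial, "fab2_g_per_vial", 0, strict_min = TRUE)
  list(mg_per_ml = max_bind * fab2_g_per_L / 1000,
       mg_per_vial = max_bind * fab2_g_per_vial)
}

#' Coupled-antivenom concentration from A280 depletion
#'
#' Protein concentration coupled to the affinity matrix, estimated
#' spectrophotometrically from the drop in absorbance at 280 nm before
#' and after coupling, using the 0.1% extinction coefficient
#' (1.36 (mg/mL)^-1 cm^-1 for F(ab')2 in a 1 cm cuvette).
#'
#' @param a280_before,a280_after absorbance units, `before >= after >= 0`.
#' @param volume_ratio dilution/volume correction factor (default 1).
#' @param extinction extinction coefficient in (mg/mL)^-1 cm^-1.
#' @return Coupled protein concentration, mg/mL.
#' @export
coupled_concentration <- function(a280_before, a280_after,
                                  volume_ratio = 1, extinction = 1.36) {
  .check_numeric(a280_before, "a280_before", 0)
  .check_numeric(a280_after, "a280_after", 0)
  .check_numeric(extinction, "extinction", 0, strict_min = TRUE)
  if (any(a280_after > a280_before))
    .fail("a280_after exceeds a280_before")
  (a280_before - a280_after) * volume_ratio / extinction
}

#' Full immunoaffinity (3GA) binding analysis
#'
#' Runs the complete third-generation antivenomics quantification on a
#' long-format dose series: per toxin and dose, the retained percentage
#' (optionally control-corrected), the immunocaptured mass, a quadratic
#' saturation fit, and the column-level maximal binding capacity with
#' unit conversions. Toxins with fewer than 3 usable doses fall back to
#' their largest observed captured mass and are flagged unsaturated.
#'
#' @param series data.frame with columns `toxin_id`, `venom_amount_ug`,
#'   `retained_area`, `nonretained_area` and optionally
#'   `control_retained_pct` (default 0).
#' @param toxin_shares named numeric vector: each toxin's share of the
#'   venom proteome (%), names matching `toxin_id`.
#' @param config analysis configuration, see [venomics_config()].
#' @param apply_control logical; subtract the control-column retention
#'   before the capture calculation (default TRUE).
#' @return List of class `binding_report`: `per_toxin` data.frame
#'   (`toxin_id`, `max_ug`, `raw_max_ug`, `saturated`, `n_doses`),
#'   `retention` data.frame (per toxin x dose `%R`), `maxbind_mg_g`,
#'   `mg_per_ml`, `mg_per_vial`.
#' @export
analyze_binding_series <- function(series, toxin_shares,
                                   config = venomics_config(),
                                   apply_control = TRUE) {
  .check_columns(series, c("toxin_id", "venom_amount_ug", "retained_area",
                           "nonretained_area"), "antivenomics series")
  if (!"control_retained_pct" %in% names(series))
    series$control_retained_pct <- 0
  ids <- unique(as.character(series$toxin_id))
  miss <- setdiff(ids, names(toxin_shares))
  if (length(miss))
    .fail("no proteome share for toxin(s): %s", paste(miss, collapse = ", "))

  pct <- retained_fraction(series$retained_area, series$nonretained_area)
  if (apply_control)
    pct <- control_correct(pct, series$control_retained_pct)
  captured <- immunocaptured_mass(
    pct, toxin_shares[as.character(series$toxin_id)],
    series$venom_amount_ug)

  per <- lapply(ids, function(id) {
    sel <- as.character(series$toxin_id) == id
    x <- series$venom_amount_ug[sel]
    if (is.unsorted(x, strictly = TRUE))
      .fail("venom amounts must be strictly increasing for toxin '%s'", id)
    y <- captured[sel]
    if (length(unique(x)) >= 3) {
      f <- fit_saturation(x, y)
      data.frame(toxin_id = id, max_ug = f$max_ug, raw_max_ug = f$raw_max_ug,
                 saturated = f$saturated, n_doses = length(x),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(toxin_id = id, max_ug = max(y), raw_max_ug = max(y),
                 saturated = FALSE, n_doses = length(x),
                 stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, per)

  maxbind <- max_binding_capacity(per$max_ug,
                                  config$antivenom$mass_on_column_mg)
  units <- capacity_units(maxbind, config$antivenom$fab2_g_per_L,
                          config$antivenom$fab2_g_per_vial)
  structure(list(
    per_toxin = per,
    retention = data.frame(toxin_id = series$toxin_id,
                           venom_amount_ug = series$venom_amount_ug,
                           percent_retained = pct,
                           captured_ug = captured,
                           stringsAsFactors = FALSE),
    maxbind_mg_g = maxbind,
    mg_per_ml = units$mg_per_ml,
    mg_per_vial = units$mg_per_vial
  ), class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat(sprintf("3GA binding report: %d toxin fractions\n", nrow(x$per_toxin)))
  cat(sprintf("MaxBind: %.2f mg venom/g antivenom (%.2f mg/mL, %.2f mg/vial)\n",
              x$maxbind_mg_g, x$mg_per_ml, x$mg_per_vial))
  invisible(x)
}
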