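#' Probit fit of a quantal dose-response table
#'
#' Maximum-likelihood binomial regression with a probit link on the
#' log10 dose, the classical Finney analysis for quantal toxicology
#' assays (LD50) and neutralization assays (ED50). The median dose is
#' `10^(-intercept/slope)`; its 95% confidence interval is obtained by
#' the delta method on the log10 scale. When the table is completely
#' separated (all-or-nothing responses with fewer than two partially
#' responding dose groups) the likelihood has no finite maximum; the
#' median is then reported as the geometric mean of the doses bracketing
#' the 50% response and `converged` is FALSE.
#'
#' @param table data.frame with columns `dose` (> 0), `n_subjects`
#'   (> 0) and `n_responders` (0..n_subjects); at least 2 distinct doses
#'   and not all responses 0 or all complete.
#' @return An object of class `probit_fit`: list with `slope`,
#'   `intercept` (on log10 dose), `median` (LD50/ED50 in dose units),
#'   `ci95` (lower, upper), `se_log10` , `loglik`, `converged`.
#' @examples
#' tab <- data.frame(dose = c(25, 50, 100, 200),
#'                   n_subjects = 10, n_responders = c(1, 4, 7, 10))
#' probit_fit(tab)
#' @export
probit_fit <- function(table) {
  .check_columns(table, c("dose", "n_subjects", "n_responders"),
                 "dose-response table")
  .check_numeric(table$dose, "dose", 0, strict_min = TRUE)
  .check_numeric(table$n_subjects, "n_subjects", 0, strict_min = TRUE)
  .check_numeric(table$n_responders, "n_responders", 0)
  if (any(table$n_responders > table$n_subjects))
    .fail("n_responders cannot exceed n_subjects")
  if (length(unique(table$dose)) < 2)
    .fail("at least 2 distinct doses are required")
  if (all(table$n_responders == 0) ||
      all(table$n_responders == table$n_subjects))
    .fail("responses are all zero or all complete; no median is estimable")

  p <- table$n_responders / table$n_subjects
  informative <- p > 0 & p < 1
  if (sum(informative) < 2 && .is_separated(table$dose, p)) {
    med <- .bracket_median(table$dose, p)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          median = med, ci95 = c(NA_real_, NA_real_),
                          se_log10 = NA_real_, loglik = NA_real_,
                          converged = FALSE),
                     class = "probit_fit"))
  }

  ld <- log10(table$dose)
  fit <- suppressWarnings(stats::glm(
    cbind(table$n_responders, table$n_subjects - table$n_responders) ~ ld,
    family = stats::binomial(link = "probit")))
  b <- unname(stats::coef(fit))             # intercept, slope
  if (!fit$converged || !is.finite(b[2]) || b[2] <= 0 || abs(b[2]) > 1e3) {
    med <- .bracket_median(table$dose, p)
    return(structure(list(slope = b[2], intercept = b[1], median = med,
                          ci95 = c(NA_real_, NA_real_),
                          se_log10 = NA_real_,
                          loglik = as.numeric(stats::logLik(fit)),
                          converged = FALSE),
                     class = "probit_fit"))
  }
  g <- -b[1] / b[2]                          # log10 median
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  v <- as.numeric(t(grad) %*% stats::vcov(fit) %*% grad)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(0.975)
  structure(list(slope = b[2], intercept = b[1], median = 10^g,
                 ci95 = 10^(g + c(-1, 1) * z * se), se_log10 = se,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = TRUE),
            class = "probit_fit")
}

# monotone step pattern: every all-0 dose below every all-1 dose
.is_separated <- function(dose, p) {
  lo <- dose[p == 0]; hi <- dose[p == 1]
  (length(lo) == 0 || length(hi) == 0 || max(lo) < min(hi))
}

# geometric mean of doses bracketing the 50% response
.bracket_median <- function(dose, p) {
  if (any(p == 0.5)) return(exp(mean(log(dose[p == 0.5]))))
  lo <- dose[p < 0.5]; hi <- dose[p > 0.5]
  if (length(lo) == 0) return(min(hi))
  if (length(hi) == 0) return(max(lo))
  sqrt(max(lo) * min(hi))
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit: median %.4g (95%% CI %.4g-%.4g), slope %.3g%s\n",
              x$median, x$ci95[1], x$ci95[2], x$slope,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Antivenom potency from the median effective dose
#'
#' In a neutralization assay the venom challenge is `n` LD50s and, at
#' the assay endpoint, one LD50 remains unneutralized (it kills 50% of
#' the animals), so only `n - 1` of the `n` LD50s are actually
#' neutralized: `P = ED50 * (n - 1) / n`, in the same venom-per-antivenom
#' units as the ED50 (mg venom / g antivenom). Applied elementwise, so
#' confidence bounds propagate unchanged.
#'
#' @param ed50 median effective dose (mg venom / g antivenom), > 0.
#' @param n_challenge number of LD50s in the challenge (> 1; the study
#'   design uses 5).
#' @return Potency in mg venom / g antivenom.
#' @examples
#' potency_from_ed50(281.4, 5)   # 225.1
#' @export
potency_from_ed50 <- function(ed50, n_challenge = 5) {
  .check_numeric(ed50, "ed50", 0, strict_min = TRUE)
  if (!is.numeric(n_challenge) || length(n_challenge) != 1 ||
      n_challenge <= 1)
    .fail("'n_challenge' must be a single number > 1")
  ed50 * (n_challenge - 1) / n_challenge
}

#' Potency from LD50 and the antivenom volume at the ED50 endpoint
#'
#' Equivalent entry point when the ED50 is expressed as antivenom amount
#' per LD50 challenge: `P = (n - 1) / ED50 * LD50`.
#'
#' @param ld50 median lethal dose (venom mass units).
#' @param ed50_av antivenom amount at which 50% of animals survive the
#'   `n`-LD50 challenge (antivenom units per challenge).
#' @param n_challenge number of LD50s in the challenge (> 1).
#' @return Potency in venom units per antivenom unit.
#' @export
potency_from_ld50 <- function(ld50, ed50_av, n_challenge = 5) {
  .check_numeric(ld50, "ld50", 0, strict_min = TRUE)
  .check_numeric(ed50_av, "ed50_av", 0, strict_min = TRUE)
  if (!is.numeric(n_challenge) || length(n_challenge) != 1 ||
      n_challenge <= 1)
    .fail("'n_challenge' must be a single number > 1")
  (n_challenge - 1) / ed50_av * ld50
}

#' Percentage of antitoxin antibodies that neutralize
#'
#' The ratio of neutralization potency to maximal binding capacity,
#' `100 * P / MaxBind`. Values above 100% arise when neutralizing a
#' subset of the toxins already abrogates the venom's lethality.
#'
#' @param potency potency (mg venom / g antivenom).
#' @param max_bind maximal binding capacity (mg venom / g antivenom, > 0).
#' @return Percentage of neutralizing antibodies.
#' @examples
#' percent_neutralizing(114.7, 93.08)  # 123.23
#' @export
percent_neutralizing <- function(potency, max_bind) {
  .check_numeric(potency, "potency", 0)
  .check_numeric(max_bind, "max_bind", 0, strict_min = TRUE)
  100 * potency / max_bind
}

#' Antivenom vials needed to neutralize one bite's venom yield
#'
#' One vial contains `fab2_g_per_vial` grams of F(ab')2 and neutralizes
#' `potency * fab2_g_per_vial` mg of venom.
#'
#' @param venom_yield_mg average venom yield of a bite (mg, > 0).
#' @param potency antivenom potency (mg venom / g antivenom, > 0).
#' @param fab2_g_per_vial grams of F(ab')2 per vial (> 0).
#' @return Number of vials (unrounded; round to 1 decimal for display).
#' @examples
#' vials_per_bite(88.5, 114.7, 0.4645)   # 1.7
#' @export
vials_per_bite <- function(venom_yield_mg, potency,
                           fab2_g_per_vial = 0.4645) {
  .check_numeric(venom_yield_mg, "venom_yield_mg", 0, strict_min = TRUE)
  .check_numeric(potency, "potency", 0, strict_min = TRUE)
  .check_numeric(fab2_g_per_vial, "fab2_g_per_vial", 0, strict_min = TRUE)
  venom_yield_mg / (potency * fab2_g_per_vial)
}

#' Minimum hemorrhagic dose from a dose-area table
#'
#' Hemorrhagic spot area grows linearly with log10 dose over the assay
#' range, so the MHD (dose producing a 1 cm^2 spot) is obtained by
#' least-squares regression of area on log10(dose), inverted at
#' area = 1. With exactly two points this reduces to log-linear
#' interpolation between them.
#'
#' @param table data.frame with columns `dose_ug` (> 0) and `area_cm2`.
#' @return List with `mhd_ug`, `slope`, `intercept` and `extrapolated`
#'   (TRUE when 1 cm^2 lies outside the observed area range).
#' @examples
#' mhd(data.frame(dose_ug = c(1, 10), area_cm2 = c(0.5, 1.5)))
#' @export
mhd <- function(table) {
  .check_columns(table, c("dose_ug", "area_cm2"), "MHD table")
  .check_numeric(table$dose_ug, "dose_ug", 0, strict_min = TRUE)
  .check_numeric(table$area_cm2, "area_cm2")
  if (nrow(table) < 2) .fail("at least 2 dose-area points are required")
  if (diff(range(table$area_cm2)) == 0 && table$area_cm2[1] != 1)
    .fail("hemorrhagic area does not vary with dose; MHD undefined")
  fit <- stats::lm(area_cm2 ~ log10(dose_ug), data = table)
  b <- unname(stats::coef(fit))
  if (abs(b[2]) < .Machine$double.eps^0.5)
    .fail("flat dose-response; MHD undefined")
  list(mhd_ug = 10^((1 - b[1]) / b[2]), slope = b[2], intercept = b[1],
       extrapolated = !(min(table$area_cm2) <= 1 &&
                          max(table$area_cm2) >= 1))
}

#' Edema as percentage increase in paw thickness
#'
#' @param test_mm venom-injected paw thickness per timepoint (mm).
#' @param control_mm contralateral saline paw thickness, same timepoints
#'   (mm, > 0).
#' @return Percentage increase per timepoint; negative differences are
#'   reported as negative percentages, not clamped.
#' @export
edema_percent <- function(test_mm, control_mm) {
  if (length(test_mm) != length(control_mm))
    .fail("test and control series must have the same timepoints")
  .check_numeric(test_mm, "test_mm", 0)
  .check_numeric(control_mm, "control_mm", 0, strict_min = TRUE)
  100 * (test_mm - control_mm) / control_mm
}

#' Collagenolytic (azocoll) specific activity
#'
#' One unit is the venom amount causing an increase of 0.003 absorbance
#' units at 540 nm; specific activity is U/min/mg venom.
#'
#' @param delta_a540 absorbance increase at 540 nm (AU, >= 0).
#' @param minutes incubation time (> 0).
#' @param venom_mg venom mass (mg, > 0).
#' @return Specific activity, U/min/mg.
#' @export
azocoll_activity <- function(delta_a540, minutes, venom_mg) {
  .check_numeric(delta_a540, "delta_a540", 0)
  .check_numeric(minutes, "minutes", 0, strict_min = TRUE)
  .check_numeric(venom_mg, "venom_mg", 0, strict_min = TRUE)
  (delta_a540 / 0.003) / minutes / venom_mg
}

#' Phospholipase A2 specific activity on 4-NOBA
#'
#' A change of 0.01 absorbance units at 425 nm corresponds to 25.8 nmol
#' of released chromophore; specific activity is nmol/min/mg venom.
#'
#' @param delta_a425 absorbance increase at 425 nm (AU, >= 0).
#' @param minutes incubation time (> 0).
#' @param venom_mg venom mass (mg, > 0).
#' @return Specific activity, nmol/min/mg.
#' @export
pla2_activity <- function(delta_a425, minutes, venom_mg) {
  .check_numeric(delta_a425, "delta_a425", 0)
  .check_numeric(minutes, "minutes", 0, strict_min = TRUE)
  .check_numeric(venom_mg, "venom_mg", 0, strict_min = TRUE)
  (delta_a425 / 0.01) * 25.8 / minutes / venom_mg
}

#' Potency, neutralizing-antibody and dosing report
#'
#' The dosing algebra that links an ED50 (with optional confidence
#' bounds) and a maximal binding capacity into potency, percentage of
#' neutralizing antibodies and vials per bite.
#'
#' @param ed50 median effective dose (mg venom / g antivenom).
#' @param max_bind maximal binding capacity (mg venom / g antivenom),
#'   or NA to skip the neutralizing-antibody percentage.
#' @param venom_yield_mg average venom yield per bite (mg), or NA to
#'   skip the vials estimate.
#' @param ed50_ci optional length-2 ED50 confidence bounds.
#' @param config analysis configuration, see [venomics_config()].
#' @return List with `ed50`, `ed50_ci`, `potency`, `potency_ci`,
#'   `percent_neutralizing`, `vials_per_bite`, `n_challenge`.
#' @examples
#' potency_report(143.4, 93.08, 88.5, ed50_ci = c(115.7, 188.6))
#' @export
potency_report <- function(ed50, max_bind = NA, venom_yield_mg = NA,
                           ed50_ci = NULL, config = venomics_config()) {
  n <- config$challenge_n
  pot <- potency_from_ed50(ed50, n)
  pot_ci <- if (!is.null(ed50_ci)) potency_from_ed50(ed50_ci, n) else
    c(NA_real_, NA_real_)
  list(ed50 = ed50,
       ed50_ci = if (is.null(ed50_ci)) c(NA_real_, NA_real_) else ed50_ci,
       potency = pot,
       potency_ci = pot_ci,
       percent_neutralizing = if (is.na(max_bind)) NA_real_ else
         percent_neutralizing(pot, max_bind),
       vials_per_bite = if (is.na(venom_yield_mg)) NA_real_ else
         vials_per_bite(venom_yield_mg, pot,
                        config$antivenom$fab2_g_per_vial),
       n_challenge = n)
}
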