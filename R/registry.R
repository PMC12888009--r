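#' Toxin-family registry with representative molecular masses
#'
#' The major toxin classes of *Bothrops* venoms together with the
#' representative molecular mass (in daltons) used to convert
#' mass-percentage abundances into molar abundances. The masses are the
#' class-representative values used for the *B. neuwiedi* clade venoms:
#' both phospholipase classes at 14 kDa, PI-SVMP at 23 kDa, PIII-SVMP at
#' 52 kDa, serine proteinases and C-type lectin-like proteins at 28 kDa,
#' disintegrins at 7.5 kDa, L-amino acid oxidase at 56 kDa, CRISP at
#' 23 kDa and the endogenous tripeptide SVMP inhibitor (pyroGlu-Xaa-Trp)
#' at 444.4 Da.
#'
#' @return A data.frame with columns `family` (character) and `mass_da`
#'   (numeric, Da).
#' @seealso [mass_to_molar()], [neuwiedi_clade_table()]
#' @export
toxin_families <- function() {
  data.frame(
    family = c("K49-PLA2", "D49-PLA2", "PI-SVMP", "PIII-SVMP", "SVSP",
               "DISI", "LAAO", "CTL", "CRISP", "SVMPi"),
    mass_da = c(1.40e4, 1.40e4, 2.30e4, 5.20e4, 2.80e4,
                7.50e3, 5.60e4, 2.80e4, 2.30e4, 444.4),
    stringsAsFactors = FALSE
  )
}

#' Family registry as a named vector
#'
#' @param registry data.frame with columns `family` and `mass_da`;
#'   defaults to [toxin_families()].
#' @return Named numeric vector of molecular masses (Da).
#' @export
family_masses <- function(registry = toxin_families()) {
  .check_columns(registry, c("family", "mass_da"), "family registry")
  if (anyDuplicated(registry$family))
    .fail("family names must be unique within a registry")
  .check_numeric(registry$mass_da, "mass_da", 0, strict_min = TRUE)
  stats::setNames(registry$mass_da, registry$family)
}

#' Published toxin-class abundances of the *B. neuwiedi* clade venoms
#'
#' Relative abundances of the major toxin classes in the seven
#' *Bothrops neuwiedi* clade venom pools, as mass percentage
#' (g per 100 g venom) and as the published molar percentage
#' (mmoles per 100 g venom). The molar column holds the values as
#' printed (3 decimals); they are reproduced in full precision by
#' `mass_to_molar(mass_percent, mass_da)` with the registry masses.
#' Classes absent from a venom (e.g. K49-PLA2 in *B. erythromelas*)
#' are omitted.
#'
#' @return A data.frame with columns `species`, `family`,
#'   `mass_percent` (g/100 g), `molar_percent` (published mmoles %).
#' @export
neuwiedi_clade_table <- function() {
  sp <- c("B. mattogrossensis", "B. diporus", "B. neuwiedi",
          "B. erythromelas", "B. pubescens", "B. pauloensis",
          "B. marmoratus")
  fam <- c("K49-PLA2", "D49-PLA2", "PI-SVMP", "PIII-SVMP", "SVSP",
           "DISI", "LAAO", "CTL", "CRISP", "SVMPi")
  # mass % (g/100 g), one column per species in `sp` order; NA = absent
  mass <- cbind(
    c(7.5,  6.4, 19.8, 28.8,  5.7, 3.2, 6.9, 2.5, 0.6,  12.8),
    c(34.3, 6.9, 10.7, 14.3,  6.3, 4.2, 4.4, 2.9, 1.2,  2.6),
    c(19.9, 10.3, 12.8, 9.7,  8.8, 3.3, 8.1, 2.4, 4.2,  8.39),
    c(NA,   26.5, 12.1, 24.0, 6.0, 3.4, 4.8, 8.0, 0.4,  6.5),
    c(32.6, 2.3,  12.2, 10.1, 13.5, 4.7, 3.9, NA, 5.00, 6.16),
    c(19.7, 15.9, 12.7, 9.3,  15.3, 2.4, 5.3, NA, 0.1,  7.77),
    c(10.7, 9.2,  18.1, 22.1, 16.1, 2.8, 3.8, NA, 2.8,  8.25)
  )
  # published mmoles % (3 d.p.), same layout
  molar <- cbind(
    c(0.536, 0.457, 0.861, 0.554, 0.204, 0.427, 0.123, 0.089, 0.026, 28.803),
    c(2.450, 0.493, 0.465, 0.275, 0.225, 0.560, 0.079, 0.104, 0.052, 5.851),
    c(1.421, 0.736, 0.557, 0.187, 0.314, 0.440, 0.145, 0.086, 0.183, 18.879),
    c(NA,    1.893, 0.526, 0.462, 0.214, 0.453, 0.086, 0.286, 0.017, 14.626),
    c(2.329, 0.164, 0.530, 0.194, 0.482, 0.627, 0.070, NA,    0.217, 13.861),
    c(1.407, 1.136, 0.552, 0.179, 0.546, 0.320, 0.095, NA,    0.004, 17.484),
    c(0.764, 0.657, 0.787, 0.425, 0.575, 0.373, 0.068, NA,    0.122, 18.564)
  )
  out <- data.frame(
    species = rep(sp, each = length(fam)),
    family = rep(fam, times = length(sp)),
    mass_percent = as.vector(mass),
    molar_percent = as.vector(molar),
    stringsAsFactors = FALSE
  )
  out[!is.na(out$mass_percent), , drop = FALSE]
}

#' Published neutralization and dosing summary for the clade venoms
#'
#' Median effective dose of the pentabothropic antivenom against a
#' five-LD50 venom challenge, with 95% confidence limits, the derived
#' potency, the antivenom maximal binding capacity (where measured),
#' the percentage of neutralizing antibodies, average venom yield per
#' bite and the resulting vials-per-bite estimate, as published.
#' `maxbind_mg_g` is NA for the species whose immunocapture series was
#' not measured in this study.
#'
#' @return A data.frame, one row per species.
#' @export
neuwiedi_neutralization_table <- function() {
  data.frame(
    species = c("B. mattogrossensis", "B. pauloensis", "B. pubescens",
                "B. diporus", "B. neuwiedi", "B. marmoratus",
                "B. erythromelas"),
    ed50 = c(143.4, 135.9, 129.5, 281.4, 210.4, 154.5, 161.8),
    ed50_lo = c(115.7, 111.3, 86.9, 228.8, 171.4, 114.6, 111.4),
    ed50_hi = c(188.6, 174.8, 180.9, 365.2, 272.4, 237.0, 295.8),
    potency = c(114.7, 108.8, 103.6, 225.1, 168.3, 123.6, 129.4),
    potency_lo = c(92.5, 89.0, 69.5, 183.1, 137.1, 91.7, 89.1),
    potency_hi = c(150.9, 139.9, 144.7, 292.1, 217.9, 189.6, 236.7),
    maxbind_mg_g = c(93.08, NA, 75.87, NA, 165.67, 102.9, NA),
    maxbind_mg_ml = c(4.32, NA, 3.52, NA, 7.70, 4.78, NA),
    pct_neutralizing = c(123.23, NA, 136.55, NA, 101.59, 120.12, NA),
    venom_yield_mg = c(88.5, 90.5, 36.5, 134.0, 61.3, 43.8, 36.3),
    vials_per_bite = c(1.7, 1.8, 0.8, 1.3, 0.8, 0.8, 0.6),
    stringsAsFactors = FALSE
  )
}
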