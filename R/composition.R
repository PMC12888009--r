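#' Integrate chromatographic peaks by the trapezoidal rule
#'
#' Computes baseline-subtracted peak areas from a sampled detector trace.
#' Each integration window is integrated by the trapezoid rule on
#' `signal - baseline`; a net-negative area (baseline above the signal)
#' is clamped to zero.
#'
#' @param time numeric vector of strictly increasing acquisition times
#'   (minutes).
#' @param signal numeric detector signal, same length as `time`.
#' @param bounds data.frame with columns `start`, `end` and optionally
#'   `baseline` (default 0) and `fraction_id` / `family` labels carried
#'   into the output. Windows must not overlap and must lie within the
#'   trace range.
#' @return A peak table data.frame with columns `fraction_id`,
#'   `retention_time_min` (signal-weighted apex position), `area`,
#'   `family` (label carried from `bounds`, else `"unassigned"`).
#' @examples
#' t <- seq(0, 2, 0.001)
#' integrate_peaks(t, pmax(0, 1 - abs(t - 1)),
#'                 data.frame(start = 0, end = 2))
#' @export
integrate_peaks <- function(time, signal, bounds) {
  if (length(time) < 2) .fail("trace must contain at least two samples")
  if (length(signal) != length(time))
    .fail("'time' and 'signal' must have the same length")
  .check_numeric(time, "time"); .check_numeric(signal, "signal")
  if (any(diff(time) <= 0)) .fail("times must be strictly increasing")
  .check_columns(bounds, c("start", "end"), "bounds")
  if (nrow(bounds) == 0) .fail("no integration bounds supplied")
  if (any(bounds$end <= bounds$start)) .fail("each bound needs end > start")
  if (any(bounds$start < time[1]) || any(bounds$end > time[length(time)]))
    .fail("bounds must lie within the trace time range")
  o <- order(bounds$start)
  if (any(bounds$start[o][-1] < bounds$end[o][-nrow(bounds)]))
    .fail("integration bounds overlap")
  baseline <- if ("baseline" %in% names(bounds)) bounds$baseline else 0
  baseline <- rep_len(baseline, nrow(bounds))
  fraction_id <- if ("fraction_id" %in% names(bounds)) bounds$fraction_id else
    sprintf("peak%02d", seq_len(nrow(bounds)))
  family <- if ("family" %in% names(bounds)) bounds$family else "unassigned"
  family <- rep_len(family, nrow(bounds))

  area <- numeric(nrow(bounds))
  apex <- numeric(nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    sel <- time >= bounds$start[i] & time <= bounds$end[i]
    if (sum(sel) < 2) .fail("bound %d covers fewer than two samples", i)
    tt <- time[sel]
    yy <- signal[sel] - baseline[i]
    a <- sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
    area[i] <- max(a, 0)
    apex[i] <- if (all(yy <= 0)) mean(tt) else sum(tt * pmax(yy, 0)) / sum(pmax(yy, 0))
  }
  data.frame(fraction_id = fraction_id, retention_time_min = apex,
             area = area, family = family, stringsAsFactors = FALSE)
}

#' Toxin-family relative abundance from a peak table
#'
#' Family-level mass percentages: the summed area of each family's peaks
#' relative to the total area of all venom protein peaks, times 100.
#' Peaks labelled `"unassigned"` enter the denominator and are reported
#' as their own bucket, so the output always sums to 100.
#'
#' @param peaks peak table data.frame with columns `area` and `family`.
#' @return Named numeric vector of mass percentages (g/100 g equivalent),
#'   one element per family (plus `unassigned` when present), summing
#'   to 100.
#' @export
relative_abundance <- function(peaks) {
  .check_columns(peaks, c("area", "family"), "peak table")
  .check_numeric(peaks$area, "area", 0)
  total <- sum(peaks$area)
  if (total <= 0) .fail("total peak area is zero")
  fam <- as.character(peaks$family)
  fam[is.na(fam) | fam == ""] <- "unassigned"
  out <- 100 * vapply(split(peaks$area, fam), sum, numeric(1)) / total
  # keep first-appearance order, unassigned last
  ord <- unique(fam)
  ord <- c(setdiff(ord, "unassigned"), intersect("unassigned", ord))
  out[ord]
}

#' Convert mass percentage to molar percentage
#'
#' Converts a toxin-class abundance in g per 100 g venom into mmoles per
#' 100 g venom using the class-representative molecular mass:
#' `molar = 1000 * mass_percent / mass_da`.
#'
#' @param mass_percent abundance in g/100 g venom (>= 0).
#' @param mass_da molecular mass in daltons (> 0). Vectors recycle.
#' @return Molar abundance in mmoles per 100 g venom.
#' @examples
#' mass_to_molar(12.8, 444.4)   # tripeptide SVMP inhibitor
#' @seealso [molar_to_mass()]
#' @export
mass_to_molar <- function(mass_percent, mass_da) {
  .check_numeric(mass_percent, "mass_percent", 0)
  .check_numeric(mass_da, "mass_da", 0, strict_min = TRUE)
  1000 * mass_percent / mass_da
}

#' Inverse of [mass_to_molar()]
#' @param molar_percent mmoles per 100 g venom (>= 0).
#' @param mass_da molecular mass in daltons (> 0).
#' @return Mass percentage in g/100 g venom.
#' @export
molar_to_mass <- function(molar_percent, mass_da) {
  .check_numeric(molar_percent, "molar_percent", 0)
  .check_numeric(mass_da, "mass_da", 0, strict_min = TRUE)
  molar_percent * mass_da / 1000
}

#' Venom composition container
#'
#' Builds a per-species composition holding family mass percentages and
#' the derived molar percentages. Mass percentages must be non-negative
#' and sum to at most 100 (small numerical tolerance).
#'
#' @param species species label.
#' @param mass_percent named numeric vector of g/100 g abundances, names
#'   are family labels present in the registry.
#' @param registry family registry data.frame (default [toxin_families()]).
#' @return An object of class `venom_composition`: list with `species`,
#'   `families`, `mass_percent`, `molar_percent` (mmoles/100 g).
#' @export
venom_composition <- function(species, mass_percent,
                              registry = toxin_families()) {
  if (is.null(names(mass_percent)) || any(names(mass_percent) == ""))
    .fail("'mass_percent' must be a named vector of family abundances")
  .check_numeric(mass_percent, "mass_percent", 0)
  if (sum(mass_percent) > 100 + 1e-6)
    .fail("mass percentages sum to %.3f > 100", sum(mass_percent))
  masses <- family_masses(registry)
  unknown <- setdiff(names(mass_percent), names(masses))
  if (length(unknown))
    .fail("families not in registry: %s", paste(unknown, collapse = ", "))
  structure(list(
    species = species,
    families = names(mass_percent),
    mass_percent = mass_percent,
    molar_percent = mass_to_molar(mass_percent, masses[names(mass_percent)])
  ), class = "venom_composition")
}

#' @export
print.venom_composition <- function(x, ...) {
  cat("Venom composition:", x$species, "\n")
  print(data.frame(family = x$families,
                   mass_percent = unname(x$mass_percent),
                   molar_percent = unname(x$molar_percent)))
  invisible(x)
}

#' Composition of a clade species from the published table
#'
#' @param species one of the species labels in [neuwiedi_clade_table()].
#' @return A [venom_composition()] built from the published mass
#'   percentages (molar values recomputed in full precision).
#' @export
clade_composition <- function(species) {
  tab <- neuwiedi_clade_table()
  tab <- tab[tab$species == species, , drop = FALSE]
  if (nrow(tab) == 0)
    .fail("unknown species '%s'; see neuwiedi_clade_table()", species)
  venom_composition(species,
                    stats::setNames(tab$mass_percent, tab$family))
}

.molar_of <- function(composition, families, allow_missing = FALSE) {
  stopifnot(inherits(composition, "venom_composition"))
  present <- families %in% composition$families
  if (!allow_missing && !all(present))
    .fail("families absent from composition: %s",
          paste(families[!present], collapse = ", "))
  sum(composition$molar_percent[families[present]])
}

#' Molar ratio between two family sets
#'
#' Ratio of the summed molar abundances of a numerator family set to a
#' denominator family set, e.g. the SVMPi : (PI+PIII)-SVMP ratio that
#' characterizes how much endogenous tripeptide inhibitor a venom stores
#' per metalloproteinase molecule.
#'
#' @param composition a [venom_composition()].
#' @param numerator,denominator character vectors of family names.
#'   Families missing from the composition contribute zero.
#' @return Dimensionless ratio.
#' @examples
#' molar_ratio(clade_composition("B. mattogrossensis"),
#'             "SVMPi", c("PI-SVMP", "PIII-SVMP"))
#' @export
molar_ratio <- function(composition, numerator, denominator) {
  num <- .molar_of(composition, numerator, allow_missing = TRUE)
  den <- .molar_of(composition, denominator, allow_missing = TRUE)
  if (den <= 0) .fail("denominator molar abundance is zero")
  num / den
}

#' Share of all venom molecules contributed by one family
#'
#' Expresses one family's molar abundance as a percentage of the summed
#' molar abundances of all families tabulated in the composition (only
#' families with a registry molecular mass enter the denominator).
#'
#' @param composition a [venom_composition()].
#' @param family family name.
#' @return Percentage of all tabulated venom molecules.
#' @export
molecule_fraction <- function(composition, family) {
  if (!family %in% composition$families)
    .fail("family '%s' absent from composition", family)
  total <- sum(composition$molar_percent)
  if (total <= 0) .fail("total molar abundance is zero")
  100 * composition$molar_percent[[family]] / total
}

#' Classify a venom into the clade's compositional patterns
#'
#' The clade venoms fall into three patterns defined by the
#' K49-PLA2/D49-PLA2 molar ratio and the PIII-SVMP content:
#' pattern `"I"` (K49-dominant phospholipase arm with low PIII-SVMP),
#' pattern `"II"` (K49 absent or negligible, D49-dominant), and pattern
#' `"III"` (comparable K49 and D49 proportions). Thresholds are explicit
#' configuration: `k49_negligible` (mmoles % below which K49 counts as
#' absent), `ratio_high`/`ratio_low` (K49/D49 bands) and `piii_low`
#' (mmoles % below which PIII-SVMP counts as low, used to resolve the
#' intermediate ratio band).
#'
#' @param composition a [venom_composition()]; families missing from it
#'   are treated as zero abundance.
#' @param thresholds list as in `venomics_config()$dichotomy`.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_dichotomy <- function(composition,
                               thresholds = venomics_config()$dichotomy) {
  g <- function(f) if (f %in% composition$families)
    composition$molar_percent[[f]] else 0
  k49 <- g("K49-PLA2"); d49 <- g("D49-PLA2"); piii <- g("PIII-SVMP")
  if (k49 < thresholds$k49_negligible) return("II")
  if (d49 <= 0) return("I")
  ratio <- k49 / d49
  if (ratio >= thresholds$ratio_high) return("I")
  if (ratio >= thresholds$ratio_low) {
    if (piii < thresholds$piii_low) "I" else "III"
  } else "II"
}

#' Allocate a chromatographic fraction's abundance to proteins
#'
#' Distributes the percentage of the chromatogram carried by one RP-HPLC
#' fraction over the proteins it contains: first across SDS-PAGE bands by
#' densitometry share, then within a band across co-migrating proteins in
#' proportion to the summed intensities of each protein's three most
#' abundant peptide ions.
#'
#' @param fraction_percent the fraction's share of the chromatogram (%).
#' @param bands list of bands; each band is a list with
#'   `share` (densitometry share, bands must sum to 1) and `proteins`, a
#'   named list mapping protein id to a numeric vector of its top peptide
#'   ion intensities (up to three are used).
#' @return Named numeric vector of per-protein percentages of the whole
#'   chromatogram, summing to `fraction_percent`.
#' @examples
#' allocate_band_abundance(10, list(list(share = 1, proteins =
#'   list(A = c(200, 80, 20), B = c(90, 10)))))
#' @export
allocate_band_abundance <- function(fraction_percent, bands) {
  .check_numeric(fraction_percent, "fraction_percent", 0)
  shares <- vapply(bands, function(b) b$share, numeric(1))
  .check_numeric(shares, "band shares", 0)
  if (abs(sum(shares) - 1) > 1e-9)
    .fail("densitometry shares must sum to 1 (got %.6f)", sum(shares))
  out <- numeric(0)
  for (b in bands) {
    ints <- vapply(b$proteins, function(v) {
      .check_numeric(v, "ion intensities", 0)
      sum(sort(v, decreasing = TRUE)[seq_len(min(3, length(v)))])
    }, numeric(1))
    if (length(ints) > 1 && sum(ints) <= 0)
      .fail("band with multiple proteins has all-zero ion intensities")
    w <- if (sum(ints) > 0) ints / sum(ints) else
      stats::setNames(rep(1 / length(ints), length(ints)), names(ints))
    out <- c(out, fraction_percent * b$share * w)
  }
  out
}
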