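#' Configuration for the synthetic-data generators
#'
#' Bundles every ground-truth parameter the generators draw from, so a
#' (config, seed) pair fully determines the generated data. Defaults
#' reflect the study conditions the analysis expects: per-species
#' compositions centred on the published clade table with anticorrelated
#' K49-PLA2/PIII-SVMP perturbations; Langmuir immunocapture with a total
#' Bmax of about 650 ug on a 7 mg antivenom column (the
#' *B. mattogrossensis* scale, MaxBind near 93 mg/g) and half-saturation
#' at 600 ug venom so the 100-3600 ug dose range visibly saturates;
#' probit lethality with median 50 ug and slope 4 per log10 dose unit;
#' and a hemorrhagic-area line with slope 0.8 cm^2 per log10 ug placing
#' the true MHD near 3 ug, inside the 1.25-15 ug assay range.
#'
#' @param seed integer random seed.
#' @param composition_cv coefficient of variation of the multiplicative
#'   lognormal noise on family mass percentages.
#' @param rho correlation between the K49-PLA2 and PIII-SVMP log
#'   perturbations, in (-1, 0].
#' @param binding_cv multiplicative noise CV on captured masses.
#' @param area_cv multiplicative noise CV on chromatographic areas.
#' @param probit list with `median` (ug) and `slope` (per log10 dose).
#' @param langmuir data.frame with `toxin_id`, `share_pct`, `bmax_ug`,
#'   `kd_ug` (per-toxin Langmuir truth; `kd_ug` in units of toxin mass).
#' @param hemorrhage list with `beta` (cm^2 per log10 ug), `alpha`
#'   (cm^2 at 1 ug) and `sd` (Gaussian area noise, cm^2).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             composition_cv = 0.15,
                             rho = -0.7,
                             binding_cv = 0.03,
                             area_cv = 0.02,
                             probit = list(median = 50, slope = 4),
                             langmuir = default_langmuir_truth(),
                             hemorrhage = list(beta = 0.8,
                                               alpha = 1 - 0.8 * log10(3),
                                               sd = 0.05)) {
  if (!is.numeric(rho) || rho <= -1 || rho >= 1)
    .fail("'rho' must lie in (-1, 1)")
  for (v in c(composition_cv, binding_cv, area_cv))
    .check_numeric(v, "noise CV", 0)
  structure(list(seed = as.integer(seed), composition_cv = composition_cv,
                 rho = rho, binding_cv = binding_cv, area_cv = area_cv,
                 probit = probit, langmuir = langmuir,
                 hemorrhage = hemorrhage),
            class = "generator_config")
}

#' Default per-toxin Langmuir truth
#'
#' Ten toxin fractions with proteome shares taken from the
#' *B. mattogrossensis* column of the clade table. Per-toxin Bmax is
#' 6.9 ug per share point (total about 650 ug on the 7 mg column) and
#' Kd is 6 ug per share point, i.e. half-saturation at 600 ug of venom
#' for every fraction, which guarantees the captured mass never exceeds
#' the toxin amount incubated at the lowest dose used (100 ug).
#'
#' @return data.frame with `toxin_id`, `share_pct`, `bmax_ug`, `kd_ug`.
#' @export
default_langmuir_truth <- function() {
  tab <- neuwiedi_clade_table()
  tab <- tab[tab$species == "B. mattogrossensis", ]
  data.frame(toxin_id = tab$family,
             share_pct = tab$mass_percent,
             bmax_ug = 6.9 * tab$mass_percent,
             kd_ug = 6 * tab$mass_percent,
             stringsAsFactors = FALSE)
}

# lognormal multiplicative factor with unit mean and given CV
.lognoise <- function(n, cv, z = stats::rnorm(n)) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(z * s - s^2 / 2)
}

#' Generate per-specimen venom compositions
#'
#' Draws specimen-level family mass percentages around each species
#' template with multiplicative lognormal noise, renormalized so every
#' specimen keeps its template's total. The log perturbations of
#' K49-PLA2 and PIII-SVMP are drawn with correlation `rho` (negative by
#' default), reproducing the inverse relationship between the two
#' classes across the clade.
#'
#' @param config a [generator_config()].
#' @param n_per_species specimens per species (>= 1).
#' @param species character vector of template species; defaults to all
#'   species of [neuwiedi_clade_table()].
#' @return data.frame with `specimen_id`, `species`, `family`,
#'   `mass_percent`.
#' @export
gen_compositions <- function(config, n_per_species,
                             species = unique(neuwiedi_clade_table()$species)) {
  stopifnot(inherits(config, "generator_config"))
  if (n_per_species < 1) .fail("'n_per_species' must be >= 1")
  set.seed(config$seed)
  tab <- neuwiedi_clade_table()
  out <- list()
  for (sp in species) {
    tpl <- tab[tab$species == sp, ]
    if (nrow(tpl) == 0) .fail("no template for species '%s'", sp)
    for (i in seq_len(n_per_species)) {
      z <- stats::rnorm(nrow(tpl))
      ik <- match("K49-PLA2", tpl$family)
      ip <- match("PIII-SVMP", tpl$family)
      if (!is.na(ik) && !is.na(ip))     # couple the two perturbations
        z[ip] <- config$rho * z[ik] +
          sqrt(1 - config$rho^2) * z[ip]
      m <- tpl$mass_percent * .lognoise(nrow(tpl), config$composition_cv, z)
      m <- m * sum(tpl$mass_percent) / sum(m)
      out[[length(out) + 1]] <- data.frame(
        specimen_id = sprintf("%s_%02d", gsub("[. ]+", "_", sp), i),
        species = sp, family = tpl$family, mass_percent = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Default elution template for synthetic chromatograms
#'
#' Retention times follow the qualitative elution order of the
#' *Bothrops* venom pattern on the RP-HPLC gradient (tripeptide
#' inhibitors first, PIII-SVMP last); the exact minutes are evenly
#' spread conventions, not measured values.
#'
#' @return data.frame with `family`, `rt_min`, `peak_sd_min`.
#' @export
default_elution_template <- function() {
  data.frame(
    family = c("SVMPi", "DISI", "BPP", "K49-PLA2", "CRISP", "D49-PLA2",
               "SVSP", "CTL", "LAAO", "PI-SVMP", "PIII-SVMP"),
    rt_min = c(8, 13, 18, 26, 32, 38, 44, 49, 56, 68, 78),
    peak_sd_min = 0.5,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic chromatogram from a composition
#'
#' Builds a detector trace with one Gaussian peak per family, its area
#' equal to the family's mass percentage, plus the matching integration
#' bounds (+/- 4 peak widths) and the ground-truth peak table. Running
#' [integrate_peaks()] then [relative_abundance()] on the output
#' recovers each family's relative abundance to within 1 percentage
#' point (in practice much closer).
#'
#' @param composition named numeric vector of family mass percentages,
#'   or a data.frame with `family` and `mass_percent` columns.
#' @param elution_template data.frame as [default_elution_template()].
#' @param dt trace sampling step (minutes, > 0).
#' @return List with `time`, `signal`, `bounds` (data.frame usable by
#'   [integrate_peaks()]) and `truth` (the intended peak table).
#' @export
gen_chromatogram <- function(composition,
                             elution_template = default_elution_template(),
                             dt = 0.02) {
  if (is.data.frame(composition)) {
    .check_columns(composition, c("family", "mass_percent"), "composition")
    composition <- stats::setNames(composition$mass_percent,
                                   composition$family)
  }
  .check_numeric(composition, "composition", 0)
  if (dt <= 0) .fail("'dt' must be > 0")
  if (any(elution_template$peak_sd_min <= 0))
    .fail("peak widths must be > 0")
  unknown <- setdiff(names(composition), elution_template$family)
  if (length(unknown))
    .fail("no elution position for family(ies): %s",
          paste(unknown, collapse = ", "))
  tpl <- elution_template[match(names(composition),
                                elution_template$family), ]
  tmax <- max(tpl$rt_min + 6 * tpl$peak_sd_min, 90)
  time <- seq(0, tmax, by = dt)
  signal <- numeric(length(time))
  for (i in seq_len(nrow(tpl)))
    signal <- signal + composition[i] *
      stats::dnorm(time, tpl$rt_min[i], tpl$peak_sd_min[i])
  bounds <- data.frame(start = tpl$rt_min - 4 * tpl$peak_sd_min,
                       end = tpl$rt_min + 4 * tpl$peak_sd_min,
                       baseline = 0,
                       fraction_id = tpl$family,
                       family = tpl$family,
                       stringsAsFactors = FALSE)
  truth <- data.frame(fraction_id = tpl$family,
                      retention_time_min = tpl$rt_min,
                      area = unname(composition),
                      family = tpl$family, stringsAsFactors = FALSE)
  list(time = time, signal = signal, bounds = bounds, truth = truth)
}

#' Generate a Langmuir immunocapture dose series
#'
#' For each toxin, the captured mass at venom dose `x` follows a
#' Langmuir isotherm on the incubated toxin amount
#' `d = x * share / 100`: `captured = bmax * d / (kd + d)`, with
#' multiplicative lognormal noise of CV `binding_cv`. Retained and
#' nonretained areas are back-computed so that [retained_fraction()] and
#' [immunocaptured_mass()] reproduce the captured mass exactly at zero
#' noise.
#'
#' @param config a [generator_config()]; Langmuir truth in
#'   `config$langmuir`.
#' @param doses venom amounts (ug), >= 3 increasing positive values;
#'   default is the seven-dose 100-3600 ug design.
#' @return data.frame with `toxin_id`, `venom_amount_ug`,
#'   `retained_area`, `nonretained_area`, `control_retained_pct`;
#'   the Langmuir truth is attached as attribute `"truth"`.
#' @export
gen_binding_series <- function(config,
                               doses = c(100, 300, 600, 1200, 1800,
                                         2400, 3600)) {
  stopifnot(inherits(config, "generator_config"))
  .check_numeric(doses, "doses", 0, strict_min = TRUE)
  if (length(doses) < 3) .fail("at least 3 doses are required")
  truth <- config$langmuir
  .check_columns(truth, c("toxin_id", "share_pct", "bmax_ug", "kd_ug"),
                 "langmuir truth")
  if (any(truth$bmax_ug <= 0) || any(truth$kd_ug < 0))
    .fail("bmax must be > 0 and kd >= 0")
  set.seed(config$seed)
  out <- list()
  for (i in seq_len(nrow(truth))) {
    d <- doses * truth$share_pct[i] / 100        # toxin ug incubated
    cap <- truth$bmax_ug[i] * d / (truth$kd_ug[i] + d)
    cap <- cap * .lognoise(length(cap), config$binding_cv)
    pct <- pmin(100, 100 * cap / d)
    out[[i]] <- data.frame(toxin_id = truth$toxin_id[i],
                           venom_amount_ug = doses,
                           retained_area = pct,
                           nonretained_area = 100 - pct,
                           control_retained_pct = 0,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- truth
  res
}

#' Generate a quantal lethality (or neutralization) table
#'
#' Deaths per dose group are Binomial draws from the probit
#' dose-mortality model
#' `p(d) = pnorm(slope * (log10(d) - log10(median)))`.
#'
#' @param config a [generator_config()]; truth in `config$probit`.
#' @param doses venom doses (ug), > 0; default six doses spanning the
#'   23-230 ug lethality design.
#' @param n_per_group animals per dose group (the assay design uses 5).
#' @return data.frame with `dose`, `n_subjects`, `n_responders`.
#' @export
gen_lethality <- function(config,
                          doses = 23 * 10^seq(0, 1, length.out = 6),
                          n_per_group = 5) {
  stopifnot(inherits(config, "generator_config"))
  .check_numeric(doses, "doses", 0, strict_min = TRUE)
  set.seed(config$seed)
  p <- stats::pnorm(config$probit$slope *
                      (log10(doses) - log10(config$probit$median)))
  data.frame(dose = doses, n_subjects = n_per_group,
             n_responders = stats::rbinom(length(doses), n_per_group, p))
}

#' Generate a hemorrhagic dose-area table
#'
#' Per-animal spot areas follow `area = beta * log10(dose) + alpha + e`,
#' `e ~ N(0, sd)`; the reported area per dose is the mean over the dose
#' group (the assay uses groups of 5 mice and defines the MHD on the
#' mean area). The configured line places the true MHD (area = 1 cm^2)
#' inside the dose range.
#'
#' @param config a [generator_config()]; truth in `config$hemorrhage`.
#' @param doses venom doses (ug), > 0; default the 1.25-15 ug design.
#' @param n_per_group animals per dose group whose areas are averaged
#'   (default 5).
#' @return data.frame with `dose_ug`, `area_cm2` (group mean); true MHD
#'   attached as attribute `"truth_mhd_ug"`.
#' @export
gen_hemorrhage <- function(config, doses = c(1.25, 2.5, 5, 10, 15),
                           n_per_group = 5) {
  stopifnot(inherits(config, "generator_config"))
  .check_numeric(doses, "doses", 0, strict_min = TRUE)
  if (n_per_group < 1) .fail("'n_per_group' must be >= 1")
  set.seed(config$seed)
  h <- config$hemorrhage
  area <- h$beta * log10(doses) + h$alpha +
    vapply(seq_along(doses),
           function(i) mean(stats::rnorm(n_per_group, 0, h$sd)),
           numeric(1))
  out <- data.frame(dose_ug = doses, area_cm2 = area)
  attr(out, "truth_mhd_ug") <- if (h$beta != 0)
    10^((1 - h$alpha) / h$beta) else NA_real_
  out
}
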