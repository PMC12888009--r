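# binomial-probit log-likelihood on log10 dose, for the grid oracle
probit_loglik <- function(tab, b0, b1)
  sum(stats::dbinom(tab$n_responders, tab$n_subjects,
                    stats::pnorm(b0 + b1 * log10(tab$dose)), log = TRUE))

test_that("probit fit finds the median dose and handles separation", {
  # perfectly symmetric table: median is the 50%-response dose
  tab <- data.frame(dose = c(10, 100, 1000), n_subjects = 10,
                    n_responders = c(0, 5, 10))
  pf <- probit_fit(tab)
  expect_equal(pf$median, 100, tolerance = 1e-6)
  expect_false(pf$converged)   # likelihood unbounded: step response

  # informative table converges with a positive slope and ordered CI
  tab <- data.frame(dose = c(25, 50, 100, 200), n_subjects = 10,
                    n_responders = c(1, 4, 7, 10))
  pf <- probit_fit(tab)
  expect_true(pf$converged)
  expect_gt(pf$slope, 0)
  expect_lt(pf$ci95[1], pf$median)
  expect_gt(pf$ci95[2], pf$median)

  # pure step data: geometric mean of bracketing doses
  tab <- data.frame(dose = c(10, 40, 160, 640), n_subjects = 5,
                    n_responders = c(0, 0, 5, 5))
  pf <- probit_fit(tab)
  expect_equal(pf$median, sqrt(40 * 160))
  expect_false(pf$converged)

  expect_error(probit_fit(data.frame(dose = 10, n_subjects = 5,
                                     n_responders = 2)), "2 distinct")
  expect_error(probit_fit(data.frame(dose = c(10, 20), n_subjects = 5,
                                     n_responders = c(0, 0))), "all zero")
})

test_that("probit ML attains the likelihood of a dense grid search", {
  tables <- list(
    data.frame(dose = c(25, 50, 100, 200), n_subjects = 10,
               n_responders = c(1, 4, 7, 10)),
    data.frame(dose = c(30, 90, 270), n_subjects = 8,
               n_responders = c(2, 4, 7)),
    data.frame(dose = c(20, 60, 180, 540), n_subjects = 6,
               n_responders = c(1, 2, 4, 5))
  )
  for (tab in tables) {
    pf <- probit_fit(tab)
    grid <- expand.grid(b0 = seq(-15, 5, 0.02), b1 = seq(0.05, 10, 0.02))
    best <- max(mapply(function(b0, b1) probit_loglik(tab, b0, b1),
                       grid$b0, grid$b1))
    expect_gte(pf$loglik, best - 1e-6)
  }
})

test_that("the probit 95% CI covers the true median at near-nominal rate", {
  hits <- 0; total <- 0
  for (s in 1:100) {
    cfg <- generator_config(seed = s)
    tab <- gen_lethality(cfg, n_per_group = 10)
    pf <- tryCatch(probit_fit(tab), error = function(e) NULL)
    total <- total + 1
    if (!is.null(pf) && pf$converged &&
        pf$ci95[1] <= cfg$probit$median && cfg$probit$median <= pf$ci95[2])
      hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("potency algebra reproduces every published ED50 -> potency pair", {
  tab <- neuwiedi_neutralization_table()
  computed <- potency_from_ed50(tab$ed50, 5)
  # B. pauloensis printed value reflects rounding of an unprinted
  # intermediate (135.9 * 0.8 = 108.72 vs printed 108.8); all pairs are
  # still within 0.1
  expect_true(all(abs(computed - tab$potency) <= 0.1))
  expect_equal(round_half_up(potency_from_ed50(281.4, 5), 1), 225.1)
  expect_equal(round_half_up(potency_from_ed50(143.4, 5), 1), 114.7)
  expect_equal(potency_from_ed50(10, 2), 5)
  expect_error(potency_from_ed50(10, 1), "> 1")

  # CI bounds propagate elementwise
  ci <- potency_from_ed50(c(115.7, 188.6), 5)
  expect_true(all(abs(ci - c(92.5, 150.9)) <= 0.1))

  # equivalent LD50 entry point: antivenom per n-LD50 challenge at the
  # endpoint is n * LD50 / (ED50 in venom-per-antivenom units)
  expect_equal(potency_from_ld50(3.29, 5 * 3.29 / 143.4, 5),
               potency_from_ed50(143.4, 5))
})

test_that("neutralizing-antibody percentages match the published chain", {
  expect_equal(round_half_up(percent_neutralizing(114.7, 93.08), 2), 123.23)
  expect_equal(round_half_up(percent_neutralizing(103.6, 75.87), 2), 136.55)
  expect_equal(round_half_up(percent_neutralizing(168.3, 165.67), 2), 101.59)
  expect_equal(round_half_up(percent_neutralizing(123.6, 102.9), 2), 120.12)
  expect_equal(percent_neutralizing(93.08, 93.08), 100)
  expect_error(percent_neutralizing(100, 0), "> 0")
})

test_that("vials-per-bite reproduces the published dosing column", {
  tab <- neuwiedi_neutralization_table()
  v <- vials_per_bite(tab$venom_yield_mg, tab$potency, 0.4645)
  expect_equal(round_half_up(v, 1), tab$vials_per_bite)
  expect_equal(vials_per_bite(114.7 * 0.4645, 114.7, 0.4645), 1.0)
})

test_that("MHD inverts the area-log dose line", {
  m <- mhd(data.frame(dose_ug = c(1, 10), area_cm2 = c(0.5, 1.5)))
  expect_equal(m$mhd_ug, 10^0.5, tolerance = 1e-12)
  expect_false(m$extrapolated)

  # a point exactly at area 1 on the fitted line is the MHD
  d <- c(2, 4, 8)
  m <- mhd(data.frame(dose_ug = d, area_cm2 = 0.9 * log10(d / 4) + 1))
  expect_equal(m$mhd_ug, 4, tolerance = 1e-9)

  # recovery from noisy group means across seeds
  ok <- 0
  for (s in 1:100) {
    hem <- gen_hemorrhage(generator_config(seed = s))
    tru <- attr(hem, "truth_mhd_ug")
    if (abs(mhd(hem)$mhd_ug - tru) / tru <= 0.10) ok <- ok + 1
  }
  expect_gte(ok, 90)

  expect_error(mhd(data.frame(dose_ug = c(1, 10), area_cm2 = c(2, 2))),
               "MHD undefined")
})

test_that("edema percentages compare paired paw thicknesses", {
  expect_equal(edema_percent(c(2, 2.2), c(2, 2.2)), c(0, 0))
  expect_equal(edema_percent(2.6, 2.0), 30)
  expect_equal(edema_percent(1.8, 2.0), -10)   # negative allowed
  expect_error(edema_percent(c(1, 2), 1), "timepoints")
})

test_that("enzymatic unit conversions scale inversely with time and mass", {
  expect_equal(azocoll_activity(0, 60, 0.00625), 0)
  expect_equal(azocoll_activity(0.3, 60, 0.00625), 266 + 2 / 3,
               tolerance = 1e-10)
  expect_equal(azocoll_activity(0.3, 60, 0.0125),
               azocoll_activity(0.3, 60, 0.00625) / 2)
  expect_error(azocoll_activity(0.1, 0, 1), "> 0")

  expect_equal(pla2_activity(0.01, 1, 1), 25.8)
  expect_equal(pla2_activity(0, 60, 0.02), 0)
  expect_equal(pla2_activity(0.1, 60, 0.02), 215.0)
  # homogeneity of degree -1 in time and mass
  expect_equal(pla2_activity(0.1, 120, 0.02),
               pla2_activity(0.1, 60, 0.02) / 2)
  expect_equal(pla2_activity(0.1, 60, 0.04),
               pla2_activity(0.1, 60, 0.02) / 2)
})

test_that("potency report assembles the dosing chain from printed inputs", {
  rep <- potency_report(143.4, 93.08, 88.5, ed50_ci = c(115.7, 188.6))
  expect_equal(rep$potency, 114.72)
  expect_true(all(abs(rep$potency_ci - c(92.5, 150.9)) <= 0.1))
  expect_equal(rep$percent_neutralizing, 100 * 114.72 / 93.08)
  expect_equal(round_half_up(rep$vials_per_bite, 1), 1.7)
})
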