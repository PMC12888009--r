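test_that("trapezoidal peak integration matches closed-form areas", {
  t <- seq(0, 10, 0.001)

  # flat zero trace -> all areas zero
  pk <- integrate_peaks(t, rep(0, length(t)),
                        data.frame(start = c(1, 5), end = c(3, 8)))
  expect_equal(pk$area, c(0, 0))

  # unit triangle (0,0)-(1,1)-(2,0): area 1
  tri <- pmax(0, 1 - abs(t - 1))
  pk <- integrate_peaks(t, tri, data.frame(start = 0, end = 2))
  expect_equal(pk$area, 1, tolerance = 1e-3)

  # two disjoint identical triangles -> equal areas, within 0.1% of 0.5
  two <- pmax(0, 0.5 - abs(t - 2)) + pmax(0, 0.5 - abs(t - 6))
  pk <- integrate_peaks(t, two, data.frame(start = c(1.5, 5.5),
                                           end = c(2.5, 6.5)))
  expect_equal(pk$area[1], pk$area[2], tolerance = 1e-12)
  expect_equal(pk$area, c(0.25, 0.25), tolerance = 1e-3)

  # baseline above signal clamps to zero, not negative
  pk <- integrate_peaks(t, rep(0.1, length(t)),
                        data.frame(start = 1, end = 2, baseline = 0.5))
  expect_equal(pk$area, 0)

  expect_error(integrate_peaks(t, rep(1, length(t)),
                               data.frame(start = c(1, 2), end = c(3, 4))),
               "overlap")
  expect_error(integrate_peaks(numeric(0), numeric(0),
                               data.frame(start = 1, end = 2)),
               "at least two")
})

test_that("relative abundance sums to 100 and matches hand arithmetic", {
  pk <- data.frame(area = 5, family = "X")
  expect_equal(unname(relative_abundance(pk)), 100)

  pk <- data.frame(area = c(2, 2, 4), family = c("X", "X", "Y"))
  expect_equal(relative_abundance(pk), c(X = 50, Y = 50))

  pk <- data.frame(area = c(1, 3), family = c("X", "Y"))
  expect_equal(relative_abundance(pk)[["X"]], 25)

  # conservation including the unassigned bucket, random tables
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pk <- data.frame(area = runif(n, 0, 10),
                     family = sample(c("A", "B", "C", "unassigned"),
                                     n, replace = TRUE))
    expect_equal(sum(relative_abundance(pk)), 100, tolerance = 1e-9)
  }

  expect_error(relative_abundance(data.frame(area = c(0, 0),
                                             family = c("X", "Y"))),
               "total peak area")
})

test_that("mass-to-molar conversion reproduces published values and round-trips", {
  expect_equal(round_half_up(mass_to_molar(7.5, 1.40e4), 3), 0.536)
  expect_equal(round_half_up(mass_to_molar(12.8, 444.4), 3), 28.803)
  expect_equal(mass_to_molar(0, 123), 0)
  expect_error(mass_to_molar(1, 0), "> 0")

  set.seed(7)
  m <- runif(50, 0, 40); da <- runif(50, 400, 6e4)
  expect_equal(molar_to_mass(mass_to_molar(m, da), da), m,
               tolerance = 1e-12)
})

test_that("every printed molar cell of the clade table reproduces to 0.001", {
  tab <- neuwiedi_clade_table()
  masses <- family_masses()
  computed <- mass_to_molar(tab$mass_percent, masses[tab$family])
  expect_true(all(abs(computed - tab$molar_percent) <= 0.001))
  # and the printed values are exactly the half-away-from-zero rounding
  expect_equal(unname(round_half_up(computed, 3)), tab$molar_percent)
})

test_that("molar ratios match the published inhibitor:SVMP figures", {
  matto <- clade_composition("B. mattogrossensis")
  expect_equal(round_half_up(
    molar_ratio(matto, "SVMPi", c("PI-SVMP", "PIII-SVMP")), 1), 20.4)
  expect_equal(molar_ratio(matto, "SVSP", "SVSP"), 1.0)
  neu <- clade_composition("B. neuwiedi")
  expect_equal(round_half_up(
    molar_ratio(neu, "SVMPi", c("PI-SVMP", "PIII-SVMP")), 1), 25.4)
  expect_error(molar_ratio(matto, "SVMPi", "BPP"), "zero")
})

test_that("molecule fraction reproduces the tripeptide's molar dominance", {
  matto <- clade_composition("B. mattogrossensis")
  expect_equal(round_half_up(molecule_fraction(matto, "SVMPi"), 1), 89.8)

  single <- venom_composition("x", c(SVSP = 5.7))
  expect_equal(molecule_fraction(single, "SVSP"), 100)

  two <- venom_composition("x", c("K49-PLA2" = 3, "D49-PLA2" = 3))
  expect_equal(molecule_fraction(two, "K49-PLA2"), 50)
  expect_error(molecule_fraction(two, "LAAO"), "absent")
})

test_that("compositional patterns classify all seven clade venoms as published", {
  expected <- c("B. diporus" = "I", "B. neuwiedi" = "I",
                "B. pubescens" = "I", "B. pauloensis" = "I",
                "B. erythromelas" = "II",
                "B. mattogrossensis" = "III", "B. marmoratus" = "III")
  for (sp in names(expected))
    expect_equal(classify_dichotomy(clade_composition(sp)),
                 unname(expected[sp]), label = sp)
})

test_that("band allocation is conservative and follows ion-intensity shares", {
  # degenerate: one band, one protein
  a <- allocate_band_abundance(10, list(list(share = 1,
                                             proteins = list(P = 5))))
  expect_equal(a, c(P = 10))

  # two proteins with top-3 intensity sums 300 vs 100 -> 7.5 / 2.5
  a <- allocate_band_abundance(10, list(list(
    share = 1, proteins = list(A = c(150, 100, 50), B = c(60, 30, 10)))))
  expect_equal(a, c(A = 7.5, B = 2.5))

  # two single-protein bands, densitometry 0.75/0.25 of an 8% fraction
  a <- allocate_band_abundance(8, list(
    list(share = 0.75, proteins = list(A = 1)),
    list(share = 0.25, proteins = list(B = 1))))
  expect_equal(a, c(A = 6, B = 2))

  # only the three most abundant ions count
  a <- allocate_band_abundance(10, list(list(
    share = 1, proteins = list(A = c(100, 100, 100, 999),
                               B = c(100, 100, 100)))))
  expect_equal(unname(a), c(10 * 1199 / 1499, 10 * 300 / 1499))

  # conservation on random allocations
  set.seed(11)
  for (i in 1:10) {
    shares <- runif(3); shares <- shares / sum(shares)
    bands <- lapply(shares, function(s)
      list(share = s, proteins = list(A = runif(3, 1, 100),
                                      B = runif(3, 1, 100))))
    frac <- runif(1, 1, 30)
    expect_equal(sum(allocate_band_abundance(frac, bands)), frac,
                 tolerance = 1e-9)
  }

  expect_error(allocate_band_abundance(10, list(list(
    share = 1, proteins = list(A = 0, B = 0)))), "all-zero")
  expect_error(allocate_band_abundance(10, list(list(
    share = 0.6, proteins = list(A = 1)))), "sum to 1")
})

test_that("composition containers validate their invariants", {
  expect_error(venom_composition("x", c(5, 5)), "named")
  expect_error(venom_composition("x", c(SVSP = 60, LAAO = 50)), "> 100")
  expect_error(venom_composition("x", c(NOTAFAM = 5)), "registry")
  comp <- clade_composition("B. erythromelas")
  expect_false("K49-PLA2" %in% comp$families)
  expect_error(clade_composition("B. atrox"), "unknown species")
})
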