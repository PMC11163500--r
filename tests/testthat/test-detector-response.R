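test_that("disk average is exact on uniform and quadratic dose maps", {
  expect_equal(volumeAverage(flatMap(level = 2.7), diameter = 1.5), 2.7,
               tolerance = 1e-12)
  # D(r) = D0 (1 - c r^2): disk mean D0 (1 - c a^2 / 2)
  D0 <- 1.3; cc <- 0.02; a <- 0.75
  m <- quadraticMap(D0 = D0, cc = cc)
  expect_equal(volumeAverage(m, diameter = 2 * a),
               D0 * (1 - cc * a^2 / 2), tolerance = 1e-4)
  expect_error(volumeAverage(flatMap(halfWidth = 1), diameter = 4),
               "exceeds")
})

test_that("disk average matches a seeded million-point Monte-Carlo oracle", {
  spec <- beamSpec(3)
  m <- makeDoseMap(spec, depth = 7, spacing = 0.1)
  got <- volumeAverage(m, diameter = 1.5)
  # sample the analytic radial dose uniformly over the disk
  f <- makeDoseProfile(spec, depth = 7, noiseLevel = 0)$truth$fun
  set.seed(2024)
  n <- 1e6
  r <- 0.75 * sqrt(runif(n))
  mc <- mean(f(r))
  expect_lt(abs(got - mc) / mc, 1e-3)
})

test_that("geometric P_vol has its closed form, flat-field limit and ordering", {
  flat <- flatMap(level = 1, halfWidth = 3)
  expect_equal(pVolGeometric(flat, flat), 1, tolerance = 1e-12)
  # identical clinical and reference fields cancel exactly
  m3 <- makeDoseMap(beamSpec(3), spacing = 0.1)
  expect_equal(pVolGeometric(m3, m3), 1, tolerance = 1e-12)
  # quadratic clinical field over a flat reference: 1 / (1 - c a^2 / 2)
  D0 <- 1; cc <- 0.05; a <- 0.75
  quad <- quadraticMap(D0 = D0, cc = cc)
  got <- pVolGeometric(quad, flat)
  # the 0.2 mm point voxel also averages the quadratic (mean r^2 = s^2/6);
  # the tolerance covers the sub-voxel midpoint-quadrature bias of a
  # footprint only two grid cells wide
  pointMean <- D0 * (1 - cc * 0.2^2 / 6)
  expect_equal(got, pointMean / (D0 * (1 - cc * a^2 / 2)), tolerance = 5e-4)
  expect_equal(got, 1 / (1 - cc * a^2 / 2), tolerance = 1e-3)
  expect_gt(got, 1)
  expect_error(pVolGeometric(quad, flat, center = c(0.5, 0)), "center")
})

test_that("geometric P_vol of the synthetic 3 mm cone lies near the published 1.075", {
  m3 <- makeDoseMap(beamSpec(3), depth = 7, spacing = 0.1)
  m25 <- makeDoseMap(beamSpec(25), depth = 7, spacing = 0.1)
  pv <- pVolGeometric(m3, m25)
  expect_gt(pv, 1.05)
  expect_lt(pv, 1.10)
  # flat-field limit: the 25 mm reference field alone is near unity
  flat <- flatMap(level = 1, halfWidth = 3)
  expect_equal(pVolGeometric(m25, flat), 1, tolerance = 5e-3)
})

test_that("perturbation factors telescope exactly and reproduce the published product", {
  # equal clinical and msr signals: all factors one
  sig <- c(M_diode = 1.1, M_si_vol = 1.2, D_w_vol = 1.3, D_w_point = 1.4)
  ps <- perturbationFromSignals(sig, sig, fieldSize = 25)
  expect_equal(ps@pHousing, 1); expect_equal(ps@pSens, 1)
  expect_equal(ps@pVol, 1); expect_equal(ps@kTotal, 1)

  # published 3 mm components multiply to the published total correction
  k3 <- 0.9725 * 0.989 * 1.075
  expect_equal(round(k3, 3), 1.034)

  # telescoping identity on 100 seeded random positive signal sets
  set.seed(11)
  for (i in 1:100) {
    clin <- exp(rnorm(4, sd = 0.3))
    msr <- exp(rnorm(4, sd = 0.3))
    names(clin) <- names(msr) <- c("M_diode", "M_si_vol", "D_w_vol",
                                   "D_w_point")
    ps <- perturbationFromSignals(clin, msr, fieldSize = 3)
    direct <- (clin[["D_w_point"]] / clin[["M_diode"]]) /
              (msr[["D_w_point"]] / msr[["M_diode"]])
    expect_lt(abs(ps@kTotal - ps@pHousing * ps@pSens * ps@pVol) /
                ps@kTotal, 1e-12)
    expect_lt(abs(ps@kTotal - direct) / direct, 1e-12)
  }
  expect_error(perturbationFromSignals(c(sig[1:3], D_w_point = -1), sig),
               "positive")
})

test_that("packaged factor table carries the published values and sign structure", {
  tab <- packagedFactorTable()
  expect_equal(packagedFactorTable(3)$p_vol, 1.075)
  expect_equal(packagedFactorTable(3)$p_housing, 0.9725)
  expect_equal(packagedFactorTable(3)$p_sens, 0.989)
  expect_equal(packagedFactorTable(4)$k_total, 0.998)
  expect_equal(packagedFactorTable(4)$p_vol, 1.022)
  expect_equal(packagedFactorTable(5)$k_total, 0.988)
  # msr field: unity by construction
  expect_equal(unlist(packagedFactorTable(25)[, c("p_housing", "p_sens",
                                                  "p_vol", "k_total")]),
               c(p_housing = 1, p_sens = 1, p_vol = 1, k_total = 1))
  # turning point: below one at 4 and 5 mm, above one at 3 mm
  expect_lt(packagedFactorTable(5)$k_total, 1)
  expect_lt(packagedFactorTable(4)$k_total, 1)
  expect_gt(packagedFactorTable(3)$k_total, 1)
  # unreported components are absent, never interpolated
  expect_true(is.na(packagedFactorTable(5)$p_vol))
  expect_error(packagedFactorTable(2), "range")
  expect_error(packagedFactorTable(10), "interpolated")
})

test_that("signal emulator preserves flat fields, the point limit, and broadens monotonically", {
  geomUnit <- detectorGeometry(
    housingResponse = data.frame(field_mm = c(3, 25), factor = c(1, 1)),
    chipResponse = data.frame(field_mm = c(3, 25), factor = c(1, 1)))
  flat <- flatMap(level = 4, halfWidth = 4)
  pos <- seq(-2, 2, 0.5)
  M <- emulateSignalProfile(flat, geomUnit, pos, fieldSize = 3)
  expect_equal(M$value, rep(4, length(pos)), tolerance = 1e-12)

  m3 <- makeDoseMap(beamSpec(3), depth = 7, spacing = 0.1, halfWidth = 6)
  prof <- extractProfile(m3)
  pos <- seq(-4, 4, 0.1)
  # point-like detector reproduces the dose profile
  geomPoint <- detectorGeometry(sensitiveDiameter = 0.01,
    housingResponse = geomUnit$housingResponse,
    chipResponse = geomUnit$chipResponse)
  Mp <- emulateSignalProfile(m3, geomPoint, pos, fieldSize = 3)
  ref <- approx(prof$position_mm, prof$value, xout = pos)$y
  expect_lt(max(abs(Mp$value - ref)) / max(ref), 1e-3)

  # finite disk: broader than the dose, by at most 0.2 mm at 1.5 mm
  fw <- vapply(c(0.01, 0.75, 1.5, 2.25), function(dia) {
    g <- detectorGeometry(sensitiveDiameter = dia,
                          housingResponse = geomUnit$housingResponse,
                          chipResponse = geomUnit$chipResponse)
    profileFWHM(emulateSignalProfile(m3, g, pos, fieldSize = 3))
  }, numeric(1L))
  fwDose <- profileFWHM(prof)
  expect_gte(fw[3L], fwDose)
  expect_lt(fw[3L] - fwDose, 0.2)
  expect_true(all(diff(fw) > 0))
})
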