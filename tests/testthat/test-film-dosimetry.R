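test_that("red channel extraction picks the first channel unchanged", {
  px <- array(0, dim = c(4, 5, 3))
  px[, , 1] <- 11; px[, , 2] <- 22; px[, , 3] <- 33
  scan <- FilmScan(px, dpi = 600)
  expect_equal(redChannel(scan), matrix(11, 4, 5))
  expect_error(redChannel(array(1, dim = c(4, 5, 2))), "3-channel")
})

test_that("net optical density follows the log ratio", {
  I0 <- matrix(40000, 3, 3)
  expect_equal(netResponse(I0, I0), matrix(0, 3, 3))
  expect_equal(netResponse(I0 / 2, I0),
               matrix(log10(2), 3, 3), tolerance = 1e-12)
  expect_error(netResponse(I0 - 40000, I0), "positive")
})

test_that("calibration fit recovers a known cubic and rejects bad designs", {
  truth <- c(0.01, 0.6, 3.5, 2.2)
  x <- seq(0.01, 0.55, length.out = 10)
  d <- truth[1] + truth[2] * x + truth[3] * x^2 + truth[4] * x^3
  cal <- fitCalibration(d, x)
  expect_equal(cal@coefficients, truth, tolerance = 1e-10)
  expect_equal(predictDose(cal, x), d, tolerance = 1e-10)

  # 10 seeded noisy points over 0-2 Gy: max dose error <= 2% of 2 Gy
  set.seed(5)
  model <- filmModel()
  doses <- seq(0, 2, length.out = 10)
  inv <- smallfieldr:::inverseCalibration(model)
  resp <- inv(doses) * (1 + c(0, rnorm(9, sd = 0.005)))
  cal2 <- fitCalibration(doses, resp)
  grid <- seq(min(resp), max(resp), length.out = 101)
  refDose <- predictDose(cal2, grid)
  trueDose <- sapply(grid, function(x)
    model@calibration[2] * x + model@calibration[3] * x^2 +
      model@calibration[4] * x^3)
  expect_lt(max(abs(refDose - trueDose)), 0.04)

  expect_error(fitCalibration(c(0, 1, 2), c(0, 0.3, 0.5)), "4 distinct")
  expect_error(fitCalibration(c(0, 1, 1.5, 2), c(0, 0.3, 0.3, 0.5)),
               "duplicate")
})

test_that("median filter matches a brute-force oracle and is idempotent on constants", {
  set.seed(9)
  img <- matrix(runif(400), 20, 20)
  got <- medianFilterImage(img, 3L)
  # brute force with reflected borders
  idx <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  brute <- img
  for (i in 1:20) for (j in 1:20) {
    vals <- numeric(9); m <- 0
    for (di in -1:1) for (dj in -1:1) {
      m <- m + 1
      vals[m] <- img[idx(i + di, 20), idx(j + dj, 20)]
    }
    brute[i, j] <- median(vals)
  }
  expect_identical(got, brute)

  const <- matrix(3, 10, 10)
  expect_equal(medianFilterImage(const, 5L), const)
  # single salt pixel removed
  salt <- const; salt[5, 5] <- 100
  expect_equal(medianFilterImage(salt, 3L), const)
  expect_error(medianFilterImage(img, 4L), "odd")
})

test_that("film pipeline round-trips flat doses within 2% over 0.1-2 Gy", {
  model <- filmModel() # 1% pixel noise, 600 dpi
  # calibration from a separate seeded film set at the 10 design doses
  calDoses <- seq(0, 2, length.out = 10)
  calSets <- lapply(seq_along(calDoses), function(i)
    makeFilmSet(calDoses[i], model, nRepeats = 1L, seed = 100 + i,
                patchPx = 48L))
  resp <- vapply(seq_along(calDoses), function(i) {
    od <- netResponse(redChannel(calSets[[i]]$films[[1]]),
                      median(redChannel(calSets[[i]]$unexposed)))
    median(medianFilterImage(od, 5L))
  }, numeric(1L))
  cal <- fitCalibration(calDoses, resp)

  # spacing follows the scanner resolution
  s1 <- makeFilmSet(1.0, model, nRepeats = 1L, seed = 1)
  m1 <- filmDoseMap(s1$films[[1]], s1$unexposed, cal)
  expect_equal(gridSpacing(m1), 25.4 / 600, tolerance = 1e-9)

  # 5-repeat sets across the dose range recover the truth within 2%
  for (dose in c(0.1, 0.5, 1.0, 2.0)) {
    fs <- makeFilmSet(dose, model, nRepeats = 5L, seed = round(dose * 1000))
    rec <- vapply(fs$films, function(f) {
      m <- filmDoseMap(f, fs$unexposed, cal)
      median(medianFilterImage(doseValues(m), 5L))
    }, numeric(1L))
    expect_lt(abs(mean(rec) - dose), 0.02 * max(dose, 1))
  }

  # unexposed film reads back about zero dose
  mu <- filmDoseMap(fs <- makeFilmSet(0, model, nRepeats = 1L,
                                      seed = 3)$films[[1]],
                    makeFilmSet(0, model, nRepeats = 1L, seed = 4)$unexposed,
                    cal)
  expect_lt(median(doseValues(mu)), 0.03)
})

test_that("film output factor recovers the constructed ratio with honest uncertainty", {
  model <- filmModel(dpi = 150) # coarser scan keeps the fixture compact
  spec25 <- beamSpec(25)
  msrMap <- makeDoseMap(spec25, depth = 7, spacing = 25.4 / 150,
                        halfWidth = 16, centralDose = 2.0)
  # the emulated clinical scenario: the clinical map is 0.443 times the
  # reference map, so the true ratio is exact at every pixel
  clinMap <- RadialDoseMap(doseValues(msrMap) * 0.443,
                           spacing = gridSpacing(msrMap))
  calDoses <- seq(0, 2, length.out = 10)
  calSets <- lapply(seq_along(calDoses), function(i)
    makeFilmSet(calDoses[i], model, nRepeats = 1L, seed = 300 + i,
                patchPx = 48L))
  resp <- vapply(seq_along(calDoses), function(i) {
    od <- netResponse(redChannel(calSets[[i]]$films[[1]]),
                      median(redChannel(calSets[[i]]$unexposed)))
    median(medianFilterImage(od, 5L))
  }, numeric(1L))
  cal <- fitCalibration(calDoses, resp)

  msrSet <- makeFilmSet(msrMap, model, nRepeats = 5L, seed = 21)
  clinSet <- makeFilmSet(clinMap, model, nRepeats = 5L, seed = 22)
  toMaps <- function(set) lapply(set$films, filmDoseMap,
                                 unexposedRef = set$unexposed,
                                 calibration = cal)
  of <- filmOutputFactor(toMaps(clinSet), toMaps(msrSet))
  expect_lt(abs(of$value - 0.443), 2 * max(of$uncertainty, 0.443 * 0.002))
  expect_length(of$perRepeat, 5L)
  expect_true(of$uncertainty > 0)

  # ratio invariance under common exposure rescaling
  ofScaled <- filmOutputFactor(
    lapply(toMaps(clinSet), function(m)
      RadialDoseMap(doseValues(m) * 0.9, gridSpacing(m))),
    lapply(toMaps(msrSet), function(m)
      RadialDoseMap(doseValues(m) * 0.9, gridSpacing(m))))
  expect_equal(ofScaled$value, of$value, tolerance = 1e-6)

  # identical maps give exactly one
  one <- filmOutputFactor(msrMap, msrMap)
  expect_equal(one$value, 1)
  expect_true(is.na(one$uncertainty))
})
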