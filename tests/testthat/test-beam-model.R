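test_that("impulse source reproduces the kernel and flat fluence conserves its integral", {
  k <- gaussianKernel(0.5, spacing = 0.1)
  # unit point impulse: one grid cell of fluence 1/spacing^2
  imp <- function(r) ifelse(r < 0.05, 1 / 0.1^2, 0)
  d <- convolveRadial(imp, k, spacing = 0.1, halfWidth = 3, subsample = 1L,
                      refine = 1L)
  prof <- extractProfile(d)
  kr <- (seq_along(kernelValues(k)) - 1L) * 0.1
  right <- prof$value[prof$position_mm >= -1e-9]
  expect_equal(right[seq_along(kr)], kernelValues(k), tolerance = 1e-10)

  # uniform fluence level c -> uniform dose c * kernel integral
  u <- convolveRadial(function(r) rep(2.5, length(r)), k, spacing = 0.1,
                      halfWidth = 6)
  pu <- extractProfile(u)
  core <- pu$value[abs(pu$position_mm) <= 2]
  expect_equal(core, rep(2.5 * kernelIntegral(k), length(core)),
               tolerance = 1e-3)
})

test_that("grid convolution matches a 0.02 mm Riemann-sum oracle within 0.1%", {
  # kernels sampled adequately relative to their width (sigma >= 4 x
  # spacing), the engine's documented sampling requirement
  cases <- list(
    list(R = 1.5, sigma = 0.5),   # the 3 mm cone with a narrow kernel
    list(R = 1.0, sigma = 0.8),
    list(R = 2.0, sigma = 0.45))
  for (cs in cases) {
    k <- gaussianKernel(cs$sigma, spacing = 0.1)
    src <- function(r) as.numeric(r <= cs$R)
    d <- convolveRadial(src, k, spacing = 0.1, halfWidth = cs$R + 3)
    prof <- extractProfile(d)
    # evaluation points on the 0.1 mm grid: axis, in-field, edge, tail
    pts <- round(c(0, cs$R * 2 / 3, cs$R, cs$R + 0.5), 1)
    oracle <- riemannConvolve(src, function(r) gauss2d(r, cs$sigma), pts,
                              h = 0.02, supportRadius = cs$R + 0.1)
    grid <- vapply(pts, function(p)
      prof$value[which.min(abs(prof$position_mm - p))], numeric(1L))
    expect_lt(max(abs(grid - oracle)) / oracle[1L], 1e-3)
  }
})

test_that("convolution is linear in the source", {
  k <- gaussianKernel(0.4, spacing = 0.1)
  f1 <- function(r) as.numeric(r <= 1.2)
  f2 <- function(r) exp(-r^2 / 2)
  a <- 1.7; b <- 0.6
  d1 <- convolveRadial(f1, k, halfWidth = 4)
  d2 <- convolveRadial(f2, k, halfWidth = 4)
  d12 <- convolveRadial(function(r) a * f1(r) + b * f2(r), k, halfWidth = 4)
  lhs <- doseValues(d12)
  rhs <- a * doseValues(d1) + b * doseValues(d2)
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
})

test_that("dose FWHM matches the closed-form disk-Gaussian convolution and approaches the top-hat diameter as the kernel narrows", {
  # closed-form FWHM via root finding on the noncentral chi-square tail
  anaFWHM <- function(R, sigma) {
    f <- function(r) diskGaussProfile(r, R, sigma)
    2 * uniroot(function(r) f(r) - f(0) / 2, c(R / 4, 3 * R))$root
  }
  got <- vapply(c(0.2, 0.5, 1.0), function(sigma) {
    k <- gaussianKernel(sigma, spacing = 0.1)
    d <- convolveRadial(function(r) as.numeric(r <= 1.5), k, halfWidth = 6)
    fw <- profileFWHM(extractProfile(d))
    expect_lt(abs(fw - anaFWHM(1.5, sigma)), 0.02)
    fw
  }, numeric(1L))
  # narrow-kernel limit: the deficit below the nominal diameter shrinks
  expect_lt(abs(got[1L] - 3), abs(got[2L] - 3))
  expect_lt(abs(got[1L] - 3), 0.05)
})

test_that("negative sources and truncating grids are rejected", {
  k <- gaussianKernel(0.5, spacing = 0.1)
  expect_error(convolveRadial(function(r) -1 + 0 * r, k, halfWidth = 3),
               "non-negative")
  tophat <- data.frame(r = seq(0, 3, 0.1),
                       value = as.numeric(seq(0, 3, 0.1) <= 2.5))
  expect_error(convolveRadial(tophat, k, halfWidth = 1.5), "truncat")
})

test_that("step decomposition reproduces piecewise-constant fluences exactly", {
  r <- seq(0, 3, by = 0.1)
  # single top-hat: one step at the support edge
  th <- data.frame(r = r, value = as.numeric(r <= 1.5))
  s1 <- decomposeSteps(th, binWidth = 3.5)
  expect_equal(stepRadii(s1), 1.5)
  expect_equal(stepWeights(s1), 1)

  # nested top-hats: plateau 3 inside 1 mm, plateau 1 out to 2 mm
  nest <- data.frame(r = r, value = 2 * (r <= 1) + 1 * (r <= 2))
  s2 <- decomposeSteps(nest, binWidth = 1)
  expect_equal(evaluateFluence(s2, c(0.5, 1.5)), c(3, 1))
  expect_equal(evaluateFluence(s2, 2.5), 0)

  # smooth fluence: evaluation matches samples at bin centers
  sm <- data.frame(r = r, value = exp(-r^2 / 1.5))
  s3 <- decomposeSteps(sm, binWidth = 0.2)
  centers <- stepRadii(s3) - diff(c(0, stepRadii(s3)))[1L] / 2
  expect_equal(evaluateFluence(s3, centers),
               approx(r, sm$value, xout = centers)$y, tolerance = 1e-12)

  expect_error(decomposeSteps(data.frame(r = c(0, 1, 0.5),
                                         value = c(1, 1, 1)), 0.5),
               "increasing")
})

test_that("extracted x and y profiles agree and preserve the radial FWHM", {
  spec <- beamSpec(3)
  m <- makeDoseMap(spec, depth = 7, spacing = 0.1)
  px <- extractProfile(m, "x")
  py <- extractProfile(m, "y")
  expect_identical(px$value, py$value)
  truth <- makeDoseProfile(spec, depth = 7, noiseLevel = 0)$truth
  expect_lt(abs(profileFWHM(px) - truth$fwhm), 0.1)
})
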