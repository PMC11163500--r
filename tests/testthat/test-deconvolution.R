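# discrete unit impulse kernel: identity of the forward operator
impulseKernel <- function(spacing = 0.1) {
  DoseKernel(c(1 / spacing^2, 0, 0, 0), spacing)
}

test_that("identity kernel returns the measurement in one iteration", {
  x <- seq(-3, 3, by = 0.1)
  d <- data.frame(position_mm = x, value = pmax(0, 1 - (x / 2)^2))
  res <- vanCittert(d, impulseKernel())
  expect_s4_class(res, "DeconvolutionResult")
  expect_identical(res@iterationsUsed, 1L)
  expect_lt(res@residualHistory[1L], 1e-10)
  expect_true(res@converged)
  r <- seq(0, 3, by = 0.1)
  expect_equal(res@fluence$value, pmax(0, 1 - (r / 2)^2), tolerance = 1e-9)
})

test_that("top-hat source is recovered from its blurred dose profile", {
  k <- gaussianKernel(0.5, spacing = 0.1)
  dmap <- convolveRadial(function(r) as.numeric(r <= 1.5), k,
                         spacing = 0.1, halfWidth = 4)
  d <- extractProfile(dmap)
  res <- vanCittert(d, k, deconvolutionSettings(maxIterations = 200L))
  # recovered fluence edge sits at the 1.5 mm top-hat radius
  expect_lt(abs(profileFWHM(mirrorProfile(res@fluence)) - 3.0), 0.1)
  # relative L2 residual well below 5%
  expect_lt(res@residualHistory[res@iterationsUsed], 0.05)
  # forward re-convolution matches the input within 1% of the axis dose
  rep <- validateForward(res, d, toleranceBand = 1)
  expect_lt(rep$maxDeviationPct, 1)
  expect_equal(rep$fracInBand, 1)
})

test_that("noisy profiles deconvolve stably with inter-iteration smoothing", {
  k <- gaussianKernel(0.5, spacing = 0.1)
  dmap <- convolveRadial(function(r) as.numeric(r <= 1.5), k,
                         spacing = 0.1, halfWidth = 4)
  clean <- extractProfile(dmap)
  set.seed(42)
  noisy <- clean
  noisy$value <- pmax(0, clean$value +
                        rnorm(nrow(clean), sd = 0.005 * max(clean$value)))
  res <- vanCittert(noisy, k,
                    deconvolutionSettings(smoothingWindow = 5L,
                                          maxIterations = 200L))
  expect_identical(res@settings$smoothingWindow, 5L)
  fwd <- extractProfile(res@forwardDose)
  ref <- approx(clean$position_mm, clean$value, xout = fwd$position_mm)$y
  keep <- !is.na(ref)
  expect_lt(max(abs(fwd$value[keep] - ref[keep])) / max(clean$value), 0.01)
  # recovery stays within a 2-sigma band of the noiseless truth
  rep <- validateForward(res, clean, toleranceBand = 1)
  expect_gte(rep$fracInBand, 0.95)
})

test_that("an exact fixed point is left unchanged", {
  k <- gaussianKernel(0.6, spacing = 0.1)
  r <- seq(0, 4, by = 0.1)
  psiTrue <- exp(-r^2 / 3)
  A <- smallfieldr:::forwardOperatorMatrix(k, length(r), 0.1)
  D <- as.vector(A %*% psiTrue)
  # one van-Cittert update from the fixed point: psi + alpha (D - A psi)
  upd <- psiTrue + 1.0 * (D - as.vector(A %*% psiTrue))
  expect_equal(upd, psiTrue, tolerance = 1e-12)
})

test_that("residuals are non-increasing for noiseless input at alpha = 1", {
  k <- gaussianKernel(0.5, spacing = 0.1)
  dmap <- convolveRadial(function(r) as.numeric(r <= 1.5), k,
                         spacing = 0.1, halfWidth = 4)
  # strict monotonicity for the unconstrained (linear) iteration
  res <- vanCittert(extractProfile(dmap), k,
                    deconvolutionSettings(maxIterations = 100L,
                                          nonnegativity = FALSE))
  expect_true(all(diff(res@residualHistory) <= 1e-12))
  # the non-negativity projection may perturb the residual only marginally
  resc <- vanCittert(extractProfile(dmap), k,
                     deconvolutionSettings(maxIterations = 100L))
  expect_true(all(diff(resc@residualHistory) <= 1e-4))
})

test_that("deconvolution sharpens the edge: recovered fluence has steeper penumbra than the dose", {
  k <- gaussianKernel(0.5, spacing = 0.1)
  dmap <- convolveRadial(function(r) as.numeric(r <= 1.5), k,
                         spacing = 0.1, halfWidth = 4)
  d <- extractProfile(dmap)
  res <- vanCittert(d, k, deconvolutionSettings(maxIterations = 200L))
  expect_lt(profilePenumbra(mirrorProfile(res@fluence), "right"),
            profilePenumbra(d, "right"))
})

test_that("validation report flags a uniform offset and a perfect match", {
  k <- impulseKernel()
  x <- seq(-2, 2, by = 0.1)
  d <- data.frame(position_mm = x, value = pmax(0, 1 - (x / 1.8)^2))
  res <- vanCittert(d, k)
  perfect <- validateForward(res, d, toleranceBand = 0.5)
  expect_equal(perfect$maxDeviationPct, 0, tolerance = 1e-8)
  expect_equal(perfect$fracInBand, 1)
  shifted <- d
  shifted$value <- d$value + 0.01 * max(d$value)
  off <- validateForward(res, shifted, toleranceBand = 0.5)
  expect_equal(off$meanDeviationPct, 1, tolerance = 0.02)
  expect_equal(off$fracInBand, 0)
})

test_that("settings are validated", {
  expect_error(deconvolutionSettings(relaxation = 0), "relaxation")
  expect_error(deconvolutionSettings(relaxation = 2.5), "relaxation")
  expect_error(deconvolutionSettings(maxIterations = 0), "maxIterations")
  expect_error(deconvolutionSettings(smoothingWindow = 4), "smoothingWindow")
})
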