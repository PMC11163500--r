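# Shared fixtures, all built in code.

# analytic lateral dose of a top-hat fluence (radius R) convolved with a
# 2D Gaussian: tail probability of a noncentral chi-square with 2 df.
# Independent of the package's grid convolution path.
diskGaussProfile <- function(r, R, sigma) {
  pchisq((R / sigma)^2, df = 2, ncp = (r / sigma)^2)
}

# brute-force 2D Riemann-sum convolution oracle at fine resolution; the
# source is evaluated with 5x5 sub-cell averaging so the oracle's own
# edge-pixelation error stays well below the comparison tolerance
riemannConvolve <- function(sourceFun, kernelFun, evalPoints, h = 0.02,
                            supportRadius = 2) {
  ax <- seq(-supportRadius, supportRadius, by = h)
  xs <- rep(ax, each = length(ax))
  ys <- rep(ax, times = length(ax))
  s <- 0
  off <- (seq_len(5L) - 3L) / 5L * h
  for (dx in off) for (dy in off)
    s <- s + sourceFun(sqrt((xs + dx)^2 + (ys + dy)^2))
  s <- s / 25
  keep <- s != 0
  xs <- xs[keep]; ys <- ys[keep]; s <- s[keep]
  vapply(evalPoints, function(p)
    sum(s * kernelFun(sqrt((p - xs)^2 + ys^2))) * h^2, numeric(1L))
}

gauss2d <- function(r, sigma) exp(-r^2 / (2 * sigma^2)) / (2 * pi * sigma^2)

# mirror a one-sided radial table (r, value) into a symmetric profile
mirrorProfile <- function(fl) {
  r <- fl[[1L]]; v <- fl[[2L]]
  data.frame(position_mm = c(-rev(r[-1L]), r), value = c(rev(v[-1L]), v))
}

# rectangle / trapezoid profiles with edges falling between samples so
# that linear interpolation localizes the crossings exactly
rectProfile <- function(width = 3, spacing = 0.1, halfWidth = 5) {
  x <- seq(-halfWidth, halfWidth, by = spacing) + spacing / 2
  data.frame(position_mm = x, value = as.numeric(abs(x) < width / 2) * 100)
}

trapezoidProfile <- function(plateau = 2, edge = 2, spacing = 0.1,
                             halfWidth = 6) {
  x <- seq(-halfWidth, halfWidth, by = spacing)
  v <- pmin(1, pmax(0, ((plateau / 2 + edge) - abs(x)) / edge)) * 100
  data.frame(position_mm = x, value = v)
}

gaussProfile <- function(sigma, spacing = 0.2, halfWidth = 6) {
  x <- seq(-halfWidth, halfWidth, by = spacing)
  data.frame(position_mm = x, value = 100 * exp(-x^2 / (2 * sigma^2)))
}

# flat-topped profile with error-function edges at +/- edgePos; the 20-80%
# distance of each edge is 1.683242 * sigmaEdge
erfProfile <- function(sigmaEdge, edgePos = 3, spacing = 0.05,
                       halfWidth = 8) {
  x <- seq(-halfWidth, halfWidth, by = spacing)
  v <- pnorm((edgePos - x) / sigmaEdge) - pnorm((-edgePos - x) / sigmaEdge)
  data.frame(position_mm = x, value = 100 * v)
}

# quadratic dose map D(r) = D0 (1 - c r^2) on a grid (closed-form disk mean)
quadraticMap <- function(D0 = 1, cc = 0.02, spacing = 0.1, halfWidth = 3) {
  hw <- as.integer(round(halfWidth / spacing))
  ax <- (-hw:hw) * spacing
  r2 <- outer(ax^2, ax^2, `+`)
  RadialDoseMap(pmax(D0 * (1 - cc * r2), 0), spacing)
}

flatMap <- function(level = 1, spacing = 0.1, halfWidth = 3) {
  hw <- as.integer(round(halfWidth / spacing))
  n <- 2L * hw + 1L
  RadialDoseMap(matrix(level, n, n), spacing)
}
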