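# Internal numerical helpers shared across modules.

# trapezoidal rule on possibly non-uniform x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# All generators are pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# linear interpolation returning 0 outside the sampled radial range
interpRadial <- function(r, values, rout) {
  stats::approx(r, values, xout = rout, rule = 2, yleft = values[1L],
                yright = 0)$y
}

# Rasterize a radial function (given as samples from r = 0) onto a square
# 2D grid of (2*halfCells + 1)^2 cells, by cell-center evaluation. Radii
# beyond the last sample map to 0. method "linear" keeps hat-basis
# functions exactly piecewise linear; "monoH.FC" (shape-preserving cubic)
# avoids the convexity bias of chords when rasterizing smooth kernels.
radialToGrid <- function(r, values, spacing, halfCells,
                         method = c("linear", "monoH.FC")) {
  method <- match.arg(method)
  ax <- (-halfCells:halfCells) * spacing
  rad <- sqrt(outer(ax^2, ax^2, `+`))
  rv <- as.vector(rad)
  if (method == "linear") {
    out <- interpRadial(r, values, rv)
  } else {
    sf <- stats::splinefun(r, values, method = "monoH.FC")
    out <- ifelse(rv > max(r), 0, pmax(sf(rv), 0))
  }
  matrix(out, nrow = length(ax))
}

# Rasterize an arbitrary radial function fun(r) with sub-cell averaging
# (anti-aliased edges): each cell value is the mean of fun over a
# subsample x subsample grid of points inside the cell.
rasterizeRadialFun <- function(fun, spacing, halfCells, subsample = 5L) {
  ax <- (-halfCells:halfCells) * spacing
  n <- length(ax)
  off <- (seq_len(subsample) - (subsample + 1) / 2) / subsample * spacing
  acc <- matrix(0, n, n)
  for (dx in off) for (dy in off) {
    rad <- sqrt(outer((ax + dx)^2, (ax + dy)^2, `+`))
    acc <- acc + matrix(fun(as.vector(rad)), n, n)
  }
  acc / subsample^2
}

# 2D linear convolution of equal-spacing grids via zero-padded FFT,
# scaled by spacing^2 (Riemann sum), cropped to the source grid centered
# on the kernel center. Kernel grid must be odd-sized.
convolve2dFFT <- function(S, K, spacing) {
  ns <- dim(S); nk <- dim(K)
  P1 <- stats::nextn(ns[1L] + nk[1L] - 1L, 2L)
  P2 <- stats::nextn(ns[2L] + nk[2L] - 1L, 2L)
  Sp <- matrix(0, P1, P2); Sp[seq_len(ns[1L]), seq_len(ns[2L])] <- S
  Kp <- matrix(0, P1, P2); Kp[seq_len(nk[1L]), seq_len(nk[2L])] <- K
  full <- Re(stats::fft(stats::fft(Sp) * stats::fft(Kp), inverse = TRUE)) /
    (P1 * P2)
  c1 <- (nk[1L] + 1L) %/% 2L; c2 <- (nk[2L] + 1L) %/% 2L
  full[c1:(c1 + ns[1L] - 1L), c2:(c2 + ns[2L] - 1L)] * spacing^2
}

# centered moving average with reflected ends; window must be odd
movingAverage <- function(y, window) {
  if (is.null(window) || window <= 1L) return(y)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  h <- (window - 1L) %/% 2L
  n <- length(y)
  ypad <- c(y[(h + 1L):2L], y, y[(n - 1L):(n - h)])
  stats::filter(ypad, rep(1 / window, window))[(h + 1L):(h + n)]
}

# k-th smallest element of each row of a matrix (vectorized selection)
rowOrderStat <- function(X, k) {
  n <- nrow(X)
  if (k > 1L) for (i in seq_len(k - 1L)) {
    j <- max.col(-X, ties.method = "first")
    X[cbind(seq_len(n), j)] <- Inf
  }
  do.call(pmin, as.data.frame(X))
}

# Exact area of intersection between a disk (center cx, cy, radius a) and
# axis-aligned rectangles [x1,x2] x [y1,y2]; vectorized over rectangles.
# Built from the signed quadrant primitive F(x, y) = area of the disk
# (centered at origin) intersected with [0,x] x [0,y].
diskRectOverlap <- function(cx, cy, a, x1, x2, y1, y2) {
  G <- function(t) 0.5 * (t * sqrt(pmax(a^2 - t^2, 0)) +
                          a^2 * asin(pmin(pmax(t / a, -1), 1)))
  Fq <- function(x, y) {
    sx <- sign(x); sy <- sign(y)
    x <- pmin(abs(x), a); y <- abs(y)
    t1 <- pmin(x, sqrt(pmax(a^2 - y^2, 0)))
    sx * sy * (y * t1 + G(x) - G(t1))
  }
  x1 <- x1 - cx; x2 <- x2 - cx; y1 <- y1 - cy; y2 <- y2 - cy
  Fq(x2, y2) - Fq(x1, y2) - Fq(x2, y1) + Fq(x1, y1)
}

# read/validate a two-column profile data.frame in various spellings
asProfileFrame <- function(profile, cols = c("position_mm", "value")) {
  if (!is.data.frame(profile) || ncol(profile) < 2L)
    stop("profile must be a data.frame with position and value columns")
  nm <- names(profile)
  pos <- if (cols[1L] %in% nm) profile[[cols[1L]]] else profile[[1L]]
  val <- if (cols[2L] %in% nm) profile[[cols[2L]]] else profile[[2L]]
  if (any(!is.finite(pos)) || any(!is.finite(val)))
    stop("profile contains non-finite entries")
  o <- order(pos)
  data.frame(position_mm = pos[o], value = val[o])
}
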