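# 3D point-pattern summary statistics: nearest-neighbour (G), empty-space
# (F) and Ripley (K) functions with edge correction, plus Monte-Carlo
# envelopes against complete spatial randomness.

#' Default distance grid for spatial summary functions
#'
#' 64 distances from 0 to one quarter of the shortest window side — a
#' standard guard against edge-dominated estimates at large r.
#'
#' @param window a [Box3D].
#' @param nr number of grid points.
#' @return increasing numeric vector of distances (\eqn{\mu m}) starting
#'   at 0.
#' @export
defaultRGrid <- function(window, nr = 64L) {
  rmax <- min(.boxSides(window)) / 4
  seq(0, rmax, length.out = nr)
}

.csrCdf <- function(r, lambda) 1 - exp(-lambda * (4 / 3) * pi * r^3)

# reduced-sample (border) estimate shared by G and F: distances d with
# border distances b, evaluated on grid r. A point contributes at r iff
# d <= r <= b, so the numerator is #\{d <= r\} - #\{b < r\} over points with
# d <= b; sorted counting makes each evaluation O(log n).
.reducedSample <- function(d, b, r, correction) {
  if (correction == "border") {
    m <- length(b)
    keep <- is.finite(d) & d <= b
    sd_ <- sort(d[keep])
    sbk <- sort(b[keep])
    sb <- sort(b)
    num <- findInterval(r, sd_) - findInterval(r, sbk, left.open = TRUE)
    den <- m - findInterval(r, sb, left.open = TRUE)
    ifelse(den > 0, num / den, NA_real_)
  } else {
    findInterval(r, sort(d[is.finite(d)])) / length(d)
  }
}

# exact truncated nearest-data-point distances on a regular m^3 lattice
# of cell-centred test sites: distances beyond 'cap' are reported as Inf
# (sufficient when the estimate is only evaluated at r <= cap)
.latticeEmptySpace <- function(xyz, window, m, cap) {
  lo <- .boxLower(window)
  sides <- .boxSides(window)
  u <- (seq_len(m) - 0.5) / m
  gx <- lo[1] + u * sides[1]
  gy <- lo[2] + u * sides[2]
  gz <- lo[3] + u * sides[3]
  d2 <- array(Inf, dim = c(m, m, m))
  for (j in seq_len(nrow(xyz))) {
    p <- xyz[j, ]
    ix <- which(abs(gx - p[1]) <= cap)
    iy <- which(abs(gy - p[2]) <= cap)
    iz <- which(abs(gz - p[3]) <= cap)
    if (!length(ix) || !length(iy) || !length(iz)) next
    sub <- outer(outer((gx[ix] - p[1])^2, (gy[iy] - p[2])^2, "+"),
                 (gz[iz] - p[3])^2, "+")
    d2[ix, iy, iz] <- pmin(d2[ix, iy, iz], sub)
  }
  bx <- pmin(gx - lo[1], lo[1] + sides[1] - gx)
  by <- pmin(gy - lo[2], lo[2] + sides[2] - gy)
  bz <- pmin(gz - lo[3], lo[3] + sides[3] - gz)
  b <- outer(outer(bx, by, pmin), bz, pmin)
  list(d = sqrt(as.vector(d2)), b = as.vector(b))
}

#' Nearest-neighbour distance distribution (G function)
#'
#' Estimates the cumulative distribution of the distance from a typical
#' point of the pattern to its nearest neighbour. The default border
#' (reduced-sample) correction lets a point contribute at distance r only
#' when its distance to the window boundary is at least r, removing the
#' censoring bias of unobserved neighbours outside the window. Under
#' complete spatial randomness,
#' \eqn{G(r) = 1 - \exp(-\lambda \frac{4}{3}\pi r^3)}.
#'
#' @param pattern a [PointPattern3D] with at least two points.
#' @param r distance grid (\eqn{\mu m}); default [defaultRGrid()].
#' @param correction \code{"border"} or \code{"none"}.
#' @return a [FunctionEstimate].
#' @examples
#' p <- generatePointPattern(csrProcess(0.5), cubeBox(125), seed = 3)
#' gFunction(p)
#' @export
gFunction <- function(pattern, r = NULL, correction = c("border", "none")) {
  stopifnot(is(pattern, "PointPattern3D"))
  correction <- match.arg(correction)
  n <- npoints(pattern)
  if (n < 2L) stop("G function needs at least 2 points")
  if (is.null(r)) r <- defaultRGrid(pattern@window)
  d <- .nnDistance(pattern@coords)
  b <- .borderDistance(pattern@coords, pattern@window)
  est <- .reducedSample(d, b, r, correction)
  lambda <- n / volume(pattern@window)
  new("FunctionEstimate", fun = "G", r = as.numeric(r), est = est,
      theo = .csrCdf(r, lambda), correction = correction, n = as.integer(n))
}

#' Empty-space function (F function)
#'
#' Estimates the distribution of the distance from an arbitrary location
#' of the window to the nearest point of the pattern, probing for holes
#' in the cloud of points. Test locations are a regular cell-centred
#' lattice by default (deterministic and reproducible) or uniform random
#' when \code{testPoints = "random"}. Border correction as in
#' [gFunction()]. Under complete spatial randomness F equals G:
#' \eqn{1 - \exp(-\lambda \frac{4}{3}\pi r^3)}.
#'
#' @param pattern a [PointPattern3D] with at least one point.
#' @param r distance grid; default [defaultRGrid()].
#' @param correction \code{"border"} or \code{"none"}.
#' @param testPoints \code{"lattice"} or \code{"random"}.
#' @param nTest test locations per axis for the lattice (default 32, i.e.
#'   32768 sites), or the total count for random locations.
#' @param seed seed for random test locations.
#' @return a [FunctionEstimate].
#' @export
fFunction <- function(pattern, r = NULL, correction = c("border", "none"),
                      testPoints = c("lattice", "random"), nTest = 32L,
                      seed = NULL) {
  stopifnot(is(pattern, "PointPattern3D"))
  correction <- match.arg(correction)
  testPoints <- match.arg(testPoints)
  n <- npoints(pattern)
  if (n < 1L) stop("F function needs at least 1 point")
  w <- pattern@window
  if (is.null(r)) r <- defaultRGrid(w)
  lo <- .boxLower(w)
  sides <- .boxSides(w)
  if (nTest < 1L) stop("zero test points")
  if (testPoints == "lattice") {
    es <- .latticeEmptySpace(pattern@coords, w, nTest,
                             cap = max(r) * (1 + 1e-9))
    d <- es$d
    b <- es$b
  } else {
    if (!is.null(seed)) set.seed(.checkSeed(seed))
    q <- cbind(stats::runif(nTest, lo[1], lo[1] + sides[1]),
               stats::runif(nTest, lo[2], lo[2] + sides[2]),
               stats::runif(nTest, lo[3], lo[3] + sides[3]))
    d <- .nearestDistance(q, pattern@coords)
    b <- .borderDistance(q, w)
  }
  est <- .reducedSample(d, b, r, correction)
  lambda <- n / volume(w)
  new("FunctionEstimate", fun = "F", r = as.numeric(r), est = est,
      theo = .csrCdf(r, lambda), correction = correction, n = as.integer(n))
}

#' Ripley's K function in 3D
#'
#' Estimates the reduced second moment function
#' \deqn{\hat K(r) = \frac{V}{n(n-1)} \sum_{i \ne j} 1[d_{ij} \le r]\, e_{ij},}
#' with the translation edge correction
#' \eqn{e_{ij} = V / V(W \cap W_{x_j - x_i})} — for a box window the
#' overlap volume is the product of \eqn{(L_a - |\Delta_a|)} over the
#' axes — or no correction. Under complete spatial randomness
#' \eqn{K(r) = \frac{4}{3}\pi r^3}.
#'
#' @param pattern a [PointPattern3D] with at least two points.
#' @param r distance grid; default [defaultRGrid()].
#' @param correction \code{"translation"} or \code{"none"}.
#' @return a [FunctionEstimate].
#' @export
kFunction <- function(pattern, r = NULL,
                      correction = c("translation", "none")) {
  stopifnot(is(pattern, "PointPattern3D"))
  correction <- match.arg(correction)
  n <- npoints(pattern)
  if (n < 2L) stop("K function needs at least 2 points")
  w <- pattern@window
  if (is.null(r)) r <- defaultRGrid(w)
  V <- volume(w)
  sides <- .boxSides(w)
  xyz <- pattern@coords
  d2 <- .crossDist2(xyz, xyz)
  pair <- upper.tri(d2)
  d <- sqrt(d2[pair])
  if (correction == "translation") {
    dx <- abs(outer(xyz[, 1], xyz[, 1], "-"))[pair]
    dy <- abs(outer(xyz[, 2], xyz[, 2], "-"))[pair]
    dz <- abs(outer(xyz[, 3], xyz[, 3], "-"))[pair]
    ov <- (sides[1] - dx) * (sides[2] - dy) * (sides[3] - dz)
    wgt <- V / ov
  } else {
    wgt <- rep(1, length(d))
  }
  ord <- order(d)
  d <- d[ord]
  cw <- cumsum(wgt[ord])
  # each unordered pair contributes twice to the double sum
  idx <- findInterval(r, d)
  est <- 2 * ifelse(idx > 0, cw[pmax(idx, 1L)], 0) * V / (n * (n - 1))
  est[idx == 0L] <- 0
  new("FunctionEstimate", fun = "K", r = as.numeric(r), est = est,
      theo = (4 / 3) * pi * r^3, correction = correction, n = as.integer(n))
}

.estimateOn <- function(fn, pattern, r, nTestF = 32L) {
  switch(fn,
         G = gFunction(pattern, r),
         F = fFunction(pattern, r, nTest = nTestF),
         K = kFunction(pattern, r))
}

#' Monte-Carlo envelope test against complete spatial randomness
#'
#' Tests whether a pattern is compatible with complete spatial
#' randomness: the selected summary functions (G, F and K by default)
#' are estimated for the observed pattern and for \code{nsim} CSR
#' simulations with the observed number of points in the observed window
#' (Poisson counts by flag), and pointwise minimum/maximum envelopes are
#' formed. The pattern is classified \code{"random"} when every selected
#' function lies within its envelope at every distance; \code{"clustered"}
#' when every breach carries the clustering signature (G above, F below,
#' K above the envelope); \code{"regular"} for the opposite signature;
#' \code{"mixed"} otherwise. Patterns with fewer points than
#' \code{minPoints} are refused, mirroring the usual exclusion of samples
#' too small for spatial inference.
#'
#' @param pattern a [PointPattern3D].
#' @param nsim number of CSR simulations (default 100, giving a pointwise
#'   rank-1 envelope).
#' @param functions subset of \code{c("G", "F", "K")}.
#' @param seed integer seed driving all simulations.
#' @param r distance grid shared by observed and simulated curves.
#' @param minPoints smallest admissible pattern (default 25).
#' @param fixedCount simulate with exactly the observed n (default TRUE);
#'   otherwise Poisson counts at the estimated intensity.
#' @param nTestF empty-space test sites per axis for the F estimates.
#'
#' @details Below the spacing of the F test-site lattice the empirical
#' empty-space function is quantized to a handful of sites and its rank
#' among simulations is meaningless, so F breaches at distances smaller
#' than one lattice spacing are not used for the classification (they are
#' still reported in the curves).
#' @return an [EnvelopeResult].
#' @examples
#' p <- generatePointPattern(csrProcess(0.3), cubeBox(200), seed = 11)
#' e <- envelopeTest(p, nsim = 19, seed = 1)
#' verdict(e)
#' @export
envelopeTest <- function(pattern, nsim = 100L, functions = c("G", "F", "K"),
                         seed, r = NULL, minPoints = 25L,
                         fixedCount = TRUE, nTestF = 32L) {
  stopifnot(is(pattern, "PointPattern3D"))
  functions <- match.arg(functions, c("G", "F", "K"), several.ok = TRUE)
  n <- npoints(pattern)
  if (n < minPoints)
    stop(sprintf("too few points for an envelope test: n = %d < %d",
                 n, minPoints))
  seed <- .checkSeed(seed)
  w <- pattern@window
  if (is.null(r)) r <- defaultRGrid(w)
  lambda <- n / volume(w)

  obs <- lapply(functions, .estimateOn, pattern = pattern, r = r,
                nTestF = nTestF)
  names(obs) <- functions
  fResolution <- max(.boxSides(w)) / nTestF

  sims <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    sp <- generatePointPattern(csrProcess(lambda), w,
                               seed = .childSeed(seed, i),
                               nFixed = if (fixedCount) n else NULL)
    while (npoints(sp) < 2L) {
      # Poisson draws can come up degenerate; redraw deterministically
      sp <- generatePointPattern(csrProcess(lambda), w,
                                 seed = .childSeed(seed, i + 7919L * nsim),
                                 nFixed = max(2L, npoints(sp) + 1L))
    }
    sims[[i]] <- lapply(functions, .estimateOn, pattern = sp, r = r,
                        nTestF = nTestF)
    names(sims[[i]]) <- functions
  }

  curves <- list()
  directions <- character(0)
  for (fn in functions) {
    mat <- vapply(sims, function(s) s[[fn]]@est, numeric(length(r)))
    lo <- apply(mat, 1L, min, na.rm = FALSE)
    hi <- apply(mat, 1L, max, na.rm = FALSE)
    o <- obs[[fn]]@est
    tol <- 1e-12
    bh <- !is.na(o) & !is.na(hi) & o > hi + tol
    bl <- !is.na(o) & !is.na(lo) & o < lo - tol
    curves[[fn]] <- data.frame(r = r, obs = o, lo = lo, hi = hi,
                               breach_high = bh, breach_low = bl)
    use <- if (fn == "F") r >= fResolution else rep(TRUE, length(r))
    if (any(bh & use)) directions <- c(directions, paste0(fn, "_high"))
    if (any(bl & use)) directions <- c(directions, paste0(fn, "_low"))
  }

  clusteredDirs <- c("G_high", "F_low", "K_high")
  regularDirs <- c("G_low", "F_high", "K_low")
  verdict <- if (length(directions) == 0L) "random"
             else if (all(directions %in% clusteredDirs)) "clustered"
             else if (all(directions %in% regularDirs)) "regular"
             else "mixed"

  new("EnvelopeResult", verdict = verdict, curves = curves,
      nsim = as.integer(nsim), n = as.integer(n))
}
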