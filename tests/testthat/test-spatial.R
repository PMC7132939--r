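test_that("G, F and K reproduce their brute-force oracles exactly", {
  for (s in c(3, 17, 401)) {
    p <- generatePointPattern(csrProcess(0.4), cubeBox(100), seed = s,
                              nFixed = 40)
    w <- spatialWindow(p)
    r <- defaultRGrid(w, nr = 24L)
    xyz <- coords(p)

    for (corr in c("border", "none")) {
      g <- gFunction(p, r, correction = corr)
      expect_equal(g@est, bruteG(xyz, w, r, corr), tolerance = 1e-12)
    }
    f <- fFunction(p, r, nTest = 8L)
    expect_equal(f@est, bruteF(xyz, w, r, m = 8L), tolerance = 1e-12)
    for (corr in c("translation", "none")) {
      k <- kFunction(p, r, correction = corr)
      expect_equal(k@est, bruteK(xyz, w, r, corr), tolerance = 1e-10)
    }
  }
})

test_that("two points give a G step at their separation (uncorrected)", {
  w <- Box3D(c(0, 10), c(0, 10), c(0, 10))
  p <- PointPattern3D(rbind(c(2, 5, 5), c(6, 5, 5)), w)  # d = 4
  g <- gFunction(p, r = c(0, 1, 3.9, 4, 5), correction = "none")
  expect_equal(g@est, c(0, 0, 0, 1, 1))
})

test_that("border correction is a no-op away from the boundary", {
  w <- Box3D(c(0, 20), c(0, 20), c(0, 20))
  set.seed(8)
  inner <- matrix(runif(90, 9, 11), ncol = 3)   # all >= 9 from every face
  p <- PointPattern3D(inner, w)
  r <- seq(0, 2, length.out = 16)
  expect_equal(gFunction(p, r, "border")@est, gFunction(p, r, "none")@est)
})

test_that("F probes empty space from test sites; F(0) = 0", {
  w <- Box3D(c(0, 4), c(0, 4), c(0, 4))
  p <- PointPattern3D(rbind(c(2, 2, 2)), w)
  r <- seq(0, 1, length.out = 9)
  f <- fFunction(p, r, correction = "none", nTest = 8L)
  # brute force: fraction of the 8^3 lattice within r of the single point
  u <- (seq_len(8) - 0.5) / 8 * 4
  q <- as.matrix(expand.grid(u, u, u))
  d <- sqrt(colSums((t(q) - c(2, 2, 2))^2))
  expect_equal(f@est, sapply(r, function(ri) mean(d <= ri)))
  expect_identical(f@est[1], 0)
  expect_error(fFunction(p, r, nTest = 0L), "test points")
})

test_that("estimates respect their range and monotonicity constraints", {
  for (s in 1:5) {
    p <- generatePointPattern(csrProcess(0.3), cubeBox(150), seed = 100 + s)
    if (npoints(p) < 2) next
    r <- defaultRGrid(spatialWindow(p))
    g <- gFunction(p, r, "none")
    f <- fFunction(p, r, correction = "none")
    k <- kFunction(p, r)
    expect_true(all(g@est >= 0 & g@est <= 1))
    expect_true(all(f@est >= 0 & f@est <= 1))
    expect_true(all(diff(g@est) >= 0))   # uncorrected G is an ecdf
    expect_true(all(diff(f@est) >= 0))
    expect_true(all(k@est >= 0))
    expect_true(all(diff(k@est) >= -1e-12))
    gb <- gFunction(p, r, "border")@est
    expect_true(all(gb[is.finite(gb)] >= 0 & gb[is.finite(gb)] <= 1))
  }
})

test_that("K is invariant under translation and axis permutation", {
  p <- generatePointPattern(csrProcess(0.5), cubeBox(64), seed = 21,
                            nFixed = 30)
  w <- spatialWindow(p)
  r <- defaultRGrid(w, nr = 16L)
  k0 <- kFunction(p, r)@est

  shift <- c(3, -2, 7)
  wS <- Box3D(w@xrange + shift[1], w@yrange + shift[2], w@zrange + shift[3])
  pS <- PointPattern3D(sweep(coords(p), 2, shift, "+"), wS)
  expect_equal(kFunction(pS, r)@est, k0, tolerance = 1e-12)

  pP <- PointPattern3D(coords(p)[, c(3, 1, 2)], w)  # cube: window unchanged
  expect_equal(kFunction(pP, r)@est, k0, tolerance = 1e-12)
})

test_that("small patterns are refused where the estimator is undefined", {
  w <- cubeBox(27)
  p1 <- PointPattern3D(rbind(c(1, 1, 1)), w)
  expect_error(gFunction(p1), "at least 2")
  expect_error(kFunction(p1), "at least 2")
  p10 <- generatePointPattern(csrProcess(1), w, seed = 2, nFixed = 10)
  expect_error(envelopeTest(p10, seed = 1), "too few points")
})

test_that("envelope testing is deterministic and reports its curves", {
  p <- generatePointPattern(csrProcess(0.3), cubeBox(200), seed = 31,
                            nFixed = 50)
  e1 <- envelopeTest(p, nsim = 19, seed = 7)
  e2 <- envelopeTest(p, nsim = 19, seed = 7)
  expect_identical(verdict(e1), verdict(e2))
  expect_identical(envelopeCurves(e1), envelopeCurves(e2))
  expect_named(envelopeCurves(e1), c("G", "F", "K"))
  cv <- envelopeCurves(e1)$K
  expect_true(all(cv$lo <= cv$hi, na.rm = TRUE))

  # a blatantly clustered pattern is flagged as clustered
  pc <- generatePointPattern(thomasProcess(0.02, 12, 0.25), cubeBox(277.23),
                             seed = 5)
  expect_gte(npoints(pc), 25)
  expect_identical(verdict(envelopeTest(pc, nsim = 99, seed = 13)),
                   "clustered")
})
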