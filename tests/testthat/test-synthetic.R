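test_that("CSR generation is deterministic and hits the target intensity", {
  w <- cubeBox(277.23)
  spec <- csrProcess(0.21)

  p1 <- generatePointPattern(spec, w, seed = 42)
  p2 <- generatePointPattern(spec, w, seed = 42)
  expect_identical(coords(p1), coords(p2))
  xy <- coords(p1)
  expect_true(all(xy >= 0 & xy <= 277.23^(1 / 3)))

  # pooled empirical intensity converges to lambda (E[N] = lambda * V)
  total <- 0
  nrep <- 1800L
  for (s in seq_len(nrep))
    total <- total + npoints(generatePointPattern(spec, w, seed = s))
  expect_gt(total, 1e5)
  empirical <- total / (nrep * volume(w))
  expect_lt(abs(empirical - 0.21) / 0.21, 0.02)

  # fixed-count variant produces exactly n points
  pf <- generatePointPattern(spec, w, seed = 9, nFixed = 58)
  expect_identical(npoints(pf), 58L)
})

test_that("Thomas process matches its effective intensity and overdisperses", {
  w <- cubeBox(277.23)
  spec <- thomasProcess(0.02, 10, clusterSd = 0.4)
  expect_equal(spec@intensity, 0.2)

  counts <- vapply(seq_len(1000L), function(s)
    npoints(generatePointPattern(spec, w, seed = s)), numeric(1))
  expected <- 0.2 * volume(w)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.5)

  # clustered counts are overdispersed relative to Poisson; CSR is not
  csrCounts <- vapply(seq_len(500L), function(s)
    npoints(generatePointPattern(csrProcess(0.2), w, seed = 10000 + s)),
    numeric(1))
  expect_gt(var(counts) / mean(counts), 2)
  expect_lt(abs(var(csrCounts) / mean(csrCounts) - 1), 0.25)
})

test_that("degenerate or invalid process specifications are rejected", {
  expect_error(csrProcess(0), "intensity")
  expect_error(csrProcess(-1), "intensity")
  expect_error(thomasProcess(0.1, 5, clusterSd = 0), "cluster_sd")
  expect_error(Box3D(c(0, 0), c(0, 1), c(0, 1)), "increasing")
  expect_error(generatePointPattern(csrProcess(1), "not a box", seed = 1))
})

test_that("catalog generation reproduces its ground-truth marginals", {
  # one very large stack so the law of large numbers bites
  spec <- catalogSpec(nStacks = 1L, windowVolumes = 1e5 / 0.21,
                      layers = "III")
  cat1 <- generateCatalog(spec, csrProcess(0.21), seed = 11)
  tab <- mvbTable(cat1)
  n <- nrow(tab)
  expect_gt(n, 9e4)

  probs <- groundTruth(cat1)$compartmentProbs
  for (cmp in names(probs))
    expect_lt(abs(mean(tab$compartment == cmp) - probs[[cmp]]), 0.01)

  # log-normal volumes: median and log-scale normality
  expect_lt(abs(median(tab$volume_um3) - exp(-5.1375)) / exp(-5.1375), 0.03)
  lg <- log(tab$volume_um3)
  g1 <- mean((lg - mean(lg))^3) / sd(lg)^3
  expect_lt(abs(g1), 0.05)

  # flag marginals
  fp <- groundTruth(cat1)$flagProbs
  expect_lt(abs(mean(tab$docked) - fp[["docked"]]), 0.01)
  expect_lt(abs(mean(tab$tubules) - fp[["tubules"]]), 0.01)
  expect_lt(abs(mean(tab$clathrin) - fp[["clathrin"]]), 0.01)
})

test_that("catalog generation is deterministic and validates its spec", {
  spec <- catalogSpec(nStacks = 3L, layers = c("I", "II", "III"))
  c1 <- generateCatalog(spec, csrProcess(0.21), seed = 5)
  c2 <- generateCatalog(spec, csrProcess(0.21), seed = 5)
  expect_identical(mvbTable(c1), mvbTable(c2))

  # zero flag probabilities give no flagged rows
  spec0 <- catalogSpec(nStacks = 2L, layers = c("I", "II"),
                       flagProbs = c(docked = 0, tubules = 0, clathrin = 0))
  tab0 <- mvbTable(generateCatalog(spec0, csrProcess(0.21), seed = 3))
  expect_false(any(tab0$docked | tab0$tubules | tab0$clathrin))

  # probability vectors must sum to one
  expect_error(
    catalogSpec(nStacks = 1L, layers = "I",
                compartmentProbs = c(dendrite = 0.5, excitatory_axon = 0.2,
                                     inhibitory_axon = 0.1,
                                     nonsynaptic = 0.1)),
    "sum to 1")
})

test_that("stack layout of the default catalog matches the study design", {
  spec <- catalogSpec()
  expect_identical(spec@nStacks, 29L)
  expect_identical(as.integer(table(spec@layers)[c("I", "II", "III", "IV",
                                                   "V", "VI")]),
                   c(3L, 4L, 10L, 5L, 3L, 4L))
  expect_equal(spec@windowVolumeRange, c(167.39, 444.11))
})
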