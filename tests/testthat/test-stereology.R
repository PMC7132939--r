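test_that("the brick rule counts inclusion faces and rejects exclusion faces", {
  fr <- countingFrame(Box3D(c(1, 3), c(1, 3), c(1, 3)))
  expect_identical(countInFrame(rbind(c(2, 2, 2)), fr), 1L)
  # on an inclusion (lower) face: counted
  expect_identical(countInFrame(rbind(c(1, 2, 2)), fr), 1L)
  expect_identical(countInFrame(rbind(c(1, 1, 1)), fr), 1L)
  # exactly on an exclusion (upper) plane: not counted
  expect_identical(countInFrame(rbind(c(3, 2, 2)), fr), 0L)
  expect_identical(countInFrame(rbind(c(2, 2, 3)), fr), 0L)
  # outside entirely
  expect_identical(countInFrame(rbind(c(0.5, 2, 2)), fr), 0L)

  # with the opposite corner convention the rule mirrors
  fru <- countingFrame(Box3D(c(1, 3), c(1, 3), c(1, 3)), inclusion = "upper")
  expect_identical(countInFrame(rbind(c(3, 2, 2)), fru), 1L)
  expect_identical(countInFrame(rbind(c(1, 2, 2)), fru), 0L)

  # a frame outside the pattern's window is refused
  w <- cubeBox(8)
  p <- generatePointPattern(csrProcess(1), w, seed = 1)
  expect_error(countInFrame(p, countingFrame(Box3D(c(-1, 1), c(0, 1), c(0, 1)))),
               "outside")
})

test_that("frame counting is translation-unbiased under CSR", {
  w <- Box3D(c(0, 5), c(0, 5), c(0, 5))
  fr <- countingFrame(Box3D(c(0.5, 4.5), c(0.5, 4.5), c(0.5, 4.5)))
  lam <- 0.2
  counts <- vapply(seq_len(1000L), function(s)
    countInFrame(generatePointPattern(csrProcess(lam), w, seed = s), fr),
    integer(1))
  dens <- counts / volume(fr)
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - lam), 2 * se + 1e-3)
})

test_that("density estimation divides counts by frame volume and aggregates", {
  # printed-style arithmetic: 58 objects in 277.23 um^3
  tab <- data.frame(id = 1:58, x_um = runif(58, 0, 6), y_um = runif(58, 0, 6),
                    z_um = runif(58, 0, 6), volume_um3 = rep(1e-3, 58),
                    layer = "IV", compartment = "dendrite", docked = FALSE,
                    tubules = FALSE, clathrin = FALSE, stack_id = "s1")
  cat1 <- MVBCatalog(table = tab,
                     windows = list(s1 = cubeBox(277.23)))
  d <- estimateDensity(cat1)
  expect_equal(round(d$density, 4), 0.2092)

  # zero count gives zero density
  far <- tab[1, ]
  far$x_um <- far$y_um <- far$z_um <- 20   # outside the frame below
  cat0 <- MVBCatalog(table = far, windows = list(s1 = cubeBox(27000)))
  d0 <- estimateDensity(cat0, frames = list(s1 = countingFrame(cubeBox(8))))
  expect_equal(d0$density, 0)

  # aggregation identities: pooling over stacks is the plain mean
  spec <- catalogSpec(nStacks = 6L,
                      layers = c("I", "I", "II", "II", "III", "III"))
  cat6 <- generateCatalog(spec, csrProcess(0.21), seed = 17)
  per <- estimateDensity(cat6)
  agg <- aggregateDensity(per, across = "stacks")
  expect_equal(agg$mean, mean(per$density))
  expect_equal(agg$mean, sum(per$density) / nrow(per))
  aggL <- aggregateDensity(per, across = "layers")
  expect_equal(aggL$mean, mean(aggL$layers$mean))
  expect_identical(nrow(aggL$layers), 3L)
})

test_that("shrinkage correction propagates into frame volumes", {
  tab <- data.frame(id = 1:10, x_um = runif(10, 0, 2), y_um = runif(10, 0, 2),
                    z_um = runif(10, 0, 2), volume_um3 = rep(1e-3, 10),
                    layer = "I", compartment = "dendrite", docked = FALSE,
                    tubules = FALSE, clathrin = FALSE, stack_id = "s1")
  cat1 <- MVBCatalog(table = tab, windows = list(s1 = cubeBox(8)))
  plain <- estimateDensity(cat1)
  corr <- estimateDensity(cat1, correction = shrinkageFactors(0.9, 0.81, 0.73))
  expect_equal(corr$frame_volume_um3, plain$frame_volume_um3 / 0.73)
  expect_equal(corr$density, plain$density * 0.73)
})

test_that("Cavalieri fractions are exact on degenerate stacks", {
  g <- StackGeometry(c(32, 32, 16), c(20, 20, 20))
  all1 <- VoxelStack(labels = array(1L, c(32, 32, 16)), geometry = g)
  gr <- cavalieriGrid(spacing = 80, sectionStep = 4L)
  expect_equal(cavalieriVolumeFraction(all1, gr, target = 1L)$fraction, 1)

  # lower half target in z: fraction 1/2 within one grid cell
  half <- array(0L, c(32, 32, 16))
  half[, , 1:8] <- 1L
  sth <- VoxelStack(labels = half, geometry = g)
  f <- cavalieriVolumeFraction(sth, cavalieriGrid(80, 1L), target = 1L)
  expect_lt(abs(f$fraction - 0.5), 1 / 16)

  # spacing equal to the voxel size and every section: exact voxel fraction
  fx <- cavalieriVolumeFraction(sth, cavalieriGrid(20, 1L), target = 1L)
  expect_equal(fx$fraction, mean(half == 1L))

  expect_error(cavalieriVolumeFraction(all1, cavalieriGrid(10, 1L), 1L),
               "spacing")
  expect_error(cavalieriVolumeFraction(all1, gr, target = 1L, reference = 5L),
               "zero reference")
})

test_that("the associated area is the squared grid constant", {
  # a 632 nm grid carries about 4e5 nm^2 per point (632^2 = 399424)
  expect_equal(associatedArea(cavalieriGrid(632, 40L)), 399424)
  expect_error(cavalieriGrid(-1), "positive")
})
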