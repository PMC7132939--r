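test_that("volumes and centroids follow the anisotropic voxel geometry", {
  # one voxel of 4 x 4 x 20 nm has volume 320 nm^3 = 3.2e-7 um^3
  a <- array(0L, c(4, 4, 4))
  a[2, 3, 1] <- 1L
  st <- VoxelStack(labels = a,
                   geometry = StackGeometry(c(4, 4, 4), c(4, 4, 20)))
  m <- measureObjects(st)
  expect_equal(m$volume_um3, 3.2e-7)
  expect_equal(m$voxel_count, 1L)
  # centroid at the voxel center, in um
  expect_equal(c(m$x_um, m$y_um, m$z_um),
               c(1.5 * 4, 2.5 * 4, 0.5 * 20) / 1000)

  # two disjoint labels give two records with independent centroids
  a[4, 1, 3] <- 2L
  st2 <- VoxelStack(labels = a,
                    geometry = StackGeometry(c(4, 4, 4), c(4, 4, 20)))
  m2 <- measureObjects(st2)
  expect_identical(m2$id, c(1L, 2L))
  expect_equal(m2$x_um[2], 3.5 * 4 / 1000)

  # empty stack: empty table, not an error
  empty <- VoxelStack(labels = array(0L, c(3, 3, 3)),
                      geometry = StackGeometry(c(3, 3, 3), c(10, 10, 10)))
  expect_identical(nrow(measureObjects(empty)), 0L)
})

test_that("a digitized sphere recovers its analytic volume within 5%", {
  st <- sphereStack(radiusVox = 10, voxNm = c(20, 20, 20))
  m <- measureObjects(st)
  analytic <- (4 / 3) * pi * (10 * 20)^3 / 1e9   # um^3
  expect_lt(abs(m$volume_um3 - analytic) / analytic, 0.05)
})

test_that("voxel counts are conserved and axis permutation is neutral", {
  set.seed(1)
  a <- array(sample(0:3, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  st <- VoxelStack(labels = a,
                   geometry = StackGeometry(c(6, 5, 4), c(4, 5, 20)))
  m <- measureObjects(st)
  expect_identical(sum(m$voxel_count) + sum(a == 0L), length(a))

  # permuted axes with permuted voxel sizes give identical volumes
  ap <- aperm(a, c(3, 1, 2))
  stp <- VoxelStack(labels = ap,
                    geometry = StackGeometry(dim(ap), c(20, 4, 5)))
  mp <- measureObjects(stp)
  expect_equal(mp$volume_um3, m$volume_um3)
})

test_that("shrinkage factors derive coherently and correct by division", {
  f <- shrinkageFactors(linear = 0.90)
  expect_equal(f@area, 0.81)
  expect_equal(f@volume, 0.729)
  # the printed study factors (0.73 is the rounded cube of 0.90)
  fp <- shrinkageFactors(0.90, 0.81, 0.73)
  expect_equal(round(f@volume, 2), fp@volume)

  expect_equal(applyShrinkage(5, "linear", shrinkageFactors(1, 1, 1)), 5)
  expect_equal(applyShrinkage(0.73, "volume", fp), 1.00)
  expect_error(shrinkageFactors(linear = 0), "in \\(0, 1\\]")
  expect_error(shrinkageFactors(linear = 0.9, area = 0.5), "inconsistent")

  m <- measureObjects(sphereStack(5), correction = fp)
  m0 <- measureObjects(sphereStack(5))
  expect_equal(m$volume_um3, m0$volume_um3 / 0.73)
})

test_that("rendering a catalog then measuring it recovers the volumes", {
  mk <- function(voxNm) {
    side <- 128 * voxNm / 1000
    tab <- data.frame(id = 1L, x_um = side / 2, y_um = side / 2,
                      z_um = side / 2, volume_um3 = 8.8e-3, layer = "III",
                      compartment = "dendrite", docked = FALSE,
                      tubules = FALSE, clathrin = FALSE, stack_id = "s1")
    g <- StackGeometry(c(128, 128, 128), rep(voxNm, 3))
    st <- renderLabelStack(MVBCatalog(table = tab), g, seed = 1)
    abs(measureObjects(st)$volume_um3 - 8.8e-3) / 8.8e-3
  }
  errs <- c(mk(80), mk(20), mk(5))
  expect_lt(errs[2], 0.05)          # nominal resolution within 5%
  expect_true(all(diff(errs) < 0))  # error shrinks with voxel size
})

test_that("rendering is deterministic and resolves overlaps by lower ID", {
  g <- StackGeometry(c(64, 64, 32), c(20, 20, 20))
  tab <- data.frame(id = c(2L, 7L),
                    x_um = c(0.60, 0.64), y_um = c(0.64, 0.64),
                    z_um = c(0.32, 0.32),
                    volume_um3 = rep(8.8e-3, 2), layer = "I",
                    compartment = "nonsynaptic", docked = FALSE,
                    tubules = FALSE, clathrin = FALSE, stack_id = "s1")
  cat2 <- MVBCatalog(table = tab)
  s1 <- renderLabelStack(cat2, g, seed = 4)
  s2 <- renderLabelStack(cat2, g, seed = 4)
  expect_identical(objectLabels(s1), objectLabels(s2))

  lab <- objectLabels(s1)
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), c(2L, 7L))
  # the overlap region belongs to the lower ID: centre voxel between them
  expect_identical(lab[31, 32, 16], 2L)

  # empty catalog renders pure background
  e <- renderLabelStack(MVBCatalog(table = tab[0, ]), g, seed = 1)
  expect_true(all(objectLabels(e) == 0L))
  expect_true(all(compartmentArray(e) > 0L))

  # an object bigger than the stack is refused
  big <- tab[1, ]
  big$volume_um3 <- 10
  expect_error(renderLabelStack(MVBCatalog(table = big), g, seed = 1),
               "out of bounds|outside")
})

test_that("tubule-flagged objects grow a protrusion that adds volume", {
  g <- StackGeometry(c(96, 96, 96), c(10, 10, 10))
  base <- data.frame(id = 1L, x_um = 0.48, y_um = 0.48, z_um = 0.48,
                     volume_um3 = 4e-3, layer = "I",
                     compartment = "dendrite", docked = FALSE,
                     tubules = FALSE, clathrin = FALSE, stack_id = "s1")
  withTub <- base
  withTub$tubules <- TRUE
  vPlain <- sum(objectLabels(
    renderLabelStack(MVBCatalog(table = base), g, seed = 2)) == 1L)
  vTub <- sum(objectLabels(
    renderLabelStack(MVBCatalog(table = withTub), g, seed = 2)) == 1L)
  expect_gt(vTub, vPlain)
})
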