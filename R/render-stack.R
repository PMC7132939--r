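#' Rasterize a catalog into a labeled voxel phantom
#'
#' Renders each cataloged object into a 3D integer label stack so that
#' the voxel-based stages (morphometry, Cavalieri point counting) can be
#' exercised end-to-end against known ground truth. Every object is drawn
#' as a sphere in physical space (an ellipsoid in anisotropic voxel
#' space) whose radius reproduces its catalog volume; objects flagged
#' with tubular protrusions additionally get a cylindrical protrusion
#' (radius 0.35 r, length 2 r) pointing along a seeded axis direction.
#' Overlaps are resolved deterministically: the lower object ID wins.
#' The background is partitioned into compartment slabs along x in
#' proportion to the catalog's ground-truth compartment probabilities
#' (all background is "nonsynaptic" when no ground truth is recorded).
#'
#' @param catalog an [MVBCatalog]; multi-stack catalogs need
#'   \code{stackId}. Centroid coordinates are interpreted in the
#'   geometry's physical frame and must lie inside it.
#' @param geom a [StackGeometry].
#' @param seed integer seed (governs tubule directions); identical
#'   catalog, geometry and seed give a bit-identical stack.
#' @param stackId which stack of a multi-stack catalog to render.
#' @return a [VoxelStack] with object labels, a compartment raster and
#'   the geometry.
#' @examples
#' g <- StackGeometry(c(64, 64, 32), voxelSize = c(20, 20, 20))
#' tab <- data.frame(id = 1L, x_um = 0.6, y_um = 0.6, z_um = 0.3,
#'                   volume_um3 = 8.8e-3, layer = "III",
#'                   compartment = "dendrite", docked = FALSE,
#'                   tubules = FALSE, clathrin = FALSE, stack_id = "s1")
#' st <- renderLabelStack(MVBCatalog(table = tab), g, seed = 1)
#' sum(objectLabels(st) == 1L)
#' @export
renderLabelStack <- function(catalog, geom, seed, stackId = NULL) {
  stopifnot(is(catalog, "MVBCatalog"), is(geom, "StackGeometry"))
  validObject(geom)
  seed <- .checkSeed(seed)
  tab <- catalog@table
  if (!is.null(stackId)) tab <- tab[tab$stack_id == stackId, , drop = FALSE]
  if (length(unique(tab$stack_id)) > 1L)
    stop("catalog has several stacks; give 'stackId'")

  shp <- geom@shape
  vs_um <- geom@voxelSize / 1000          # um per voxel
  ext <- as.numeric(shp) * vs_um          # physical size, um
  lower <- geom@origin
  upper <- lower + ext

  labels <- array(0L, dim = shp)

  if (nrow(tab)) {
    cen <- as.matrix(tab[, c("x_um", "y_um", "z_um")])
    inside <- cen[, 1] >= lower[1] & cen[, 1] <= upper[1] &
              cen[, 2] >= lower[2] & cen[, 2] <= upper[2] &
              cen[, 3] >= lower[3] & cen[, 3] <= upper[3]
    if (!all(inside))
      stop("catalog centroids lie outside the stack geometry")
    radii <- (3 * tab$volume_um3 / (4 * pi))^(1 / 3)
    if (any(2 * radii > min(ext)))
      stop("object larger than the stack: out of bounds")

    set.seed(seed)
    dirs <- sample(1:6, nrow(tab), replace = TRUE)  # +-x, +-y, +-z

    ord <- order(tab$id)                  # ascending ID: lower ID wins
    for (k in ord) {
      r <- radii[k]
      c0 <- cen[k, ] - lower              # stack-local um
      reach <- if (tab$tubules[k]) 3 * r else r
      # voxel index range touched by the object
      i0 <- pmax(1L, floor((c0 - reach) / vs_um) + 1L)
      i1 <- pmin(as.integer(shp), ceiling((c0 + reach) / vs_um))
      if (any(i0 > i1)) next
      ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
      # voxel-center offsets from the centroid, um
      dx <- (ix - 0.5) * vs_um[1] - c0[1]
      dy <- (iy - 0.5) * vs_um[2] - c0[2]
      dz <- (iz - 0.5) * vs_um[3] - c0[3]
      DX <- array(dx, dim = c(length(ix), length(iy), length(iz)))
      DY <- aperm(array(dy, dim = c(length(iy), length(ix), length(iz))),
                  c(2, 1, 3))
      DZ <- aperm(array(dz, dim = c(length(iz), length(ix), length(iy))),
                  c(2, 3, 1))
      mask <- DX^2 + DY^2 + DZ^2 <= r^2
      if (tab$tubules[k]) {
        ax <- c(1L, 1L, 2L, 2L, 3L, 3L)[dirs[k]]
        sgn <- c(1, -1, 1, -1, 1, -1)[dirs[k]]
        axial <- switch(ax, DX, DY, DZ) * sgn
        rad2 <- DX^2 + DY^2 + DZ^2 - axial^2
        mask <- mask | (axial >= 0 & axial <= 3 * r & rad2 <= (0.35 * r)^2)
      }
      sub <- labels[ix, iy, iz, drop = FALSE]
      write <- mask & sub == 0L
      if (any(write)) {
        sub[write] <- as.integer(tab$id[k])
        labels[ix, iy, iz] <- sub
      }
    }
  }

  # compartment slabs along x, proportional to ground-truth probabilities
  probs <- catalog@groundTruth$compartmentProbs
  if (is.null(probs))
    probs <- c(dendrite = 0, excitatory_axon = 0, inhibitory_axon = 0,
               nonsynaptic = 1)
  codes <- seq_along(.COMPARTMENTS)
  names(codes) <- .COMPARTMENTS
  bounds <- round(cumsum(probs[.COMPARTMENTS]) * shp[1])
  bounds[length(bounds)] <- shp[1]
  slab <- integer(shp[1])
  lo <- 1L
  for (j in seq_along(bounds)) {
    if (bounds[j] >= lo) slab[lo:bounds[j]] <- codes[j]
    lo <- as.integer(bounds[j]) + 1L
  }
  slab[slab == 0L] <- codes[["nonsynaptic"]]
  compartments <- array(slab, dim = shp)  # x varies fastest: slab recycles

  VoxelStack(labels = labels, compartments = compartments,
             compartmentCodes = codes, geometry = geom)
}
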