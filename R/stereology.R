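#' Count objects in an unbiased 3D counting frame
#'
#' Applies the brick counting rule to object centroids (the unique
#' counting point of each object): a centroid is counted iff it lies
#' inside the frame, counting points exactly on the three inclusion faces
#' and rejecting points on or beyond the three exclusion faces. With the
#' default lower inclusion corner, a centroid is counted when
#' \code{lower <= p < upper} on every axis.
#'
#' @param x a [PointPattern3D], an [MVBCatalog] or a 3-column coordinate
#'   matrix (\eqn{\mu m}).
#' @param frame a [CountingFrame]. When \code{x} carries an observation
#'   window the frame must lie inside it.
#' @return integer count.
#' @examples
#' w <- cubeBox(277.23)
#' p <- generatePointPattern(csrProcess(0.21), w, seed = 2)
#' countInFrame(p, countingFrame(w))
#' @export
countInFrame <- function(x, frame) {
  stopifnot(is(frame, "CountingFrame"))
  validObject(frame)
  win <- NULL
  if (is(x, "PointPattern3D")) {
    win <- x@window
    xyz <- x@coords
  } else if (is(x, "MVBCatalog")) {
    xyz <- as.matrix(x@table[, c("x_um", "y_um", "z_um")])
    if (length(x@windows) == 1L) win <- x@windows[[1L]]
  } else {
    xyz <- as.matrix(x)
    stopifnot(ncol(xyz) == 3L)
  }
  b <- frame@box
  if (!is.null(win)) {
    tol <- 1e-9
    if (b@xrange[1] < win@xrange[1] - tol || b@xrange[2] > win@xrange[2] + tol ||
        b@yrange[1] < win@yrange[1] - tol || b@yrange[2] > win@yrange[2] + tol ||
        b@zrange[1] < win@zrange[1] - tol || b@zrange[2] > win@zrange[2] + tol)
      stop("counting frame lies outside the stack window")
  }
  if (nrow(xyz) == 0L) return(0L)
  if (frame@inclusion == "lower") {
    inside <- xyz[, 1] >= b@xrange[1] & xyz[, 1] < b@xrange[2] &
              xyz[, 2] >= b@yrange[1] & xyz[, 2] < b@yrange[2] &
              xyz[, 3] >= b@zrange[1] & xyz[, 3] < b@zrange[2]
  } else {
    inside <- xyz[, 1] > b@xrange[1] & xyz[, 1] <= b@xrange[2] &
              xyz[, 2] > b@yrange[1] & xyz[, 2] <= b@yrange[2] &
              xyz[, 3] > b@zrange[1] & xyz[, 3] <= b@zrange[2]
  }
  sum(inside)
}

#' Estimate object density per stack
#'
#' Density is the brick count divided by the (shrinkage-corrected)
#' counting-frame volume, computed per stack. Use [aggregateDensity()]
#' for layer means and the grand mean.
#'
#' @param catalog an [MVBCatalog] (one row per object, any number of
#'   stacks).
#' @param frames optional named list of [CountingFrame] keyed by
#'   \code{stack_id}; by default each stack's full window is used as its
#'   frame.
#' @param correction optional [ShrinkageFactors]; when given, frame
#'   volumes are divided by the volume factor before forming densities
#'   (measurements on processed tissue are inflated back to
#'   pre-processing scale).
#' @return data.frame with columns \code{stack_id}, \code{layer},
#'   \code{count}, \code{frame_volume_um3}, \code{density} (objects per
#'   \eqn{\mu m^3}).
#' @examples
#' cat3 <- generateCatalog(catalogSpec(nStacks = 3, layers = c("I","I","II")),
#'                         csrProcess(0.21), seed = 5)
#' estimateDensity(cat3)
#' @export
estimateDensity <- function(catalog, frames = NULL, correction = NULL) {
  stopifnot(is(catalog, "MVBCatalog"))
  tab <- catalog@table
  ids <- unique(tab$stack_id)
  out <- lapply(ids, function(sid) {
    win <- catalog@windows[[sid]]
    fr <- if (!is.null(frames)) frames[[sid]]
          else if (!is.null(win)) countingFrame(win)
          else stop("no frame and no window available for ", sid)
    sub <- tab[tab$stack_id == sid, , drop = FALSE]
    pat <- as.matrix(sub[, c("x_um", "y_um", "z_um")])
    cnt <- countInFrame(pat, fr)
    V <- volume(fr)
    if (!is.null(correction))
      V <- applyShrinkage(V, "volume", correction)
    if (V <= 0) stop("frame volume must be positive")
    data.frame(stack_id = sid,
               layer = if (nrow(sub)) sub$layer[1] else NA_character_,
               count = cnt, frame_volume_um3 = V, density = cnt / V,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-stack densities to layer and grand means
#'
#' Layer summaries are the mean and standard error over that layer's
#' stacks. The grand mean is, by default, the unweighted mean of the
#' layer means ("across layers"); stack-weighted pooling over all stacks
#' is available with \code{across = "stacks"}.
#'
#' @param perStack data.frame from [estimateDensity()].
#' @param across \code{"layers"} (mean of layer means, the default) or
#'   \code{"stacks"} (mean over all stacks).
#' @return list with \code{layers} (data.frame: layer, n_stacks, mean,
#'   sem), \code{mean}, \code{sem} and \code{across}.
#' @export
aggregateDensity <- function(perStack, across = c("layers", "stacks")) {
  across <- match.arg(across)
  stopifnot(all(c("layer", "density") %in% names(perStack)))
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  layers <- unique(perStack$layer)
  ls <- do.call(rbind, lapply(layers, function(l) {
    d <- perStack$density[perStack$layer == l]
    data.frame(layer = l, n_stacks = length(d), mean = mean(d),
               sem = sem(d), stringsAsFactors = FALSE)
  }))
  rownames(ls) <- NULL
  if (across == "layers") {
    m <- mean(ls$mean)
    s <- sem(ls$mean)
  } else {
    m <- mean(perStack$density)
    s <- sem(perStack$density)
  }
  list(layers = ls, mean = m, sem = s, across = across)
}

#' Cavalieri point-grid volume fraction
#'
#' Superimposes a systematic square grid on every k-th section of a
#' labeled stack and estimates the volume fraction of a target label set
#' as the ratio of grid points hitting the target to grid points hitting
#' the reference space (by default, every grid point falling on the
#' image). The grid origin is fixed at half a spacing (deterministic)
#' unless a seed is given, in which case the XY origin is uniform within
#' one grid cell and the starting section uniform within one section
#' period — the randomization that makes the estimator unbiased.
#'
#' @param stack a [VoxelStack].
#' @param grid a [CavalieriGrid]; the spacing must be at least the
#'   in-plane voxel size.
#' @param target integer label values that count as the structure of
#'   interest.
#' @param channel \code{"objects"} (the object-label raster) or
#'   \code{"compartments"}.
#' @param reference optional label values defining the reference space;
#'   \code{NULL} means all sampled grid points.
#' @param seed optional integer seed for origin randomization.
#' @return list with \code{fraction}, \code{targetHits},
#'   \code{referenceHits}, \code{sections} (sampled section indices) and
#'   \code{origin_nm} (XY grid origin used).
#' @export
cavalieriVolumeFraction <- function(stack, grid, target,
                                    channel = c("objects", "compartments"),
                                    reference = NULL, seed = NULL) {
  stopifnot(is(stack, "VoxelStack"), is(grid, "CavalieriGrid"))
  channel <- match.arg(channel)
  validObject(grid)
  g <- stack@geometry
  vs <- g@voxelSize                       # nm
  if (grid@spacing < max(vs[1:2]))
    stop("grid spacing must be at least the in-plane voxel size")
  arr <- if (channel == "objects") stack@labels else {
    if (!length(stack@compartments))
      stop("stack carries no compartment raster")
    stack@compartments
  }
  shp <- dim(arr)
  s <- grid@spacing
  k <- grid@sectionStep
  if (!is.null(seed)) {
    set.seed(.checkSeed(seed))
    ox <- stats::runif(1, 0, s)
    oy <- stats::runif(1, 0, s)
    z0 <- sample.int(k, 1L)
  } else {
    ox <- s / 2
    oy <- s / 2
    z0 <- 1L
  }
  zs <- seq.int(z0, shp[3], by = k)
  if (!length(zs)) stop("section step larger than the stack depth")
  xs <- seq(ox, shp[1] * vs[1], by = s)
  ys <- seq(oy, shp[2] * vs[2], by = s)
  xs <- xs[xs < shp[1] * vs[1]]
  ys <- ys[ys < shp[2] * vs[2]]
  if (!length(xs) || !length(ys))
    stop("no grid points fall on the image: zero total points")
  ix <- pmin(shp[1], floor(xs / vs[1]) + 1L)
  iy <- pmin(shp[2], floor(ys / vs[2]) + 1L)
  vals <- as.vector(arr[ix, iy, zs])
  if (is.null(reference)) {
    refHits <- length(vals)
    inRef <- rep(TRUE, length(vals))
  } else {
    inRef <- vals %in% reference
    refHits <- sum(inRef)
  }
  if (refHits == 0L) stop("zero reference points hit: cannot form a ratio")
  tgtHits <- sum(vals %in% target & inRef)
  list(fraction = tgtHits / refHits, targetHits = tgtHits,
       referenceHits = refHits, sections = zs, origin_nm = c(ox, oy))
}
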