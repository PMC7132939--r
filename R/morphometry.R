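#' Measure labeled objects in a voxel stack
#'
#' Computes, for every distinct nonzero label, the voxel count, the
#' physical volume (voxel count times the anisotropic voxel volume) and
#' the centroid (unweighted mean of voxel-center positions, mapped to
#' micrometres through the stack geometry). Labels are trusted as object
#' identity; an empty stack yields an empty table, not an error.
#'
#' @param stack a [VoxelStack].
#' @param correction optional [ShrinkageFactors]; when given, volumes are
#'   divided by the volume factor (restoring pre-processing scale).
#' @return data.frame with columns \code{id}, \code{voxel_count},
#'   \code{volume_um3}, \code{x_um}, \code{y_um}, \code{z_um}, ordered by
#'   \code{id}.
#' @examples
#' a <- array(0L, c(8, 8, 4)); a[2:3, 2:3, 2] <- 1L
#' st <- VoxelStack(labels = a,
#'                  geometry = StackGeometry(c(8, 8, 4), c(4, 4, 20)))
#' measureObjects(st)
#' @export
measureObjects <- function(stack, correction = NULL) {
  stopifnot(is(stack, "VoxelStack"))
  validObject(stack)
  g <- stack@geometry
  voxVol <- prod(g@voxelSize) / 1e9        # um^3 per voxel
  vs_um <- g@voxelSize / 1000

  lab <- stack@labels
  idx <- which(lab != 0L)
  if (length(idx) == 0L) {
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0)))
  }
  labs <- lab[idx]
  ind <- arrayInd(idx, dim(lab))
  # voxel-center physical coordinates, um
  pos <- sweep(sweep(ind - 0.5, 2L, vs_um, "*"), 2L, g@origin, "+")
  counts <- rowsum(rep(1L, length(labs)), labs)
  sums <- rowsum(pos, labs)
  ids <- as.integer(rownames(counts))
  n <- as.integer(counts[, 1])
  cen <- sums / n
  out <- data.frame(id = ids, voxel_count = n, volume_um3 = n * voxVol,
                    x_um = cen[, 1], y_um = cen[, 2], z_um = cen[, 3])
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(correction))
    out$volume_um3 <- applyShrinkage(out$volume_um3, "volume", correction)
  out
}

#' Apply tissue-shrinkage correction
#'
#' Measurements made on processed (shrunken) tissue are divided by the
#' shrinkage factor of the matching dimension — linear, area or volume —
#' to restore the scale before osmication and embedding. Factors are the
#' after/before ratios, so they lie in (0, 1] and correction inflates the
#' measurement.
#'
#' @param value numeric measurement(s) taken after processing.
#' @param dimension \code{"linear"}, \code{"area"} or \code{"volume"}.
#' @param factors a [ShrinkageFactors].
#' @return corrected measurement(s), \code{value / factor}.
#' @examples
#' applyShrinkage(0.73, "volume", shrinkageFactors(0.90, 0.81, 0.73))
#' @export
applyShrinkage <- function(value, dimension = c("linear", "area", "volume"),
                           factors = shrinkageFactors()) {
  dimension <- match.arg(dimension)
  stopifnot(is(factors, "ShrinkageFactors"))
  validObject(factors)
  f <- slot(factors, dimension)
  if (!is.finite(f) || f <= 0) stop("shrinkage factor must be positive")
  value / f
}

#' Build a catalog from measured objects
#'
#' Wraps the measurement table of [measureObjects()] into an
#' [MVBCatalog], attaching layer, compartment and morphology-flag
#' annotations (which come from the reconstruction, not from the raster).
#'
#' @param measurements data.frame from [measureObjects()].
#' @param stack the measured [VoxelStack] (provides the window).
#' @param stackId stack identifier for the catalog.
#' @param layer cortical layer label.
#' @param annotations optional data.frame keyed by \code{id} with any of
#'   \code{compartment}, \code{docked}, \code{tubules}, \code{clathrin}.
#' @return an [MVBCatalog].
#' @export
objectsToCatalog <- function(measurements, stack, stackId = "stack_01",
                             layer = "I", annotations = NULL) {
  stopifnot(is.data.frame(measurements), is(stack, "VoxelStack"))
  n <- nrow(measurements)
  tab <- data.frame(
    id = measurements$id,
    x_um = measurements$x_um, y_um = measurements$y_um,
    z_um = measurements$z_um,
    volume_um3 = measurements$volume_um3,
    layer = rep(layer, n),
    compartment = rep("nonsynaptic", n),
    docked = rep(FALSE, n), tubules = rep(FALSE, n),
    clathrin = rep(FALSE, n),
    stack_id = rep(stackId, n), stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    m <- match(tab$id, annotations$id)
    for (col in intersect(c("compartment", "docked", "tubules", "clathrin"),
                          names(annotations))) {
      hit <- !is.na(m)
      tab[[col]][hit] <- annotations[[col]][m[hit]]
    }
  }
  win <- list(spatialWindow(stack))
  names(win) <- stackId
  MVBCatalog(table = tab, windows = win, groundTruth = list())
}
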