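# S4 class definitions for the quantitative volume-EM toolkit.
# Linear units: object-space coordinates and window extents are micrometres;
# voxel sizes and stereological grid constants are nanometres (the scales at
# which FIB-SEM metadata are reported).

.COMPARTMENTS <- c("dendrite", "excitatory_axon", "inhibitory_axon",
                   "nonsynaptic")
.FLAGS <- c("docked", "tubules", "clathrin")
.CATALOG_COLUMNS <- c("id", "x_um", "y_um", "z_um", "volume_um3", "layer",
                      "compartment", "docked", "tubules", "clathrin",
                      "stack_id")

#' Axis-aligned 3D box window
#'
#' The observation window of a point pattern or the brick of a counting
#' frame: an axis-aligned box given by its coordinate ranges in
#' micrometres.
#'
#' @slot xrange,yrange,zrange numeric length-2 vectors, min and max in
#'   \eqn{\mu m}.
#' @param xrange,yrange,zrange numeric length-2 ranges (\eqn{\mu m}).
#' @return a \code{Box3D} object.
#' @examples
#' b <- Box3D(c(0, 6.5), c(0, 6.5), c(0, 6.5))
#' volume(b)
#' @aliases Box3D
#' @export Box3D
#' @exportClass Box3D
Box3D <- setClass("Box3D",
  representation(xrange = "numeric", yrange = "numeric", zrange = "numeric"),
  validity = function(object) {
    for (s in c("xrange", "yrange", "zrange")) {
      r <- slot(object, s)
      if (length(r) != 2L || anyNA(r) || !all(is.finite(r)))
        return(sprintf("'%s' must be two finite numbers", s))
      if (r[2] <= r[1])
        return(sprintf("'%s' must be strictly increasing", s))
    }
    TRUE
  })

#' @rdname Box3D-class
#' @export
setMethod("initialize", "Box3D", function(.Object, xrange = c(0, 1),
                                          yrange = c(0, 1), zrange = c(0, 1),
                                          ...) {
  callNextMethod(.Object, xrange = as.numeric(xrange),
                 yrange = as.numeric(yrange), zrange = as.numeric(zrange), ...)
})

#' Cubic box of a given volume
#'
#' Convenience constructor for the cubic observation window used when only
#' a sampled tissue volume (e.g. a counting-frame volume in \eqn{\mu m^3})
#' is specified.
#'
#' @param volume box volume in \eqn{\mu m^3}.
#' @param origin numeric length-3 lower corner (\eqn{\mu m}).
#' @return a [Box3D].
#' @examples
#' cubeBox(277.23)
#' @export
cubeBox <- function(volume, origin = c(0, 0, 0)) {
  stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0)
  side <- volume^(1 / 3)
  Box3D(c(origin[1], origin[1] + side),
        c(origin[2], origin[2] + side),
        c(origin[3], origin[3] + side))
}

#' Voxel geometry of an image stack
#'
#' Shape and anisotropic voxel size of a raster volume. FIB-SEM stacks
#' have fine in-plane resolution (a few nm/pixel) and coarser section
#' thickness (here 20 nm), so the three axes are independently settable.
#'
#' @slot shape integer length-3: voxels along x, y, z.
#' @slot voxelSize numeric length-3: nm per voxel along x, y, z.
#' @slot origin numeric length-3: physical position of the stack's lower
#'   corner, \eqn{\mu m}.
#' @param shape,voxelSize,origin see slots.
#' @return a \code{StackGeometry}.
#' @examples
#' StackGeometry(c(256, 256, 128), voxelSize = c(20, 20, 20))
#' @aliases StackGeometry
#' @export StackGeometry
#' @exportClass StackGeometry
StackGeometry <- setClass("StackGeometry",
  representation(shape = "integer", voxelSize = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("'shape' must be three positive voxel counts")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("'voxelSize' must be three positive nm values")
    if (length(object@origin) != 3L || anyNA(object@origin))
      return("'origin' must be three finite values")
    TRUE
  })

#' @rdname StackGeometry-class
#' @export
setMethod("initialize", "StackGeometry",
  function(.Object, shape = c(256L, 256L, 128L), voxelSize = c(20, 20, 20),
           origin = c(0, 0, 0), ...) {
    callNextMethod(.Object, shape = as.integer(shape),
                   voxelSize = as.numeric(voxelSize),
                   origin = as.numeric(origin), ...)
  })

#' 3D point pattern in a box window
#'
#' Object centroids (\eqn{\mu m}) inside an axis-aligned observation
#' window; the input to the G, F and K spatial statistics.
#'
#' @slot coords numeric matrix, one row per point, columns x, y, z
#'   (\eqn{\mu m}).
#' @slot window a [Box3D].
#' @param coords,window see slots.
#' @return a \code{PointPattern3D}.
#' @examples
#' w <- Box3D(c(0, 5), c(0, 5), c(0, 5))
#' PointPattern3D(matrix(runif(30, 0, 5), ncol = 3), w)
#' @aliases PointPattern3D
#' @export PointPattern3D
#' @exportClass PointPattern3D
PointPattern3D <- setClass("PointPattern3D",
  representation(coords = "matrix", window = "Box3D"),
  validity = function(object) {
    xy <- object@coords
    if (ncol(xy) != 3L) return("'coords' must have three columns (x, y, z)")
    if (nrow(xy) > 0) {
      if (anyNA(xy) || !all(is.finite(xy)))
        return("point coordinates must be finite")
      w <- object@window
      tol <- 1e-9
      inside <- xy[, 1] >= w@xrange[1] - tol & xy[, 1] <= w@xrange[2] + tol &
                xy[, 2] >= w@yrange[1] - tol & xy[, 2] <= w@yrange[2] + tol &
                xy[, 3] >= w@zrange[1] - tol & xy[, 3] <= w@zrange[2] + tol
      if (!all(inside)) return("all points must lie inside the window")
    }
    TRUE
  })

#' @rdname PointPattern3D-class
#' @export
setMethod("initialize", "PointPattern3D",
  function(.Object, coords = matrix(numeric(0), ncol = 3), window = Box3D(),
           ...) {
    coords <- as.matrix(coords)
    if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 3)
    storage.mode(coords) <- "double"
    colnames(coords) <- c("x", "y", "z")
    callNextMethod(.Object, coords = coords, window = window, ...)
  })

#' Catalog of segmented objects
#'
#' The pipeline's central currency: one row per reconstructed organelle,
#' with centroid position, volume, cortical layer, subcellular compartment
#' and boolean morphology flags (docked on a mitochondrion, tubular
#' protrusions, clathrin coat). Synthetic catalogs additionally carry the
#' generator's ground-truth parameters for parameter-recovery testing.
#'
#' @slot table data.frame with columns \code{id}, \code{x_um}, \code{y_um},
#'   \code{z_um}, \code{volume_um3}, \code{layer}, \code{compartment},
#'   \code{docked}, \code{tubules}, \code{clathrin}, \code{stack_id}.
#' @slot windows named list of [Box3D], one per \code{stack_id}.
#' @slot groundTruth named list of generator parameters (may be empty).
#' @param table,windows,groundTruth see slots.
#' @return an \code{MVBCatalog}.
#' @aliases MVBCatalog
#' @export MVBCatalog
#' @exportClass MVBCatalog
MVBCatalog <- setClass("MVBCatalog",
  representation(table = "data.frame", windows = "list",
                 groundTruth = "list"),
  validity = function(object) {
    tab <- object@table
    missing <- setdiff(.CATALOG_COLUMNS, names(tab))
    if (length(missing))
      return(paste("catalog table lacks columns:",
                   paste(missing, collapse = ", ")))
    if (nrow(tab) > 0) {
      if (any(!is.finite(tab$volume_um3)) || any(tab$volume_um3 <= 0))
        return("all volumes must be positive and finite")
      bad <- setdiff(unique(as.character(tab$compartment)), .COMPARTMENTS)
      if (length(bad))
        return(paste("unknown compartment labels:",
                     paste(bad, collapse = ", ")))
    }
    if (length(object@windows) &&
        !all(vapply(object@windows, is, logical(1), class2 = "Box3D")))
      return("'windows' must be a list of Box3D")
    TRUE
  })

#' Labeled voxel volume
#'
#' A 3D integer raster of object labels (0 = background), an optional
#' parallel raster of compartment codes, and the voxel geometry. This is
#' the in-memory form of a segmented FIB-SEM stack.
#'
#' @slot labels 3D integer array of object IDs; 0 is background.
#' @slot compartments 3D integer array of compartment codes with the same
#'   shape, or an empty array when absent.
#' @slot compartmentCodes named integer vector mapping compartment names
#'   to codes.
#' @slot geometry a [StackGeometry] consistent with \code{dim(labels)}.
#' @param labels,compartments,compartmentCodes,geometry see slots.
#' @return a \code{VoxelStack}.
#' @aliases VoxelStack
#' @export VoxelStack
#' @exportClass VoxelStack
VoxelStack <- setClass("VoxelStack",
  representation(labels = "array", compartments = "array",
                 compartmentCodes = "integer", geometry = "StackGeometry"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L)
      return("'labels' must be a 3D array")
    if (!identical(dim(object@labels), as.integer(object@geometry@shape)))
      return("raster shape does not match geometry")
    if (any(object@labels < 0L))
      return("labels must be nonnegative (0 = background)")
    if (length(object@compartments) &&
        !identical(dim(object@compartments), dim(object@labels)))
      return("'compartments' must match the shape of 'labels'")
    TRUE
  })

#' @rdname VoxelStack-class
#' @export
setMethod("initialize", "VoxelStack",
  function(.Object, labels, compartments = array(integer(0), c(0, 0, 0)),
           compartmentCodes = integer(0), geometry = NULL, ...) {
    storage.mode(labels) <- "integer"
    if (length(compartments)) storage.mode(compartments) <- "integer"
    if (is.null(geometry))
      geometry <- StackGeometry(shape = dim(labels))
    callNextMethod(.Object, labels = labels, compartments = compartments,
                   compartmentCodes = as.integer(compartmentCodes),
                   geometry = geometry, ...)
  })

#' Spatial process specification
#'
#' Generative model for organelle centroid positions: \code{"CSR"}
#' (homogeneous Poisson, the complete-spatial-randomness null) or
#' \code{"THOMAS"} (a Poisson cluster process: Poisson parents, each with
#' a Poisson number of offspring displaced by an isotropic Gaussian),
#' used as the clustered alternative.
#'
#' Use the constructors [csrProcess()] and [thomasProcess()].
#'
#' @slot kind \code{"CSR"} or \code{"THOMAS"}.
#' @slot intensity expected objects per \eqn{\mu m^3} (\eqn{\lambda}); for
#'   a Thomas process this is \eqn{\kappa \mu_c}.
#' @slot parentIntensity Thomas parent intensity \eqn{\kappa}
#'   (\eqn{\mu m^{-3}}); \code{NA} for CSR.
#' @slot meanOffspring Thomas mean offspring per parent \eqn{\mu_c};
#'   \code{NA} for CSR.
#' @slot clusterSd Thomas isotropic offspring dispersion (\eqn{\mu m});
#'   \code{NA} for CSR.
#' @aliases ProcessSpec
#' @exportClass ProcessSpec
setClass("ProcessSpec",
  representation(kind = "character", intensity = "numeric",
                 parentIntensity = "numeric", meanOffspring = "numeric",
                 clusterSd = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("CSR", "THOMAS"))
      return("kind must be 'CSR' or 'THOMAS'")
    if (!is.finite(object@intensity) || object@intensity <= 0)
      return("intensity must be positive")
    if (object@kind == "THOMAS") {
      if (!is.finite(object@parentIntensity) || object@parentIntensity <= 0)
        return("parent intensity must be positive")
      if (!is.finite(object@meanOffspring) || object@meanOffspring <= 0)
        return("mean offspring must be positive")
      if (!is.finite(object@clusterSd) || object@clusterSd <= 0)
        return("cluster_sd must be positive")
      eff <- object@parentIntensity * object@meanOffspring
      if (abs(eff - object@intensity) > 1e-9 * max(1, eff))
        return("intensity must equal parentIntensity * meanOffspring")
    }
    TRUE
  })

#' Homogeneous Poisson (CSR) process specification
#'
#' @param intensity expected objects per \eqn{\mu m^3}. The study tissue
#'   has about 0.21 organelles per \eqn{\mu m^3}.
#' @return a [ProcessSpec].
#' @examples
#' csrProcess(0.21)
#' @export
csrProcess <- function(intensity = 0.21) {
  new("ProcessSpec", kind = "CSR", intensity = as.numeric(intensity),
      parentIntensity = NA_real_, meanOffspring = NA_real_,
      clusterSd = NA_real_)
}

#' Thomas cluster process specification
#'
#' @param parentIntensity Poisson parent intensity \eqn{\kappa},
#'   \eqn{\mu m^{-3}}.
#' @param meanOffspring mean offspring count per parent \eqn{\mu_c}.
#' @param clusterSd isotropic Gaussian offspring dispersion, \eqn{\mu m}.
#' @return a [ProcessSpec] with effective intensity
#'   \eqn{\kappa \mu_c}.
#' @examples
#' thomasProcess(0.02, 10, clusterSd = 0.4)
#' @export
thomasProcess <- function(parentIntensity, meanOffspring, clusterSd) {
  new("ProcessSpec", kind = "THOMAS",
      intensity = as.numeric(parentIntensity) * as.numeric(meanOffspring),
      parentIntensity = as.numeric(parentIntensity),
      meanOffspring = as.numeric(meanOffspring),
      clusterSd = as.numeric(clusterSd))
}

#' Synthetic catalog specification
#'
#' Ground-truth parameters for the catalog generator. The defaults are the
#' study conditions of the tissue this toolkit targets: 29 stacks spread
#' over cortical layers I-VI (3, 4, 10, 5, 3 and 4 stacks respectively),
#' counting-frame volumes between 167.39 and 444.11 \eqn{\mu m^3},
#' log-normal object volumes with \eqn{\mu = -5.1375},
#' \eqn{\sigma = 0.9173} on the natural-log scale, compartment proportions
#' 39.14 / 15.87 / 2.29 / 42.70 % (dendrite, excitatory axon, inhibitory
#' axon, nonsynaptic), and marginal flag frequencies 18.16 % docked,
#' 6.66 % tubular, 19.74 % clathrin-coated.
#'
#' @slot nStacks number of stacks.
#' @slot windowVolumes per-stack window volumes (\eqn{\mu m^3}); empty
#'   means draw uniformly from \code{windowVolumeRange} at generation
#'   time.
#' @slot windowVolumeRange length-2 range for drawn window volumes.
#' @slot lognormalMu,lognormalSigma natural-log-scale volume parameters.
#' @slot compartmentProbs named probabilities over the four compartments.
#' @slot flagProbs named probabilities for the three morphology flags.
#' @slot layers character layer label per stack.
#' @param nStacks,windowVolumes,windowVolumeRange,lognormalMu,lognormalSigma
#'   see slots.
#' @param compartmentProbs,flagProbs,layers see slots.
#' @return a \code{CatalogSpec}.
#' @examples
#' catalogSpec(nStacks = 4, layers = c("I", "II", "III", "IV"))
#' @aliases CatalogSpec catalogSpec
#' @export catalogSpec
#' @exportClass CatalogSpec
setClass("CatalogSpec",
  representation(nStacks = "integer", windowVolumes = "numeric",
                 windowVolumeRange = "numeric", lognormalMu = "numeric",
                 lognormalSigma = "numeric", compartmentProbs = "numeric",
                 flagProbs = "numeric", layers = "character"),
  validity = function(object) {
    if (object@nStacks < 1L) return("nStacks must be >= 1")
    p <- object@compartmentProbs
    if (length(p) != 4L || is.null(names(p)) ||
        !setequal(names(p), .COMPARTMENTS))
      return("compartmentProbs must be named over the four compartments")
    if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      return("compartmentProbs must sum to 1 (within 1e-9)")
    f <- object@flagProbs
    if (length(f) != 3L || is.null(names(f)) || !setequal(names(f), .FLAGS))
      return("flagProbs must be named docked, tubules, clathrin")
    if (any(f < 0) || any(f > 1)) return("flag probabilities must be in [0,1]")
    if (object@lognormalSigma <= 0) return("lognormalSigma must be positive")
    if (length(object@layers) != object@nStacks)
      return("one layer label per stack required")
    if (length(object@windowVolumes) &&
        (length(object@windowVolumes) != object@nStacks ||
         any(object@windowVolumes <= 0)))
      return("windowVolumes must be positive, one per stack")
    if (length(object@windowVolumeRange) != 2L ||
        any(object@windowVolumeRange <= 0) ||
        diff(object@windowVolumeRange) < 0)
      return("windowVolumeRange must be an increasing positive range")
    TRUE
  })

#' @rdname CatalogSpec-class
#' @export
catalogSpec <- function(nStacks = 29L,
                        windowVolumes = numeric(0),
                        windowVolumeRange = c(167.39, 444.11),
                        lognormalMu = -5.1375,
                        lognormalSigma = 0.9173,
                        compartmentProbs = c(dendrite = 0.3914,
                                             excitatory_axon = 0.1587,
                                             inhibitory_axon = 0.0229,
                                             nonsynaptic = 0.4270),
                        flagProbs = c(docked = 0.1816, tubules = 0.0666,
                                      clathrin = 0.1974),
                        layers = NULL) {
  if (is.null(layers)) {
    if (nStacks == 29L) {
      # sampled stacks per cortical layer: 3 I, 4 II, 10 III, 5 IV, 3 V, 4 VI
      layers <- rep(c("I", "II", "III", "IV", "V", "VI"),
                    times = c(3, 4, 10, 5, 3, 4))
    } else {
      layers <- rep(c("I", "II", "III", "IV", "V", "VI"),
                    length.out = nStacks)
    }
  }
  new("CatalogSpec", nStacks = as.integer(nStacks),
      windowVolumes = as.numeric(windowVolumes),
      windowVolumeRange = as.numeric(windowVolumeRange),
      lognormalMu = as.numeric(lognormalMu),
      lognormalSigma = as.numeric(lognormalSigma),
      compartmentProbs = compartmentProbs[.COMPARTMENTS],
      flagProbs = flagProbs[.FLAGS],
      layers = as.character(layers))
}

#' Unbiased 3D counting frame (brick)
#'
#' A sampling brick with three inclusion faces meeting at one designated
#' corner and three exclusion faces (extended by the usual guard planes),
#' so that every object has the same probability of being counted
#' regardless of where it lies relative to frame boundaries. Objects are
#' counted through a unique point (the centroid): a centroid on an
#' inclusion face counts, one on an exclusion face does not.
#'
#' @slot box the frame brick, a [Box3D] (\eqn{\mu m}).
#' @slot inclusion \code{"lower"} or \code{"upper"}: which corner's three
#'   faces are the inclusion faces.
#' @param box,inclusion see slots.
#' @return a \code{CountingFrame}.
#' @examples
#' countingFrame(cubeBox(277.23))
#' @aliases CountingFrame countingFrame
#' @export countingFrame
#' @exportClass CountingFrame
setClass("CountingFrame",
  representation(box = "Box3D", inclusion = "character"),
  validity = function(object) {
    if (!object@inclusion %in% c("lower", "upper"))
      return("inclusion corner must be 'lower' or 'upper'")
    TRUE
  })

#' @rdname CountingFrame-class
#' @export
countingFrame <- function(box, inclusion = c("lower", "upper")) {
  new("CountingFrame", box = box, inclusion = match.arg(inclusion))
}

#' Cavalieri point-counting grid
#'
#' Systematic point grid for volume-fraction estimation: a square XY grid
#' of a given spacing (grid constant, nm) applied to every k-th section of
#' a stack. Each grid point is associated with an area of
#' \code{spacing^2} nm^2; by the Cavalieri principle the ratio of points
#' hitting the target structure to points hitting the reference space
#' estimates the target's volume fraction.
#'
#' @slot spacing grid constant in nm.
#' @slot sectionStep sample every k-th section.
#' @param spacing,sectionStep see slots. Defaults follow common practice
#'   for this tissue: a 632 nm grid on every 40th 20-nm section (800 nm in
#'   z).
#' @return a \code{CavalieriGrid}.
#' @examples
#' g <- cavalieriGrid(632, 40)
#' associatedArea(g)   # nm^2 per point
#' @aliases CavalieriGrid cavalieriGrid
#' @export cavalieriGrid
#' @exportClass CavalieriGrid
setClass("CavalieriGrid",
  representation(spacing = "numeric", sectionStep = "integer"),
  validity = function(object) {
    if (!is.finite(object@spacing) || object@spacing <= 0)
      return("spacing must be positive")
    if (object@sectionStep < 1L) return("sectionStep must be >= 1")
    TRUE
  })

#' @rdname CavalieriGrid-class
#' @export
cavalieriGrid <- function(spacing = 632, sectionStep = 40L) {
  new("CavalieriGrid", spacing = as.numeric(spacing),
      sectionStep = as.integer(sectionStep))
}

#' @rdname CavalieriGrid-class
#' @param x a \code{CavalieriGrid}.
#' @export
associatedArea <- function(x) {
  stopifnot(is(x, "CavalieriGrid"))
  x@spacing^2
}

#' Tissue shrinkage correction factors
#'
#' Linear, area and volume shrinkage factors measured as the ratio of
#' dimensions after to before processing for electron microscopy (so all
#' lie in (0, 1]); measurements taken on processed tissue are divided by
#' the appropriate factor to restore pre-processing scale. When only the
#' linear factor is given, area and volume default to its square and
#' cube. For the reference tissue the printed factors are 0.90 (linear),
#' 0.81 (area) and 0.73 (volume).
#'
#' @slot linear,area,volume dimensionless factors in (0, 1].
#' @param linear,area,volume see slots; \code{area}/\code{volume} default
#'   to \code{linear^2}/\code{linear^3}.
#' @return a \code{ShrinkageFactors}.
#' @examples
#' shrinkageFactors(linear = 0.90)      # derives area 0.81, volume 0.729
#' shrinkageFactors(0.90, 0.81, 0.73)   # printed study factors
#' @aliases ShrinkageFactors shrinkageFactors
#' @export shrinkageFactors
#' @exportClass ShrinkageFactors
setClass("ShrinkageFactors",
  representation(linear = "numeric", area = "numeric", volume = "numeric"),
  validity = function(object) {
    v <- c(object@linear, object@area, object@volume)
    if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
      return("all shrinkage factors must lie in (0, 1]")
    # consistency within rounding of printed two-decimal factors
    if (abs(object@area - object@linear^2) > 0.015)
      return("area factor inconsistent with linear^2")
    if (abs(object@volume - object@linear^3) > 0.015)
      return("volume factor inconsistent with linear^3")
    TRUE
  })

#' @rdname ShrinkageFactors-class
#' @export
shrinkageFactors <- function(linear = 0.90, area = linear^2,
                             volume = linear^3) {
  new("ShrinkageFactors", linear = as.numeric(linear),
      area = as.numeric(area), volume = as.numeric(volume))
}

#' Estimated spatial summary function
#'
#' One estimated G (nearest neighbour), F (empty space) or K (Ripley)
#' function on a distance grid, together with its theoretical value under
#' complete spatial randomness at the pattern's estimated intensity.
#'
#' @slot fun \code{"G"}, \code{"F"} or \code{"K"}.
#' @slot r distance grid, \eqn{\mu m}.
#' @slot est estimate at each r (may be \code{NA} where the edge-corrected
#'   estimator has an empty at-risk set).
#' @slot theo CSR reference curve at each r.
#' @slot correction edge correction used.
#' @slot n number of points in the pattern.
#' @aliases FunctionEstimate
#' @exportClass FunctionEstimate
setClass("FunctionEstimate",
  representation(fun = "character", r = "numeric", est = "numeric",
                 theo = "numeric", correction = "character", n = "integer"),
  validity = function(object) {
    if (!object@fun %in% c("G", "F", "K")) return("fun must be G, F or K")
    if (length(object@r) != length(object@est) ||
        length(object@r) != length(object@theo))
      return("r, est and theo must have equal length")
    if (any(diff(object@r) <= 0)) return("r grid must be increasing")
    ok <- is.finite(object@est)
    if (object@fun %in% c("G", "F")) {
      if (any(object@est[ok] < -1e-9 | object@est[ok] > 1 + 1e-9))
        return("G and F estimates must lie in [0, 1]")
    } else if (any(object@est[ok] < -1e-9)) {
      return("K estimates must be nonnegative")
    }
    TRUE
  })

#' Envelope test result
#'
#' The outcome of testing an observed pattern against pointwise
#' Monte-Carlo envelopes of the G, F and K functions under complete
#' spatial randomness, with the departure classification: a pattern is
#' \code{random} when every selected function stays inside its envelope;
#' \code{clustered} when all breaches carry the clustering signature
#' (G above, F below, K above the envelope); \code{regular} for the
#' opposite signature; \code{mixed} otherwise.
#'
#' @slot verdict \code{"random"}, \code{"clustered"}, \code{"regular"} or
#'   \code{"mixed"}.
#' @slot curves named list (per function) of data.frames with columns
#'   \code{r}, \code{obs}, \code{lo}, \code{hi}, \code{breach_high},
#'   \code{breach_low}.
#' @slot nsim number of CSR simulations.
#' @slot n points in the observed pattern.
#' @aliases EnvelopeResult
#' @exportClass EnvelopeResult
setClass("EnvelopeResult",
  representation(verdict = "character", curves = "list", nsim = "integer",
                 n = "integer"),
  validity = function(object) {
    if (!object@verdict %in% c("random", "clustered", "regular", "mixed"))
      return("unknown verdict")
    TRUE
  })

#' Maximum-likelihood log-normal fit
#'
#' Fit of a log-normal size distribution to object volumes:
#' \eqn{\hat\mu} is the mean of the natural logs and \eqn{\hat\sigma} the
#' root mean squared deviation (MLE, divisor n). Includes the maximised
#' log-likelihood and a Kolmogorov-Smirnov goodness-of-fit summary against
#' the fitted distribution.
#'
#' @slot mu,sigma natural-log-scale location and dispersion.
#' @slot n sample size.
#' @slot logLik maximised log-likelihood.
#' @slot ksStatistic,ksPValue KS distance to the fitted CDF and its
#'   (approximate, parameters-estimated) p-value.
#' @aliases LognormalFit
#' @exportClass LognormalFit
setClass("LognormalFit",
  representation(mu = "numeric", sigma = "numeric", n = "integer",
                 logLik = "numeric", ksStatistic = "numeric",
                 ksPValue = "numeric"),
  validity = function(object) {
    if (!is.finite(object@mu)) return("mu must be finite")
    if (!is.finite(object@sigma) || object@sigma < 0)
      return("sigma must be nonnegative")
    TRUE
  })

#' Chi-squared contingency / goodness-of-fit result
#'
#' @slot observed observed counts (vector or matrix).
#' @slot expected expected counts under the null.
#' @slot statistic chi-squared statistic.
#' @slot df degrees of freedom.
#' @slot pValue p-value.
#' @slot method \code{"goodness_of_fit"} or \code{"independence"}.
#' @aliases ContingencyResult
#' @exportClass ContingencyResult
setClass("ContingencyResult",
  representation(observed = "ANY", expected = "ANY", statistic = "numeric",
                 df = "numeric", pValue = "numeric", method = "character"))
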