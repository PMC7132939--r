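#' @include AllClasses.R
NULL

#' Physical volume of an object
#'
#' Returns the volume in cubic micrometres of a spatial container:
#' a [Box3D], a [CountingFrame] (its brick), a [StackGeometry] or a
#' [VoxelStack] (the physical extent of the raster).
#'
#' @param x the object.
#' @param ... further arguments (unused).
#' @return numeric scalar, \eqn{\mu m^3}.
#' @examples
#' volume(Box3D(c(0, 2), c(0, 3), c(0, 4)))
#' @export
setGeneric("volume", function(x, ...) standardGeneric("volume"))

#' Number of points in a pattern
#'
#' @param x a [PointPattern3D] or [MVBCatalog].
#' @return integer count.
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' Point coordinates
#'
#' @param x a [PointPattern3D].
#' @return numeric matrix with columns \code{x}, \code{y}, \code{z} (in
#'   micrometres).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Observation window
#'
#' The axis-aligned box a pattern or frame lives in.
#'
#' @param x a [PointPattern3D], [CountingFrame] or [VoxelStack].
#' @return a [Box3D].
#' @export
setGeneric("spatialWindow", function(x) standardGeneric("spatialWindow"))

#' Voxel geometry of a stack
#'
#' @param x a [VoxelStack].
#' @return a [StackGeometry].
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Voxel size in nanometres
#'
#' @param x a [StackGeometry] or [VoxelStack].
#' @return numeric length-3 vector (x, y, z), nm per voxel.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Object-label raster of a stack
#'
#' @param x a [VoxelStack].
#' @return 3D integer array; 0 is background.
#' @export
setGeneric("objectLabels", function(x) standardGeneric("objectLabels"))

#' Compartment-label raster of a stack
#'
#' @param x a [VoxelStack].
#' @return 3D integer array of compartment codes (see
#'   \code{compartmentCodes}), or \code{NULL} when the stack carries none.
#' @export
setGeneric("compartmentArray", function(x) standardGeneric("compartmentArray"))

#' Catalog table
#'
#' The per-object table of an [MVBCatalog]: one row per segmented object
#' with centroid coordinates, volume, layer, compartment and morphology
#' flags.
#'
#' @param x an [MVBCatalog].
#' @return a data.frame.
#' @export
setGeneric("mvbTable", function(x) standardGeneric("mvbTable"))

#' Ground-truth parameters of a synthetic catalog
#'
#' @param x an [MVBCatalog].
#' @return named list of generator parameters (empty for measured
#'   catalogs).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Per-stack observation windows of a catalog
#'
#' @param x an [MVBCatalog].
#' @return named list of [Box3D], keyed by \code{stack_id}.
#' @export
setGeneric("stackWindows", function(x) standardGeneric("stackWindows"))

#' Spatial-randomness verdict of an envelope test
#'
#' @param x an [EnvelopeResult].
#' @return character scalar: \code{"random"}, \code{"clustered"},
#'   \code{"regular"} or \code{"mixed"}.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' Envelope curves of an envelope test
#'
#' @param x an [EnvelopeResult].
#' @return named list (one element per summary function) of data.frames
#'   with columns \code{r}, \code{obs}, \code{lo}, \code{hi},
#'   \code{breach_high}, \code{breach_low}.
#' @export
setGeneric("envelopeCurves", function(x) standardGeneric("envelopeCurves"))
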