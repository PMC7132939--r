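#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname volume
#' @export
setMethod("volume", "Box3D", function(x, ...) {
  diff(x@xrange) * diff(x@yrange) * diff(x@zrange)
})

#' @rdname volume
#' @export
setMethod("volume", "CountingFrame", function(x, ...) volume(x@box))

#' @rdname volume
#' @export
setMethod("volume", "StackGeometry", function(x, ...) {
  # nm^3 -> um^3
  prod(as.numeric(x@shape) * x@voxelSize) / 1e9
})

#' @rdname volume
#' @export
setMethod("volume", "VoxelStack", function(x, ...) volume(x@geometry))

#' @rdname npoints
#' @export
setMethod("npoints", "PointPattern3D", function(x) nrow(x@coords))

#' @rdname npoints
#' @export
setMethod("npoints", "MVBCatalog", function(x) nrow(x@table))

#' @rdname coords
#' @export
setMethod("coords", "PointPattern3D", function(x) x@coords)

#' @rdname spatialWindow
#' @export
setMethod("spatialWindow", "PointPattern3D", function(x) x@window)

#' @rdname spatialWindow
#' @export
setMethod("spatialWindow", "CountingFrame", function(x) x@box)

#' @rdname spatialWindow
#' @export
setMethod("spatialWindow", "VoxelStack", function(x) {
  g <- x@geometry
  ext <- as.numeric(g@shape) * g@voxelSize / 1000  # um
  Box3D(c(g@origin[1], g@origin[1] + ext[1]),
        c(g@origin[2], g@origin[2] + ext[2]),
        c(g@origin[3], g@origin[3] + ext[3]))
})

#' @rdname geometry
#' @export
setMethod("geometry", "VoxelStack", function(x) x@geometry)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "StackGeometry", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelStack", function(x) x@geometry@voxelSize)

#' @rdname objectLabels
#' @export
setMethod("objectLabels", "VoxelStack", function(x) x@labels)

#' @rdname compartmentArray
#' @export
setMethod("compartmentArray", "VoxelStack", function(x) {
  if (length(x@compartments)) x@compartments else NULL
})

#' @rdname mvbTable
#' @export
setMethod("mvbTable", "MVBCatalog", function(x) x@table)

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "MVBCatalog", function(x) x@groundTruth)

#' @rdname stackWindows
#' @export
setMethod("stackWindows", "MVBCatalog", function(x) x@windows)

#' @rdname verdict
#' @export
setMethod("verdict", "EnvelopeResult", function(x) x@verdict)

#' @rdname envelopeCurves
#' @export
setMethod("envelopeCurves", "EnvelopeResult", function(x) x@curves)

#' @describeIn MVBCatalog-class coerce to the underlying data.frame.
#' @param x an \code{MVBCatalog}.
#' @param row.names,optional,... passed on (unused).
#' @export
setMethod("as.data.frame", "MVBCatalog",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "Box3D", function(object) {
  cat(sprintf("Box3D window: [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g] um, volume %.4g um^3\n",
              object@xrange[1], object@xrange[2], object@yrange[1],
              object@yrange[2], object@zrange[1], object@zrange[2],
              volume(object)))
})

setMethod("show", "StackGeometry", function(object) {
  cat(sprintf("StackGeometry: %d x %d x %d voxels at %.3g x %.3g x %.3g nm (%.4g um^3)\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              volume(object)))
})

setMethod("show", "PointPattern3D", function(object) {
  cat(sprintf("PointPattern3D: %d points in a %.4g um^3 box window\n",
              npoints(object), volume(object@window)))
})

setMethod("show", "MVBCatalog", function(object) {
  tab <- object@table
  cat(sprintf("MVBCatalog: %d objects in %d stack(s)\n",
              nrow(tab), length(unique(tab$stack_id))))
  if (nrow(tab)) {
    cmp <- table(factor(tab$compartment, levels = .COMPARTMENTS))
    cat("  compartments:",
        paste(sprintf("%s=%d", names(cmp), as.integer(cmp)), collapse = ", "),
        "\n")
    cat(sprintf("  volumes: median %.3g um^3 (range %.3g-%.3g)\n",
                stats::median(tab$volume_um3), min(tab$volume_um3),
                max(tab$volume_um3)))
  }
  if (length(object@groundTruth))
    cat("  synthetic catalog with recorded ground truth\n")
})

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@labels)
  nob <- length(setdiff(unique(as.vector(object@labels)), 0L))
  cat(sprintf("VoxelStack: %d x %d x %d voxels, %d labeled object(s)%s\n",
              d[1], d[2], d[3], nob,
              if (length(object@compartments)) ", with compartment raster"
              else ""))
})

setMethod("show", "ProcessSpec", function(object) {
  if (object@kind == "CSR") {
    cat(sprintf("ProcessSpec: CSR, intensity %.4g per um^3\n",
                object@intensity))
  } else {
    cat(sprintf(
      "ProcessSpec: Thomas, kappa %.4g, mu_c %.4g, cluster sd %.4g um (intensity %.4g)\n",
      object@parentIntensity, object@meanOffspring, object@clusterSd,
      object@intensity))
  }
})

setMethod("show", "CountingFrame", function(object) {
  cat(sprintf("CountingFrame: %.4g um^3 brick, inclusion corner '%s'\n",
              volume(object@box), object@inclusion))
})

setMethod("show", "FunctionEstimate", function(object) {
  cat(sprintf("%s-function estimate (%s correction), n = %d, r in [%.3g, %.3g] um\n",
              object@fun, object@correction, object@n, min(object@r),
              max(object@r)))
})

setMethod("show", "EnvelopeResult", function(object) {
  cat(sprintf("EnvelopeResult: verdict '%s' (n = %d, %d CSR simulations)\n",
              object@verdict, object@n, object@nsim))
  for (fn in names(object@curves)) {
    cv <- object@curves[[fn]]
    nh <- sum(cv$breach_high, na.rm = TRUE)
    nl <- sum(cv$breach_low, na.rm = TRUE)
    cat(sprintf("  %s: %d high / %d low breach points\n", fn, nh, nl))
  }
})

setMethod("show", "LognormalFit", function(object) {
  cat(sprintf("Log-normal fit: mu = %.4f, sigma = %.4f (n = %d)\n",
              object@mu, object@sigma, object@n))
  cat(sprintf("  logLik = %.2f, KS D = %.4f (p ~ %.3g)\n", object@logLik,
              object@ksStatistic, object@ksPValue))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("Chi-squared %s test: X2 = %.4g, df = %g, p = %.4g\n",
              gsub("_", "-", object@method), object@statistic, object@df,
              object@pValue))
})
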