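#' Simulate a 3D point pattern in a box window
#'
#' Draws organelle centroid positions under either complete spatial
#' randomness (homogeneous Poisson process) or a Thomas cluster process.
#' CSR places \code{Poisson(lambda V)} points i.i.d. uniformly in the
#' window, or exactly \code{nFixed} points when a fixed-count (binomial)
#' pattern is requested — the variant used when simulating envelope null
#' patterns conditioned on the observed count. The Thomas process places
#' Poisson parents in a window expanded by \code{4 * clusterSd} on every
#' face (so clusters straddling the boundary are not truncated), gives
#' each parent a Poisson number of offspring displaced by an isotropic
#' Gaussian, and keeps the offspring that fall inside the window.
#'
#' @param spec a [ProcessSpec] from [csrProcess()] or [thomasProcess()].
#' @param window a [Box3D] observation window (positive volume).
#' @param seed integer seed; the same spec, window and seed always yield
#'   the same pattern.
#' @param nFixed optional fixed point count (CSR only): overrides the
#'   Poisson draw and produces a binomial process with exactly
#'   \code{nFixed} points.
#' @return a [PointPattern3D].
#' @examples
#' w <- cubeBox(277.23)
#' p <- generatePointPattern(csrProcess(0.21), w, seed = 1)
#' npoints(p)
#' @export
generatePointPattern <- function(spec, window, seed, nFixed = NULL) {
  if (!is(spec, "ProcessSpec")) stop("'spec' must be a ProcessSpec")
  if (!is(window, "Box3D")) stop("'window' must be a Box3D")
  validObject(spec)
  validObject(window)
  V <- volume(window)
  if (!is.finite(V) || V <= 0) stop("window must have positive volume")
  seed <- .checkSeed(seed)
  set.seed(seed)

  if (spec@kind == "CSR") {
    n <- if (is.null(nFixed)) stats::rpois(1L, spec@intensity * V)
         else {
           stopifnot(nFixed >= 0)
           as.integer(nFixed)
         }
    pts <- cbind(stats::runif(n, window@xrange[1], window@xrange[2]),
                 stats::runif(n, window@yrange[1], window@yrange[2]),
                 stats::runif(n, window@zrange[1], window@zrange[2]))
  } else {
    if (!is.null(nFixed))
      stop("fixed-count simulation is defined for CSR only")
    ext <- .expandBox(window, 4 * spec@clusterSd)
    nParents <- stats::rpois(1L, spec@parentIntensity * volume(ext))
    parents <- cbind(stats::runif(nParents, ext@xrange[1], ext@xrange[2]),
                     stats::runif(nParents, ext@yrange[1], ext@yrange[2]),
                     stats::runif(nParents, ext@zrange[1], ext@zrange[2]))
    nOff <- if (nParents > 0) stats::rpois(nParents, spec@meanOffspring)
            else integer(0)
    total <- sum(nOff)
    if (total > 0) {
      centers <- parents[rep.int(seq_len(nParents), nOff), , drop = FALSE]
      pts <- centers + matrix(stats::rnorm(3 * total, sd = spec@clusterSd),
                              ncol = 3)
      pts <- pts[.insideBox(pts, window), , drop = FALSE]
    } else {
      pts <- matrix(numeric(0), ncol = 3)
    }
  }
  PointPattern3D(coords = pts, window = window)
}
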