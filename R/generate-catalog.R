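#' Generate a synthetic ground-truth object catalog
#'
#' Composes the generative assumptions of the analysis into one table:
#' per-stack centroid positions from [generatePointPattern()], log-normal
#' object volumes, multinomial compartment assignment and independent
#' Bernoulli morphology flags. The ground-truth parameters are recorded in
#' the catalog so downstream estimators can be validated by parameter
#' recovery. Each stack gets its own cubic window (either the specified
#' volume or one drawn uniformly from the spec's volume range) and a
#' deterministic RNG substream derived from the global seed, so
#' multi-stack experiments reproduce stack-by-stack.
#'
#' @param spec a [CatalogSpec] (defaults are the study conditions; see
#'   [catalogSpec()]).
#' @param process a [ProcessSpec] for the centroid positions.
#' @param seed integer global seed.
#' @return an [MVBCatalog] whose \code{groundTruth} records the generator
#'   parameters.
#' @examples
#' cat3 <- generateCatalog(catalogSpec(nStacks = 3, layers = c("I","II","III")),
#'                         csrProcess(0.21), seed = 7)
#' npoints(cat3)
#' @export
generateCatalog <- function(spec = catalogSpec(), process = csrProcess(),
                            seed) {
  if (!is(spec, "CatalogSpec")) stop("'spec' must be a CatalogSpec")
  if (!is(process, "ProcessSpec")) stop("'process' must be a ProcessSpec")
  validObject(spec)
  validObject(process)
  seed <- .checkSeed(seed)

  nS <- spec@nStacks
  if (length(spec@windowVolumes)) {
    vols <- spec@windowVolumes
  } else {
    set.seed(.childSeed(seed, 0L))
    vols <- stats::runif(nS, spec@windowVolumeRange[1],
                         spec@windowVolumeRange[2])
  }

  windows <- vector("list", nS)
  rows <- vector("list", nS)
  nextId <- 1L
  for (s in seq_len(nS)) {
    win <- cubeBox(vols[s])
    windows[[s]] <- win
    pat <- generatePointPattern(process, win, seed = .childSeed(seed, s))
    n <- npoints(pat)
    set.seed(.childSeed(seed, s + nS))
    vol <- stats::rlnorm(n, meanlog = spec@lognormalMu,
                         sdlog = spec@lognormalSigma)
    comp <- sample(.COMPARTMENTS, n, replace = TRUE,
                   prob = spec@compartmentProbs)
    flags <- vapply(.FLAGS, function(f)
      stats::runif(n) < spec@flagProbs[[f]], logical(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1,
                                 dimnames = list(NULL, .FLAGS))
    xyz <- coords(pat)
    rows[[s]] <- data.frame(
      id = seq.int(nextId, length.out = n),
      x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
      volume_um3 = vol,
      layer = rep(spec@layers[s], n),
      compartment = comp,
      docked = if (n) flags[, "docked"] else logical(0),
      tubules = if (n) flags[, "tubules"] else logical(0),
      clathrin = if (n) flags[, "clathrin"] else logical(0),
      stack_id = rep(sprintf("stack_%02d", s), n),
      stringsAsFactors = FALSE)
    nextId <- nextId + n
  }
  tab <- do.call(rbind, rows)
  names(windows) <- sprintf("stack_%02d", seq_len(nS))

  MVBCatalog(table = tab, windows = windows,
             groundTruth = list(
               process = process,
               lognormalMu = spec@lognormalMu,
               lognormalSigma = spec@lognormalSigma,
               compartmentProbs = spec@compartmentProbs,
               flagProbs = spec@flagProbs,
               windowVolumes = vols,
               layers = spec@layers,
               seed = seed))
}

#' Extract one stack of a catalog as a point pattern
#'
#' @param catalog an [MVBCatalog].
#' @param stackId a \code{stack_id} present in the catalog (default: the
#'   only stack).
#' @return a [PointPattern3D] of that stack's centroids in its window.
#' @export
catalogPattern <- function(catalog, stackId = NULL) {
  stopifnot(is(catalog, "MVBCatalog"))
  tab <- catalog@table
  ids <- unique(tab$stack_id)
  if (is.null(stackId)) {
    if (length(ids) != 1L)
      stop("catalog has several stacks; give 'stackId'")
    stackId <- ids
  }
  if (!stackId %in% ids) stop("unknown stack_id: ", stackId)
  win <- catalog@windows[[stackId]]
  if (is.null(win)) stop("catalog carries no window for ", stackId)
  sub <- tab[tab$stack_id == stackId, , drop = FALSE]
  PointPattern3D(coords = as.matrix(sub[, c("x_um", "y_um", "z_um")]),
                 window = win)
}
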