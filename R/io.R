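# Catalog CSV, label-stack TIFF and run-configuration I/O.
# CSV dialect: comma separated, UTF-8, header row, "." decimal, units in
# column names. Coordinates are physical micrometres externally.

#' Write a catalog to CSV
#'
#' One row per object with columns \code{id, x_um, y_um, z_um,
#' volume_um3, layer, compartment, docked, tubules, clathrin, stack_id}.
#' Full numeric precision is kept so catalogs round-trip losslessly.
#'
#' @param catalog an [MVBCatalog].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCatalogCsv <- function(catalog, path) {
  stopifnot(is(catalog, "MVBCatalog"))
  tab <- catalog@table[, .CATALOG_COLUMNS]
  utils::write.csv(format(tab, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a catalog from CSV
#'
#' @param path CSV file in the dialect of [writeCatalogCsv()].
#' @param windows optional named list of [Box3D] observation windows per
#'   \code{stack_id} (needed for spatial statistics).
#' @return an [MVBCatalog].
#' @export
readCatalogCsv <- function(path, windows = list()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.CATALOG_COLUMNS, names(tab))
  if (length(missing))
    stop("catalog CSV lacks columns: ", paste(missing, collapse = ", "))
  for (col in c("x_um", "y_um", "z_um", "volume_um3"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab$id <- as.integer(tab$id)
  for (col in .FLAGS) tab[[col]] <- as.logical(tab[[col]])
  tab$layer <- as.character(tab$layer)
  tab$compartment <- as.character(tab$compartment)
  tab$stack_id <- as.character(tab$stack_id)
  MVBCatalog(table = tab[, .CATALOG_COLUMNS], windows = windows,
             groundTruth = list())
}

#' Write a label stack as multi-page TIFF
#'
#' One 16-bit page per z section, integer labels stored exactly (labels
#' must not exceed 65535). Geometry is not embedded; keep it in the run
#' configuration.
#'
#' @param stack a [VoxelStack].
#' @param path output TIFF.
#' @param channel \code{"objects"} or \code{"compartments"}.
#' @return the path, invisibly.
#' @export
writeLabelStack <- function(stack, path, channel = c("objects",
                                                     "compartments")) {
  channel <- match.arg(channel)
  stopifnot(is(stack, "VoxelStack"))
  arr <- if (channel == "objects") stack@labels else stack@compartments
  if (!length(arr)) stop("stack carries no ", channel, " raster")
  if (max(arr) > 65535L) stop("labels exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(arr)[3]), function(z)
    t(arr[, , z]) / 65535)  # TIFF pages are row-major (y rows, x cols)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF label stack
#'
#' @param path TIFF written by [writeLabelStack()] (or any integer-label
#'   multi-page TIFF).
#' @param geom a [StackGeometry] describing the voxel size; its shape
#'   must match the pages.
#' @return a [VoxelStack] (object-label channel only).
#' @export
readLabelStack <- function(path, geom = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0L, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) arr[, , z] <- as.integer(t(pages[[z]]))
  if (is.null(geom)) geom <- StackGeometry(shape = c(nx, ny, nz))
  if (!identical(as.integer(geom@shape), dim(arr)))
    stop("geometry shape does not match the TIFF pages")
  VoxelStack(labels = arr, geometry = geom)
}

#' Read and validate a JSON run configuration
#'
#' The configuration drives [runPipeline()]: a seed, the synthetic
#' catalog/process settings (or input catalog paths), envelope settings,
#' shrinkage factors and an output directory. Unknown fields are
#' rejected so typos fail loudly.
#'
#' @param path JSON file.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("seed", "out_dir", "catalog_csv", "n_stacks", "intensity",
               "process", "lognormal_mu", "lognormal_sigma",
               "compartment_probs", "flag_probs", "window_volumes",
               "window_volume_range", "envelope_nsim", "envelope_min_points",
               "shrinkage_linear", "volume_fractions", "render_stacks",
               "render_shape", "render_voxel_nm", "cavalieri_spacing_nm",
               "cavalieri_section_step")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a 'seed'")
  if (is.null(cfg$out_dir)) stop("config must set 'out_dir'")
  if (!is.null(cfg$catalog_csv) && !file.exists(cfg$catalog_csv))
    stop("input catalog not found: ", cfg$catalog_csv)
  cfg
}
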