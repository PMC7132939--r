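#' Run the full analysis pipeline
#'
#' Executes the quantification stages in order on either a synthetic
#' catalog (generated from the configured process and catalog settings)
#' or a catalog read from CSV: per-stack density estimation with the
#' brick counting rule and layer/grand aggregation; compartment
#' percentages, concentration ratios and the chi-squared occupancy test
#' (when reference volume fractions are configured); the log-normal size
#' fit; and per-stack G/F/K envelope tests for stacks with enough
#' points. Optionally renders a subset of stacks to voxel phantoms,
#' re-measures them and runs Cavalieri volume-fraction estimation,
#' closing the loop from catalog to raster and back.
#'
#' All outputs are written under \code{out_dir}: \code{catalog.csv},
#' \code{density.csv} (per-stack rows, then one row per layer, then a
#' pooled row), \code{compartments.csv}, \code{concentration.csv},
#' \code{lognormal_fit.json}, \code{envelopes.json}, optionally
#' \code{volume_fractions.csv}, plus \code{run_config.json} (the resolved
#' configuration) and \code{run_log.txt}. The same configuration and seed
#' always produce identical files.
#'
#' @param config configuration list from [readRunConfig()], or a path to
#'   a JSON configuration.
#' @return invisibly, a list with the in-memory results (catalog,
#'   density, aggregation, fit, envelopes, ...).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$seed) || is.null(config$out_dir))
    stop("config must set 'seed' and 'out_dir'")
  seed <- .checkSeed(config$seed)
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  # no timestamps: identical config + seed must give byte-identical outputs
  note <- function(fmt, ...) {
    logLines <<- c(logLines, sprintf(fmt, ...))
  }

  note("pipeline start, seed %d, mvbquant %s", seed,
       as.character(utils::packageVersion("mvbquant")))

  # --- stage: catalog ------------------------------------------------
  if (!is.null(config$catalog_csv)) {
    catalog <- readCatalogCsv(config$catalog_csv)
    note("read catalog %s: %d objects", config$catalog_csv,
         npoints(catalog))
  } else {
    spec <- catalogSpec(
      nStacks = if (is.null(config$n_stacks)) 29L else config$n_stacks,
      lognormalMu = if (is.null(config$lognormal_mu)) -5.1375
                    else config$lognormal_mu,
      lognormalSigma = if (is.null(config$lognormal_sigma)) 0.9173
                       else config$lognormal_sigma)
    process <- if (!is.null(config$process) &&
                   identical(config$process$kind, "THOMAS")) {
      thomasProcess(config$process$parent_intensity,
                    config$process$mean_offspring,
                    config$process$cluster_sd)
    } else {
      csrProcess(if (is.null(config$intensity)) 0.21 else config$intensity)
    }
    catalog <- generateCatalog(spec, process, seed = seed)
    note("generated catalog: %d objects in %d stacks", npoints(catalog),
         spec@nStacks)
  }
  writeCatalogCsv(catalog, file.path(outDir, "catalog.csv"))

  # --- stage: density ------------------------------------------------
  correction <- if (!is.null(config$shrinkage_linear))
    shrinkageFactors(linear = config$shrinkage_linear) else NULL
  perStack <- estimateDensity(catalog, correction = correction)
  agg <- aggregateDensity(perStack)
  densityRows <- rbind(
    data.frame(row_type = "stack", id = perStack$stack_id,
               layer = perStack$layer, count = perStack$count,
               frame_volume_um3 = round(perStack$frame_volume_um3, 4),
               density = round(perStack$density, 6),
               stringsAsFactors = FALSE),
    data.frame(row_type = "layer", id = agg$layers$layer,
               layer = agg$layers$layer, count = NA,
               frame_volume_um3 = NA, density = round(agg$layers$mean, 6),
               stringsAsFactors = FALSE),
    data.frame(row_type = "pooled", id = "I-VI", layer = "I-VI",
               count = sum(perStack$count), frame_volume_um3 = NA,
               density = round(agg$mean, 6), stringsAsFactors = FALSE))
  utils::write.csv(densityRows, file.path(outDir, "density.csv"),
                   row.names = FALSE)
  note("density: grand mean %.4f per um^3 over %d stacks", agg$mean,
       nrow(perStack))

  # --- stage: compartments -------------------------------------------
  compTable <- layerCompartmentSummary(catalog, "percent")
  utils::write.csv(compTable, file.path(outDir, "compartments.csv"),
                   row.names = FALSE)
  sizeTable <- layerCompartmentSummary(catalog, "volume")
  utils::write.csv(sizeTable, file.path(outDir, "sizes.csv"),
                   row.names = FALSE)
  concResult <- NULL
  if (!is.null(config$volume_fractions)) {
    vf <- unlist(config$volume_fractions)
    tab <- mvbTable(catalog)
    counts <- vapply(names(vf), function(cmp)
      sum(tab$compartment == cmp), numeric(1))
    pct <- 100 * counts / sum(counts)
    conc <- concentrationRatio(pct, 100 * vf, names(vf))
    chi <- compartmentChiSquare(counts, vf / sum(vf))
    utils::write.csv(cbind(conc,
                           chi2 = round(chi@statistic, 4),
                           chi2_p = signif(chi@pValue, 4)),
                     file.path(outDir, "concentration.csv"),
                     row.names = FALSE)
    concResult <- list(ratios = conc, chi = chi)
    note("concentration: chi2 = %.3f (p = %.3g)", chi@statistic,
         chi@pValue)
  }

  # --- stage: sizes --------------------------------------------------
  fit <- fitLognormal(mvbTable(catalog)$volume_um3)
  jsonlite::write_json(
    list(mu = fit@mu, sigma = fit@sigma, n = fit@n, logLik = fit@logLik,
         ks_statistic = fit@ksStatistic,
         mean_volume_um3 = exp(fit@mu + fit@sigma^2 / 2)),
    file.path(outDir, "lognormal_fit.json"), auto_unbox = TRUE,
    digits = 10)
  note("log-normal fit: mu = %.4f, sigma = %.4f (n = %d)", fit@mu,
       fit@sigma, fit@n)

  # --- stage: spatial ------------------------------------------------
  minPts <- if (is.null(config$envelope_min_points)) 25L
            else config$envelope_min_points
  nsim <- if (is.null(config$envelope_nsim)) 100L else config$envelope_nsim
  envs <- list()
  stackIds <- names(stackWindows(catalog))
  for (i in seq_along(stackIds)) {
    sid <- stackIds[i]
    pat <- catalogPattern(catalog, sid)
    if (npoints(pat) < minPts) {
      envs[[sid]] <- list(stack_id = sid, n = npoints(pat),
                          verdict = "excluded_too_few_points")
      next
    }
    e <- envelopeTest(pat, nsim = nsim, seed = .childSeed(seed, 5000L + i),
                      minPoints = minPts)
    cvs <- lapply(envelopeCurves(e), function(cv)
      list(r = cv$r, obs = cv$obs, lo = cv$lo, hi = cv$hi,
           breach_high = which(cv$breach_high),
           breach_low = which(cv$breach_low)))
    envs[[sid]] <- list(stack_id = sid, n = e@n, verdict = verdict(e),
                        nsim = e@nsim, curves = cvs)
  }
  jsonlite::write_json(envs, file.path(outDir, "envelopes.json"),
                       auto_unbox = TRUE, digits = 8, pretty = FALSE)
  verdicts <- vapply(envs, function(e) e$verdict, character(1))
  note("spatial: %d stacks tested (%s)", sum(verdicts != "excluded_too_few_points"),
       paste(sprintf("%s=%d", names(table(verdicts)), table(verdicts)),
             collapse = ", "))

  # --- stage: optional raster round trip -----------------------------
  volfrac <- NULL
  if (!is.null(config$render_stacks) && config$render_stacks > 0) {
    shp <- if (is.null(config$render_shape)) c(128L, 128L, 64L)
           else as.integer(config$render_shape)
    vox <- if (is.null(config$render_voxel_nm)) c(20, 20, 20)
           else as.numeric(config$render_voxel_nm)
    grid <- cavalieriGrid(
      spacing = if (is.null(config$cavalieri_spacing_nm)) 4 * max(vox[1:2])
                else config$cavalieri_spacing_nm,
      sectionStep = if (is.null(config$cavalieri_section_step)) 4L
                    else config$cavalieri_section_step)
    geomPh <- StackGeometry(shape = shp, voxelSize = vox)
    extPh <- shp * vox / 1000
    nRender <- min(as.integer(config$render_stacks), length(stackIds))
    rows <- lapply(seq_len(nRender), function(i) {
      sid <- stackIds[i]
      tab <- mvbTable(catalog)
      sub <- tab[tab$stack_id == sid, , drop = FALSE]
      # rescale centroids into the phantom extent, keep radii clear of edges
      rmax <- max((3 * sub$volume_um3 / (4 * pi))^(1 / 3))
      for (ax in 1:3) {
        col <- c("x_um", "y_um", "z_um")[ax]
        rng <- range(sub[[col]])
        span <- max(rng[2] - rng[1], 1e-6)
        sub[[col]] <- (sub[[col]] - rng[1]) / span *
          (extPh[ax] - 2.2 * rmax) + 1.1 * rmax
      }
      small <- MVBCatalog(table = sub, windows = list(),
                          groundTruth = catalog@groundTruth)
      st <- renderLabelStack(small, geomPh, seed = .childSeed(seed, 9000L + i))
      meas <- measureObjects(st)
      cv <- cavalieriVolumeFraction(st, grid, target = sub$id)
      data.frame(stack_id = sid, n_rendered = nrow(meas),
                 voxel_fraction = round(sum(st@labels > 0L) /
                                          length(st@labels), 6),
                 cavalieri_fraction = round(cv$fraction, 6),
                 stringsAsFactors = FALSE)
    })
    volfrac <- do.call(rbind, rows)
    utils::write.csv(volfrac, file.path(outDir, "volume_fractions.csv"),
                     row.names = FALSE)
    note("rendered %d stacks for Cavalieri cross-check", nRender)
  }

  # --- resolved config + log -----------------------------------------
  jsonlite::write_json(config, file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(logLines, file.path(outDir, "run_log.txt"))

  invisible(list(catalog = catalog, density = perStack, aggregate = agg,
                 fit = fit, envelopes = envs, concentration = concResult,
                 volume_fractions = volfrac))
}
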