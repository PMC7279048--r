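## Run configuration and the staged pipeline.

.knownStageKeys <- list(
  simulate_linescan = c("n_lines", "n_pixels", "pixel_size_um",
                        "line_length_um", "pixel_dwell_s", "line_period_s",
                        "bidirectional", "waist_um", "box_x_um", "box_y_um",
                        "preset", "species", "out"),
  simulate_cells = c("image_shape_px", "frame_interval_s", "n_frames",
                     "center_px", "radii_px", "shell_fraction",
                     "photon_scale", "gaussian_sd", "channels", "out"),
  filters = c("input", "preset", "out"),
  fscs = c("input", "preset", "species", "n_species", "max_delta_um",
           "delta_px", "col_stride", "m", "out"),
  profile = c("input", "preset", "species_a", "species_b", "n_segments",
              "m", "out"),
  translocation = c("input", "channel", "boundary", "out"),
  pearson = c("input", "frame", "channel_a", "channel_b", "combine", "out"),
  calcium = c("input", "channel", "roi", "out"),
  clusterstd = c("input", "channel", "roi", "out"),
  kymograph = c("input", "channel", "line_px", "width_px", "out"))

.speciesFromConfig <- function(sp, preset) {
  spectrum <- if (!is.null(sp[["spectrum_kind"]]))
    syntheticSpectrum(sp[["spectrum_kind"]], preset)
  else readSpectrumTSV(sp[["spectrum_tsv"]])
  SpeciesSpec(label = sp[["label"]] %||% "species",
              D = sp[["d_um2_s"]] %||% 1,
              brightness = sp[["brightness"]] %||% 1,
              density = sp[["density_um2"]] %||% 20,
              spectrum = spectrum,
              mobile = sp[["mobile"]] %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration file
#'
#' Plain-text YAML with one block per stage; keys carry explicit units
#' (e.g. \code{pixel_size_um}).  Unknown stage names or keys are
#' rejected by \code{\link{runPipeline}}.
#'
#' @param path YAML file path.
#' @return a named list of stage configurations.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

.configHash <- function(config) {
  # polynomial rolling hash over the deparsed config: a stable,
  # dependency-free run identifier (not cryptographic)
  s <- charToRaw(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in as.integer(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in their dependency order
#' (simulation, then filters, then correlation/fitting; image stages
#' independently), writing TSV/TIFF/container artifacts into
#' \code{outDir} plus a machine-readable JSON run summary.  Every
#' artifact header embeds the seed and a hash of the configuration, and
#' two runs with identical config and seed produce byte-identical
#' outputs.
#'
#' @param config a configuration list (see \code{\link{readRunConfig}})
#'   or path to a YAML file.
#' @param seed integer seed applied to every stochastic stage.
#' @param outDir output directory, created if missing.
#' @return the run summary list, invisibly.
#' @export
runPipeline <- function(config, seed = 1L, outDir = ".") {
  if (is.character(config)) config <- readRunConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  unknownStages <- setdiff(names(config), names(.knownStageKeys))
  if (length(unknownStages))
    stop("unknown pipeline stage: ", paste(unknownStages, collapse = ", "))
  for (st in names(config)) {
    bad <- setdiff(names(config[[st]]), .knownStageKeys[[st]])
    if (length(bad))
      stop(sprintf("unknown key '%s' in stage '%s'", bad[1], st))
  }
  hash <- .configHash(config)
  provlines <- c(sprintf("config_hash: %s", hash), sprintf("seed: %d", seed))
  summary <- list(config_hash = hash, seed = seed, stages = list())
  out <- function(name) file.path(outDir, name)
  stacks <- list()   # in-memory artifacts keyed by stage output name

  for (st in names(config)) {
    cfg <- config[[st]]
    res <- switch(st,
      simulate_linescan = {
        preset <- cfg[["preset"]] %||% "six"
        geom <- ScanGeometry(
          lineLength = cfg[["line_length_um"]] %||% 5.355,
          nPixels = cfg[["n_pixels"]] %||% 256L,
          pixelSize = cfg[["pixel_size_um"]] %||% 0.021,
          pixelDwell = cfg[["pixel_dwell_s"]] %||% 0.51e-6,
          linePeriod = cfg[["line_period_s"]] %||% 154e-6,
          nLines = cfg[["n_lines"]] %||% 50000L,
          bidirectional = cfg[["bidirectional"]] %||% TRUE)
        species <- lapply(cfg[["species"]] %||%
                            list(list(label = "green",
                                      spectrum_kind = "green")),
                          .speciesFromConfig, preset = preset)
        stack <- simulateLineScan(
          species, geom, PSFModel(cfg[["waist_um"]] %||% 0.25),
          boxSize = c(cfg[["box_x_um"]] %||% 10, cfg[["box_y_um"]] %||% 3),
          seed = seed)
        fn <- out(cfg[["out"]] %||% "linescan.lsc")
        writeLineScan(stack, fn)
        stacks[["linescan"]] <- stack
        list(file = fn, n_lines = geom@nLines)
      },
      simulate_cells = {
        chans <- lapply(cfg[["channels"]] %||% list(list(label = "ch1")),
                        function(ch) cellChannel(
          label = ch[["label"]] %||% "ch1",
          totalIntensity = unlist(ch[["total_intensity"]]) %||% 1e4,
          membraneFraction = unlist(ch[["membrane_fraction"]]) %||% 0.5,
          nClusters = ch[["n_clusters"]] %||% 0L,
          clusterRadius = ch[["cluster_radius_px"]] %||% 2,
          clusterAmplitude = ch[["cluster_amplitude"]] %||% 0,
          onsetFrame = ch[["onset_frame"]] %||% NA_integer_))
        spec <- CellMovieSpec(
          imageShape = unlist(cfg[["image_shape_px"]]) %||% c(64L, 64L),
          frameInterval = cfg[["frame_interval_s"]] %||% 1,
          nFrames = cfg[["n_frames"]] %||% 20L,
          center = unlist(cfg[["center_px"]]) %||%
            ((unlist(cfg[["image_shape_px"]]) %||% c(64, 64)) / 2),
          radii = unlist(cfg[["radii_px"]]) %||% c(20, 24),
          shellFraction = cfg[["shell_fraction"]] %||% 0.25,
          channels = chans,
          photonScale = cfg[["photon_scale"]] %||% 0,
          gaussianSd = cfg[["gaussian_sd"]] %||% 0)
        sim <- simulateCellMovie(spec, seed = seed)
        fn <- out(cfg[["out"]] %||% "cells.tif")
        writeHyperstack(sim$movie, fn)
        writeTruthTSV(sim$truth, paste0(fn, ".truth.tsv"))
        stacks[["cells"]] <- sim
        list(file = fn, n_frames = spec@nFrames)
      },
      filters = {
        stack <- stacks[["linescan"]] %||% .readStageInput(cfg, out, st, readLineScan)
        preset <- cfg[["preset"]] %||% "six"
        refs <- list(syntheticSpectrum("green", preset),
                     syntheticSpectrum("red", preset))
        fs <- stackFilters(stack, refs, labels = c("green", "red"))
        fn <- out(cfg[["out"]] %||% "filters.tsv")
        writeFilterTSV(fs, fn, provlines)
        stacks[["filters"]] <- fs
        list(file = fn)
      },
      fscs = {
        stack <- stacks[["linescan"]] %||% .readStageInput(cfg, out, st, readLineScan)
        stack <- reorderBidirectional(stack)
        fs <- stacks[["filters"]]
        flt <- if (!is.null(fs)) fs@filters[cfg[["species"]] %||% 1L, ]
               else rep(1, dim(stack@counts)[3])
        surf <- assembleSurface(
          stack, flt,
          deltaPx = cfg[["delta_px"]] %||% seq(0, 24, by = 2),
          colStride = cfg[["col_stride"]] %||% 2L, m = cfg[["m"]] %||% 16L,
          maxDelta = cfg[["max_delta_um"]] %||% 0.6)
        fit <- fitNSpecies(surf, cfg[["n_species"]] %||% 1L)
        curve <- new("CorrelationCurve", lagTimes = surf@lagTimes,
                     G = surf@G[, 1], nSamples = surf@nSamples,
                     species = c("a", "a"))
        tt <- transitionTime(curve, surf@waist)
        fn <- out(cfg[["out"]] %||% "fscs_fit.tsv")
        writeResultTSV(fit, fn, provlines)
        writeCurveTSV(curve, out("fscs_curve.tsv"), provlines)
        writeResultTSV(tt, out("fscs_transition.tsv"), provlines)
        list(file = fn, waist_um = surf@waist, D_fit = fit@D,
             D_transition = tt@D)
      },
      profile = {
        stack <- stacks[["linescan"]] %||% .readStageInput(cfg, out, st, readLineScan)
        stack <- reorderBidirectional(stack)
        fs <- stacks[["filters"]]
        if (is.null(fs)) stop("profile stage requires a filters stage")
        sp <- spatialCrossCorrelation(stack, fs@filters[1, ])
        prof <- diffusionProfile(stack, fs, sp[["waist"]],
                                 nSegments = cfg[["n_segments"]] %||% 20L,
                                 m = cfg[["m"]] %||% 16L)
        fn <- out(cfg[["out"]] %||% "profile.tsv")
        writeResultTSV(prof, fn, provlines)
        list(file = fn, correlation = prof@correlation,
             excluded = prof@excluded)
      },
      translocation = {
        movie <- if (!is.null(stacks[["cells"]])) stacks[["cells"]]$movie
                 else .readStageInput(cfg, out, st, readHyperstack)
        fr <- movieFrames(movie)
        mid <- fr[1, , , cfg[["channel"]] %||% 1L]
        fp <- .ellipseRadial(dim(mid), dim(mid) / 2,
                             dim(mid) / 2 - 2) <= 1
        fpDetect <- tryCatch(detectCell(mid), error = function(e) fp)
        masks <- radialMasks(fpDetect, cfg[["boundary"]] %||% 0.25)
        tr <- translocationTrace(movie, masks, cfg[["channel"]] %||% 1L)
        fn <- out(cfg[["out"]] %||% "translocation.tsv")
        con <- file(fn, "w")
        for (p in provlines) writeLines(paste0("# ", p), con)
        write.table(data.frame(frame = seq_along(tr@ratio),
                               ratio = tr@ratio,
                               fold_change = tr@foldChange),
                    con, sep = "\t", row.names = FALSE, quote = FALSE)
        close(con)
        list(file = fn, final_fold = tr@foldChange[length(tr@foldChange)])
      },
      pearson = {
        movie <- if (!is.null(stacks[["cells"]])) stacks[["cells"]]$movie
                 else .readStageInput(cfg, out, st, readHyperstack)
        fr <- movieFrames(movie)
        t <- cfg[["frame"]] %||% dim(fr)[1]
        r <- pearsonColocalization(fr[t, , , cfg[["channel_a"]] %||% 1L],
                                   fr[t, , , cfg[["channel_b"]] %||% 2L],
                                   combine = cfg[["combine"]] %||% "union")
        fn <- out(cfg[["out"]] %||% "pearson.tsv")
        .writeScalarTSV(fn, provlines, pearson = r)
        list(file = fn, pearson = r)
      },
      calcium = {
        movie <- if (!is.null(stacks[["cells"]])) stacks[["cells"]]$movie
                 else .readStageInput(cfg, out, st, readHyperstack)
        ch <- .getChannel(movie, cfg[["channel"]] %||% 1L)
        roi <- unlist(cfg[["roi"]]) %||% c(1, dim(ch)[2], 1, dim(ch)[3])
        trace <- vapply(seq_len(dim(ch)[1]), function(t)
          mean(ch[t, roi[1]:roi[2], roi[3]:roi[4]]), 0)
        fold <- calciumFoldIncrease(trace)
        fn <- out(cfg[["out"]] %||% "calcium.tsv")
        .writeScalarTSV(fn, provlines, fold_increase = fold)
        list(file = fn, fold_increase = fold)
      },
      clusterstd = {
        movie <- if (!is.null(stacks[["cells"]])) stacks[["cells"]]$movie
                 else .readStageInput(cfg, out, st, readHyperstack)
        d <- dim(movieFrames(movie))
        roi <- unlist(cfg[["roi"]]) %||% c(1, d[2], 1, d[3])
        tr <- roiStdTrace(movie, roi, cfg[["channel"]] %||% 1L)
        fn <- out(cfg[["out"]] %||% "clusterstd.tsv")
        con <- file(fn, "w")
        for (p in provlines) writeLines(paste0("# ", p), con)
        write.table(data.frame(frame = seq_along(tr), std = tr), con,
                    sep = "\t", row.names = FALSE, quote = FALSE)
        close(con)
        list(file = fn)
      },
      kymograph = {
        movie <- if (!is.null(stacks[["cells"]])) stacks[["cells"]]$movie
                 else .readStageInput(cfg, out, st, readHyperstack)
        km <- kymograph(movie, unlist(cfg[["line_px"]]),
                        cfg[["width_px"]] %||% 1L, cfg[["channel"]] %||% 1L)
        fn <- out(cfg[["out"]] %||% "kymograph.tsv")
        con <- file(fn, "w")
        for (p in provlines) writeLines(paste0("# ", p), con)
        write.table(as.data.frame(km), con, sep = "\t",
                    row.names = FALSE, quote = FALSE)
        close(con)
        list(file = fn)
      })
    summary$stages[[st]] <- res
  }
  jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

.writeScalarTSV <- function(path, provlines, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provlines) writeLines(paste0("# ", p), con)
  vals <- list(...)
  write.table(data.frame(metric = names(vals),
                         value = unlist(vals)), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readStageInput <- function(cfg, out, stage, reader) {
  if (is.null(cfg[["input"]]))
    stop(sprintf(
      "stage '%s' has no upstream stage in this run; set its 'input' key to an existing file",
      stage))
  path <- cfg[["input"]]
  if (!file.exists(path)) path <- out(cfg[["input"]])
  if (!file.exists(path))
    stop(sprintf("stage '%s': input file '%s' not found", stage,
                 cfg[["input"]]))
  reader(path)
}
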