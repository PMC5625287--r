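#' @useDynLib kmclearn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

stageStep <- function(stage, verbose, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (verbose) message("[", stage, "] done")
  res
}

# small deterministic content hash (polynomial, 31-bit) for run manifests
contentHash <- function(txt) {
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full learning pipeline
#'
#' Executes extract -> estimate -> (optional reduce) -> simulate ->
#' evaluate on a bond trajectory and writes the artifact bundle:
#' the learned network (JSON), the rate table (CSV), the concentration
#' trajectory and event log (CSV), the reduced network (JSON, when a
#' reduction method is configured), the error report (CSV) and a
#' machine-readable run manifest (JSON with package version, seeds and
#' the configuration). Deterministic given the configured seeds. Any
#' stage error aborts with the stage name; files written before the
#' failure are recorded in `manifest_partial.json`.
#'
#' @param config configuration list as returned by
#'   [readPipelineConfig()] (or an equivalent list).
#' @param trajectoryInput a [BondTrajectory-class], or a path to a
#'   bond-list text file (see [readBondList()]) or multi-frame XYZ file
#'   (cutoffs from `config$cutoffs` are then applied).
#' @param outputDir output directory (default from config).
#' @param verbose log one line per stage.
#' @return invisibly, a list with the main in-memory artifacts
#'   (`network`, `counts`, `trajectory`, `reduction`, `errorReport`,
#'   `files`).
#' @export
runPipeline <- function(config, trajectoryInput,
                        outputDir = config$output_dir, verbose = TRUE) {
  for (req in c("tau_frames", "frame_dt"))
    if (is.null(config[[req]]))
      stop("pipeline stage 'config' failed: missing required key ", req,
           call. = FALSE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) {
    files <<- c(files, name)
    file.path(outputDir, name)
  }
  bondTraj <- stageStep("input", verbose, {
    if (is(trajectoryInput, "BondTrajectory")) trajectoryInput
    else if (grepl("\\.xyz$", trajectoryInput, ignore.case = TRUE)) {
      if (is.null(config$cutoffs))
        stop("coordinate input requires 'cutoffs' in the configuration")
      xyz <- readXYZ(trajectoryInput)
      bondStatesFromCoordinates(xyz$frames, xyz$elements,
                                unlist(config$cutoffs),
                                frameDt = config$frame_dt)
    } else readBondList(trajectoryInput, frameDt = config$frame_dt)
  })
  ext <- stageStep("extract", verbose,
                   extractReactions(bondTraj, tau = config$tau_frames))
  if (verbose)
    message("[extract] ", nReactions(ext$network), " reaction types, ",
            nrow(ext$events), " events, ", nSpecies(ext$network),
            " species")
  writeNetworkJSON(ext$network, emit("network.json"))
  if (!is.null(ext$informative))
    exportRateTableCSV(ext$network, ext$informative, emit("rates.csv"))
  writeTrajectoryCSV(ext$trajectory, emit("trajectory.csv"))
  writeEventsCSV(ext$events, emit("events.csv"))
  writeCountsCSV(ext$counts, emit("counts.csv"))

  reduction <- NULL
  method <- if (is.null(config$method)) "none" else config$method
  if (method != "none" && nReactions(ext$network) > 0L) {
    reduction <- stageStep("reduce", verbose, {
      if (method == "count") {
        countBasedReduce(ext$network, ext$counts, f = config$min_count)
      } else {
        x0 <- countsMatrix(ext$trajectory)[1L, ]
        Tn <- nrow(countsMatrix(ext$trajectory)) - 1L
        samp <- sampleTrajectory(
          simulateSSA(ext$network, x0, Tn * config$frame_dt,
                      seed = config$seed),
          (0:Tn) * config$frame_dt, ext$network)
        moment <- buildMomentSystem(ext$network, samp,
                                    dt = config$frame_dt)
        lambda <- if (is.null(config$lambda) || is.na(config$lambda))
          nReactions(ext$network) else config$lambda
        if (method == "iqp") reduceIQP(moment, lambda, ext$network)
        else reduceLasso(moment, lambda, ext$network,
                         epsilon = config$epsilon)
      }
    })
    if (verbose)
      message("[reduce] method=", method, " kept ",
              sum(reduction@support), "/", length(reduction@support),
              if (!is.na(reduction@objective))
                paste0(" objective=", format(reduction@objective,
                                             digits = 6)) else "")
    writeNetworkJSON(reduction@network, emit("reduced.json"))
  }

  errorReport <- NULL
  simNetwork <- if (!is.null(reduction)) reduction@network else ext$network
  if (nReactions(simNetwork) > 0L) {
    errorReport <- stageStep("simulate+evaluate", verbose, {
      ref <- ext$trajectory
      x0 <- countsMatrix(ref)[1L, ]
      sims <- simulateEnsemble(simNetwork, x0, ref@times,
                               S = config$replicates,
                               seed = config$seed + 1000L)
      rmseVsReference(sims, ref, burnIn = config$burn_in)
    })
    writeErrorReportCSV(errorReport, emit("error_report.csv"))
  }

  cfgJson <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE))
  manifest <- list(
    package = "kmclearn",
    version = as.character(utils::packageVersion("kmclearn")),
    seed = config$seed,
    config = config,
    configHash = contentHash(cfgJson),
    files = files)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(network = ext$network, counts = ext$counts,
                 trajectory = ext$trajectory, events = ext$events,
                 reduction = reduction, errorReport = errorReport,
                 files = c(files, "manifest.json"),
                 outputDir = outputDir))
}
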