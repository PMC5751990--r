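## End-to-end orchestration, RF container I/O and run manifests.

RF_SCHEMA_VERSION <- 1L

#' Write an RF frame to a plain-text container
#'
#' The container is a pair of files sharing a prefix: `<path>.csv` holds the
#' sample matrix (one RF line per column, full double precision) and
#' `<path>.json` holds every acquisition field plus the origin depth and a
#' schema version. The round trip through [readRFContainer()] is lossless.
#'
#' @param frame an \linkS4class{RFFrame}.
#' @param path file prefix (without extension).
#' @return the prefix, invisibly.
#' @export
writeRFContainer <- function(frame, path) {
  stopifnot(is(frame, "RFFrame"))
  acq <- frame@acquisition
  meta <- list(schemaVersion = RF_SCHEMA_VERSION,
               nSamples = nrow(frame@samples), nLines = ncol(frame@samples),
               samplingRate = acq@samplingRate,
               centerFrequency = acq@centerFrequency,
               band = acq@band, soundSpeed = acq@soundSpeed,
               linePitch = acq@linePitch,
               pulseBandwidthFraction = acq@pulseBandwidthFraction,
               originDepth = frame@originDepth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  lines <- apply(frame@samples, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, paste0(path, ".csv"))
  invisible(path)
}

#' Read an RF frame from a plain-text container
#'
#' @param path file prefix used in [writeRFContainer()].
#' @return an \linkS4class{RFFrame}.
#' @export
readRFContainer <- function(path) {
  jsonPath <- paste0(path, ".json")
  csvPath <- paste0(path, ".csv")
  if (!file.exists(jsonPath) || !file.exists(csvPath))
    stopf("RF container %s.{csv,json} not found", path)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  need <- c("schemaVersion", "nSamples", "nLines", "samplingRate",
            "centerFrequency", "band", "soundSpeed", "linePitch",
            "pulseBandwidthFraction", "originDepth")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("RF container missing attributes: %s", paste(miss, collapse = ", "))
  if (meta$schemaVersion > RF_SCHEMA_VERSION)
    stopf("unsupported RF container schema version %s", meta$schemaVersion)
  txt <- readLines(csvPath)
  if (length(txt) != meta$nSamples)
    stopf("truncated RF container: expected %d sample rows, found %d",
          meta$nSamples, length(txt))
  rows <- strsplit(txt, ",", fixed = TRUE)
  if (any(lengths(rows) != meta$nLines))
    stopf("truncated RF container: inconsistent line count")
  samples <- matrix(as.numeric(unlist(rows)), nrow = meta$nSamples,
                    ncol = meta$nLines, byrow = TRUE)
  if (any(!is.finite(samples))) stopf("corrupt RF container: non-finite samples")
  acq <- AcquisitionConfig(samplingRate = meta$samplingRate,
                           centerFrequency = meta$centerFrequency,
                           band = meta$band, soundSpeed = meta$soundSpeed,
                           linePitch = meta$linePitch,
                           pulseBandwidthFraction = meta$pulseBandwidthFraction)
  RFFrame(samples, acq, meta$originDepth)
}

#' Write a parametric map as a CSV grid with a JSON sidecar
#'
#' @param map a \linkS4class{ParametricMap}.
#' @param path file prefix.
#' @return the prefix, invisibly.
#' @export
writeParametricMap <- function(map, path) {
  v <- mapValues(map)
  v[!mapMask(map)] <- NA_real_
  utils::write.table(v, paste0(path, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  g <- map@gridGeometry
  jsonlite::write_json(
    list(parameter = parameterName(map), units = mapUnits(map),
         nAxial = nrow(v), nLateral = ncol(v),
         windowLambdas = g$windowLambdas, overlap = g$overlap),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for a reproducible end-to-end run. The
#' defaults define a desk-scale demonstration: a small homogeneous phantom
#' plus reference, a reduced hyperparameter grid, and a compact cohort.
#'
#' @param seed run seed; every stage derives its own sub-seed from it.
#' @param outDir output directory.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param tumorSpec,refSpec \linkS4class{PhantomSpec}s for the sample and
#'   reference media.
#' @param mapParameters parameters to map over the demo phantom.
#' @param windowLambdas,overlap windowing controls; `overlap = 1` is rejected
#'   (zero hop).
#' @param cohortSpec a \linkS4class{CohortSpec}.
#' @param scanTime scan time for classification.
#' @param mode feature mode for classification.
#' @param classifier a [classifierConfig()].
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           outDir = tempfile("qusrm-run-"),
                           acq = AcquisitionConfig(),
                           tumorSpec = PhantomSpec(effectiveRadius = 60,
                                                   numberDensity = 300,
                                                   attenuationSlope = 0.9,
                                                   extent = c(10, 4)),
                           refSpec = referencePhantom(extent = c(10, 4)),
                           mapParameters = c("MBF", "SS", "SI", "AAC"),
                           windowLambdas = 10, overlap = 0.8,
                           cohortSpec = CohortSpec(
                             groupSizes = c(CR = 7L, PR = 10L, NR = 7L)),
                           scanTime = "week4",
                           mode = "combined",
                           classifier = classifierConfig(
                             CGrid = 2^c(0, 4, 8), gammaGrid = 2^c(-8, -4, 0),
                             nSubsets = 10L, nSelected = 3L)) {
  if (overlap >= 1) stopf("overlap = 1 gives a zero hop; must be < 1")
  structure(list(seed = as.integer(seed), outDir = outDir, acq = acq,
                 tumorSpec = tumorSpec, refSpec = refSpec,
                 mapParameters = mapParameters,
                 windowLambdas = windowLambdas, overlap = overlap,
                 cohortSpec = cohortSpec, scanTime = scanTime, mode = mode,
                 classifier = classifier),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> extract -> texture -> assemble -> classify ->
#' stats/survival on synthetic inputs, writing CSV/JSON outputs and a run
#' manifest with per-file checksums. Identical configuration and seed yield
#' byte-identical feature tables.
#'
#' @param config a [pipelineConfig()].
#' @return a list of class `RunManifest` (also written as `manifest.json`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outDir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ## simulate
  frames <- stage("simulate", {
    tumor <- simulatePhantomRF(config$tumorSpec, config$acq,
                               deriveSeed(config$seed, 1L))
    ref <- simulatePhantomRF(config$refSpec, config$acq,
                             deriveSeed(config$seed, 2L))
    writeRFContainer(tumor, out("tumor_rf"))
    writeRFContainer(ref, out("reference_rf"))
    list(tumor = tumor, ref = ref)
  })

  ## extract parametric maps
  maps <- stage("extract", {
    d <- dim(rfSamples(frames$tumor))
    roi <- c(1L, 1L, d[1], d[2])
    qc <- qusConfig(frames$ref, config$refSpec,
                    windowLambdas = config$windowLambdas,
                    overlap = config$overlap)
    m <- computeQusMaps(frames$tumor, roi, config$mapParameters, qc)
    for (p in names(m)) writeParametricMap(m[[p]], out(paste0("map_", p)))
    m
  })

  ## texture features of the maps
  textures <- stage("texture", {
    tx <- lapply(maps, function(m)
      tryCatch(textureFeatures(m), error = function(e) NULL))
    keep <- !vapply(tx, is.null, logical(1))
    df <- do.call(rbind, lapply(names(tx)[keep], function(p)
      data.frame(parameter = p, CON = tx[[p]]$CON, COR = tx[[p]]$COR,
                 ENE = tx[[p]]$ENE, HOM = tx[[p]]$HOM)))
    utils::write.csv(df, out("phantom_textures.csv"), row.names = FALSE)
    df
  })

  ## cohort simulation + feature assembly
  cohort <- stage("assemble", {
    co <- simulateCohort(config$cohortSpec, deriveSeed(config$seed, 3L))
    utils::write.csv(co$patients, out("patients.csv"), row.names = FALSE)
    utils::write.csv(co$features, out("features.csv"), row.names = FALSE)
    utils::write.csv(
      co$patients[, c("id", "label", "recurrenceMonths", "event")],
      out("survival.csv"), row.names = FALSE)
    ft <- cohortFeatureTable(co, config$scanTime)
    utils::write.csv(ft, out(paste0("feature_vectors_", config$scanTime, ".csv")),
                     row.names = FALSE)
    list(cohort = co, featureTable = ft)
  })

  ## classification
  clf <- stage("classify", {
    cfg <- config$classifier
    cfg$seed <- deriveSeed(config$seed, 4L)
    res <- runResponseClassification(cohort$featureTable, config$mode, cfg)
    jsonlite::write_json(
      list(mode = res$mode, task = cfg$task, meanAccuracy = res$meanAccuracy,
           consensus = res$selection$consensus,
           perSubsetAccuracy = vapply(res$perSubset, function(m) m$accuracy,
                                      numeric(1))),
      out("classification_metrics.json"), auto_unbox = TRUE, digits = NA)
    hist <- as.data.frame(res$selection$histogram)
    names(hist) <- c("feature", "count")
    utils::write.csv(hist[hist$count > 0, ], out("feature_histogram.csv"),
                     row.names = FALSE)
    res
  })

  ## statistics and survival
  statsOut <- stage("stats", {
    ft <- cohort$featureTable
    groups <- split(ft$dAAC, ft$label)
    mg <- multiGroupTest(groups, correct = TRUE)
    pats <- cohort$cohort$patients
    lr <- logrankCompare(pats$recurrenceMonths, pats$event, pats$label)
    kms <- lapply(split(pats, pats$label), function(g)
      kmEstimate(g$recurrenceMonths, g$event))
    rfs5 <- vapply(kms, survivalAt, numeric(1), t = 60)
    jsonlite::write_json(
      list(dAAC_group_test = list(test = mg$testName, p = mg$pValue),
           logrank = list(chisq = lr$statistic, p = lr$pValue),
           rfs5yr = as.list(100 * rfs5)),
      out("stats_survival.json"), auto_unbox = TRUE, digits = NA)
    ok <- tryCatch({
      grDevices::png(out("km_curves.png"), width = 640, height = 480)
      fit <- survival::survfit(
        survival::Surv(recurrenceMonths, as.integer(event)) ~ label, data = pats)
      graphics::plot(fit, col = seq_along(kms), xlab = "Months",
                     ylab = "Recurrence-free survival")
      graphics::legend("bottomleft", legend = names(kms),
                       col = seq_along(kms), lty = 1)
      grDevices::dev.off()
      TRUE
    }, error = function(e) { try(grDevices::dev.off(), silent = TRUE); FALSE })
    list(groupTest = mg, logrank = lr, rfs5yr = rfs5, plotted = ok)
  })

  files <- list.files(config$outDir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "qusrm",
    version = as.character(utils::packageVersion("qusrm")),
    seed = config$seed, scanTime = config$scanTime, mode = config$mode,
    groupSizes = as.list(config$cohortSpec@groupSizes),
    nSubsets = config$classifier$nSubsets,
    meanAccuracy = clf$meanAccuracy,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  structure(c(manifest, list(outDir = config$outDir)), class = "RunManifest")
}

#' @export
print.RunManifest <- function(x, ...) {
  cat(sprintf("RunManifest: qusrm %s, seed %d, %d output files in %s\n",
              x$version, x$seed, length(x$checksums), x$outDir))
  invisible(x)
}
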