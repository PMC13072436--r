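## End-to-end orchestration: config validation, staged execution with
## deterministic per-stage seeding, structured logging, CSV/TIFF/JSON
## artifact export and a provenance manifest.

.configSchema <- function() list(
  seed = NA,
  simulate = as.list(setNames(rep(NA, length(defaultSimConfig())),
                              names(defaultSimConfig()))),
  inputs = list(ims = list(path = NA, dialect = NA),
                mxif = list(path = NA),
                panel = list(path = NA),
                roi = list(mask = NA, depth_table = NA),
                transform = list(path = NA),
                landmarks = list(path = NA)),
  segmentation = list(k = NA, channels = NA, n_init = NA, max_iter = NA,
                      tol = NA, similarity_threshold = NA, seed = NA),
  labeling = list(min_count = NA),
  normalization = list(tic = NA),
  classifier = list(folds = NA, group_by = NA, nrounds = NA, max_depth = NA,
                    eta = NA, subsample = NA, colsample = NA),
  attribution = list(method = NA, background_n = NA, n_eval = NA,
                     n_samples = NA, r_min = NA, top_n = NA,
                     cor_method = NA),
  depth = list(enabled = NA, min_rois_per_class = NA))

.checkKeys <- function(cfg, schema, path = "") {
  for (k in names(cfg)) {
    if (!k %in% names(schema))
      stop(sprintf("unknown config key '%s%s'", path, k), call. = FALSE)
    if (is.list(schema[[k]]) && !is.null(cfg[[k]])) {
      if (!is.list(cfg[[k]]))
        stop(sprintf("config key '%s%s' must be a block", path, k),
             call. = FALSE)
      .checkKeys(cfg[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys, requires exactly one of a `simulate` block or an
#' `inputs` block, and catches incoherent settings (e.g. depth analysis
#' requested without ROI mask or depth table) before any computation.
#'
#' @param config a named list, typically from [yaml::read_yaml()].
#' @return the config with defaults filled in, invisibly on success.
#' @export
validateConfig <- function(config) {
  .checkKeys(config, .configSchema())
  hasSim <- !is.null(config$simulate)
  hasInp <- !is.null(config$inputs)
  if (hasSim == hasInp)
    stop("config must contain exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  if (isTRUE(config$depth$enabled) && hasInp) {
    if (is.null(config$inputs$roi$mask))
      stop("depth analysis requires inputs.roi.mask", call. = FALSE)
    if (is.null(config$inputs$roi$depth_table))
      stop("depth analysis requires inputs.roi.depth_table", call. = FALSE)
  }
  if (hasInp && is.null(config$inputs$ims$path))
    stop("inputs.ims.path is required", call. = FALSE)
  invisible(config)
}

#' Read and validate a YAML pipeline config
#' @param path YAML path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateConfig(cfg)
  cfg
}

.logStage <- function(stage, msg)
  message(sprintf("[glomint] %s: %s", stage, msg))

#' Run the integrated IMS + MxIF pipeline
#'
#' Executes the stages in order — read or simulate, register, segment,
#' transfer labels, per-segment spectra, classify, attribute, export —
#' writing every stage artifact plus a provenance manifest into `outDir`.
#' Identical config and seed give identical outputs. Any stage's hard
#' error halts the run; the manifest is still written with the failing
#' stage recorded.
#'
#' @param config validated config list (see [validateConfig()]); a path to
#'   a YAML file is also accepted.
#' @param outDir output directory (created if missing).
#' @param seed global seed; per-stage seeds derive from it via
#'   [stageSeed()]. Defaults to `config$seed`, else 1.
#' @param resume reuse cached simulate-stage inputs found in `outDir`.
#' @return (invisibly) a list with the in-memory stage objects:
#'   `segmentation`, `labeled`, `classifier`, `attribution`, `spectra`,
#'   `manifest`, and for simulated runs `truth`.
#' @export
runPipeline <- function(config, outDir, seed = NULL, resume = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validateConfig(config)
  if (is.null(seed)) seed <- config$seed %||% 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("glomint")),
                   seed = seed,
                   config_hash = .hashConfig(config),
                   stages = list(), warnings = character())
  result <- list()
  finishStage <- function(stage, t0, files) {
    manifest$stages[[stage]] <<- list(
      seed = stageSeed(seed, stage),
      wall_clock_s = round(as.numeric(Sys.time()) - t0, 3),
      outputs = .hashFiles(files))
  }
  writeManifest <- function(failedStage = NULL) {
    if (!is.null(failedStage)) manifest$failed_stage <- failedStage
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- "input"
  tryCatch(withCallingHandlers({
    ## ---- input / simulate ----
    t0 <- as.numeric(Sys.time())
    panel <- if (!is.null(config$inputs$panel$path))
      readPanel(config$inputs$panel$path) else glomerularPanel()
    if (!is.null(config$simulate)) {
      cached <- file.path(outDir, c("ims.csv", "mxif.tif", "roi_mask.tif",
                                    "roi_depth.csv", "landmarks.csv",
                                    "ims_geometry.json"))
      if (resume && all(file.exists(cached))) {
        .logStage(stage, "resuming from cached simulated inputs")
        geom <- jsonlite::read_json(cached[6L], simplifyVector = TRUE)
        ims <- readIMS(cached[1L], "csv", pitchUm = geom$pitch_um,
                       originUm = as.numeric(geom$origin_um))
        mxif <- readMxIF(cached[2L], panel)
        roi <- readROIMask(cached[3L], cached[4L])
        lm <- readLandmarks(cached[5L])
        landmarks <- lm
        transform <- NULL
        finishStage(stage, t0, cached)
      } else {
      .logStage(stage, "simulating paired dataset")
      sim <- simulateGlomeruli(config$simulate, seed = seed)
      ims <- sim$ims; mxif <- sim$mxif; roi <- sim$roi
      result$truth <- sim$truth
      writeIMS(ims, file.path(outDir, "ims.csv"), "csv")
      jsonlite::write_json(list(pitch_um = pitchUm(ims),
                                origin_um = originUm(ims)),
                           file.path(outDir, "ims_geometry.json"),
                           auto_unbox = TRUE, digits = NA)
      writeMxIF(mxif, file.path(outDir, "mxif.tif"))
      writeROIMask(roi, file.path(outDir, "roi_mask.tif"),
                   file.path(outDir, "roi_depth.csv"))
      write.csv(data.frame(x_mxif_um = sim$landmarks$mxif[, 1],
                           y_mxif_um = sim$landmarks$mxif[, 2],
                           x_ims_um = sim$landmarks$ims[, 1],
                           y_ims_um = sim$landmarks$ims[, 2]),
                file.path(outDir, "landmarks.csv"), row.names = FALSE)
      .writeTruthJSON(sim$truth, file.path(outDir, "truth.json"))
      finishStage(stage, t0, file.path(outDir, c(
        "ims.csv", "mxif.tif", "roi_mask.tif", "roi_depth.csv",
        "landmarks.csv", "truth.json")))
      landmarks <- sim$landmarks
      transform <- NULL
      }
    } else {
      .logStage(stage, "reading inputs")
      inp <- config$inputs
      ims <- readIMS(inp$ims$path, inp$ims$dialect %||% "csv")
      mxif <- readMxIF(inp$mxif$path, panel)
      roi <- if (!is.null(inp$roi$mask))
        readROIMask(inp$roi$mask, inp$roi$depth_table) else NULL
      landmarks <- if (!is.null(inp$landmarks$path))
        readLandmarks(inp$landmarks$path) else NULL
      transform <- if (!is.null(inp$transform$path))
        readTransform(inp$transform$path) else NULL
      finishStage(stage, t0, character())
    }
    ## ---- register ----
    stage <- "register"
    t0 <- as.numeric(Sys.time())
    if (is.null(transform)) {
      transform <- if (!is.null(landmarks)) {
        tr <- estimateAffine(landmarks$mxif, landmarks$ims)
        .logStage(stage, sprintf("landmark affine fit, residual RMS %.3g um",
                                 attr(tr, "rms")))
        tr
      } else {
        .logStage(stage, "no landmarks or transform supplied; assuming aligned frames")
        RegistrationTransform()
      }
    }
    writeTransform(transform, file.path(outDir, "transform.json"))
    association <- associatePixels(mxif, ims, transform)
    finishStage(stage, t0, file.path(outDir, "transform.json"))
    ## ---- segment ----
    stage <- "segment"
    t0 <- as.numeric(Sys.time())
    sg <- config$segmentation
    if (is.null(roi)) stop("segmentation requires an ROI mask", call. = FALSE)
    segmentation <- segmentMxIF(
      mxif, roi,
      channels = unlist(sg$channels) %||% defaultSegmentationChannels(),
      k = sg$k %||% 6, seed = sg$seed %||% stageSeed(seed, stage),
      nInit = sg$n_init %||% 10, maxIter = sg$max_iter %||% 100,
      tol = sg$tol %||% 1e-8,
      similarityThreshold = sg$similarity_threshold %||% 0.3)
    .logStage(stage, sprintf("k = %d segments over %d in-ROI pixels",
                             segmentation@k, sum(!is.na(segmentation@labels))))
    dims <- dim(channelArray(mxif))[1:2]
    lab <- segmentRaster(segmentation, dims)
    lab[is.na(lab)] <- 0L
    tiff::writeTIFF(lab / 65535, file.path(outDir, "segment_labels.tif"),
                    bits.per.sample = 16L, compression = "none")
    profi <- data.frame(segment = seq_len(segmentation@k),
                        cell_type = segmentation@cellTypes,
                        segmentation@clusterProfiles, check.names = FALSE)
    write.csv(profi, file.path(outDir, "cluster_profiles.csv"),
              row.names = FALSE)
    finishStage(stage, t0, file.path(outDir, c("segment_labels.tif",
                                               "cluster_profiles.csv")))
    result$segmentation <- segmentation
    ## ---- label transfer ----
    stage <- "label"
    t0 <- as.numeric(Sys.time())
    labeled <- labelIMSPixels(association, segmentation, ims, roi,
                              minCount = config$labeling$min_count %||% 5)
    .logStage(stage, sprintf("%d IMS pixels labeled, %d excluded",
                             nrow(labeled@table), nrow(labeled@excluded)))
    .writeLabeledCSV(labeled, file.path(outDir, "labeled_ims.csv"))
    finishStage(stage, t0, file.path(outDir, "labeled_ims.csv"))
    result$labeled <- labeled
    ## ---- spectra ----
    stage <- "spectra"
    t0 <- as.numeric(Sys.time())
    spectra <- segmentSpectra(labeled)
    write.csv(spectra, file.path(outDir, "segment_spectra.csv"),
              row.names = FALSE)
    finishStage(stage, t0, file.path(outDir, "segment_spectra.csv"))
    result$spectra <- spectra
    ## ---- classify ----
    stage <- "classify"
    t0 <- as.numeric(Sys.time())
    cc <- config$classifier
    spec <- classifierSpec(folds = cc$folds %||% 5,
                           groupBy = cc$group_by %||% "roi",
                           nrounds = cc$nrounds %||% 150,
                           maxDepth = cc$max_depth %||% 5,
                           eta = cc$eta %||% 0.2,
                           subsample = cc$subsample %||% 0.9,
                           colsample = cc$colsample %||% 0.9,
                           seed = stageSeed(seed, stage))
    tic <- isTRUE(config$normalization$tic)
    classifier <- trainSegmentClassifier(labeled, spec, ticNormalize = tic)
    .logStage(stage, sprintf("minimum fold-mean metric %.3f",
                             min(classMetrics(classifier)$mean)))
    write.csv(classMetrics(classifier),
              file.path(outDir, "classifier_metrics.csv"), row.names = FALSE)
    write.csv(as.data.frame(confusionMatrix(classifier)),
              file.path(outDir, "confusion.csv"), row.names = FALSE)
    finishStage(stage, t0, file.path(outDir, c("classifier_metrics.csv",
                                               "confusion.csv")))
    result$classifier <- classifier
    ## ---- attribute ----
    stage <- "attribute"
    t0 <- as.numeric(Sys.time())
    at <- config$attribution
    attribution <- attributeSegments(
      classifier, labeled, method = at$method %||% "permutation",
      backgroundN = at$background_n %||% 200, nEval = at$n_eval %||% 300,
      nSamples = at$n_samples %||% 30, rMin = at$r_min %||% 0.1,
      corMethod = at$cor_method %||% "pearson",
      seed = stageSeed(seed, stage), ticNormalize = tic)
    .writeAttributionCSVs(attribution, outDir, topN = at$top_n %||% 10)
    finishStage(stage, t0, file.path(outDir, c(
      "global_scores.csv", "directions.csv", "rankings.csv", "bubble.csv")))
    result$attribution <- attribution
    ## ---- depth (optional) ----
    if (isTRUE(config$depth$enabled)) {
      stage <- "depth"
      t0 <- as.numeric(Sys.time())
      depthRes <- runDepthComparison(
        labeled, spec = spec,
        minRoisPerClass = config$depth$min_rois_per_class %||% 2,
        topN = at$top_n %||% 10, nSamples = at$n_samples %||% 30,
        backgroundN = at$background_n %||% 200, nEval = at$n_eval %||% 300,
        rMin = at$r_min %||% 0.1, seed = stageSeed(seed, stage),
        ticNormalize = tic)
      if (!is.null(depthRes)) {
        write.csv(depthRes$metrics, file.path(outDir, "depth_metrics.csv"),
                  row.names = FALSE)
        write.csv(depthRes$rankings, file.path(outDir, "depth_rankings.csv"),
                  row.names = FALSE)
        finishStage(stage, t0, file.path(outDir, c("depth_metrics.csv",
                                                   "depth_rankings.csv")))
        result$depth <- depthRes
      }
    }
    writeManifest()
    result$manifest <- manifest
  }, warning = function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }), error = function(e) {
    writeManifest(failedStage = stage)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Intrasample deep vs superficial comparison per segment
#'
#' For every segment whose pixels cover both depth classes with at least
#' `minRoisPerClass` glomeruli each, trains a glomerulus-grouped binary
#' depth classifier and interprets it with Shapley attributions, returning
#' per-segment binary metrics and the signed top-feature ranking for the
#' deep class. Segments without usable depth information are skipped with
#' a warning; an all-unknown dataset returns NULL with a warning.
#'
#' @param labeled a [LabeledIMSTable-class].
#' @param spec classifier settings ([classifierSpec()]).
#' @param segments segment ids to analyze (default all present).
#' @param minRoisPerClass minimum glomeruli per depth class (default 2).
#' @param topN rows kept per segment in the ranking table.
#' @param backgroundN,nEval,nSamples,rMin attribution settings.
#' @param seed integer seed.
#' @param ticNormalize as in [trainSegmentClassifier()].
#' @return list: `metrics` (one row per segment x metric), `rankings`
#'   (per segment, `topN` features by global score with deep-class sign),
#'   `classifiers`, `attributions`; or NULL when depth is unknown.
#' @export
runDepthComparison <- function(labeled, spec = classifierSpec(),
                               segments = NULL, minRoisPerClass = 2,
                               topN = 10, backgroundN = 200, nEval = 300,
                               nSamples = 30, rMin = 0.1, seed = 1,
                               ticNormalize = FALSE) {
  tb <- labeled@table
  if (!any(tb$depth_class %in% c("deep", "superficial"))) {
    warning("depth classes unknown; depth comparison skipped", call. = FALSE)
    return(NULL)
  }
  if (is.null(segments)) segments <- sort(unique(tb$segment))
  metrics <- list(); rankings <- list()
  classifiers <- list(); attributions <- list()
  for (s in segments) {
    sel <- tb$segment == s & tb$depth_class %in% c("deep", "superficial")
    nRois <- table(unique(tb[sel, c("roi_id", "depth_class")])$depth_class)
    if (length(nRois) < 2L || any(nRois < minRoisPerClass)) {
      warning(sprintf("segment %s: not enough glomeruli per depth class; skipped", s),
              call. = FALSE)
      next
    }
    cls <- trainDepthClassifier(labeled, s, spec,
                                ticNormalize = ticNormalize)
    sub <- new("LabeledIMSTable",
               table = tb[sel, , drop = FALSE],
               intensities = labeled@intensities[sel, , drop = FALSE],
               mz = labeled@mz, excluded = data.frame())
    att <- attributeSegments(cls, sub, backgroundN = backgroundN,
                             nEval = nEval, nSamples = nSamples, rMin = rMin,
                             seed = stageSeed(seed, paste0("depth", s)),
                             ticNormalize = ticNormalize)
    metrics[[length(metrics) + 1L]] <-
      cbind(segment_id = s, classMetrics(cls))
    deepRank <- rankings(att)[["deep"]]
    top <- head(deepRank, topN)
    rankings[[length(rankings) + 1L]] <- data.frame(
      segment_id = s, rank = seq_along(top), mz = att@mz[top],
      score = globalScores(att)["deep", top],
      sign = directions(att)["deep", top])
    classifiers[[as.character(s)]] <- cls
    attributions[[as.character(s)]] <- att
  }
  if (!length(metrics)) return(NULL)
  list(metrics = do.call(rbind, metrics),
       rankings = do.call(rbind, rankings),
       classifiers = classifiers, attributions = attributions)
}

.hashConfig <- function(config)
  unname(tools::md5sum(local({
    f <- tempfile()
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
    f
  })))

.hashFiles <- function(paths) {
  paths <- paths[file.exists(paths)]
  out <- as.list(tools::md5sum(paths))
  names(out) <- basename(paths)
  out
}

.writeLabeledCSV <- function(labeled, path) {
  m <- labeled@intensities
  colnames(m) <- mzLabel(labeled@mz)
  write.csv(cbind(labeled@table, as.data.frame(m, check.names = FALSE)),
            path, row.names = FALSE, quote = FALSE)
}

.writeAttributionCSVs <- function(att, outDir, topN = 10) {
  sc <- globalScores(att)
  colnames(sc) <- mzLabel(att@mz)
  write.csv(data.frame(segment = att@classes, sc, check.names = FALSE),
            file.path(outDir, "global_scores.csv"), row.names = FALSE)
  dir_ <- directions(att)
  colnames(dir_) <- mzLabel(att@mz)
  write.csv(data.frame(segment = att@classes, dir_, check.names = FALSE),
            file.path(outDir, "directions.csv"), row.names = FALSE)
  rk <- do.call(rbind, lapply(att@classes, function(cl) {
    r <- rankings(att)[[cl]]
    data.frame(segment = cl, rank = seq_along(r), mz = att@mz[r],
               score = sc[cl, r], sign = dir_[cl, r])
  }))
  write.csv(rk, file.path(outDir, "rankings.csv"), row.names = FALSE)
  write.csv(exportBubbleTable(att, topN), file.path(outDir, "bubble.csv"),
            row.names = FALSE)
}

.writeTruthJSON <- function(truth, path) {
  jsonlite::write_json(list(
    cell_types = truth@cellTypes,
    planted_markers = truth@plantedMarkers,
    depth_effects = truth@depthEffects,
    expression_matrix = truth@expressionMatrix,
    lipid_matrix = truth@lipidMatrix,
    true_transform = list(matrix = truth@trueTransform@matrix,
                          offset = truth@trueTransform@offset,
                          direction = truth@trueTransform@direction),
    seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
}
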