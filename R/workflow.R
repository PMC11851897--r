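# Run configuration and the end-to-end smoke pipeline:
# phantom -> dataset -> train / register -> noise -> evaluate.

.default_run_config <- function() {
  list(
    seed = 1L,
    outputRoot = "runs",
    volume = list(source = "phantom", path = "", dims = 128L,
                  spacing = 1, seed = 1L),
    geometry = list(sdd = 1020, detSize = 1536L, pixelSpacing = 0.194),
    range = "chest",
    # renderSize 0 renders at the detector's full resolution
    dataset = list(nTrain = 64L, nTest = 16L, imageSize = 224L,
                   renderSize = 0L, seedTrain = 11L, seedTest = 97L),
    model = list(preset = "mini", epochs = 3L, batchSize = 16L,
                 lr = 1e-5, dropout = 0.2),
    optimizer = list(method = "powell", tol = 1e-3, maxIter = 100L,
                     renderSize = 224L, nCases = 4L),
    noise = list(levels = c("low", "medium", "high"))
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validate_run_config <- function(cfg) {
  chk <- function(ok, key, msg) if (!ok) stop("invalid config '", key,
                                              "': ", msg)
  chk(cfg$model$lr > 0, "lr", "learning rate must be positive")
  chk(cfg$model$dropout >= 0 && cfg$model$dropout < 1, "dropout",
      "must be in [0, 1)")
  chk(cfg$dataset$nTrain >= 1, "nTrain", "must be >= 1")
  chk(cfg$dataset$imageSize >= 16, "imageSize", "must be >= 16")
  chk(cfg$geometry$sdd > 0, "sdd", "must be positive")
  chk(cfg$optimizer$tol > 0, "tol", "must be positive")
  chk(cfg$range %in% c("head", "chest", "pelvis"), "range",
      "must be head, chest or pelvis")
  chk(cfg$volume$source %in% c("phantom", "file"), "volume.source",
      "must be phantom or file")
  if (cfg$volume$source == "file")
    chk(nzchar(cfg$volume$path) && file.exists(cfg$volume$path),
        "volume.path", "file not found")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills every unspecified field with the
#' package defaults (SDD 1020 mm, 1536 x 1536 detector at 0.194 mm,
#' 224 x 224 model input, learning rate 1e-5, dropout 0.2), rejects
#' unknown keys, and validates values, naming the offending key on
#' failure. An empty file yields the full-default configuration.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return a validated configuration list of class \code{RunConfig}.
#' @export
loadRunConfig <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- .validate_run_config(.merge_config(.default_run_config(), user))
  structure(cfg, class = "RunConfig")
}

#' @describeIn loadRunConfig write a configuration back to YAML.
#' @param config a \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end registration pipeline
#'
#' Executes the requested stages in order: \code{phantom} (or volume
#' load), \code{dataset}, \code{train}, \code{register-learned},
#' \code{register-optim}, \code{noise}, \code{evaluate}. Every artifact is
#' written under a run directory with a manifest; re-running with an
#' identical configuration and seeds reproduces the deterministic
#' artifacts bit-identically.
#'
#' @param config a [loadRunConfig()] configuration.
#' @param stages character vector of stages to execute.
#' @param outDir run directory; default
#'   \code{<outputRoot>/run-<timestamp>}.
#' @param verbose print stage progress.
#' @return the run directory path, invisibly; artifacts include
#'   \code{report.csv} when the evaluate stage runs.
#' @export
runPipeline <- function(config = loadRunConfig(),
                        stages = c("phantom", "dataset", "train",
                                   "register-learned", "register-optim",
                                   "noise", "evaluate"),
                        outDir = NULL, verbose = FALSE) {
  known <- c("phantom", "dataset", "train", "register-learned",
             "register-optim", "noise", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(outDir))
    outDir <- file.path(config$outputRoot,
                        format(Sys.time(), "run-%Y%m%d-%H%M%S"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  log_lines <- character(0)
  note <- function(stage, detail) {
    log_lines <<- c(log_lines, jsonlite::toJSON(
      list(stage = stage, detail = detail,
           time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      auto_unbox = TRUE))
  }

  vol <- NULL
  need_vol <- function() {
    if (is.null(vol)) {
      vol <<- if (config$volume$source == "phantom") {
        makePhantom(phantomSpec(dims = config$volume$dims,
                                spacing = config$volume$spacing,
                                seed = config$volume$seed))
      } else loadCT(config$volume$path)
    }
    vol
  }
  geom <- projectionGeometry(sdd = config$geometry$sdd,
                             detRows = config$geometry$detSize,
                             detCols = config$geometry$detSize,
                             pixelSpacing = config$geometry$pixelSpacing)
  range <- captureRangePreset(config$range)
  ds <- NULL
  model <- NULL
  results <- list()

  for (stage in intersect(known, stages)) {
    say("stage: ", stage)
    if (stage == "phantom") {
      saveCT(need_vol(), file.path(outDir, "volume.nii.gz"))
      note(stage, "volume.nii.gz")
    } else if (stage == "dataset") {
      dsdir <- file.path(outDir, "dataset")
      rsz <- if (config$dataset$renderSize > 0)
        config$dataset$renderSize else NULL
      ds <- buildPoseDataset(need_vol(), geom, range,
                             n = config$dataset$nTrain,
                             seed = config$dataset$seedTrain,
                             dir = dsdir, split = "train",
                             imageSize = config$dataset$imageSize,
                             renderSize = rsz,
                             overwrite = TRUE)
      ds <- buildPoseDataset(need_vol(), geom, range,
                             n = config$dataset$nTest,
                             seed = config$dataset$seedTest,
                             dir = dsdir, split = "test",
                             imageSize = config$dataset$imageSize,
                             renderSize = rsz,
                             overwrite = TRUE)
      note(stage, sprintf("%d images", nrow(ds@manifest)))
    } else if (stage == "train") {
      if (is.null(ds)) ds <- loadPoseDataset(file.path(outDir, "dataset"))
      mcfg <- if (config$model$preset == "mini")
        miniEncoderConfig(inputSize = config$dataset$imageSize,
                          dropout = config$model$dropout)
      else encoderConfig(inputSize = config$dataset$imageSize,
                         dropout = config$model$dropout)
      tr_rows <- which(ds@manifest$split == "train")
      imgs <- datasetImages(ds, tr_rows)
      ref <- .pipeline_reference(need_vol(), geom, range, ds)
      fit <- trainPoseModel(mcfg, imgs, datasetLabels(ds)[tr_rows, ],
                            ref, range = range,
                            epochs = config$model$epochs,
                            batchSize = config$model$batchSize,
                            lr = config$model$lr, seed = config$seed)
      model <- fit$model
      saveModel(model, file.path(outDir, "model.rds"))
      utils::write.csv(fit$history, file.path(outDir, "history.csv"),
                       row.names = FALSE)
      note(stage, sprintf("final train loss %.5f",
                          utils::tail(fit$history$trainLoss, 1)))
    } else if (stage == "register-learned") {
      if (is.null(model)) model <- loadModel(file.path(outDir, "model.rds"))
      if (is.null(ds)) ds <- loadPoseDataset(file.path(outDir, "dataset"))
      te <- which(ds@manifest$split == "test")
      ref <- .pipeline_reference(need_vol(), geom, range, ds)
      pred <- predictPose(model,
                          .as_image_array(datasetImages(ds, te),
                                          model$config$inputSize),
                          reference = ref)
      truth <- datasetLabels(ds)[te, , drop = FALSE]
      lm <- defaultLandmarks(ctGeometry(need_vol()))
      mt <- vapply(seq_len(nrow(pred)), function(i)
        mtre(do.call(pose6, as.list(pred[i, ])),
             do.call(pose6, as.list(truth[i, ])), lm), numeric(1))
      results[["learned"]] <- list(pred = pred, truth = truth, mtre = mt)
      note(stage, sprintf("mean mTRE %.2f mm", mean(mt)))
    } else if (stage == "register-optim") {
      if (is.null(ds)) ds <- loadPoseDataset(file.path(outDir, "dataset"))
      te <- which(ds@manifest$split == "test")
      te <- te[seq_len(min(length(te), config$optimizer$nCases))]
      proto <- optimizerProtocol(method = config$optimizer$method,
                                 tol = config$optimizer$tol,
                                 maxIter = config$optimizer$maxIter,
                                 renderSize = config$optimizer$renderSize)
      truth <- datasetLabels(ds)[te, , drop = FALSE]
      lm <- defaultLandmarks(ctGeometry(need_vol()))
      imgs <- datasetImages(ds, te)
      pred <- matrix(0, length(te), 6,
                     dimnames = list(NULL, .POSE_NAMES))
      mt <- numeric(length(te))
      for (i in seq_along(te)) {
        init <- .with_seed(config$seed + i, {
          tp <- truth[i, ]
          tp[1:3] <- tp[1:3] + stats::runif(3, -10, 10)
          tp[4:6] <- tp[4:6] + stats::runif(3, -20, 20)
          tp
        })
        rr <- registerOptim(need_vol(), geom, imgs[[i]], proto,
                            init = do.call(pose6, as.list(init)),
                            seed = config$seed + i)
        pred[i, ] <- poseParams(resultPose(rr))
        mt[i] <- mtre(resultPose(rr), do.call(pose6, as.list(truth[i, ])),
                      lm)
      }
      results[[config$optimizer$method]] <-
        list(pred = pred, truth = truth, mtre = mt)
      note(stage, sprintf("mean mTRE %.2f mm", mean(mt)))
    } else if (stage == "noise") {
      if (is.null(ds)) ds <- loadPoseDataset(file.path(outDir, "dataset"))
      te <- which(ds@manifest$split == "test")[1]
      img <- datasetImages(ds, te)[[1]]
      ndir <- file.path(outDir, "noise")
      dir.create(ndir, showWarnings = FALSE)
      for (lev in config$noise$levels) {
        nl <- noiseLevel(lev)
        noisy <- addPoissonGaussian(img, nl, seed = config$seed)
        tiff::writeTIFF(noisy, file.path(ndir, paste0(lev, ".tiff")),
                        bits.per.sample = 16L)
        jsonlite::write_json(nl[c("name", "lam", "sigma")],
                             file.path(ndir, paste0(lev, ".json")),
                             auto_unbox = TRUE)
      }
      note(stage, paste(config$noise$levels, collapse = ","))
    } else if (stage == "evaluate") {
      if (length(results) == 0)
        stop("evaluate stage needs at least one registration stage first")
      rep <- buildReport(results)
      writeReport(rep, file.path(outDir, "report.csv"))
      writeReport(rep, file.path(outDir, "report.md"))
      note(stage, "report.csv")
    }
  }
  writeLines(log_lines, file.path(outDir, "log.jsonl"))
  writeRunConfig(config, file.path(outDir, "config.yaml"))
  invisible(outDir)
}

# Reference image: the DRR at the capture-range midpoint pose (a pose with
# prominent, centered features), preprocessed like the dataset images.
.pipeline_reference <- function(vol, geom, range, ds) {
  mid <- rangeMidpoint(range)
  drr <- projectSiddon(huToAttenuation(vol), ds@geometry,
                       do.call(pose6, as.list(mid)))
  preprocessXray(drr, size = ds@imageSize)
}

#' Reference image for a volume and capture range
#'
#' Renders the DRR at the capture-range midpoint pose — a view with the
#' anatomy centered and prominent — and preprocesses it to the model
#' input size. Any manually chosen radiograph can be substituted.
#'
#' @param vol a [CTVolume-class].
#' @param geom a [ProjectionGeometry-class] (the rendering grid).
#' @param range a [CaptureRange-class].
#' @param imageSize preprocessed output side.
#' @return a numeric matrix in [0, 1].
#' @export
referenceImage <- function(vol, geom, range, imageSize = 224L) {
  drr <- projectSiddon(huToAttenuation(vol), geom,
                       do.call(pose6, as.list(rangeMidpoint(range))))
  preprocessXray(drr, size = imageSize)
}
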