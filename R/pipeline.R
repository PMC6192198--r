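#' Pipeline configuration
#'
#' Bundles the physical and sampling defaults used by [runPipeline()]:
#' tumor-image calibration, vessel-field imaging parameters, the perfusion
#' threshold, and the permeability constants.
#'
#' @param tumorPixelSize um/pixel of rendered tumor overview frames.
#' @param tumorDim tumor frame size (pixels).
#' @param perfusionThreshold minimum velocity (um/s) counting as perfused.
#' @param HT microvascular hematocrit fraction.
#' @param K plasma clearance time constant (s).
#' @param sampleInterval,traceDuration permeability sampling scheme (s).
#' @param noiseSigma log-scale SD of cohort area noise.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(tumorPixelSize = 32, tumorDim = c(128L, 128L),
                           perfusionThreshold = 10, HT = 0.19, K = 9.1e3,
                           sampleInterval = 30, traceDuration = 600,
                           noiseSigma = 0.15) {
  cfg <- list(tumorPixelSize = tumorPixelSize, tumorDim = tumorDim,
              perfusionThreshold = perfusionThreshold, HT = HT, K = K,
              sampleInterval = sampleInterval, traceDuration = traceDuration,
              noiseSigma = noiseSigma)
  stopifnot(all(vapply(cfg, function(x) all(x > 0), logical(1))))
  cfg
}

writeCsvDeterministic <- function(df, file, seed, cfgHash) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", as.integer(seed), cfgHash), con)
  utils::write.csv(df, con, row.names = FALSE)
  file
}

configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run the simulate-quantify-stats pipeline
#'
#' Executes the requested stages in order, writing all artifacts under
#' `outDir` and a manifest (`manifest.json`) listing every produced file
#' with its MD5 checksum, the seed, and the configuration hash. Identical
#' configuration and seed reproduce byte-identical CSV/JSON outputs.
#'
#' Stages: `simulate` generates one cohort per preset (CSV per group);
#' `tumor` renders and re-measures every observed area through the imaging
#' pipeline and writes per-observation and per-group summaries; `vessels`
#' simulates and quantifies one vessel field per tissue; `permeability`
#' generates and inverts extravasation traces per tissue; `stats` runs the
#' repeated-measures ANOVA on measured relative growth per group. `stats`
#' requires the `tumor` output (`tumor_measured.csv`) to exist, and `tumor`
#' requires the simulated cohort CSVs.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; stage-level seeds are derived from it.
#' @param stages subset of
#'   `c("simulate", "tumor", "vessels", "permeability", "stats")`.
#' @param presets named list of [GrowthPreset-class] objects (default: the
#'   six shipped groups).
#' @param config a [pipelineConfig()] list.
#' @param verbose print stage progress.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(outDir, seed = 1,
                        stages = c("simulate", "tumor", "vessels",
                                   "permeability", "stats"),
                        presets = NULL, config = pipelineConfig(),
                        verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed)
  if (is.null(presets)) presets <- growthPresets(config$noiseSigma)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- configHash(config)
  files <- character()
  say <- function(...) if (verbose) message(sprintf(...))

  keyOf <- function(p) paste0(p@tissue, ":", p@cellLine)
  cohortFile <- function(key) file.path(outDir,
                                        sprintf("cohort_%s.csv", gsub(":", "_", key)))

  if ("simulate" %in% stages) {
    say("stage simulate: %d presets", length(presets))
    for (i in seq_along(presets)) {
      co <- generateCohort(presets[[i]], seed = seed + i)
      f <- cohortFile(keyOf(presets[[i]]))
      writeCsvDeterministic(co@observations, f, seed, cfgHash)
      files <- c(files, f)
    }
  }

  if ("tumor" %in% stages) {
    needed <- vapply(presets, function(p) cohortFile(keyOf(p)), character(1))
    if (!all(file.exists(needed)))
      stop("dependency error: stage 'tumor' requires cohort CSVs from ",
           "stage 'simulate'")
    say("stage tumor: measuring %d cohorts", length(needed))
    measured <- list()
    summaries <- list()
    for (i in seq_along(needed)) {
      ob <- readCohortCsv(needed[i])
      set.seed(seed + 1000L + i)
      ob$measuredAreaMm2 <- vapply(seq_len(nrow(ob)), function(j) {
        if (is.na(ob$areaMm2[j])) return(NA_real_)
        img <- renderTumorFrame(ob$areaMm2[j],
                                pixelSize = config$tumorPixelSize,
                                dim = config$tumorDim)
        segmentTumorArea(img, pixelSize = config$tumorPixelSize)
      }, numeric(1))
      mo <- ob
      mo$areaMm2 <- mo$measuredAreaMm2
      mo <- relativeGrowth(mo)
      measured[[i]] <- mo
      cr <- summarizeCohort(mo)
      summaries[[i]] <- data.frame(
        tissue = cr@tissue, cellLine = cr@cellLine,
        nImplanted = cr@nImplanted, nEngrafted = cr@nEngrafted,
        takeRatePct = cr@takeRatePct, cr@growth)
    }
    f1 <- writeCsvDeterministic(do.call(rbind, measured),
                                file.path(outDir, "tumor_measured.csv"),
                                seed, cfgHash)
    f2 <- writeCsvDeterministic(do.call(rbind, summaries),
                                file.path(outDir, "tumor_summary.csv"),
                                seed, cfgHash)
    files <- c(files, f1, f2)
  }

  if ("vessels" %in% stages) {
    say("stage vessels: one field per tissue")
    rows <- list()
    tissues <- list(
      FW = vesselFieldParams(fieldSize = c(220, 220), pixelSize = 1,
                             nSegments = 3L, diameterRange = c(12, 20),
                             velocityRange = c(300, 600), frameRate = 10),
      DSC = vesselFieldParams(fieldSize = c(220, 220), pixelSize = 1,
                              nSegments = 5L, diameterRange = c(8, 12),
                              velocityRange = c(150, 350), frameRate = 10))
    for (tn in names(tissues)) {
      fov <- generateVesselField(tissues[[tn]], seed = seed + 2000L +
                                   match(tn, names(tissues)))
      q <- quantifyField(fov,
                         perfusionThreshold = config$perfusionThreshold)
      rows[[tn]] <- data.frame(tissue = tn, t(q$metrics),
                               areaCm2 = q$areaCm2,
                               nSegments = nrow(q$segments))
    }
    f <- writeCsvDeterministic(do.call(rbind, rows),
                               file.path(outDir, "vessel_metrics.csv"),
                               seed, cfgHash)
    files <- c(files, f)
  }

  if ("permeability" %in% stages) {
    say("stage permeability: one trace per tissue")
    pTrue <- c(FW = 3e-7, DSC = 1.5e-7)   # bone leakier than muscle
    rows <- list()
    for (tn in names(pTrue)) {
      tr <- generatePermeabilityTrace(
        pTrue[[tn]], I0 = 100, Ib = 10, vsRatio = 3,
        HT = config$HT, K = config$K,
        sampleInterval = config$sampleInterval,
        duration = config$traceDuration, noiseSd = 0.5,
        seed = seed + 3000L + match(tn, names(pTrue)))
      est <- estimatePermeability(tr)
      if (est$flag != "ok")
        warning("permeability estimate flagged '", est$flag, "' for ", tn)
      rows[[tn]] <- data.frame(tissue = tn, pTrue = pTrue[[tn]],
                               pEstimated = est$P, slope = est$slope,
                               flag = est$flag)
    }
    f <- writeCsvDeterministic(do.call(rbind, rows),
                               file.path(outDir, "permeability.csv"),
                               seed, cfgHash)
    files <- c(files, f)
  }

  if ("stats" %in% stages) {
    mf <- file.path(outDir, "tumor_measured.csv")
    if (!file.exists(mf))
      stop("dependency error: stage 'stats' requires 'tumor_measured.csv' ",
           "from stage 'tumor'")
    say("stage stats: RM-ANOVA per group")
    ob <- readCohortCsv(mf)
    ob <- ob[!is.na(ob$relativeArea), ]
    out <- list()
    for (key in unique(paste(ob$tissue, ob$cellLine, sep = ":"))) {
      g <- ob[paste(ob$tissue, ob$cellLine, sep = ":") == key, ]
      res <- tryCatch(
        rmAnova(g, subject = "animalId", time = "day",
                value = "relativeArea"),
        error = function(e) NULL)
      if (is.null(res)) next
      out[[key]] <- list(F = res@F, df1 = res@df1, df2 = res@df2,
                         p = res@p, epsilonGG = res@epsilonGG,
                         mauchlyP = res@mauchlyP,
                         sphericityApplied = res@sphericityApplied,
                         nSubjects = res@nSubjects,
                         posthoc = res@posthoc, summary = res@summary)
    }
    f <- file.path(outDir, "stats.json")
    jsonlite::write_json(list(seed = seed, config = cfgHash, groups = out),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  manifest <- list(seed = seed, configHash = cfgHash, config = config,
                   stages = stages,
                   files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
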