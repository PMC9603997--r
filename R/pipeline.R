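#' Default end-to-end run configuration
#'
#' A plain named list holding every tunable of the pipeline: cohort
#' design (6 DIPG vs 4 sham, pons V_T multiplier 2, dose 169 +/- 39
#' kBq/g), the 24-frame schedule, the 25.5-60 min static window, the
#' 0-60 min AUC interval, Logan t* = 22.5 min, the striatum reference
#' region, the voxel-mask fraction 0.2, the phantom noise level, and
#' alpha = 0.05. `readRunConfig()` reads the same fields from a YAML file,
#' falling back to these defaults for anything unspecified.
#'
#' @param outDir output directory for [runPipeline()].
#' @param seed master seed of the run.
#' @param ... overrides of any default field.
#' @return Named list of configuration values.
#' @export
defaultRunConfig <- function(outDir, seed = 1, ...) {
  cfg <- list(
    out_dir = outDir, seed = seed,
    n_dipg = 6L, n_sham = 4L,
    vt_multiplier = 2, tumor_region = "pons",
    reference_region = "striatum",
    dose_per_gram_mean = 169, dose_per_gram_sd = 39,
    weight_mean = 100, weight_sd = 10,
    noise_level = 1,
    static_window = c(25.5, 60), auc_interval = c(0, 60),
    t_star = 22.5, mask_fraction = 0.2,
    alpha = 0.05, welch = TRUE, voxelwise = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @rdname defaultRunConfig
#' @param path YAML file of configuration fields.
#' @export
readRunConfig <- function(path, outDir = NULL) {
  if (!file.exists(path)) petStop("io", "config not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user$out_dir) && is.null(outDir))
    petStop("config", "config must set out_dir (or pass outDir)")
  cfg <- defaultRunConfig(outDir = if (is.null(outDir)) user$out_dir else outDir,
                          seed = if (is.null(user$seed)) 1 else user$seed)
  keep <- intersect(names(user), names(cfg))
  cfg[keep] <- user[keep]
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    petStop("config", "unknown config field(s): %s",
            paste(unknown, collapse = ", "))
  cfg
}

cohortFromConfig <- function(config) {
  CohortSpec(nDipg = config$n_dipg, nSham = config$n_sham,
             vtMultiplier = config$vt_multiplier,
             tumorRegion = config$tumor_region,
             dosePerGramMean = config$dose_per_gram_mean,
             dosePerGramSd = config$dose_per_gram_sd,
             weightMean = config$weight_mean, weightSd = config$weight_sd,
             phantom = defaultPhantomSpec(noiseLevel = config$noise_level),
             schedule = defaultFrameSchedule())
}

runStage <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e) {
    who <- if (is.null(subject)) "" else sprintf(" (subject %s)", subject)
    petStop("stage", "stage '%s' failed%s: %s", stage, who,
            conditionMessage(e))
  })
}

#' Run the full simulate - quantify - model - compare pipeline
#'
#' Simulates a DIPG-versus-sham cohort, writes every study to disk
#' (NIfTI + sidecar), and produces per subject: the late-window static
#' SUV image, the seven-region TAC table, AUC and reference-region AUC
#' ratios, ROI Logan V_T per region and (optionally) the voxel-wise V_T
#' parametric map. Per cohort it writes the tidy measurement table,
#' per-region summaries, the structure-by-group ANOVA with Bonferroni
#' pairwise comparisons for SUV, AUC and V_T, the AUC-ratio group test,
#' and a JSON manifest with the full configuration, per-stage wall times
#' and MD5 checksums of every output file. A fixed seed reproduces
#' identical numeric outputs.
#'
#' @param config configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return Invisibly, a list: `measurements`, `summaries`, `anova`,
#'   `comparisons`, `aucrTest`, `mapSummaries`, `truth`, `manifest`.
#' @export
runPipeline <- function(config) {
  t0 <- Sys.time()
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(name, expr) {
    tic <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    res
  }

  cohortSpec <- cohortFromConfig(config)
  cohort <- clock("simulate", runStage("simulate", NULL,
                                       simulateCohort(cohortSpec, config$seed)))
  studies <- cohort$studies
  n <- length(studies)
  seeds <- deriveSeeds(config$seed, n)

  clock("write_inputs", runStage("write_inputs", NULL, {
    writeLabelVolume(studies[[1]]@labels, file.path(outDir, "labels.nii.gz"))
    writeSubjectsTable(studies, seeds, file.path(outDir, "subjects.tsv"))
    writeResultsTable(cohort$truth, file.path(outDir, "ground_truth.tsv"))
    for (sim in studies) {
      sdir <- file.path(outDir, sim@study@subject@subjectId)
      dir.create(sdir, showWarnings = FALSE)
      writeDynamicStudy(sim@study, file.path(sdir, "dynamic.nii.gz"))
    }
  }))

  brainRegions <- setdiff(names(studies[[1]]@labels@regionNames),
                          cohortSpec@phantom@bloodRegion)
  measurements <- list()
  tacRows <- list()
  mapSummaries <- list()

  for (sim in studies) {
    study <- sim@study
    sub <- study@subject
    sid <- sub@subjectId
    sdir <- file.path(outDir, sid)

    tacs <- runStage("extract_tac", sid,
                     lapply(brainRegions, function(rn)
                       extractTac(study, sim@labels, rn)))
    names(tacs) <- brainRegions
    idif <- runStage("idif", sid, extractIdif(study, sim@labels,
                                              cohortSpec@phantom@bloodRegion))
    tacRows[[sid]] <- tacTable(tacs, sub@injectedDose, sub@bodyWeight)

    suvStatic <- runStage("static_suv", sid, {
      img <- suvTransform(staticAverage(study, config$static_window),
                          sub@injectedDose, sub@bodyWeight)
      RNifti::writeNifti(asNiftiOnGrid(img, study@grid),
                         file.path(sdir, "suv_static.nii.gz"))
      img
    })
    suvByRegion <- vapply(brainRegions, function(rn)
      mean(suvStatic[regionVoxels(sim@labels, rn)]), numeric(1))

    aucs <- runStage("auc", sid, lapply(tacs, function(tac)
      tacAuc(suvTransform(tac, sub@injectedDose, sub@bodyWeight),
             config$auc_interval)))
    refAuc <- aucs[[config$reference_region]]
    aucr <- vapply(aucs, function(a) aucRatio(a, refAuc), numeric(1))

    fits <- runStage("logan_roi", sid, lapply(tacs, function(tac)
      loganFit(tac, idif, tStar = config$t_star)))
    vts <- vapply(fits, function(f) f@vt, numeric(1))

    if (isTRUE(config$voxelwise)) {
      map <- runStage("logan_map", sid,
        loganParametricMap(study, idif, tStar = config$t_star,
                           labels = sim@labels,
                           maskFraction = config$mask_fraction,
                           window = config$static_window,
                           bloodRegion = cohortSpec@phantom@bloodRegion))
      RNifti::writeNifti(asNiftiOnGrid(map@values, study@grid),
                         file.path(sdir, "vt_map.nii.gz"))
      ms <- summarizeParametricMap(map, sim@labels, brainRegions)
      ms$subject_id <- sid
      mapSummaries[[sid]] <- ms
    }

    measurements[[sid]] <- data.frame(
      subject_id = sid, group = sub@group,
      region = rep(brainRegions, 4),
      measure = rep(c("SUV", "AUC", "AUCr", "VT"), each = length(brainRegions)),
      value = c(suvByRegion, vapply(aucs, function(a) a@value, numeric(1)),
                aucr, vts),
      stringsAsFactors = FALSE)
  }
  timings[["per_subject"]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  measurements <- do.call(rbind, measurements)
  rownames(measurements) <- NULL
  clock("tables", {
    writeResultsTable(do.call(rbind, tacRows), file.path(outDir, "tacs.tsv"))
    writeResultsTable(measurements, file.path(outDir, "measurements.tsv"))
  })

  stats <- clock("statistics", runStage("statistics", NULL, {
    summaries <- do.call(rbind, lapply(c("SUV", "AUC", "AUCr", "VT"),
      function(m) cbind(measure = m, summarizeMeasures(measurements, m))))
    tests <- lapply(c("SUV", "AUC", "VT"), function(m)
      structureGroupAnova(measurements, m, alpha = config$alpha,
                          welch = config$welch))
    names(tests) <- c("SUV", "AUC", "VT")
    anova <- do.call(rbind, lapply(names(tests), function(m)
      cbind(measure = m, tests[[m]]$anova)))
    comparisons <- do.call(rbind, lapply(names(tests), function(m)
      tests[[m]]$pairwise))
    aucrTest <- twoGroupTest(measurements, config$tumor_region, "AUCr",
                             welch = config$welch)
    writeResultsTable(summaries, file.path(outDir, "summaries.tsv"))
    writeResultsTable(anova, file.path(outDir, "anova.tsv"))
    writeResultsTable(comparisons, file.path(outDir, "comparisons.tsv"))
    writeResultsTable(aucrTest, file.path(outDir, "aucr_test.tsv"))
    list(summaries = summaries, anova = anova, comparisons = comparisons,
         aucrTest = aucrTest)
  }))

  mapSummaries <- if (length(mapSummaries)) do.call(rbind, mapSummaries)
                  else NULL
  if (!is.null(mapSummaries)) {
    rownames(mapSummaries) <- NULL
    writeResultsTable(mapSummaries, file.path(outDir, "vt_map_summaries.tsv"))
  }

  files <- setdiff(list.files(outDir, recursive = TRUE), "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(outDir, files)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("ponsPET")),
    config = config,
    config_hash = configHash(config),
    wall_time_s = timings,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(measurements = measurements,
                 summaries = stats$summaries, anova = stats$anova,
                 comparisons = stats$comparisons, aucrTest = stats$aucrTest,
                 mapSummaries = mapSummaries, truth = cohort$truth,
                 manifest = manifest))
}

# MD5 of the canonical JSON serialisation of the config.
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
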