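# End-to-end orchestration: statistics -> features -> filter -> train ->
# predict -> merge -> evaluate, separately for the SNV and indel streams,
# with a deterministic run manifest.

#' Load filter and model settings from a YAML config file
#'
#' Expected layout (all sections optional; omitted entries keep package
#' defaults):
#'
#' ```yaml
#' filters:
#'   good: {missing_rate: [-.inf, 0.01], hwe_p: [0.01, .inf]}
#'   bad:  {missing_rate: [-.inf, 0.05]}
#'   na_tolerance: 0
#' model: {trees: 50, probability_threshold: 0.5}
#' features: {calibration_chrom: "1", window_size: 1000}
#' ```
#'
#' @param path YAML file; `NULL` returns all defaults.
#' @return list with `filterConfig` ([FilterConfig-class]), `nTrees`,
#'   `probabilityThreshold`, `calibChrom`, `windowSize`.
#' @export
readQcConfig <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  toBounds <- function(b) lapply(b, function(x) as.numeric(unlist(x)))
  fc <- filterConfig(good = toBounds(y$filters$good %||% list()),
                     bad = toBounds(y$filters$bad %||% list()),
                     naTolerance = y$filters$na_tolerance %||% 0L)
  list(filterConfig = fc,
       nTrees = as.integer(y$model$trees %||% 50L),
       probabilityThreshold = y$model$probability_threshold %||% 0.5,
       calibChrom = as.character(y$features$calibration_chrom %||% "1"),
       windowSize = as.integer(y$features$window_size %||% 1000L))
}

.runStream <- function(stats, config, nTrees, probabilityThreshold, seed) {
  labels <- classifyByFilters(stats, config)
  rep <- withCallingHandlers(
    partitionReport(labels),
    warning = function(w) invokeRestart("muffleWarning"))
  und <- which(labels == "UNDETERMINED")
  result <- data.frame(
    chrom = stats$chrom, pos = stats$pos, ref = stats$ref, alt = stats$alt,
    label = as.character(labels), stage = "FILTER",
    probability = NA_real_, stringsAsFactors = FALSE)
  predictedKeys <- list(high = character(), low = character())
  imputedN <- 0L
  if (length(und) > 0L) {
    ts <- buildTrainingSet(stats, labels, seed = seed)
    model <- trainQcModel(ts, nTrees = nTrees,
                          probabilityThreshold = probabilityThreshold,
                          seed = seed)
    pred <- predictQc(model, stats[und, , drop = FALSE])
    result$label[und] <- as.character(pred$label)
    result$stage[und] <- "PREDICTED"
    result$probability[und] <- pred$probability
    imputedN <- sum(pred$imputed)
    predictedKeys <- list(high = stats$key[und][pred$label == "HIGH"],
                          low = stats$key[und][pred$label == "LOW"])
  } else model <- NULL
  final <- mergeFinalSets(stats$key[labels == "HIGH"],
                          stats$key[labels == "LOW"],
                          predictedKeys$high, predictedKeys$low)
  stopifnot(length(final$high) + length(final$low) == nrow(stats))
  list(result = result, labels = labels, filterReport = rep,
       final = final, model = model, imputed = imputedN)
}

#' Run the full variant-QC pipeline
#'
#' Reads the inputs, computes statistics and features, applies the hard
#' filters, trains a forest per stream (SNVs and indels are filtered,
#' trained and predicted as two fully separate streams), predicts the
#' undetermined variants, merges the final HIGH/LOW sets, evaluates them,
#' and writes into `outDir`:
#'
#' * `labels.tsv` — one row per variant (chrom, pos, ref, alt, type, label,
#'   stage, probability);
#' * `high.vcf` / `low.vcf` — the input records split by final label,
#'   byte-faithful to the input;
#' * `metrics.json` — [summarizeQc()] reports of the final HIGH and LOW
#'   sets;
#' * `manifest.json` — seed, config hash, per-stage counts and warnings
#'   (written on failure too, with the failing stage).
#'
#' All randomness derives from `seed`; reruns with identical inputs and
#' seed produce byte-identical labels and manifest.
#'
#' @param vcf path to the input VCF.
#' @param fasta path to the reference FASTA (GC features).
#' @param ped optional pedigree (PED) path; without it the Mendelian-error
#'   filter is disabled.
#' @param known optional known-sites path (VCF or TSV).
#' @param chip optional microarray genotype TSV path.
#' @param config optional YAML config path (see [readQcConfig()]).
#' @param outDir output directory, created if needed.
#' @param seed integer master seed.
#' @param calibChrom calibration chromosome override.
#' @param probabilityThreshold,nTrees model overrides of the config values.
#' @return the manifest, invisibly, as a list.
#' @export
runQc <- function(vcf, fasta, ped = NULL, known = NULL, chip = NULL,
                  config = NULL, outDir, seed = 1L,
                  calibChrom = NULL, probabilityThreshold = NULL,
                  nTrees = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cfg <- readQcConfig(config)
  calibChrom <- calibChrom %||% cfg$calibChrom
  probabilityThreshold <- probabilityThreshold %||% cfg$probabilityThreshold
  nTrees <- nTrees %||% cfg$nTrees

  ## config hash over the resolved settings, for the manifest
  cfgFile <- file.path(outDir, "config_used.yaml")
  yaml::write_yaml(list(
    filters = list(good = cfg$filterConfig@good, bad = cfg$filterConfig@bad,
                   na_tolerance = cfg$filterConfig@naTolerance),
    model = list(trees = nTrees,
                 probability_threshold = probabilityThreshold),
    features = list(calibration_chrom = calibChrom,
                    window_size = cfg$windowSize)), cfgFile)
  configHash <- unname(tools::md5sum(cfgFile))

  manifest <- list(
    tool = "VariantForest",
    version = as.character(packageVersion("VariantForest")),
    inputs = list(vcf = vcf, fasta = fasta, ped = ped, known = known,
                  chip = chip, config = config),
    seed = seed, configHash = configHash, status = "running",
    warnings = character())
  warnings <- character()
  stage <- "setup"
  writeManifest <- function() {
    manifest$warnings <<- warnings
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }

  res <- tryCatch({
    stage <- "read"
    vcs <- readVariantCallSet(vcf)
    pedObj <- if (!is.null(ped)) readPedigree(ped) else NULL
    knownObj <- if (!is.null(known)) readKnownSites(known) else NULL
    chipObj <- if (!is.null(chip)) readMicroarray(chip) else NULL

    stage <- "features"
    gcIndex <- buildGcIndex(fasta, windowSize = cfg$windowSize)
    thresholds <- calibrateOutlierThresholds(vcs, chrom = calibChrom)

    stage <- "stats"
    stats <- withCallingHandlers(
      computeVariantStats(vcs, ped = pedObj, thresholds = thresholds,
                          gcIndex = gcIndex),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (is.null(pedObj)) warnings <- c(warnings, "ME: disabled (no pedigree)")

    stage <- "classify"
    streams <- list(snv = which(stats$type == "snv"),
                    indel = which(stats$type == "indel"))
    streamOut <- list()
    for (k in seq_along(streams)) {
      rows <- streams[[k]]
      if (!length(rows)) next
      streamOut[[names(streams)[k]]] <- .runStream(
        stats[rows, , drop = FALSE], cfg$filterConfig, nTrees,
        probabilityThreshold, seed + k - 1L)
    }

    stage <- "write"
    resultRows <- do.call(rbind, lapply(names(streamOut), function(nm) {
      r <- streamOut[[nm]]$result
      r$type <- nm
      r$row <- streams[[nm]]
      r
    }))
    resultRows <- resultRows[order(resultRows$row), , drop = FALSE]
    resultRows$row <- NULL
    writeLabels(file.path(outDir, "labels.tsv"),
                resultRows[, c("chrom", "pos", "ref", "alt", "type",
                               "label", "stage", "probability")],
                nExpected = nrow(vcs))
    writeFilteredVcfs(vcf, resultRows$label,
                      file.path(outDir, "high.vcf"),
                      file.path(outDir, "low.vcf"))

    stage <- "evaluate"
    finalHigh <- resultRows$label == "HIGH"
    metrics <- list(
      high = summarizeQc(vcs[finalHigh, ], ped = pedObj, chip = chipObj,
                         known = knownObj),
      low = summarizeQc(vcs[!finalHigh, ], ped = pedObj, chip = chipObj,
                        known = knownObj))
    metrics <- rapply(metrics, function(x)
      ifelse(is.nan(x), NA_real_, x), classes = "numeric", how = "replace")
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10,
                         na = "null", null = "null", dataframe = "columns")
    list(streamOut = streamOut, resultRows = resultRows)
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failedStage <<- stage
    manifest$error <<- conditionMessage(e)
    writeManifest()
    ## remove partial outputs, keep the manifest
    for (f in c("labels.tsv", "high.vcf", "low.vcf", "metrics.json"))
      unlink(file.path(outDir, f))
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })

  counts <- lapply(res$streamOut, function(s) {
    fc <- s$filterReport$counts
    list(input = unname(fc[["total"]]),
         filter_high = unname(fc[["HIGH"]]),
         filter_low = unname(fc[["LOW"]]),
         undetermined = unname(fc[["UNDETERMINED"]]),
         predicted_high = length(s$final$high) - unname(fc[["HIGH"]]),
         predicted_low = length(s$final$low) - unname(fc[["LOW"]]),
         final_high = length(s$final$high),
         final_low = length(s$final$low),
         imputed_features = s$imputed)
  })
  manifest$status <- "ok"
  manifest$counts <- counts
  writeManifest()
  invisible(manifest)
}
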