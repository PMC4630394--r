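# End-to-end workflow: simulate (or load) -> preprocess -> calibrate ->
# integrity -> report.  The same building blocks back both the R-level
# runPipeline() and the command-line interface, so the two paths
# produce identical artifacts.

#' Default per-constituent wavenumber windows
#'
#' The modelling windows used by default for each constituent:
#' extractives 1750-1250, lignin 1800-800, cellulose 1500-1000,
#' hemicellulose 1750-800 cm^-1.
#'
#' @return Named list of `c(low, high)` pairs (cm^-1).
#' @export
defaultWindows <- function() {
  list(extractives   = c(1250, 1750),
       lignin        = c(800, 1800),
       cellulose     = c(1000, 1500),
       hemicellulose = c(800, 1750))
}

#' Assemble a pipeline run configuration
#'
#' One mandatory top-level seed feeds independent sub-streams for
#' generation, splitting and cross-validation, so adding a stage never
#' perturbs earlier stages' draws.
#'
#' @param seed integer master seed (mandatory).
#' @param generator a [generatorConfig()]; defaults to the standard
#'   37-sample configuration seeded from `seed`.
#' @param windows named list of per-constituent `c(low, high)` windows.
#' @param modes pretreatments to run: subset of `"raw"`,
#'   `"first_derivative"`.
#' @param algorithms subset of `"PCR"`, `"PLS1"`.
#' @param sgWindow,sgPolyorder Savitzky-Golay settings for the
#'   derivative mode.
#' @param windowBeforeDerivative apply the window before the
#'   derivative (default) or after.
#' @param nCal,nVal calibration / validation split sizes.
#' @param balanceTol split balance tolerance (see [splitSamples()]).
#' @param kMax largest component count scanned in cross-validation.
#' @param cvFolds number of CV folds; `NULL` means leave-one-out.
#' @param minProminence,minSeparation peak-extraction settings (see
#'   [extractPeaks()]).
#' @param matchTolerance band-matching tolerance in cm^-1 (see
#'   [matchBands()]).
#' @param histogramBinWidth residual histogram bin width (cm^-1).
#' @param outDir optional output directory for run artifacts.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed,
                      generator = generatorConfig(seed = seed),
                      windows = defaultWindows(),
                      modes = c("raw", "first_derivative"),
                      algorithms = c("PCR", "PLS1"),
                      sgWindow = 9L, sgPolyorder = 2L,
                      windowBeforeDerivative = TRUE,
                      nCal = 31L, nVal = 6L, balanceTol = 0.5,
                      kMax = 10L, cvFolds = NULL,
                      minProminence = 0.1, minSeparation = 16,
                      matchTolerance = 50, histogramBinWidth = 5,
                      outDir = NULL) {
  if (missing(seed)) stop("'seed' is mandatory")
  modes <- match.arg(modes, c("raw", "first_derivative"), several.ok = TRUE)
  algorithms <- match.arg(algorithms, c("PCR", "PLS1"), several.ok = TRUE)
  if (!length(modes) || !length(algorithms))
    stop("at least one mode and one algorithm are required")
  bad <- setdiff(names(windows), WOOD_CONSTITUENTS)
  if (length(bad))
    stop("unknown constituent(s) in windows: ", paste(bad, collapse = ", "))
  structure(list(
    seed = as.integer(seed), generator = generator, windows = windows,
    modes = modes, algorithms = algorithms,
    sgWindow = as.integer(sgWindow), sgPolyorder = as.integer(sgPolyorder),
    windowBeforeDerivative = isTRUE(windowBeforeDerivative),
    nCal = as.integer(nCal), nVal = as.integer(nVal),
    balanceTol = balanceTol, kMax = as.integer(kMax), cvFolds = cvFolds,
    minProminence = minProminence, minSeparation = minSeparation,
    matchTolerance = matchTolerance,
    histogramBinWidth = histogramBinWidth, outDir = outDir
  ), class = "RunConfig")
}

# Window + optional derivative for one constituent/mode.
preprocessSpectra <- function(spectra, constituent, mode, config) {
  win <- config$windows[[constituent]]
  if (is.null(win))
    stop("no window configured for constituent '", constituent, "'")
  if (mode == "raw")
    return(selectWindow(spectra, win[1], win[2]))
  if (config$windowBeforeDerivative) {
    firstDerivative(selectWindow(spectra, win[1], win[2]),
                    config$sgWindow, config$sgPolyorder)
  } else {
    selectWindow(firstDerivative(spectra, config$sgWindow,
                                 config$sgPolyorder), win[1], win[2])
  }
}

#' Calibrate all constituent x algorithm x mode combinations
#'
#' For each combination: preprocess, select the component count by
#' cross-validation on all samples, fit on the calibration subset,
#' compute diagnostics on the held-out validation subset, and record
#' the interpretation profile.
#'
#' @param spectra a [SpectraSet-class].
#' @param compositions aligned composition data.frame.
#' @param config a [runConfig()].
#' @return list with `diagnostics` (one row per combination),
#'   `profiles` (long data.frame: constituent, algorithm, mode,
#'   wavenumber, value), `models` (named list of
#'   [CalibrationModel-class]) and `split`.
#' @export
calibrateAll <- function(spectra, compositions, config) {
  stopifnot(inherits(config, "RunConfig"))
  cons <- intersect(names(config$windows),
                    intersect(names(compositions), WOOD_CONSTITUENTS))
  if (!length(cons)) stop("no constituent is both configured and present")
  split <- withStage("split", sprintf("nCal=%d nVal=%d", config$nCal,
                                      config$nVal),
                     splitSamples(spectra, compositions, config$nCal,
                                  config$nVal, seed = config$seed,
                                  balanceTol = config$balanceTol))
  diagRows <- list(); profRows <- list(); models <- list()
  for (cc in cons) for (mode in config$modes) {
    ctx <- paste(cc, mode, sep = "/")
    pp <- withStage("preprocess", ctx,
                    preprocessSpectra(spectra, cc, mode, config))
    y <- compositions[[cc]]
    folds <- if (is.null(config$cvFolds)) nrow(pp) else config$cvFolds
    for (alg in config$algorithms) {
      ctxA <- paste(cc, alg, mode, sep = "/")
      cv <- withStage("cross-validate", ctxA,
                      crossValidate(pp, y, algorithm = alg,
                                    kMax = config$kMax, folds = folds,
                                    seed = config$seed))
      fitFun <- if (alg == "PCR") fitPCR else fitPLS1
      ppre <- list(mode = mode, window = config$windows[[cc]],
                   sgWindow = config$sgWindow,
                   sgPolyorder = config$sgPolyorder)
      model <- withStage("fit", ctxA,
                         fitFun(pp[split$calIdx, ], y[split$calIdx], cv$k,
                                constituent = cc, preprocess = ppre))
      dg <- withStage("diagnostics", ctxA,
                      modelDiagnostics(model, pp[split$calIdx, ],
                                       y[split$calIdx],
                                       pp[split$valIdx, ],
                                       y[split$valIdx]))
      prof <- withStage("profile", ctxA, coefficientProfile(model))
      key <- paste(cc, alg, mode, sep = ".")
      models[[key]] <- model
      diagRows[[key]] <- data.frame(
        constituent = cc, algorithm = alg, mode = mode,
        windowLow = config$windows[[cc]][1],
        windowHigh = config$windows[[cc]][2],
        k = cv$k, r2 = dg$r2, rmsec = dg$rmsec, rmsep = dg$rmsep,
        rpd = dg$rpd, nCal = dg$nCal, nVal = dg$nVal,
        stringsAsFactors = FALSE)
      profRows[[key]] <- data.frame(
        constituent = cc, algorithm = alg, mode = mode,
        wavenumber = wavenumbers(pp), value = prof,
        stringsAsFactors = FALSE)
    }
  }
  list(diagnostics = do.call(rbind, c(diagRows, make.row.names = FALSE)),
       profiles = do.call(rbind, c(profRows, make.row.names = FALSE)),
       models = models, split = split)
}

#' Extract and match loading peaks for all fitted profiles
#'
#' @param profiles long profile data.frame from [calibrateAll()].
#' @param bands band-assignment table.
#' @param config a [runConfig()].
#' @return data.frame of residual records: `algorithm`, `mode`,
#'   `constituent`, `W`, `BA_L`, `R`, `functional_group`.
#' @export
integrityAll <- function(profiles, bands, config) {
  stopifnot(inherits(config, "RunConfig"))
  keys <- unique(profiles[, c("constituent", "algorithm", "mode")])
  rows <- list()
  for (r in seq_len(nrow(keys))) {
    cc <- keys$constituent[r]; alg <- keys$algorithm[r]
    mode <- keys$mode[r]
    ctx <- paste(cc, alg, mode, sep = "/")
    sel <- profiles$constituent == cc & profiles$algorithm == alg &
      profiles$mode == mode
    sub <- profiles[sel, , drop = FALSE]
    sub <- sub[order(sub$wavenumber, decreasing = TRUE), , drop = FALSE]
    peaks <- withStage("peaks", ctx,
                       extractPeaks(sub$value, sub$wavenumber,
                                    config$minProminence,
                                    config$minSeparation))
    recs <- withStage("match", ctx,
                      matchBands(peaks, bands, cc, config$matchTolerance))
    if (nrow(recs))
      rows[[ctx]] <- cbind(data.frame(algorithm = alg, mode = mode,
                                      stringsAsFactors = FALSE), recs)
  }
  if (!length(rows))
    return(data.frame(algorithm = character(0), mode = character(0),
                      constituent = character(0), W = numeric(0),
                      BA_L = numeric(0), R = numeric(0),
                      functional_group = character(0)))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[, c("algorithm", "mode", "constituent", "W", "BA_L", "R",
          "functional_group")]
}

#' Pooled residual summaries and between-model tests
#'
#' Pools residual records per algorithm (across constituents and
#' modes), summarizes each pool, and runs the variance F-test and
#' two-sample t-test between the PLS1 and PCR pools when both are
#' present.
#'
#' @param residuals residual-record data.frame from [integrityAll()].
#' @param config a [runConfig()].
#' @return list with `perAlgorithm` (summaries + histograms), `fTest`,
#'   `tTest` (either may be `NULL` if an algorithm pool is too small).
#' @export
summarizeIntegrity <- function(residuals, config) {
  stopifnot(inherits(config, "RunConfig"))
  per <- list()
  for (alg in unique(residuals$algorithm)) {
    r <- residuals$R[residuals$algorithm == alg]
    per[[alg]] <- list(
      summary = if (length(r) >= 2) poolResiduals(r) else
        list(n = length(r)),
      histogram = residualHistogram(r, config$histogramBinWidth))
  }
  rPls <- residuals$R[residuals$algorithm == "PLS1"]
  rPcr <- residuals$R[residuals$algorithm == "PCR"]
  fT <- tT <- NULL
  if (length(rPls) >= 2 && length(rPcr) >= 2 &&
      stats::var(rPls) > 0 && stats::var(rPcr) > 0) {
    fT <- varianceFTest(rPls, rPcr)
    tT <- meanTTest(rPls, rPcr, "pooled")
  }
  list(perAlgorithm = per, fTest = fT, tTest = tT)
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

reportJSON <- function(report) {
  jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   na = "null")
}

#' Run the full simulate-calibrate-integrity workflow
#'
#' Generates a synthetic dataset from the configured generator, fits
#' every constituent x algorithm x mode combination, extracts and
#' matches loading peaks, and assembles the pooled residual statistics
#' and tests into a run report.  With `outDir` set, writes
#' `diagnostics.tsv`, `profiles.tsv`, `residuals.tsv`, per-algorithm
#' `histogram_<alg>.tsv`, `report.json` and `manifest.json` (the
#' manifest captures the seed and a checksum of the effective
#' configuration).  Identical configurations produce byte-identical
#' reports.
#'
#' @param config a [runConfig()].
#' @return Invisibly, the report list (`manifest`, `diagnostics`,
#'   `residuals`, `summary`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  ds <- withStage("simulate", sprintf("n=%d", config$generator$nSamples),
                  generateDataset(config$generator))
  cal <- calibrateAll(ds$spectra, ds$compositions, config)
  res <- integrityAll(cal$profiles, ds$bands, config)
  summ <- summarizeIntegrity(res, config)
  cfgString <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "outDir")])), collapse = "\n")
  manifest <- list(
    seed = config$seed,
    configChecksum = checksumString(cfgString),
    nSamples = config$generator$nSamples,
    nCombinations = nrow(cal$diagnostics),
    nResiduals = nrow(res))
  report <- list(manifest = manifest, diagnostics = cal$diagnostics,
                 residuals = res, summary = summ)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeTSV(cal$diagnostics, file.path(config$outDir, "diagnostics.tsv"))
    writeTSV(cal$profiles, file.path(config$outDir, "profiles.tsv"))
    writeTSV(res, file.path(config$outDir, "residuals.tsv"))
    for (alg in names(summ$perAlgorithm))
      writeTSV(summ$perAlgorithm[[alg]]$histogram,
               file.path(config$outDir,
                         sprintf("histogram_%s.tsv", alg)))
    writeLines(reportJSON(report), file.path(config$outDir, "report.json"))
    writeLines(reportJSON(manifest), file.path(config$outDir,
                                               "manifest.json"))
  }
  invisible(report)
}

#' Replicate study of the residual-variance direction
#'
#' Runs the full pipeline on `nReplicates` independently seeded
#' synthetic datasets and records, per replicate, the pooled residual
#' variances of the two algorithms and the one-tailed F-test p value,
#' plus the fraction of replicates in which var(R_PLS) > var(R_PCR)
#' and an F-test on the residuals pooled across all replicates.
#'
#' @param nReplicates number of replicates (default 50).
#' @param seed master seed; replicate r uses an independent sub-seed.
#' @param configure function(seed) returning the [runConfig()] for one
#'   replicate; defaults to the standard configuration.
#' @return list with `perReplicate` (data.frame), `fractionPlsGreater`
#'   and `pooledFTest`.
#' @export
replicateVarianceStudy <- function(nReplicates = 50L, seed = 1L,
                                   configure = function(s) runConfig(seed = s)) {
  rows <- list(); allPls <- numeric(0); allPcr <- numeric(0)
  for (i in seq_len(nReplicates)) {
    s <- subSeed(seed, paste0("replicate", i))
    rep <- runPipeline(configure(s))
    rPls <- rep$residuals$R[rep$residuals$algorithm == "PLS1"]
    rPcr <- rep$residuals$R[rep$residuals$algorithm == "PCR"]
    allPls <- c(allPls, rPls); allPcr <- c(allPcr, rPcr)
    rows[[i]] <- data.frame(
      replicate = i, seed = s,
      nPls = length(rPls), nPcr = length(rPcr),
      varPls = if (length(rPls) >= 2) stats::var(rPls) else NA_real_,
      varPcr = if (length(rPcr) >= 2) stats::var(rPcr) else NA_real_)
  }
  per <- do.call(rbind, rows)
  ok <- is.finite(per$varPls) & is.finite(per$varPcr)
  frac <- mean(per$varPls[ok] > per$varPcr[ok])
  pooled <- if (length(allPls) >= 2 && length(allPcr) >= 2)
    varianceFTest(allPls, allPcr) else NULL
  list(perReplicate = per, fractionPlsGreater = frac, pooledFTest = pooled)
}
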