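#' Default mid-infrared wavenumber grid
#'
#' The acquisition grid emulated by the synthetic generator: 4000 down
#' to 650 cm^-1.  The default step of 2 cm^-1 is a typical ATR export
#' interval (instrument spectral resolution is commonly 4 cm^-1) and
#' gives 1676 points.
#'
#' @param high,low grid end points (cm^-1), `high > low`.
#' @param step positive grid spacing (cm^-1).
#' @return Numeric vector of wavenumbers, descending from `high` to
#'   `low`.
#' @examples
#' length(wavenumberGrid())  # 1676
#' @export
wavenumberGrid <- function(high = 4000, low = 650, step = 2) {
  assertScalarNumber(high, "high"); assertScalarNumber(low, "low")
  assertScalarNumber(step, "step")
  if (step <= 0) stop("'step' must be positive")
  if (low >= high) stop("'low' must be below 'high'")
  seq(high, low, by = -step)
}

# The reference band-assignment table: literature infrared band centers
# (cm^-1) per wood constituent with functional-group labels.  Where the
# literature gives a range (e.g. the carbohydrate C-O stretch region),
# both endpoints are stored as separate entries rather than guessing a
# single representative center.
.bandTableData <- function() {
  rows <- list(
    # extractives
    c("extractives", 1730, "C=O stretching, ester carbonyl", "wood extractives IR"),
    c("extractives", 1633, "olefinic C=C stretching", "wood extractives IR"),
    c("extractives", 1600, "C=C stretching / aromatic ring deformation", "wood extractives IR"),
    c("extractives", 1510, "benzene ring deformation vibration", "wood extractives IR"),
    c("extractives", 1271, "C-O stretch with in-plane C-OH bending, carboxylic acids", "wood extractives IR"),
    # lignin
    c("lignin", 1735, "C=O stretching", "lignin IR"),
    c("lignin", 1658, "conjugated C=O stretching", "lignin IR"),
    c("lignin", 1510, "aromatic skeletal vibration", "lignin IR"),
    c("lignin", 1425, "aromatic skeletal vibration", "lignin IR"),
    c("lignin", 1375, "phenolic OH and aliphatic C-H in methyl groups", "lignin IR"),
    c("lignin", 1328, "aromatic skeletal vibration", "lignin IR"),
    c("lignin", 1269, "G ring with C=O stretching", "lignin IR"),
    c("lignin", 1220, "C-C, C-O and C=O stretching", "lignin IR"),
    c("lignin", 1140, "C-H in-plane deformation of G ring; secondary alcohols; C=O stretch", "lignin IR"),
    c("lignin", 1116, "aromatic C-H deformation in S ring", "lignin IR"),
    c("lignin", 1033, "aromatic C-H in-plane deformation; C-O of primary alcohols; C=O stretch", "lignin IR"),
    c("lignin",  835, "C-H out-of-plane deformation, positions 2 and 6 of S ring", "lignin IR"),
    # cellulose
    c("cellulose", 1440, "O-H in-plane bending", "cellulose IR"),
    c("cellulose", 1380, "C-H bending", "cellulose IR"),
    c("cellulose", 1310, "CH2 wagging", "cellulose IR"),
    c("cellulose", 1280, "C-H bending", "cellulose IR"),
    c("cellulose", 1220, "O-H in-plane bending", "cellulose IR"),
    c("cellulose", 1160, "C-O-C asymmetric stretching", "cellulose IR"),
    c("cellulose", 1047, "C-O stretching, range endpoint", "cellulose IR"),
    c("cellulose", 1004, "C-O stretching, range endpoint", "cellulose IR"),
    # hemicellulose
    c("hemicellulose", 1639, "absorbed water / conjugated carbonyl (acetylated xylan)", "hemicellulose IR"),
    c("hemicellulose", 1453, "CH2 symmetric bending", "hemicellulose IR"),
    c("hemicellulose", 1426, "CH and OH bending", "hemicellulose IR"),
    c("hemicellulose", 1338, "CH wagging", "hemicellulose IR"),
    c("hemicellulose", 1051, "glycosidic C-O-C stretching, range endpoint", "hemicellulose IR"),
    c("hemicellulose", 1008, "glycosidic C-O-C stretching, range endpoint", "hemicellulose IR")
  )
  data.frame(
    constituent = vapply(rows, `[`, "", 1L),
    center_cm1 = as.numeric(vapply(rows, `[`, "", 2L)),
    functional_group = vapply(rows, `[`, "", 3L),
    literature_ref = vapply(rows, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Reference infrared band assignments for wood constituents
#'
#' Returns the shipped table of literature band centers (cm^-1) used
#' both to build synthetic spectra and to score extracted loading peaks
#' against their expected locations.  The same table is shipped as a TSV
#' under `inst/extdata/band_assignments.tsv`.
#'
#' @return data.frame with columns `constituent`, `center_cm1`,
#'   `functional_group`, `literature_ref`.
#' @examples
#' head(defaultBandTable())
#' @export
defaultBandTable <- function() .bandTableData()

validateBandTable <- function(bands) {
  need <- c("constituent", "center_cm1", "functional_group")
  if (!all(need %in% names(bands)))
    stop("band table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(bands$constituent), WOOD_CONSTITUENTS)
  if (length(bad))
    stop("unknown constituent(s) ", paste(bad, collapse = ", "),
         "; vocabulary: ", paste(WOOD_CONSTITUENTS, collapse = ", "))
  out <- which(bands$center_cm1 < 650 | bands$center_cm1 > 4000)
  if (length(out))
    stop(sprintf("band center %g cm^-1 (row %d) outside the 650-4000 cm^-1 range",
                 bands$center_cm1[out[1]], out[1]))
  invisible(bands)
}

#' Configuration for the synthetic spectra generator
#'
#' The generator emulates an ATR FT-IR study of hardwood meal: each
#' sample's spectrum is the composition-weighted sum of Gaussian bands
#' centered at the literature assignments, plus a per-sample linear
#' baseline and white noise.  Defaults describe a 37-sample hardwood
#' set with plausible composition ranges.
#'
#' @param nSamples number of samples to generate.
#' @param seed integer seed; all draws are taken from sub-streams
#'   derived from it, so outputs are bit-reproducible.
#' @param compositionRanges named list of `c(min, max)` percent w/w
#'   ranges per constituent.  Degenerate ranges (`min == max`) are
#'   allowed and give constant columns.
#' @param baseline `c(intercept, slope)`: the baseline is
#'   `intercept + slope * wavenumber` (absorbance units; slope per
#'   cm^-1).  [generateDataset()] draws per-sample coefficients
#'   uniformly on `[0, 2 * value]` so baselines vary across samples
#'   around these magnitudes; [renderSpectrum()] uses the values as
#'   given.
#' @param noiseSd Gaussian noise standard deviation (absorbance units).
#' @param bands band table (see [defaultBandTable()]); columns
#'   `width_cm1` (Gaussian sigma) and `amplitude` (absorbance per unit
#'   mass fraction) are added with the defaults below when absent.
#' @param bandWidth,bandAmplitude defaults for missing `width_cm1` /
#'   `amplitude` columns.
#' @param grid wavenumber grid (see [wavenumberGrid()]).
#' @return A list of class `GeneratorConfig`.
#' @examples
#' cfg <- generatorConfig(seed = 1)
#' str(cfg$compositionRanges)
#' @export
generatorConfig <- function(nSamples = 37L,
                            seed = 1L,
                            compositionRanges = list(
                              extractives   = c(1, 8),
                              lignin        = c(18, 30),
                              cellulose     = c(38, 52),
                              hemicellulose = c(18, 32)),
                            baseline = c(intercept = 0.02, slope = 1e-5),
                            noiseSd = 0.005,
                            bands = defaultBandTable(),
                            bandWidth = 12,
                            bandAmplitude = 1,
                            grid = wavenumberGrid()) {
  if (nSamples < 1) stop("'nSamples' must be >= 1")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (length(baseline) != 2L) stop("'baseline' must be c(intercept, slope)")
  for (nm in names(compositionRanges)) {
    r <- compositionRanges[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 100)
      stop(sprintf("composition range for '%s' must be c(min, max) within [0, 100] with min <= max", nm))
  }
  bad <- setdiff(names(compositionRanges), WOOD_CONSTITUENTS)
  if (length(bad))
    stop("unknown constituent(s) in compositionRanges: ",
         paste(bad, collapse = ", "))
  validateBandTable(bands)
  if (is.null(bands$width_cm1)) bands$width_cm1 <- bandWidth
  if (is.null(bands$amplitude)) bands$amplitude <- bandAmplitude
  if (any(bands$width_cm1 <= 0)) stop("band widths must be positive")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  structure(list(
    nSamples = as.integer(nSamples), seed = as.integer(seed),
    compositionRanges = compositionRanges,
    baseline = as.numeric(baseline), noiseSd = noiseSd,
    bands = bands, grid = grid
  ), class = "GeneratorConfig")
}

#' Draw a synthetic composition table
#'
#' Each constituent is drawn uniformly from its configured range; rows
#' whose constituent sum exceeds 100% w/w are rejected and redrawn
#' (bounded attempts).  Fully deterministic for a fixed seed.
#'
#' @param config a [generatorConfig()].
#' @param maxAttempts redraw budget per sample before failing.
#' @return data.frame with `sample_id` and one percent-w/w column per
#'   configured constituent.
#' @examples
#' head(sampleCompositions(generatorConfig(nSamples = 5, seed = 1)))
#' @export
sampleCompositions <- function(config, maxAttempts = 1000L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  ranges <- config$compositionRanges
  cons <- names(ranges)
  set.seed(subSeed(config$seed, "compositions"))
  rows <- matrix(NA_real_, config$nSamples, length(cons),
                 dimnames = list(NULL, cons))
  for (i in seq_len(config$nSamples)) {
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      draw <- vapply(ranges, function(r) stats::runif(1, r[1], r[2]), 0)
      if (sum(draw) <= 100) { rows[i, ] <- draw; ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(
        "could not draw a composition with sum <= 100%% within %d attempts; tighten the configured ranges",
        maxAttempts))
  }
  data.frame(sample_id = paste0("s", seq_len(config$nSamples)), rows,
             stringsAsFactors = FALSE)
}

# Constituent signal profiles on the grid: one row per constituent,
# the sum of that constituent's Gaussian bands at unit mass fraction.
constituentProfiles <- function(bands, grid, constituents = NULL) {
  if (is.null(constituents)) constituents <- unique(bands$constituent)
  G <- matrix(0, length(constituents), length(grid),
              dimnames = list(constituents, NULL))
  for (b in seq_len(nrow(bands))) {
    cc <- bands$constituent[b]
    if (!cc %in% constituents) next
    G[cc, ] <- G[cc, ] + bands$amplitude[b] *
      exp(-(grid - bands$center_cm1[b])^2 / (2 * bands$width_cm1[b]^2))
  }
  G
}

#' Render one synthetic spectrum from a composition
#'
#' The absorbance at wavenumber v is
#' `baseline(v) + sum_c (fraction_c / 100) * sum_bands a * exp(-(v - center)^2 / (2 sigma^2)) + noise(v)`,
#' with `baseline(v) = intercept + slope * v` and seeded Gaussian noise
#' drawn from the current RNG stream (seed it, or let
#' [generateDataset()] manage sub-streams).
#'
#' @param composition named numeric vector (or single-row data.frame)
#'   of percent w/w values; names must be constituents present in the
#'   configured band table.
#' @param config a [generatorConfig()].
#' @param grid wavenumber grid; defaults to the configured grid.
#' @param baseline `c(intercept, slope)` actually applied; defaults to
#'   the configured values.
#' @param noiseSd noise level actually applied.
#' @return numeric absorbance vector over `grid`.
#' @examples
#' cfg <- generatorConfig()
#' sp <- renderSpectrum(c(lignin = 25), cfg, noiseSd = 0)
#' @export
renderSpectrum <- function(composition, config, grid = config$grid,
                           baseline = config$baseline,
                           noiseSd = config$noiseSd) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (is.data.frame(composition)) {
    composition <- composition[, setdiff(names(composition), "sample_id"),
                               drop = FALSE]
    composition <- unlist(composition[1, , drop = FALSE])
  }
  cons <- names(composition)
  known <- unique(config$bands$constituent)
  bad <- setdiff(cons, known)
  if (length(bad))
    stop("composition names unknown to the band table: ",
         paste(bad, collapse = ", "))
  G <- constituentProfiles(config$bands, grid, cons)
  signal <- as.numeric(composition / 100) %*% G
  out <- baseline[1] + baseline[2] * grid + as.numeric(signal)
  if (noiseSd > 0) out <- out + stats::rnorm(length(grid), 0, noiseSd)
  out
}

#' Generate a complete synthetic dataset
#'
#' Draws compositions, per-sample baselines and noise from independent
#' sub-streams of the configured seed and renders one spectrum per
#' sample.  Returns the ground-truth band table alongside the data so
#' downstream peak-recovery checks know where the true centers are.
#'
#' @param config a [generatorConfig()].
#' @return list with elements `spectra` ([SpectraSet-class]),
#'   `compositions` (data.frame) and `bands` (the band table with the
#'   widths/amplitudes actually used).
#' @examples
#' ds <- generateDataset(generatorConfig(nSamples = 8, seed = 7))
#' ds$spectra
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  comps <- sampleCompositions(config)
  n <- config$nSamples
  grid <- config$grid
  set.seed(subSeed(config$seed, "baseline"))
  b0 <- stats::runif(n, 0, 2 * config$baseline[1])
  b1 <- stats::runif(n, 0, 2 * config$baseline[2])
  set.seed(subSeed(config$seed, "noise"))
  A <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    A[i, ] <- renderSpectrum(comps[i, ], config, grid,
                             baseline = c(b0[i], b1[i]),
                             noiseSd = config$noiseSd)
  }
  list(spectra = SpectraSet(A, grid, comps$sample_id),
       compositions = comps,
       bands = config$bands)
}
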