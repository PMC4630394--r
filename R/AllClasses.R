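#' SpectraSet: absorbance spectra on a shared wavenumber grid
#'
#' Container for a set of mid-infrared absorbance spectra.  Rows are
#' samples, columns are wavenumbers.  The grid is stored in the
#' conventional infrared orientation: strictly descending, uniformly
#' spaced wavenumbers (cm^-1).
#'
#' @slot absorbance numeric matrix, samples x wavenumbers; no missing
#'   values.
#' @slot wavenumbers numeric vector of grid wavenumbers (cm^-1),
#'   strictly descending with uniform spacing.
#' @slot sampleIds character vector of unique sample identifiers, one
#'   per row of `absorbance`.
#'
#' @seealso [SpectraSet()] for construction, [wavenumbers()],
#'   [absorbance()], [sampleIds()] for access, [selectWindow()] and
#'   [firstDerivative()] for preprocessing.
#' @export
setClass("SpectraSet",
  representation(
    absorbance  = "matrix",
    wavenumbers = "numeric",
    sampleIds   = "character"
  )
)

setValidity("SpectraSet", function(object) {
  msgs <- character()
  wn <- object@wavenumbers
  ab <- object@absorbance
  if (length(wn) < 1L) msgs <- c(msgs, "wavenumber grid is empty")
  if (ncol(ab) != length(wn))
    msgs <- c(msgs, sprintf("absorbance has %d columns but grid has %d points",
                            ncol(ab), length(wn)))
  if (nrow(ab) != length(object@sampleIds))
    msgs <- c(msgs, sprintf("absorbance has %d rows but %d sample ids",
                            nrow(ab), length(object@sampleIds)))
  if (anyDuplicated(object@sampleIds))
    msgs <- c(msgs, "sample ids must be unique")
  if (anyNA(ab)) msgs <- c(msgs, "absorbance contains missing values")
  if (length(wn) >= 2L) {
    st <- diff(wn)
    if (any(st >= 0))
      msgs <- c(msgs, "wavenumbers must be strictly descending")
    else if (max(abs(st - st[1])) > 1e-6 * abs(st[1]))
      msgs <- c(msgs, "wavenumber spacing must be uniform")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix (samples x wavenumbers).  A single
#'   spectrum may be given as a vector.
#' @param wavenumbers numeric descending wavenumber grid (cm^-1).
#'   Ascending input is accepted and reversed (with the absorbance
#'   columns) to the canonical descending orientation.
#' @param sampleIds character identifiers; defaults to `s1, s2, ...`.
#' @return A [SpectraSet-class] object.
#' @examples
#' grid <- wavenumberGrid()
#' ss <- SpectraSet(matrix(0, 2, length(grid)), grid)
#' ss
#' @export
SpectraSet <- function(absorbance, wavenumbers,
                       sampleIds = paste0("s", seq_len(nrow(absorbance)))) {
  if (is.null(dim(absorbance)))
    absorbance <- matrix(absorbance, nrow = 1L)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(wavenumbers) >= 2L && wavenumbers[1] < wavenumbers[2]) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  dimnames(absorbance) <- NULL
  new("SpectraSet", absorbance = absorbance,
      wavenumbers = as.numeric(wavenumbers),
      sampleIds = as.character(sampleIds))
}

#' @describeIn SpectraSet Grid accessor.
#' @param x,object a `SpectraSet`
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet
#' @export
setMethod("wavenumbers", "SpectraSet", function(x) x@wavenumbers)

#' @rdname SpectraSet
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet
#' @export
setMethod("absorbance", "SpectraSet", function(x) x@absorbance)

#' @rdname SpectraSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectraSet
#' @export
setMethod("sampleIds", "SpectraSet", function(x) x@sampleIds)

#' @rdname SpectraSet
#' @export
setMethod("nrow", "SpectraSet", function(x) nrow(x@absorbance))

#' @param i sample (row) index
#' @param j wavenumber (column) index
#' @param ... ignored
#' @param drop ignored; subsetting always returns a `SpectraSet`
#' @rdname SpectraSet
#' @export
setMethod("[", "SpectraSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@absorbance))
  if (missing(j)) j <- seq_along(x@wavenumbers)
  new("SpectraSet",
      absorbance = x@absorbance[i, j, drop = FALSE],
      wavenumbers = x@wavenumbers[j],
      sampleIds = x@sampleIds[i])
})

setMethod("show", "SpectraSet", function(object) {
  wn <- object@wavenumbers
  step <- if (length(wn) >= 2) abs(wn[2] - wn[1]) else NA_real_
  cat(sprintf(
    "SpectraSet: %d spectra x %d wavenumbers (%g to %g cm^-1, step %g)\n",
    nrow(object@absorbance), length(wn),
    if (length(wn)) wn[1] else NA, if (length(wn)) wn[length(wn)] else NA,
    step))
})

#' CalibrationModel: a fitted PCR or PLS1 spectral calibration
#'
#' Latent-variable regression of one wood constituent (% w/w) on
#' mean-centered absorbance spectra.  For principal components
#' regression (PCR) the loadings slot holds the principal-component
#' loading vectors; for NIPALS partial least squares with a single
#' response (PLS1) it holds the X-loadings, and `weights` the NIPALS
#' weight vectors.  The coefficient vector maps a centered spectrum to a
#' centered prediction; [predict()] applies centering and un-centering.
#'
#' @slot algorithm `"PCR"` or `"PLS1"`.
#' @slot constituent name of the response constituent (may be `NA`).
#' @slot preprocess list describing the pretreatment that produced the
#'   training matrix (mode, Savitzky-Golay settings, window); recorded
#'   for provenance, not re-applied at prediction time.
#' @slot k number of latent components retained.
#' @slot xCenter training column means of the spectra.
#' @slot yCenter training mean of the response.
#' @slot coefficients regression coefficient vector, one entry per
#'   retained wavenumber.
#' @slot loadings loadings matrix (wavenumbers x components).
#' @slot weights NIPALS weight matrix (PLS1) or a 0-column matrix (PCR).
#' @slot yLoadings per-component regression of the response on scores.
#' @slot scoreYCorrelations absolute correlation of each score column
#'   with the response (PCR; used to pick the "related" component for
#'   interpretation plots).
#' @slot wavenumbers retained wavenumber grid (cm^-1); may be empty when
#'   the model was fitted on a bare matrix.
#'
#' @seealso [fitPCR()], [fitPLS1()], [coefficientProfile()],
#'   [modelDiagnostics()].
#' @export
setClass("CalibrationModel",
  representation(
    algorithm   = "character",
    constituent = "character",
    preprocess  = "list",
    k           = "integer",
    xCenter     = "numeric",
    yCenter     = "numeric",
    coefficients = "numeric",
    loadings    = "matrix",
    weights     = "matrix",
    yLoadings   = "numeric",
    scoreYCorrelations = "numeric",
    wavenumbers = "numeric"
  )
)

setValidity("CalibrationModel", function(object) {
  msgs <- character()
  if (!object@algorithm %in% c("PCR", "PLS1"))
    msgs <- c(msgs, "algorithm must be 'PCR' or 'PLS1'")
  if (object@k < 1L)
    msgs <- c(msgs, "k must be >= 1")
  if (length(object@coefficients) != length(object@xCenter))
    msgs <- c(msgs, "coefficient vector length must equal the number of retained wavenumbers")
  if (length(object@wavenumbers) &&
      length(object@wavenumbers) != length(object@coefficients))
    msgs <- c(msgs, "wavenumbers length must match coefficient vector")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (%s), constituent: %s\n", object@algorithm,
              object@constituent))
  cat(sprintf("  %d components over %d wavenumbers\n", object@k,
              length(object@coefficients)))
  if (length(object@wavenumbers))
    cat(sprintf("  window: %g to %g cm^-1\n",
                max(object@wavenumbers), min(object@wavenumbers)))
})
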