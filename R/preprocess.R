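# Pretreatment applied before calibration: wavenumber-window selection
# and the Savitzky-Golay first derivative.

#' Restrict a SpectraSet to a wavenumber window
#'
#' Keeps exactly the grid points v with `low <= v <= high` (closed
#' interval), preserving the descending storage order.  Applying the
#' same window twice is the identity on the already-windowed set.
#'
#' @param spectra a [SpectraSet-class].
#' @param low,high window bounds in cm^-1 (`low < high`).
#' @return A windowed [SpectraSet-class].
#' @examples
#' ss <- SpectraSet(matrix(0, 1, 1676), wavenumberGrid())
#' nsel <- length(wavenumbers(selectWindow(ss, 1250, 1750)))  # 251
#' @export
selectWindow <- function(spectra, low, high) {
  stopifnot(is(spectra, "SpectraSet"))
  assertScalarNumber(low, "low"); assertScalarNumber(high, "high")
  if (low >= high) stop("'low' must be below 'high'")
  keep <- which(wavenumbers(spectra) >= low & wavenumbers(spectra) <= high)
  if (!length(keep))
    stop(sprintf("window %g-%g cm^-1 does not overlap the grid (%g-%g cm^-1)",
                 low, high, min(wavenumbers(spectra)),
                 max(wavenumbers(spectra))))
  spectra[, keep]
}

#' Savitzky-Golay first derivative of spectra
#'
#' Per-sample first derivative of absorbance with respect to
#' wavenumber, computed with a Savitzky-Golay polynomial filter.  The
#' sign convention is the derivative with respect to *increasing*
#' wavenumber; the descending storage order is handled internally.
#' Output has the same length as the input: boundary points use the
#' one-sided polynomial fits of the filter, so the derivative is exact
#' for polynomials up to `sgPolyorder` even at the edges.
#'
#' @param spectra a [SpectraSet-class] on a uniform grid.
#' @param sgWindow odd filter length in points (default 9).
#' @param sgPolyorder polynomial order (default 2); must be below
#'   `sgWindow`.
#' @return A [SpectraSet-class] of derivatives (absorbance per cm^-1)
#'   on the same grid.
#' @examples
#' ss <- SpectraSet(matrix(seq(4000, 650, by = -2), 1), wavenumberGrid())
#' d <- firstDerivative(ss)   # linear ramp: derivative 1 everywhere
#' @export
firstDerivative <- function(spectra, sgWindow = 9L, sgPolyorder = 2L) {
  stopifnot(is(spectra, "SpectraSet"))
  sgWindow <- as.integer(sgWindow); sgPolyorder <- as.integer(sgPolyorder)
  if (sgWindow %% 2L == 0L) stop("'sgWindow' must be odd")
  if (sgPolyorder >= sgWindow) stop("'sgPolyorder' must be below 'sgWindow'")
  wn <- wavenumbers(spectra)
  if (sgWindow > length(wn))
    stop(sprintf("Savitzky-Golay window (%d points) exceeds the grid length (%d)",
                 sgWindow, length(wn)))
  step <- abs(wn[1] - wn[2])
  A <- absorbance(spectra)
  # work in ascending-wavenumber order so d/dv has the standard sign
  idx <- rev(seq_along(wn))
  D <- t(apply(A[, idx, drop = FALSE], 1, function(x)
    signal::sgolayfilt(x, p = sgPolyorder, n = sgWindow, m = 1L, ts = step)))
  D <- D[, rev(seq_along(wn)), drop = FALSE]
  SpectraSet(D, wn, sampleIds(spectra))
}

#' Mean-center data against a training set
#'
#' Subtracts the training column means from both the training data and
#' (optionally) new data, returning the centering record needed to
#' undo or reapply the transform at prediction time.
#'
#' @param train numeric matrix (or vector, treated as one column).
#' @param applyTo optional matrix/vector to center with the *training*
#'   means.
#' @return list with `train`, `applyTo` (or `NULL`) and `center` (the
#'   training column means).
#' @export
meanCenter <- function(train, applyTo = NULL) {
  tv <- is.null(dim(train))
  tm <- if (tv) matrix(train, ncol = 1) else as.matrix(train)
  ctr <- colMeans(tm)
  ctrain <- sweep(tm, 2, ctr)
  capply <- NULL
  if (!is.null(applyTo)) {
    av <- is.null(dim(applyTo))
    am <- if (av) matrix(applyTo, ncol = ncol(tm), byrow = FALSE) else as.matrix(applyTo)
    if (av && length(applyTo) == ncol(tm)) am <- matrix(applyTo, nrow = 1)
    capply <- sweep(am, 2, ctr)
    if (av && length(applyTo) == ncol(tm)) capply <- drop(capply)
  }
  if (tv) ctrain <- drop(ctrain)
  list(train = ctrain, applyTo = capply, center = ctr)
}
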