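# PCR and PLS1 calibration of constituent content on absorbance
# spectra, with the split / cross-validation / diagnostics machinery
# around them.  Both fitters take the raw (windowed, optionally
# derivative) data and mean-center internally, storing the centering
# record in the model.

asXMatrix <- function(X) {
  if (is(X, "SpectraSet")) absorbance(X) else as.matrix(X)
}

xWavenumbers <- function(X) {
  if (is(X, "SpectraSet")) wavenumbers(X) else numeric(0)
}

checkFitInputs <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    stop(sprintf("length(y) = %d but X has %d rows", length(y), n))
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  kmax <- min(n - 1L, p)
  if (k < 1L || k > kmax)
    stop(sprintf("k must lie in 1..%d (n - 1 = %d, p = %d)", kmax, n - 1L, p))
  invisible(NULL)
}

#' Fit a principal components regression (PCR) calibration
#'
#' Principal components are taken from the singular value decomposition
#' of the mean-centered training spectra; the centered response is
#' regressed on the first `k` score columns.  At `k = rank(X)` the
#' coefficient vector equals the minimum-norm least-squares solution.
#'
#' @param X training spectra: a [SpectraSet-class] or numeric matrix
#'   (samples x wavenumbers).
#' @param y response vector (constituent percent w/w).
#' @param k number of principal components to retain.
#' @param constituent optional response name stored in the model.
#' @param preprocess optional list recording the pretreatment that
#'   produced `X` (provenance only).
#' @return A [CalibrationModel-class].
#' @seealso [fitPLS1()], [predict,CalibrationModel-method],
#'   [coefficientProfile()]
#' @export
fitPCR <- function(X, y, k, constituent = NA_character_,
                   preprocess = list()) {
  wn <- xWavenumbers(X)
  X <- asXMatrix(X); y <- as.numeric(y); k <- as.integer(k)
  checkFitInputs(X, y, k)
  n <- nrow(X)
  mc <- meanCenter(X)
  Xc <- mc$train
  ym <- mean(y); yc <- y - ym
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (k > r)
    stop(sprintf("k = %d exceeds the rank of the centered training matrix (rank %d)",
                 k, r))
  u <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  v <- sv$v[, seq_len(k), drop = FALSE]
  q <- drop(crossprod(u, yc)) / d       # per-component response loading
  beta <- drop(v %*% q)
  scores <- sweep(u, 2, d, `*`)
  sdy <- stats::sd(yc)
  corY <- if (sdy == 0) rep(0, k) else
    abs(apply(scores, 2, function(t)
      if (stats::sd(t) == 0) 0 else stats::cor(t, yc)))
  new("CalibrationModel",
      algorithm = "PCR", constituent = as.character(constituent),
      preprocess = preprocess, k = k,
      xCenter = mc$center, yCenter = ym,
      coefficients = beta, loadings = v,
      weights = matrix(0, ncol(X), 0L), yLoadings = q,
      scoreYCorrelations = corY, wavenumbers = wn)
}

#' Fit a PLS1 calibration by NIPALS
#'
#' Partial least squares with a single response, fit by the NIPALS
#' algorithm: for each component the weight vector is `w = X'y`
#' (normalized), scores `t = Xw`, X-loading `p = X't / t't`, response
#' loading `q = y't / t't`, followed by deflation of both `X` and `y`.
#' The coefficient vector `b = W (P'W)^-1 q` maps centered spectra to
#' centered predictions; at `k = rank(X)` it equals the least-squares
#' solution.  With one response each weight vector is a fixed point of
#' the NIPALS iteration, so no inner iteration is needed.
#'
#' @inheritParams fitPCR
#' @return A [CalibrationModel-class].
#' @export
fitPLS1 <- function(X, y, k, constituent = NA_character_,
                    preprocess = list()) {
  wn <- xWavenumbers(X)
  X <- asXMatrix(X); y <- as.numeric(y); k <- as.integer(k)
  checkFitInputs(X, y, k)
  if (stats::sd(y) == 0)
    stop("response has zero variance; PLS1 is undefined")
  mc <- meanCenter(X)
  Xc <- mc$train
  ym <- mean(y); yc <- y - ym
  r <- matrixRank(Xc)
  if (k > r)
    stop(sprintf("k = %d exceeds the rank of the centered training matrix (rank %d)",
                 k, r))
  p <- ncol(Xc); n <- nrow(Xc)
  W <- P <- matrix(0, p, k)
  q <- numeric(k)
  Xd <- Xc; yd <- yc
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stop(sprintf("no covariance left at component %d; reduce k", a))
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-28)
      stop(sprintf("degenerate score at component %d; reduce k", a))
    pv <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  beta <- drop(W %*% solve(crossprod(P, W), q))
  new("CalibrationModel",
      algorithm = "PLS1", constituent = as.character(constituent),
      preprocess = preprocess, k = k,
      xCenter = mc$center, yCenter = ym,
      coefficients = beta, loadings = P,
      weights = W, yLoadings = q,
      scoreYCorrelations = numeric(0), wavenumbers = wn)
}

#' Predict constituent content from spectra
#'
#' Applies the stored centering, the coefficient vector, and
#' un-centering.  The pretreatment recorded in the model is *not*
#' re-applied: the caller must supply data preprocessed the same way as
#' the training set (same window, same derivative mode).
#'
#' @param object a [CalibrationModel-class].
#' @param newdata a [SpectraSet-class] on the model's retained grid, or
#'   a numeric matrix/vector with one column per retained wavenumber.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "CalibrationModel", function(object, newdata, ...) {
  if (is(newdata, "SpectraSet") && length(object@wavenumbers)) {
    wn <- wavenumbers(newdata)
    mwn <- object@wavenumbers
    if (length(wn) != length(mwn) || max(abs(wn - mwn)) > 1e-6)
      stop(sprintf(
        "grid mismatch: model expects %d wavenumbers from %g down to %g cm^-1",
        length(mwn), max(mwn), min(mwn)))
  }
  X <- asXMatrix(newdata)
  if (is.null(dim(newdata)) && !is(newdata, "SpectraSet") &&
      length(newdata) == length(object@coefficients))
    X <- matrix(newdata, nrow = 1)
  if (ncol(X) != length(object@coefficients))
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), length(object@coefficients)))
  drop(sweep(X, 2, object@xCenter) %*% object@coefficients) + object@yCenter
})

#' Split samples into calibration and validation sets
#'
#' Seeded random split, redrawn (bounded attempts) until the validation
#' mean of every constituent lies within `balanceTol` standard
#' deviations of the calibration mean, mirroring the practice of
#' checking that the two populations have a similar mean and range.
#'
#' @param spectra a [SpectraSet-class].
#' @param compositions composition data.frame aligned with `spectra`.
#' @param nCal,nVal calibration / validation sizes
#'   (`nCal + nVal == nrow(spectra)`); defaults 31 / 6.
#' @param seed integer seed for the split draws.
#' @param balanceTol tolerance on the standardized mean difference per
#'   constituent; `Inf` accepts the first draw.
#' @param maxAttempts redraw budget.
#' @return list with `calIdx`, `valIdx`, and the corresponding
#'   `calSpectra`, `valSpectra`, `calCompositions`, `valCompositions`;
#'   `attempts` records how many draws were needed.
#' @export
splitSamples <- function(spectra, compositions, nCal = 31L, nVal = 6L,
                         seed = 1L, balanceTol = 0.5, maxAttempts = 500L) {
  stopifnot(is(spectra, "SpectraSet"))
  n <- nrow(spectra)
  if (nCal + nVal != n)
    stop(sprintf("nCal + nVal = %d but there are %d samples", nCal + nVal, n))
  cons <- intersect(names(compositions), WOOD_CONSTITUENTS)
  if (!length(cons)) stop("no constituent columns in 'compositions'")
  set.seed(subSeed(seed, "split"))
  best <- Inf; bestIdx <- NULL; bestAttempt <- NA_integer_
  for (att in seq_len(maxAttempts)) {
    valIdx <- sort(sample.int(n, nVal))
    calIdx <- setdiff(seq_len(n), valIdx)
    worst <- 0
    for (cc in cons) {
      v <- compositions[[cc]]
      s <- stats::sd(v)
      if (s == 0) next
      worst <- max(worst, abs(mean(v[valIdx]) - mean(v[calIdx])) / s)
    }
    if (worst < best) { best <- worst; bestIdx <- valIdx; bestAttempt <- att }
    if (worst <= balanceTol) {
      return(list(
        calIdx = calIdx, valIdx = valIdx,
        calSpectra = spectra[calIdx, ], valSpectra = spectra[valIdx, ],
        calCompositions = compositions[calIdx, , drop = FALSE],
        valCompositions = compositions[valIdx, , drop = FALSE],
        attempts = att))
    }
  }
  stop(sprintf(
    "balanced split not attained in %d attempts; best max standardized mean difference %.3f (attempt %d)",
    maxAttempts, best, bestAttempt))
}

#' Cross-validate component count for PCR or PLS1
#'
#' Computes RMSECV for `k = 1..kMax` and selects the smallest `k` whose
#' RMSECV is within 5% of the global minimum (parsimony rule).  The
#' default is leave-one-out; with fewer folds the assignment is seeded.
#' If some fold cannot support `kMax` components the scan is truncated
#' to the feasible maximum, with a notice.
#'
#' @param X spectra ([SpectraSet-class] or matrix).
#' @param y response vector.
#' @param algorithm `"PCR"` or `"PLS1"`.
#' @param kMax largest component count to scan.
#' @param folds number of folds; `>= nrow(X)` means leave-one-out.
#' @param seed seed for fold assignment (ignored for leave-one-out).
#' @return list with `table` (data.frame `k`, `rmsecv`), the selected
#'   `k`, and `truncated` (logical).
#' @export
crossValidate <- function(X, y, algorithm = c("PLS1", "PCR"), kMax,
                          folds = nrow(asXMatrix(X)), seed = NULL) {
  algorithm <- match.arg(algorithm)
  X <- asXMatrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (stats::sd(y) == 0)
    stop("response has zero variance; cross-validation is undefined")
  if (folds < 2) stop("'folds' must be >= 2")
  folds <- min(folds, n)
  assign <- rep_len(seq_len(folds), n)
  if (folds < n) {
    if (!is.null(seed)) set.seed(subSeed(seed, "cvfolds"))
    assign <- sample(assign)
  } else assign <- seq_len(n)
  kMax <- as.integer(kMax)
  preds <- matrix(NA_real_, n, kMax)
  kFeasible <- kMax
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    train <- setdiff(seq_len(n), test)
    mc <- meanCenter(X[train, , drop = FALSE], X[test, , drop = FALSE])
    ym <- mean(y[train]); yc <- y[train] - ym
    Xt <- mc$applyTo
    if (is.null(dim(Xt))) Xt <- matrix(Xt, nrow = length(test))
    sv <- svd(mc$train)
    tol <- max(dim(mc$train)) * .Machine$double.eps * max(sv$d, 0)
    r <- sum(sv$d > tol)
    kf <- min(kMax, r)
    kFeasible <- min(kFeasible, kf)
    if (algorithm == "PCR") {
      u <- sv$u[, seq_len(kf), drop = FALSE]
      d <- sv$d[seq_len(kf)]
      v <- sv$v[, seq_len(kf), drop = FALSE]
      q <- drop(crossprod(u, yc)) / d
      Z <- Xt %*% v                       # nt x kf score projections
      contrib <- sweep(Z, 2, q, `*`)
      cum <- t(apply(contrib, 1, cumsum))
      if (kf == 1L) cum <- matrix(contrib, ncol = 1)
      preds[test, seq_len(kf)] <- ym + cum
    } else {
      fitk <- fitPLS1(X[train, , drop = FALSE], y[train], kf)
      # reuse the per-component decomposition for every k <= kf
      W <- fitk@weights; P <- fitk@loadings; q <- fitk@yLoadings
      Xc <- sweep(X[test, , drop = FALSE], 2, fitk@xCenter)
      for (kk in seq_len(kf)) {
        bk <- drop(W[, seq_len(kk), drop = FALSE] %*%
                     solve(crossprod(P[, seq_len(kk), drop = FALSE],
                                     W[, seq_len(kk), drop = FALSE]),
                           q[seq_len(kk)]))
        preds[test, kk] <- drop(Xc %*% bk) + ym
      }
    }
  }
  truncated <- kFeasible < kMax
  if (truncated)
    message(sprintf("kMax truncated from %d to %d (rank limit in some fold)",
                    kMax, kFeasible))
  ks <- seq_len(kFeasible)
  rmsecv <- vapply(ks, function(k) sqrt(mean((preds[, k] - y)^2)), 0)
  sel <- ks[which(rmsecv <= 1.05 * min(rmsecv))[1]]
  list(table = data.frame(k = ks, rmsecv = rmsecv), k = sel,
       truncated = truncated)
}

#' Calibration and prediction diagnostics
#'
#' Computes the standard chemometric performance measures: r-squared in
#' percent (100 x squared Pearson correlation between predicted and
#' reference on the calibration set), RMSEC and RMSEP (root mean square
#' error with a 1/n denominator on the calibration / validation set),
#' and RPD (the n-1 standard deviation of the validation reference
#' values divided by RMSEP).  A perfect validation fit (RMSEP = 0)
#' yields an undefined RPD, flagged rather than reported as infinity.
#'
#' @param model a [CalibrationModel-class].
#' @param Xcal,ycal calibration spectra and reference values.
#' @param Xval,yval validation spectra and reference values.
#' @return list with `r2`, `rmsec`, `rmsep`, `rpd`, `rpdDefined`,
#'   `nCal`, `nVal`.
#' @export
modelDiagnostics <- function(model, Xcal, ycal, Xval, yval) {
  ycal <- as.numeric(ycal); yval <- as.numeric(yval)
  if (!length(ycal) || !length(yval)) stop("empty calibration or validation set")
  pc <- predict(model, Xcal)
  pv <- predict(model, Xval)
  r2 <- if (stats::sd(pc) == 0 || stats::sd(ycal) == 0) NA_real_ else
    100 * stats::cor(pc, ycal)^2
  rmsec <- sqrt(mean((pc - ycal)^2))
  rmsep <- sqrt(mean((pv - yval)^2))
  if (rmsep > 0) {
    rpd <- stats::sd(yval) / rmsep
    rpdDefined <- TRUE
  } else {
    rpd <- NA_real_
    rpdDefined <- FALSE
  }
  list(r2 = r2, rmsec = rmsec, rmsep = rmsep, rpd = rpd,
       rpdDefined = rpdDefined, nCal = length(ycal), nVal = length(yval))
}

#' Interpretation profile of a fitted model
#'
#' Returns the per-wavenumber vector that is inspected for band
#' assignment: for PCR the loading vector of a single "related"
#' principal component (by default the component whose score column has
#' the largest absolute correlation with the response, overridable via
#' `pcIndex`); for PLS1 the full regression coefficient vector.
#' Requesting a single-component loading from a PLS1 model is an error:
#' PLS interpretation uses the coefficient plot.
#'
#' @param model a [CalibrationModel-class].
#' @param source `"auto"` (algorithm-appropriate default),
#'   `"regression_coefficients"`, or `"single_pc_loading"`.
#' @param pcIndex principal-component index (PCR only); must not exceed
#'   the number of fitted components.
#' @return Numeric vector over the retained wavenumbers.
#' @export
coefficientProfile <- function(model,
                               source = c("auto", "regression_coefficients",
                                          "single_pc_loading"),
                               pcIndex = NULL) {
  stopifnot(is(model, "CalibrationModel"))
  source <- match.arg(source)
  if (source == "auto")
    source <- if (model@algorithm == "PCR") "single_pc_loading"
              else "regression_coefficients"
  if (source == "regression_coefficients")
    return(model@coefficients)
  if (model@algorithm != "PCR")
    stop("single_pc_loading profiles are only defined for PCR models; use the regression coefficient plot for PLS1")
  if (is.null(pcIndex))
    pcIndex <- which.max(model@scoreYCorrelations)
  pcIndex <- as.integer(pcIndex)
  if (pcIndex < 1L || pcIndex > model@k)
    stop(sprintf("pcIndex = %d but only %d components were fitted",
                 pcIndex, model@k))
  model@loadings[, pcIndex]
}
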