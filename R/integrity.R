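# Model-integrity statistics: extract peaks from loading/coefficient
# profiles, match them to literature band assignments, and analyse the
# wavenumber residuals R = W - BA_L for bias and precision differences
# between calibration algorithms.

#' Extract peaks from a loading or coefficient profile
#'
#' Local maxima of the *absolute* profile (both positive and negative
#' coefficient lobes carry band information) with prominence at least
#' `minProminence` times the profile's maximum absolute value, thinned
#' so retained peaks are at least `minSeparation` cm^-1 apart (greedy,
#' strongest first).  Peak locations are refined off-grid by a
#' three-point parabolic interpolation around the grid maximum.
#'
#' @param profile numeric vector over `wavenumbers` (length >= 3).
#' @param wavenumbers descending wavenumber grid (cm^-1) of the same
#'   length.
#' @param minProminence threshold as a fraction of `max(abs(profile))`.
#' @param minSeparation minimum distance between retained peaks
#'   (cm^-1).
#' @return data.frame with columns `wavenumber` (refined, cm^-1),
#'   `value` (signed profile value at the grid maximum) and
#'   `prominence` (fraction of the profile maximum), sorted by
#'   descending wavenumber.  Empty for an all-zero profile.
#' @export
extractPeaks <- function(profile, wavenumbers, minProminence = 0.1,
                         minSeparation = 16) {
  if (length(profile) < 3L) stop("profile must have at least 3 points")
  if (length(profile) != length(wavenumbers))
    stop("profile and wavenumbers lengths differ")
  a <- abs(profile)
  m <- max(a)
  empty <- data.frame(wavenumber = numeric(0), value = numeric(0),
                      prominence = numeric(0))
  if (m == 0) return(empty)
  thr <- minProminence * m
  n <- length(a)
  i <- 2:(n - 1L)
  cand <- i[a[i] >= a[i - 1L] & a[i] >= a[i + 1L] & a[i] >= thr &
              (a[i] > a[i - 1L] | a[i] > a[i + 1L])]
  if (!length(cand)) return(empty)
  cand <- cand[order(a[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (ci in cand) {
    if (!length(kept) ||
        all(abs(wavenumbers[ci] - wavenumbers[kept]) >= minSeparation))
      kept <- c(kept, ci)
  }
  refine <- vapply(kept, function(ci) {
    y0 <- a[ci - 1L]; y1 <- a[ci]; y2 <- a[ci + 1L]
    den <- y0 - 2 * y1 + y2
    off <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    off <- max(-0.5, min(0.5, off))
    wavenumbers[ci] + off * (wavenumbers[ci + 1L] - wavenumbers[ci])
  }, 0)
  out <- data.frame(wavenumber = refine, value = profile[kept],
                    prominence = a[kept] / m)
  out[order(out$wavenumber, decreasing = TRUE), , drop = FALSE]
}

#' Match extracted peaks to literature band assignments
#'
#' Pairs peaks W with the band assignments BA_L of one constituent and
#' records the signed residual `R = W - BA_L`.  Candidate pairs are
#' taken greedily by ascending absolute residual (ties broken toward
#' the higher-wavenumber assignment); each assignment and each peak is
#' used at most once, and pairs farther apart than `tolerance` are
#' discarded.
#'
#' @param peaks data.frame from [extractPeaks()].
#' @param bands band table (see [defaultBandTable()]).
#' @param constituent which constituent's assignments to match against.
#' @param tolerance maximum |W - BA_L| (cm^-1) for an accepted pair.
#' @return data.frame with columns `constituent`, `W`, `BA_L`, `R`,
#'   `functional_group`; zero rows if nothing matches.
#' @export
matchBands <- function(peaks, bands, constituent, tolerance = 50) {
  if (tolerance <= 0) stop("'tolerance' must be positive")
  ba <- bands[bands$constituent == constituent, , drop = FALSE]
  if (!nrow(ba))
    stop("band table has no assignments for constituent '", constituent, "'")
  empty <- data.frame(constituent = character(0), W = numeric(0),
                      BA_L = numeric(0), R = numeric(0),
                      functional_group = character(0))
  if (!nrow(peaks)) return(empty)
  cand <- expand.grid(pi = seq_len(nrow(peaks)), bi = seq_len(nrow(ba)))
  cand$R <- peaks$wavenumber[cand$pi] - ba$center_cm1[cand$bi]
  cand <- cand[abs(cand$R) <= tolerance, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # ascending |R|; ties toward the higher-wavenumber assignment
  cand <- cand[order(abs(cand$R), -ba$center_cm1[cand$bi]), , drop = FALSE]
  usedP <- logical(nrow(peaks)); usedB <- logical(nrow(ba))
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    pi <- cand$pi[r]; bi <- cand$bi[r]
    if (usedP[pi] || usedB[bi]) next
    usedP[pi] <- TRUE; usedB[bi] <- TRUE
    keep <- c(keep, r)
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    constituent = constituent,
    W = peaks$wavenumber[cand$pi],
    BA_L = ba$center_cm1[cand$bi],
    R = cand$R,
    functional_group = ba$functional_group[cand$bi],
    stringsAsFactors = FALSE)
  out[order(out$W, decreasing = TRUE), , drop = FALSE]
}

#' Summarize pooled wavenumber residuals
#'
#' Mean, sample variance (n - 1 denominator), standard deviation and
#' the 95% confidence interval for the mean
#' (`mean +/- t_{0.975, n-1} * SD / sqrt(n)`) of a pooled residual set.
#'
#' @param residuals numeric vector of residuals R (cm^-1), or a
#'   data.frame with an `R` column.
#' @param level confidence level for the interval.
#' @return list with `n`, `mean`, `variance`, `sd`, `ciHalfwidth`,
#'   `ciLow`, `ciHigh`.
#' @export
poolResiduals <- function(residuals, level = 0.95) {
  r <- if (is.data.frame(residuals)) residuals$R else as.numeric(residuals)
  n <- length(r)
  if (n < 2L) stop("at least 2 residuals are required")
  m <- mean(r)
  v <- stats::var(r)
  s <- sqrt(v)
  hw <- ciHalfwidth(s, n, level)
  list(n = n, mean = m, variance = v, sd = s,
       ciHalfwidth = hw, ciLow = m - hw, ciHigh = m + hw)
}

#' Half-width of the t confidence interval for a mean
#'
#' `t_{(1+level)/2, n-1} * sd / sqrt(n)`.
#'
#' @param sd sample standard deviation.
#' @param n sample size (>= 2).
#' @param level confidence level (default 0.95).
#' @return The half-width, in the units of `sd`.
#' @examples
#' ciHalfwidth(7.45, 49)  # ~2.14
#' @export
ciHalfwidth <- function(sd, n, level = 0.95) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  stats::qt((1 + level) / 2, df = n - 1) * sd / sqrt(n)
}

fTestCore <- function(varPls, varPcr, dfPls, dfPcr, alpha = 0.05) {
  if (varPls <= 0 || varPcr <= 0)
    stop("zero variance in a residual set; the F-test is undefined")
  fUpper <- varPls / varPcr
  fLower <- varPcr / varPls
  pUpper <- stats::pf(fUpper, dfPls, dfPcr, lower.tail = FALSE)
  pLower <- stats::pf(fLower, dfPcr, dfPls, lower.tail = TRUE)
  list(
    varPls = varPls, varPcr = varPcr, dfPls = dfPls, dfPcr = dfPcr,
    fUpper = fUpper,                 # var(R_PLS) / var(R_PCR), upper tail
    pUpperOneTail = pUpper,
    fLower = fLower,                 # var(R_PCR) / var(R_PLS), lower tail
    pLowerOneTail = pLower,
    pTwoTail = 2 * min(pUpper, 1 - pUpper),
    criticalUpper = stats::qf(1 - alpha, dfPls, dfPcr),
    criticalLower = stats::qf(alpha, dfPcr, dfPls),
    alternative = "var(R_PLS) > var(R_PCR)", alpha = alpha)
}

#' One-sided F-test of residual variance between PLS and PCR
#'
#' Tests H0: var(R_PLS) = var(R_PCR) against Ha: var(R_PLS) >
#' var(R_PCR).  Both presentations are reported: the upper-tail ratio
#' `F = var_PLS / var_PCR` and the equivalent lower-tail ratio
#' `F = var_PCR / var_PLS` (with its 5% lower critical value), which is
#' how spreadsheet F-test output is usually printed.  The two one-tail
#' p values are identical by construction.
#'
#' @param residualsPls,residualsPcr residual vectors (cm^-1) or
#'   data.frames with an `R` column.
#' @param alpha significance level for the reported critical values.
#' @return list with the variance pair, both F orientations, one- and
#'   two-tailed p values, degrees of freedom, and critical values.
#' @seealso [fTestFromVariances()] for summary-statistic input.
#' @export
varianceFTest <- function(residualsPls, residualsPcr, alpha = 0.05) {
  r1 <- if (is.data.frame(residualsPls)) residualsPls$R else as.numeric(residualsPls)
  r2 <- if (is.data.frame(residualsPcr)) residualsPcr$R else as.numeric(residualsPcr)
  if (length(r1) < 2L || length(r2) < 2L)
    stop("both residual sets need at least 2 values")
  fTestCore(stats::var(r1), stats::var(r2),
            length(r1) - 1L, length(r2) - 1L, alpha)
}

#' @rdname varianceFTest
#' @param varPls,varPcr sample variances of the two residual sets.
#' @param dfPls,dfPcr their degrees of freedom (n - 1).
#' @export
fTestFromVariances <- function(varPls, varPcr, dfPls, dfPcr, alpha = 0.05) {
  fTestCore(varPls, varPcr, dfPls, dfPcr, alpha)
}

#' Two-sample t-test for residual location bias between models
#'
#' Standard two-sample t statistic (pooled-variance or Welch) on the
#' residual sets, used to check whether one algorithm's loading peaks
#' are systematically displaced relative to the other's.
#'
#' @inheritParams varianceFTest
#' @param variant `"pooled"` (equal-variance) or `"welch"`.
#' @return list with `t`, `df`, `pTwoTail`, `meanPls`, `meanPcr`.
#' @export
meanTTest <- function(residualsPls, residualsPcr,
                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  r1 <- if (is.data.frame(residualsPls)) residualsPls$R else as.numeric(residualsPls)
  r2 <- if (is.data.frame(residualsPcr)) residualsPcr$R else as.numeric(residualsPcr)
  if (length(r1) < 2L || length(r2) < 2L)
    stop("both residual sets need at least 2 values")
  tt <- stats::t.test(r1, r2, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pTwoTail = tt$p.value, meanPls = mean(r1), meanPcr = mean(r2),
       variant = variant)
}

#' Histogram of wavenumber residuals
#'
#' Counts residuals into bins of width `binWidth` whose edges are
#' anchored at zero; each bin is the left-open interval
#' `((k-1) * width, k * width]`.  All bins between the extremes are
#' reported, including empty ones, and the counts sum to the number of
#' residuals.
#'
#' @param residuals numeric residual vector or data.frame with column
#'   `R`.
#' @param binWidth positive bin width (cm^-1).
#' @return data.frame with `binLow`, `binHigh`, `count`.
#' @export
residualHistogram <- function(residuals, binWidth = 5) {
  if (binWidth <= 0) stop("'binWidth' must be positive")
  r <- if (is.data.frame(residuals)) residuals$R else as.numeric(residuals)
  if (!length(r))
    return(data.frame(binLow = numeric(0), binHigh = numeric(0),
                      count = integer(0)))
  idx <- ceiling(r / binWidth)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(k) sum(idx == k), 0L)
  data.frame(binLow = (rng - 1) * binWidth, binHigh = rng * binWidth,
             count = counts)
}
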