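test_that("peak extraction finds isolated band maxima with sub-grid refinement", {
  grid <- wavenumberGrid()
  g <- exp(-(grid - 1510)^2 / (2 * 12^2))
  pk <- extractPeaks(g, grid)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$wavenumber, 1510, tolerance = 1e-6)

  expect_equal(nrow(extractPeaks(rep(1, length(grid)), grid)), 0)
  expect_equal(nrow(extractPeaks(rep(0, length(grid)), grid)), 0)

  two <- exp(-(grid - 1600)^2 / (2 * 12^2)) -
    0.8 * exp(-(grid - 1270)^2 / (2 * 12^2))   # signed lobes both count
  pk2 <- extractPeaks(two, grid)
  expect_equal(nrow(pk2), 2)
  expect_lte(abs(pk2$wavenumber[1] - 1600), 2)
  expect_lte(abs(pk2$wavenumber[2] - 1270), 2)
  expect_lt(pk2$value[2], 0)

  # off-grid center recovered by parabolic interpolation
  g3 <- exp(-(grid - 1510.7)^2 / (2 * 12^2))
  expect_lt(abs(extractPeaks(g3, grid)$wavenumber - 1510.7), 0.1)
})

test_that("band matching pairs peaks to nearest assignments within tolerance", {
  bt <- defaultBandTable()
  pk <- data.frame(wavenumber = 1514, value = 1, prominence = 1)
  rec <- matchBands(pk, bt, "extractives")
  expect_equal(rec$BA_L, 1510)
  expect_equal(rec$R, 4)

  pk0 <- data.frame(wavenumber = 1730, value = 1, prominence = 1)
  expect_equal(matchBands(pk0, bt, "extractives")$R, 0)

  far <- data.frame(wavenumber = 900, value = 1, prominence = 1)
  expect_equal(nrow(matchBands(far, bt, "lignin", tolerance = 50)), 0)

  expect_error(matchBands(pk, bt[bt$constituent == "lignin", ],
                          "extractives"), "no assignments")

  # each assignment is used at most once; R = W - BA_L holds exactly
  pks <- data.frame(wavenumber = c(1512, 1508, 1600), value = 1,
                    prominence = 1)
  recs <- matchBands(pks, bt, "extractives")
  expect_lte(sum(recs$BA_L == 1510), 1)
  expect_equal(recs$W - recs$BA_L - recs$R, rep(0, nrow(recs)))
})

test_that("pooled residual summaries match hand arithmetic", {
  s <- poolResiduals(c(-2, 0, 4))
  expect_equal(s$mean, 2 / 3, tolerance = 1e-12)
  expect_equal(s$variance, 28 / 3, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(28 / 3), tolerance = 1e-12)
  expect_equal(s$ciHalfwidth, qt(0.975, 2) * sqrt(28 / 3) / sqrt(3),
               tolerance = 1e-12)
  expect_equal(round(s$ciHalfwidth, 2), 7.59)

  z <- poolResiduals(rep(0, 5))
  expect_equal(z$mean, 0)
  expect_equal(z$variance, 0)
  expect_equal(z$ciHalfwidth, 0)
  expect_error(poolResiduals(1), "at least 2")

  expect_equal(round(ciHalfwidth(7.45, 49), 1), 2.1)
  expect_equal(round(ciHalfwidth(9.62, 49), 1), 2.8)
  expect_equal(ciHalfwidth(0, 10), 0)
})

test_that("the variance F-test reports both orientations and is swap-symmetric", {
  ft <- fTestFromVariances(varPls = 92.6, varPcr = 55.5,
                           dfPls = 48, dfPcr = 48)
  expect_equal(round(ft$fLower, 2), 0.60)
  expect_equal(round(ft$criticalLower, 2), 0.62)
  expect_equal(ft$pLowerOneTail, pf(55.5 / 92.6, 48, 48), tolerance = 1e-12)
  expect_equal(ft$pLowerOneTail, ft$pUpperOneTail, tolerance = 1e-12)
  expect_equal(ft$pTwoTail, 2 * min(ft$pUpperOneTail, 1 - ft$pUpperOneTail))

  x <- c(1, 3, 2, 5, 4)
  same <- varianceFTest(x, x)
  expect_equal(same$fUpper, 1)
  expect_equal(same$pUpperOneTail, 0.5)

  set.seed(10)
  a <- rnorm(8, sd = 2); b <- rnorm(12)
  f1 <- varianceFTest(a, b)
  f2 <- varianceFTest(b, a)
  expect_equal(f2$fUpper, 1 / f1$fUpper, tolerance = 1e-12)
  expect_equal(f2$pUpperOneTail, 1 - f1$pUpperOneTail, tolerance = 1e-12)

  expect_error(varianceFTest(rep(1, 5), b), "zero variance")
})

test_that("F-tail probabilities agree with a sampling oracle", {
  set.seed(2024)
  draws <- 1e5
  fsim <- (rchisq(draws, 3) / 3) / (rchisq(draws, 3) / 3)
  phat <- mean(fsim < 0.5)
  ft <- fTestFromVariances(varPls = 2, varPcr = 1, dfPls = 3, dfPcr = 3)
  # the implementation's lower-tail law, evaluated at 0.5
  pimpl <- pf(0.5, 3, 3)
  expect_lt(abs(pimpl - phat), 3 * sqrt(phat * (1 - phat) / draws))
  expect_equal(ft$pLowerOneTail, pf(0.5, 3, 3), tolerance = 1e-12)
})

test_that("the two-sample t-test detects bias and matches a permutation oracle", {
  x <- c(1, 2, 3, 4)
  tt <- meanTTest(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$pTwoTail, 1)

  set.seed(5)
  sep <- meanTTest(rnorm(4, sd = 1e-3), 1 + rnorm(4, sd = 1e-3), "pooled")
  expect_lt(sep$pTwoTail, 0.01)

  set.seed(77)
  r1 <- rnorm(20)
  r2 <- rnorm(20, mean = 0.5)
  obs <- abs(mean(r1) - mean(r2))
  comb <- c(r1, r2)
  nPerm <- 1e5
  set.seed(78)
  perm <- vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(40, 20)
    abs(mean(comb[idx]) - mean(comb[-idx]))
  }, 0)
  pPerm <- mean(perm >= obs - 1e-12)
  pImpl <- meanTTest(r1, r2, "pooled")$pTwoTail
  expect_lt(abs(pImpl - pPerm), 0.02)
})

test_that("residual histograms bin on zero-anchored right-closed intervals", {
  h <- residualHistogram(c(-7, -2, 3, 12), 5)
  getCount <- function(lo) h$count[h$binLow == lo]
  expect_equal(getCount(-10), 1)
  expect_equal(getCount(-5), 1)
  expect_equal(getCount(0), 1)
  expect_equal(getCount(10), 1)
  expect_equal(getCount(5), 0)
  expect_equal(sum(h$count), 4)

  hz <- residualHistogram(rep(0, 7), 5)
  expect_equal(sum(hz$count > 0), 1)
  expect_equal(sum(hz$count), 7)

  set.seed(3)
  r <- rnorm(33, sd = 8)
  expect_equal(sum(residualHistogram(r, 5)$count), 33)
})

test_that("PCR first-component loadings recover isolated generator bands", {
  # single varying constituent, no noise, no baseline: the centered
  # spectra are rank one and PC1 is the constituent profile
  cfg <- generatorConfig(nSamples = 12, seed = 9, noiseSd = 0,
                         baseline = c(0, 0),
                         compositionRanges = list(extractives = c(1, 8)))
  ds <- generateDataset(cfg)
  y <- ds$compositions$extractives
  m <- fitPCR(ds$spectra, y, 1)
  prof <- coefficientProfile(m, "single_pc_loading", pcIndex = 1)
  pk <- extractPeaks(prof, wavenumbers(ds$spectra))
  isolated <- c(1730, 1510, 1271)   # nearest other band >= 90 cm^-1 away
  for (ctr in isolated) {
    d <- min(abs(pk$wavenumber - ctr))
    expect_lte(d, 2)                # within one grid step
  }
})
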