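test_that("PCR handles a constant response and full rank recovers least squares", {
  prob <- randomProblem(1)
  m0 <- fitPCR(prob$X, rep(5, nrow(prob$X)), 3)
  expect_equal(m0@coefficients, rep(0, ncol(prob$X)))
  expect_equal(predict(m0, prob$X), rep(5, nrow(prob$X)))

  for (s in 1:5) {
    prob <- randomProblem(s)
    m <- fitPCR(prob$X, prob$y, k = 8)
    expect_lt(max(abs(m@coefficients - pinvCoef(prob$X, prob$y))), 1e-8)
  }

  # one dominant variance direction aligned with y
  set.seed(99)
  t <- rnorm(20)
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  X <- outer(t, v) + matrix(rnorm(600, sd = 1e-4), 20, 30)
  m1 <- fitPCR(X, t, 1)
  pred <- predict(m1, X)
  expect_gte(100 * cor(pred, t)^2, 99)

  expect_error(fitPCR(prob$X, prob$y, k = 20), "1\\.\\.8")
  Xr <- cbind(prob$X[, 1:3], prob$X[, 1:3])   # rank-deficient
  expect_error(fitPCR(Xr, prob$y, k = 5), "rank")
})

test_that("PLS1 matches its first-component direction, least squares and an independent NIPALS oracle", {
  prob <- randomProblem(2)
  m1 <- fitPLS1(prob$X, prob$y, 1)
  w <- drop(crossprod(sweep(prob$X, 2, colMeans(prob$X)),
                      prob$y - mean(prob$y)))
  cosang <- sum(m1@coefficients * w) /
    sqrt(sum(m1@coefficients^2) * sum(w^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-10)

  for (s in 1:5) {
    prob <- randomProblem(s + 10)
    mf <- fitPLS1(prob$X, prob$y, 8)
    expect_lt(max(abs(mf@coefficients - pinvCoef(prob$X, prob$y))), 1e-8)
    m3 <- fitPLS1(prob$X, prob$y, 3)
    expect_lt(max(abs(m3@coefficients - nipalsOracle(prob$X, prob$y, 3))),
              1e-8)
  }

  expect_error(fitPLS1(prob$X, rep(1, nrow(prob$X)), 2), "zero variance")
})

test_that("prediction is consistent with centering and the RMSEC definition", {
  ds <- generateDataset(generatorConfig(nSamples = 20, seed = 4))
  X <- selectWindow(ds$spectra, 800, 1800)
  y <- ds$compositions$lignin
  m <- fitPLS1(X, y, 4)
  # the training-mean spectrum predicts the training mean of y
  expect_equal(predict(m, colMeans(absorbance(X))), mean(y),
               tolerance = 1e-10)
  dg <- modelDiagnostics(m, X, y, X[1:5, ], y[1:5])
  expect_equal(sqrt(mean((predict(m, X) - y)^2)), dg$rmsec,
               tolerance = 1e-12)
  # grid mismatch is refused with the expected window
  expect_error(predict(m, selectWindow(ds$spectra, 1000, 1500)),
               "grid mismatch")

  # noiseless validation data are predicted exactly at sufficient k
  clean <- generateDataset(generatorConfig(nSamples = 20, seed = 5,
                                           noiseSd = 0, baseline = c(0, 0)))
  Xc <- selectWindow(clean$spectra, 800, 1800)
  yc <- clean$compositions$lignin
  mc <- fitPLS1(Xc[1:14, ], yc[1:14], 4)
  expect_lt(sqrt(mean((predict(mc, Xc[15:20, ]) - yc[15:20])^2)), 1e-6)
})

test_that("splitSamples returns balanced seeded 31/6 splits", {
  ds <- generateDataset(generatorConfig(nSamples = 37, seed = 6))
  s1 <- splitSamples(ds$spectra, ds$compositions, 31, 6, seed = 2)
  expect_equal(length(s1$calIdx), 31)
  expect_equal(length(s1$valIdx), 6)
  expect_equal(nrow(s1$calSpectra), 31)
  s2 <- splitSamples(ds$spectra, ds$compositions, 31, 6, seed = 2)
  expect_identical(s1$valIdx, s2$valIdx)
  sInf <- splitSamples(ds$spectra, ds$compositions, 31, 6, seed = 3,
                       balanceTol = Inf)
  expect_equal(sInf$attempts, 1)
  expect_error(splitSamples(ds$spectra, ds$compositions, 31, 6, seed = 3,
                            balanceTol = 1e-6, maxAttempts = 5),
               "best max standardized")
})

test_that("cross-validation selects parsimonious k by the 5% rule", {
  set.seed(123)
  t <- rnorm(24)
  v <- rnorm(40)
  X <- outer(t, v)                      # exactly one latent variable
  y <- 2 * t + 1
  expect_message(cv <- crossValidate(X, y, "PLS1", kMax = 3),
                 "truncated")
  expect_equal(cv$k, 1)

  ds <- generateDataset(generatorConfig(nSamples = 24, seed = 8))
  Xs <- selectWindow(ds$spectra, 1000, 1500)
  yv <- ds$compositions$cellulose
  for (alg in c("PCR", "PLS1")) {
    cv <- crossValidate(Xs, yv, alg, kMax = 6)
    expect_lte(cv$table$rmsecv[cv$table$k == cv$k],
               1.05 * min(cv$table$rmsecv))
    expect_true(all(cv$table$rmsecv[cv$table$k < cv$k] >
                      1.05 * min(cv$table$rmsecv)))
  }
  expect_error(crossValidate(Xs, rep(1, 24), "PLS1", kMax = 3),
               "zero variance")
})

test_that("diagnostics reproduce their closed-form values", {
  # identity model: prediction passes the lone X column through
  idm <- new("CalibrationModel", algorithm = "PLS1", constituent = "x",
             preprocess = list(), k = 1L, xCenter = 0, yCenter = 0,
             coefficients = 1, loadings = matrix(1, 1, 1),
             weights = matrix(1, 1, 1), yLoadings = 1,
             scoreYCorrelations = numeric(0), wavenumbers = numeric(0))
  yval <- 1:5
  yhat <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  dg <- modelDiagnostics(idm, matrix(yval), yval, matrix(yhat), yval)
  expect_equal(dg$r2, 100)
  expect_equal(dg$rmsec, 0)
  expect_equal(dg$rmsep, sqrt(0.022), tolerance = 1e-12)
  expect_equal(dg$rpd, sd(yval) / sqrt(0.022), tolerance = 1e-12)
  expect_equal(round(dg$rpd, 2), 10.66)

  # constant prediction at the validation mean
  y3 <- 1:3
  dg2 <- modelDiagnostics(idm, matrix(y3), y3, matrix(rep(2, 3)), y3)
  expect_equal(dg2$rmsep, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(dg2$rpd, sqrt(3 / 2), tolerance = 1e-12)

  # perfect validation prediction: RPD flagged undefined, not infinite
  dg3 <- modelDiagnostics(idm, matrix(y3), y3, matrix(y3), y3)
  expect_false(dg3$rpdDefined)
  expect_true(is.na(dg3$rpd))
})

test_that("coefficient profiles follow the per-algorithm convention", {
  ss <- singleBandSpectra()
  y <- absorbance(ss)[, which(wavenumbers(ss) == 1510)]
  m <- fitPCR(ss, y, 1)
  prof <- coefficientProfile(m)
  expect_equal(wavenumbers(ss)[which.max(abs(prof))], 1510)
  expect_error(coefficientProfile(m, "single_pc_loading", pcIndex = 9),
               "only 1 components")

  prob <- randomProblem(3)
  mp <- fitPLS1(prob$X, prob$y, 3)
  expect_identical(coefficientProfile(mp), mp@coefficients)
  expect_error(coefficientProfile(mp, "single_pc_loading", pcIndex = 1),
               "only defined for PCR")
})

test_that("RMSEC decreases in k and PLS1 dominates PCR in training fit", {
  set.seed(31)
  n <- 15; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  rmsecOf <- function(m) sqrt(mean((predict(m, X) - y)^2))
  prevP <- prevL <- Inf
  for (k in 1:8) {
    rp <- rmsecOf(fitPCR(X, y, k))
    rl <- rmsecOf(fitPLS1(X, y, k))
    expect_lte(rp, prevP + 1e-10)
    expect_lte(rl, prevL + 1e-10)
    expect_lte(rl, rp + 1e-10)          # Krylov optimality of PLS1
    prevP <- rp; prevL <- rl
  }

  # adding a constant offset to every spectrum leaves predictions alone
  off <- matrix(rnorm(p), n, p, byrow = TRUE)
  m1 <- fitPLS1(X, y, 3)
  m2 <- fitPLS1(X + off, y, 3)
  expect_equal(predict(m1, X), predict(m2, X + off), tolerance = 1e-8)
})
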