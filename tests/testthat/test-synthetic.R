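test_that("default band table carries the expected assignments", {
  bt <- defaultBandTable()
  centersOf <- function(cc) sort(bt$center_cm1[bt$constituent == cc])
  expect_equal(centersOf("extractives"), sort(c(1730, 1633, 1600, 1510, 1271)))
  expect_equal(centersOf("lignin"),
               sort(c(1735, 1658, 1510, 1425, 1375, 1328, 1269, 1220,
                      1140, 1116, 1033, 835)))
  expect_equal(centersOf("cellulose"),
               sort(c(1440, 1380, 1310, 1280, 1220, 1160, 1047, 1004)))
  expect_equal(centersOf("hemicellulose"),
               sort(c(1639, 1453, 1426, 1338, 1051, 1008)))
  ext1730 <- bt[bt$constituent == "extractives" & bt$center_cm1 == 1730, ]
  expect_match(ext1730$functional_group, "ester carbonyl")
  cel1160 <- bt[bt$constituent == "cellulose" & bt$center_cm1 == 1160, ]
  expect_match(cel1160$functional_group, "C-O-C asymmetric")
  expect_true(all(bt$center_cm1 >= 650 & bt$center_cm1 <= 4000))
})

test_that("composition sampling respects ranges, seeds and the sum cap", {
  degen <- generatorConfig(nSamples = 3, seed = 5,
                           compositionRanges = list(lignin = c(25, 25),
                                                    cellulose = c(45, 45)))
  cd <- sampleCompositions(degen)
  expect_equal(nrow(cd), 3)
  expect_equal(cd$lignin, rep(25, 3))
  expect_equal(cd$cellulose, rep(45, 3))

  cfg <- generatorConfig(nSamples = 37, seed = 1)
  c1 <- sampleCompositions(cfg)
  c2 <- sampleCompositions(cfg)
  expect_identical(c1, c2)
  cons <- setdiff(names(c1), "sample_id")
  expect_true(all(rowSums(c1[, cons]) <= 100))
  for (cc in cons) {
    r <- cfg$compositionRanges[[cc]]
    expect_true(all(c1[[cc]] >= r[1] & c1[[cc]] <= r[2]))
  }
  # impossible ranges exhaust the redraw budget
  bad <- generatorConfig(nSamples = 2,
                         compositionRanges = list(cellulose = c(60, 70),
                                                  lignin = c(50, 60)))
  expect_error(sampleCompositions(bad, maxAttempts = 10), "100")
})

test_that("renderSpectrum builds composition-weighted Gaussian bands", {
  cfg <- generatorConfig()
  grid <- cfg$grid
  zero <- renderSpectrum(c(extractives = 0, lignin = 0, cellulose = 0,
                           hemicellulose = 0),
                         cfg, baseline = c(0, 0), noiseSd = 0)
  expect_equal(zero, rep(0, length(grid)))

  oneBand <- generatorConfig(bands = data.frame(
    constituent = "lignin", center_cm1 = 1510,
    functional_group = "aromatic skeletal vibration",
    width_cm1 = 12, amplitude = 1))
  sp <- renderSpectrum(c(lignin = 100), oneBand, baseline = c(0, 0),
                       noiseSd = 0)
  expect_equal(max(sp), 1.0)
  expect_equal(grid[which.max(sp)], 1510)

  expect_error(renderSpectrum(c(starch = 10), cfg), "starch")

  # each band of a noiseless spectrum peaks within one grid step of its
  # center when rendered in isolation (brute-force argmax oracle)
  bt <- defaultBandTable()
  lig <- bt[bt$constituent == "lignin", ]
  for (i in seq_len(nrow(lig))) {
    c1 <- generatorConfig(bands = lig[i, , drop = FALSE])
    sp <- renderSpectrum(c(lignin = 50), c1, baseline = c(0, 0), noiseSd = 0)
    expect_lte(abs(grid[which.max(sp)] - lig$center_cm1[i]), 2)
  }
})

test_that("generateDataset is reproducible, linear and exactly invertible without noise", {
  cfg <- generatorConfig(nSamples = 37, seed = 1)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(absorbance(d1$spectra), absorbance(d2$spectra))
  expect_identical(d1$compositions, d2$compositions)
  expect_equal(nrow(d1$spectra), 37)
  expect_equal(nrow(d1$compositions), 37)
  expect_equal(length(wavenumbers(d1$spectra)), 1676)

  # zero-noise linearity: a 50/50 mixture's spectrum is the average of
  # the two components' spectra (baseline counted once)
  quiet <- generatorConfig(noiseSd = 0)
  a <- c(extractives = 4, lignin = 20, cellulose = 40, hemicellulose = 20)
  b <- c(extractives = 8, lignin = 30, cellulose = 50, hemicellulose = 10)
  base <- c(0.01, 1e-5)
  sa <- renderSpectrum(a, quiet, baseline = base, noiseSd = 0)
  sb <- renderSpectrum(b, quiet, baseline = base, noiseSd = 0)
  sm <- renderSpectrum((a + b) / 2, quiet, baseline = base, noiseSd = 0)
  expect_equal(sm, (sa + sb) / 2, tolerance = 1e-12)

  # noiseless signal is non-negative
  sOnly <- renderSpectrum(b, quiet, baseline = c(0, 0), noiseSd = 0)
  expect_true(all(sOnly >= 0))

  # with no noise and no baseline, each constituent is an exact linear
  # function of the absorbances at its own band centers
  clean <- generatorConfig(nSamples = 37, seed = 2, noiseSd = 0,
                           baseline = c(0, 0))
  ds <- generateDataset(clean)
  grid <- wavenumbers(ds$spectra)
  A <- absorbance(ds$spectra)
  for (cc in WOOD_CONSTITUENTS <- c("extractives", "lignin", "cellulose",
                                    "hemicellulose")) {
    centers <- ds$bands$center_cm1[ds$bands$constituent == cc]
    idx <- vapply(centers, function(v) which.min(abs(grid - v)), 0L)
    H <- A[, idx, drop = FALSE]
    fit <- lm.fit(cbind(1, H), ds$compositions[[cc]])
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})
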