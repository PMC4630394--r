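# woodChemIR

Chemometric calibration of wood chemical composition from mid-infrared
(FT-IR) absorbance spectra, together with a statistical audit of how
precisely each calibration algorithm's loading peaks land on literature
infrared band assignments.

## Who it is for

Wood chemists and chemometricians who calibrate extractives, lignin,
cellulose and hemicellulose content (% w/w) on ATR FT-IR spectra and who use
the fitted models' loading/coefficient plots to reason about functional
groups.  Since reference spectra with wet-chemistry ground truth are rarely
shareable, the package includes a synthetic-spectrum generator with known
band structure so the entire workflow is testable end to end.

## What it computes

**Calibration.** Two latent-variable regressions of a constituent `y` on
mean-centered spectra `X` (samples × wavenumbers):

* **PCR** — principal components from the SVD of `X`; regress `y` on the
  first `k` score columns.
* **PLS1** — NIPALS: for each component, weight `w ∝ Xᵀy`, score `t = Xw`,
  loadings `p = Xᵀt/tᵀt`, `q = yᵀt/tᵀt`, then deflation of `X` and `y`;
  coefficients `b = W(PᵀW)⁻¹q`.

Pretreatment: per-constituent wavenumber windows and an optional
Savitzky–Golay first derivative.  Model selection by cross-validation
(smallest `k` with RMSECV within 5% of the minimum).  Diagnostics: r²
(percent), RMSEC, RMSEP, RPD.

**Integrity.** For each fitted model the interpretation profile (single
"related" PC loading for PCR; the regression coefficient vector for PLS1)
is scanned for peaks `W`, each peak is matched to the nearest literature
band assignment `BA_L` of that constituent, and the residual

```
R = W − BA_L        (cm⁻¹)
```

is pooled per algorithm.  The pooled sets are summarized (mean, variance,
SD, 95% t-interval) and compared with a one-sided F-test of

```
H0: var(R_PLS) = var(R_PCR)     Ha: var(R_PLS) > var(R_PCR)
```

plus a two-sample t-test for location bias and a residual histogram.  A
smaller residual variance marks the algorithm whose loadings are more
trustworthy for band interpretation.

## Worked example

```r
library(woodChemIR)

report <- runPipeline(runConfig(seed = 1))

dg <- report$diagnostics
dg[dg$mode == "first_derivative" & dg$algorithm == "PLS1",
   c("constituent", "k", "r2", "rmsec", "rmsep", "rpd")]
#>    constituent k     r2   rmsec   rmsep   rpd
#>    extractives 6  99.94 0.04480 0.11952 16.80
#>         lignin 4  99.97 0.05126 0.06337 45.47
#>      cellulose 3  99.94 0.08812 0.11510 32.75
#>  hemicellulose 6 100.00 0.01642 0.11279 46.16

ft <- report$summary$fTest
sprintf("F = var(R_PLS)/var(R_PCR) = %.3f, one-tail p = %.3f",
        ft$fUpper, ft$pUpperOneTail)
#> "F = var(R_PLS)/var(R_PCR) = 0.743, one-tail p = 0.875"

s <- report$summary$perAlgorithm$PCR$summary
sprintf("PCR residuals: n = %d, mean = %.2f, SD = %.2f, 95%% CI ± %.2f",
        s$n, s$mean, s$sd, s$ciHalfwidth)
#> "PCR residuals: n = 62, mean = 0.95, SD = 9.04, 95% CI ± 2.30"
```

Reading the output: each row is one constituent model fitted on 31
calibration samples and validated on 6 held-out samples at the
cross-validation-selected component count `k`.  The near-perfect r² and the
large RPD values (RPD > 4 is usually taken as quantitative grade) reflect
the synthetic generator's exactly linear signal and small noise — real wood
spectra are harder.  The F-ratio compares the pooled loading-peak location
variances of the two algorithms; here the PCR pool is the *more* variable
one (F < 1), and its mean residual's confidence interval covers zero,
indicating no location bias.

A command-line front end over the same functions is shipped at
`inst/cli/woodchemir.R` with subcommands `simulate`, `calibrate`,
`integrity` and `report`.

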