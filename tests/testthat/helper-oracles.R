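# Independent oracles used to cross-check the package's fitters.
# These are written directly from the algorithm statements and share no
# code with the implementation under test.

# Minimum-norm least-squares coefficients of the mean-centered problem,
# via the SVD pseudoinverse.
pinvCoef <- function(X, y, tol = 1e-10) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sv <- svd(Xc)
  keep <- sv$d > tol * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% yc) / sv$d[keep]))
}

# Textbook NIPALS PLS1, coded independently: explicit inner iteration
# on the score vector until convergence, deflating X and y.
nipalsOracle <- function(X, y, k) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  p <- ncol(Xc)
  W <- P <- matrix(0, p, k)
  q <- numeric(k)
  for (a in seq_len(k)) {
    w <- t(Xc) %*% yc
    w <- w / sqrt(sum(w^2))
    t_old <- rep(Inf, nrow(Xc))
    for (it in 1:500) {
      tv <- Xc %*% w
      if (sqrt(sum((tv - t_old)^2)) < 1e-12 * sqrt(sum(tv^2))) break
      t_old <- tv
      w <- t(Xc) %*% yc      # single response: fixed point immediately
      w <- w / sqrt(sum(w^2))
    }
    tv <- drop(Xc %*% w)
    pv <- drop(t(Xc) %*% tv) / sum(tv^2)
    qa <- sum(yc * tv) / sum(tv^2)
    Xc <- Xc - outer(tv, pv)
    yc <- yc - qa * tv
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  drop(W %*% solve(t(P) %*% W) %*% q)
}

# Random calibration-style problem with a planted linear signal.
randomProblem <- function(seed, n = 10, p = 8, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y)
}

# A spectra set whose rows are multiples of one Gaussian band profile.
singleBandSpectra <- function(center = 1510, sigma = 12, n = 9,
                              grid = wavenumberGrid()) {
  fracs <- seq(0.2, 1, length.out = n)
  g <- exp(-(grid - center)^2 / (2 * sigma^2))
  SpectraSet(outer(fracs, g), grid)
}
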