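# Internal helpers shared across modules.

#: constituent vocabulary used by composition tables and the band table
WOOD_CONSTITUENTS <- c("extractives", "lignin", "cellulose", "hemicellulose")

# Derive a reproducible sub-stream seed from a top-level seed and a stage
# label, so adding a stage never perturbs the draws of earlier stages.
# Result is kept below 2^31 - 1 (R integers are 32-bit).
subSeed <- function(seed, label) {
  v <- utf8ToInt(label)
  as.integer((as.numeric(seed) * 48271 + sum(v * seq_along(v)) * 7919) %%
               2147483629)
}

# Small deterministic checksum for run manifests (djb2 variant).
checksumString <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Numerical rank of a matrix from its singular values.
matrixRank <- function(X, tol = NULL) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Wrap a stage of the pipeline so failures carry stage / context labels.
withStage <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s | %s] %s", stage, context, conditionMessage(e)),
         call. = FALSE)
  })
}
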