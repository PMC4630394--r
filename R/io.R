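# File formats: spectra CSV (first column wavenumber, one column per
# sample), composition CSV (sample_id + one column per constituent,
# percent w/w), band-assignment TSV.  Comma-separated, UTF-8, "."
# decimal; values written with 17 significant digits so read(write(x))
# round-trips to full double precision.

fmtNum <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Read a spectra CSV file
#'
#' Expects a header row of sample identifiers, a first column named
#' `wavenumber` (cm^-1) and one numeric column per sample.  The grid
#' must be strictly monotone with uniform spacing; ascending files are
#' accepted and reversed to the canonical descending orientation (a
#' notice is emitted).
#'
#' @param path file path.
#' @return A [SpectraSet-class].
#' @seealso [writeSpectraCSV()]
#' @export
readSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L) stop("spectra file has no columns: ", path)
  wn <- as.numeric(df[[1]])
  ids <- names(df)[-1]
  if (anyDuplicated(ids))
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(wn) >= 2L) {
    st <- diff(wn)
    if (all(st > 0)) {
      message("ascending wavenumber grid in ", basename(path),
              "; reversing to descending order")
    } else if (!all(st < 0)) {
      bad <- which(sign(st) != sign(st[1]))[1] + 1L
      stop(sprintf("wavenumber column is not monotone at row %d (%g after %g)",
                   bad, wn[bad], wn[bad - 1L]))
    }
    ust <- abs(st)
    if (max(abs(ust - ust[1])) > 1e-6 * ust[1]) {
      bad <- which(abs(ust - ust[1]) > 1e-6 * ust[1])[1] + 1L
      stop(sprintf("wavenumber spacing is not uniform at row %d (step %g, expected %g)",
                   bad, ust[bad - 1L], ust[1]))
    }
  }
  A <- t(as.matrix(df[, -1, drop = FALSE]))
  if (anyNA(A)) stop("spectra file contains missing values")
  SpectraSet(A, wn, ids)   # constructor normalizes ascending input
}

#' Write a spectra CSV file
#'
#' @param spectra a [SpectraSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @seealso [readSpectraCSV()]
#' @export
writeSpectraCSV <- function(spectra, path) {
  stopifnot(is(spectra, "SpectraSet"))
  header <- paste(c("wavenumber", sampleIds(spectra)), collapse = ",")
  body <- cbind(fmtNum(wavenumbers(spectra)),
                if (nrow(spectra) > 0)
                  apply(absorbance(spectra), 1, fmtNum)
                else NULL)
  lines <- c(header, apply(body, 1, paste, collapse = ","))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

validateCompositions <- function(df, context = "composition table") {
  if (!"sample_id" %in% names(df))
    stop(context, " must have a 'sample_id' column")
  cons <- setdiff(names(df), "sample_id")
  bad <- setdiff(cons, WOOD_CONSTITUENTS)
  if (length(bad))
    stop("unknown constituent column(s) ", paste(bad, collapse = ", "),
         "; vocabulary: ", paste(WOOD_CONSTITUENTS, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop(context, " has duplicated sample ids")
  for (cc in cons) {
    v <- df[[cc]]
    out <- which(!is.finite(v) | v < 0 | v > 100)
    if (length(out))
      stop(sprintf("%s: %s = %g for sample '%s' is outside [0, 100]",
                   context, cc, v[out[1]], df$sample_id[out[1]]))
  }
  sums <- rowSums(df[, cons, drop = FALSE])
  over <- which(sums > 100 + 1e-9)
  if (length(over))
    stop(sprintf("%s: constituents of sample '%s' sum to %.3f%% (> 100%%)",
                 context, df$sample_id[over[1]], sums[over[1]]))
  invisible(df)
}

#' Read / write a composition CSV file
#'
#' Columns: `sample_id` plus one percent-w/w column per constituent
#' (vocabulary: extractives, lignin, cellulose, hemicellulose).
#' Values are validated against `[0, 100]` and row sums against 100%.
#'
#' @param path file path.
#' @return `readCompositionCSV`: a validated data.frame.
#' @export
readCompositionCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character"))
  validateCompositions(df, context = basename(path))
  df
}

#' @rdname readCompositionCSV
#' @param compositions data.frame as returned by [sampleCompositions()].
#' @export
writeCompositionCSV <- function(compositions, path) {
  validateCompositions(compositions)
  cons <- setdiff(names(compositions), "sample_id")
  lines <- c(paste(c("sample_id", cons), collapse = ","),
             vapply(seq_len(nrow(compositions)), function(i) {
               paste(c(compositions$sample_id[i],
                       fmtNum(unlist(compositions[i, cons]))), collapse = ",")
             }, ""))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write a band-assignment TSV file
#'
#' Tab-separated with columns `constituent`, `center_cm1`,
#' `functional_group`, `literature_ref` and optionally `width_cm1`,
#' `amplitude`.  Centers must lie within 650-4000 cm^-1.
#'
#' @param path file path.
#' @return `readBandTableTSV`: a validated data.frame.
#' @export
readBandTableTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validateBandTable(df)
  df
}

#' @rdname readBandTableTSV
#' @param bands band table data.frame (see [defaultBandTable()]).
#' @export
writeBandTableTSV <- function(bands, path) {
  validateBandTable(bands)
  num <- vapply(bands, is.numeric, TRUE)
  out <- bands
  for (j in which(num)) out[[j]] <- fmtNum(bands[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Minimal JCAMP-DX single-spectrum reader
#'
#' Optional convenience import of one spectrum from a JCAMP-DX file
#' whose `##XYDATA=(X++(Y..Y))` block uses plain (AFFN) numbers.
#' Compressed forms (SQZ/DIF/DUP) and multi-spectra files are not
#' supported.
#'
#' @param path file path.
#' @param sampleId identifier for the resulting single-row set.
#' @return A [SpectraSet-class] with one spectrum.
#' @export
readJCAMP <- function(path, sampleId = "jcamp") {
  lines <- readLines(path, warn = FALSE)
  getLdr <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  xfac <- as.numeric(getLdr("XFACTOR")); if (is.na(xfac)) xfac <- 1
  yfac <- as.numeric(getLdr("YFACTOR")); if (is.na(yfac)) yfac <- 1
  npt <- as.numeric(getLdr("NPOINTS"))
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  if (is.na(end)) end <- length(lines) + 1L
  block <- lines[(start[1] + 1L):(end - 1L)]
  x <- numeric(0); y <- numeric(0)
  for (ln in block) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (!length(vals) || anyNA(vals))
      stop("unsupported (non-AFFN) XYDATA line in ", path, ": ", ln)
    nY <- length(vals) - 1L
    if (nY < 1L) next
    y <- c(y, vals[-1] * yfac)
    x <- c(x, vals[1] * xfac)   # first abscissa of the line
  }
  # reconstruct the full abscissa from line starts and counts
  firstx <- as.numeric(getLdr("FIRSTX")) * xfac
  lastx <- as.numeric(getLdr("LASTX")) * xfac
  if (is.na(npt)) npt <- length(y)
  if (length(y) != npt)
    stop(sprintf("expected %d points, found %d in %s", npt, length(y), path))
  grid <- seq(firstx, lastx, length.out = npt)
  SpectraSet(matrix(y, nrow = 1), grid, sampleId)
}
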