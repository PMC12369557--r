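#' Build a descending wavenumber grid
#'
#' FT-NIR acquisitions in this workflow run from high to low wavenumber;
#' the internal convention is a strictly descending, evenly spaced grid.
#' The spectrometer's optical resolution does not fix the digitised point
#' spacing, so the spacing is an explicit argument.
#'
#' @param start first grid point (cm^-1); must exceed `end`.
#' @param end last grid point (cm^-1); positive.
#' @param step spacing between points (cm^-1); positive.
#' @return numeric vector from `start` down to `end` inclusive.
#' @examples
#' length(defaultGrid(10000, 4000, 4))  # 1501 points
#' @export
defaultGrid <- function(start = 10000, end = 4000, step = 4) {
    if (!is.finite(step) || step <= 0)
        stop("'step' must be a positive number of cm^-1")
    if (!is.finite(start) || !is.finite(end) || end <= 0)
        stop("'start' and 'end' must be positive wavenumbers")
    if (start < end)
        stop("'start' must exceed 'end' (descending grid convention)")
    seq(start, end, by = -step)
}

#' Read a spectral dataset from delimited text
#'
#' The on-disk format is a plain CSV: a header row
#' `sample_id,brand,target,<w1>,...,<wd>` whose trailing names are the
#' wavenumber grid, then one row per sample.  An ascending header grid is
#' accepted and reordered to the descending convention with a notice;
#' ragged rows, non-numeric absorbance cells and non-monotone grids are
#' rejected with errors naming the offence.
#'
#' @param path path to a CSV file written by [writeSpectra()] (or any file
#'   matching the layout above).
#' @param format storage dialect; only `"csv"` is supported.
#' @return a validated [SpectralSet-class]; row order is preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSpectra(exampleSpectralSet(), f)
#' ds <- readSpectra(f)
#' @export
readSpectra <- function(path, format = c("csv")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    nf <- utils::count.fields(path, sep = ",", quote = "\"",
                              comment.char = "")
    if (!length(nf)) stop("empty file: ", path)
    if (any(nf != nf[1L])) {
        bad <- which(nf != nf[1L])[1L]
        stop(sprintf(
            "format error in '%s': row %d has %d fields, expected %d",
            path, bad, nf[bad], nf[1L]))
    }
    if (nf[1L] < 4L)
        stop("format error: need at least sample_id, brand, target and one ",
             "wavenumber column")
    dt <- data.table::fread(path, header = TRUE, sep = ",",
                            colClasses = list(character = 1:2),
                            data.table = FALSE, showProgress = FALSE)
    hdr <- names(dt)
    w <- suppressWarnings(as.numeric(hdr[-(1:3)]))
    if (any(is.na(w)))
        stop("format error: header wavenumbers are not numeric: ",
             paste(utils::head(hdr[-(1:3)][is.na(w)], 3), collapse = ", "))
    n <- nrow(dt)
    A <- matrix(numeric(), nrow = n, ncol = length(w))
    if (n) {
        A <- suppressWarnings(
            vapply(dt[-(1:3)], as.numeric, numeric(n), USE.NAMES = FALSE))
        if (n == 1L) A <- matrix(A, nrow = 1L)
        if (any(!is.finite(A))) {
            bad <- which(!is.finite(A), arr.ind = TRUE)[1L, ]
            stop(sprintf(
                "parse error: non-numeric or non-finite absorbance at row %d, wavenumber %s",
                bad[1L], hdr[-(1:3)][bad[2L]]))
        }
    }
    target <- suppressWarnings(as.numeric(dt[[3L]]))
    if (n && any(is.na(target)))
        stop("parse error: non-numeric target at row ",
             which(is.na(target))[1L])
    if (length(w) > 1L) {
        dw <- diff(w)
        if (!all(dw < 0) && !all(dw > 0))
            stop("validation error: wavenumber grid is not strictly monotone")
    }
    SpectralSet(A, w, target = target, brand = if (n) dt[[2L]] else character(),
                sampleID = if (n) dt[[1L]] else character())
}

#' Write a spectral dataset as delimited text
#'
#' Emits the CSV layout read by [readSpectra()].  Numeric values are
#' written with enough significant digits (15) that a write/read round
#' trip preserves them to at least 12 significant digits.
#'
#' @param ds a [SpectralSet-class].
#' @param path destination file path.
#' @return invisibly, `path`.
#' @export
writeSpectra <- function(ds, path) {
    stopifnot(is(ds, "SpectralSet"))
    validObject(ds)
    w <- wavenumbers(ds)
    A <- absorbance(ds)
    df <- data.frame(sample_id = sampleIDs(ds), brand = brands(ds),
                     target = blendTarget(ds), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(A) == 0L)
        df <- df[0L, , drop = FALSE]
    M <- as.data.frame(A)
    names(M) <- format(w, trim = TRUE, digits = 10, scientific = FALSE)
    out <- cbind(df, M)
    ok <- tryCatch({
        data.table::fwrite(out, path, sep = ",", quote = FALSE,
                           scipen = 999)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("I/O error writing '", path, "': ", conditionMessage(ok))
    invisible(path)
}
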