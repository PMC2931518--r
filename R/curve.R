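#' Scattering intensity curve
#'
#' Container for a one-dimensional SAXS intensity curve: q values (A^-1),
#' intensities (arbitrary units) and optional per-point standard deviations.
#'
#' @param q Strictly increasing vector of momentum values (A^-1).
#' @param I Intensities, same length as `q`. Small negative values down to
#'   `-1e-9 * I[1]` are tolerated as numerical noise; anything lower errors.
#' @param sigma Optional per-point standard deviations, strictly positive.
#' @return A data frame of class `saxs_curve` with columns `q`, `I` and,
#'   when given, `sigma`.
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  stopifnot(length(q) == length(I), length(q) >= 1L)
  if (any(!is.finite(q)) || any(!is.finite(I)))
    stop("q and I must be finite")
  if (any(diff(q) <= 0)) stop("q values must be strictly increasing")
  eps <- 1e-9 * max(abs(I[1L]), 1e-300)
  if (any(I < -eps)) stop("intensities must be nonnegative (beyond numerical noise)")
  out <- data.frame(q = q, I = I)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    stopifnot(length(sigma) == length(q))
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be strictly positive where present")
    out$sigma <- sigma
  }
  class(out) <- c("saxs_curve", "data.frame")
  out
}

#' Write a scattering curve as 3-column ASCII
#'
#' Writes whitespace-separated `q I sigma` (or `q I` when no sigma is
#' present) with a one-line comment header, the layout used by ATSAS-style
#' `.dat` files.
#'
#' @param curve A `saxs_curve`.
#' @param path Output file path.
#' @param comment Header text placed after the leading `#`.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path, comment = "cgsaxs scattering curve: q I sigma") {
  stopifnot(inherits(curve, "saxs_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  if (is.null(curve$sigma)) {
    writeLines(sprintf("%.6e %.6e", curve$q, curve$I), con)
  } else {
    writeLines(sprintf("%.6e %.6e %.6e", curve$q, curve$I, curve$sigma), con)
  }
  invisible(path)
}

#' Read a scattering curve from ASCII
#'
#' Reads 3-column `q I sigma` files (ATSAS `.dat` dialect); tolerant of
#' 2-column files (no sigma) and of comment/label lines, which are skipped.
#'
#' @param path Input file path.
#' @return A `saxs_curve`.
#' @export
read_dat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) return(NULL)
    parts <- strsplit(ln, "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || length(vals) < 2L) return(NULL)  # header/label line
    vals
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no numeric data rows found in ", path)
  ncol <- min(vapply(rows, length, 1L))
  mat <- do.call(rbind, lapply(rows, function(v) v[seq_len(ncol)]))
  if (ncol >= 3L && all(mat[, 3L] > 0)) {
    scattering_curve(mat[, 1L], mat[, 2L], mat[, 3L])
  } else {
    scattering_curve(mat[, 1L], mat[, 2L])
  }
}

#' Read a CRYSOL .int intensity file
#'
#' CRYSOL `.int` files carry five columns; column 1 is q and column 2 the
#' total theoretical intensity. Remaining columns are ignored.
#'
#' @param path Input file path.
#' @return A `saxs_curve` without sigma.
#' @export
read_crysol_int <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals[1:2]) || length(vals) < 2L) return(NULL)
    vals[1:2]
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no numeric data rows found in ", path)
  mat <- do.call(rbind, rows)
  scattering_curve(mat[, 1L], mat[, 2L])
}
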