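#' Spectrum objects
#'
#' A `spectrum` is the common currency of the NEXAFS and FTIR stages: an
#' ordered axis (photon energy in eV or wavenumber in cm-1) paired with an
#' intensity vector, plus free-form metadata (sample ID, edge, horizon,
#' treatment).
#'
#' @param axis numeric, strictly increasing positions (eV or cm-1).
#' @param intensity numeric, same length as `axis`; must be finite.
#' @param axis_kind `"energy_eV"` or `"wavenumber_cm1"`.
#' @param meta named list of metadata carried through transformations.
#'
#' @return An object of class `spectrum` with fields `axis`, `intensity`,
#'   `axis_kind` and `meta`.
#' @export
spectrum <- function(axis, intensity,
                     axis_kind = c("energy_eV", "wavenumber_cm1"),
                     meta = list()) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have equal length")
  }
  if (length(axis) < 16L) {
    stop("spectrum needs at least 16 grid points")
  }
  if (any(!is.finite(axis)) || any(!is.finite(intensity))) {
    stop("spectrum contains non-finite values")
  }
  if (any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing")
  }
  structure(list(axis = axis, intensity = intensity,
                 axis_kind = axis_kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %s [%.4g, %.4g]\n",
              length(x$axis), x$axis_kind, min(x$axis), max(x$axis)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Read and write two-column spectra
#'
#' Spectra are exchanged as whitespace- or comma-delimited two-column text
#' (axis, intensity); lines starting with `#` are comments. `write_spectrum`
#' records the axis kind in a comment header so a round trip preserves it.
#'
#' @param path file path.
#' @param axis_kind axis kind to assume when the file header does not name one.
#' @return `read_spectrum` returns a [spectrum]; `write_spectrum` returns
#'   `path` invisibly.
#' @export
read_spectrum <- function(path, axis_kind = NULL) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  kind_line <- grep("axis_kind:", header, value = TRUE)
  if (is.null(axis_kind)) {
    axis_kind <- if (length(kind_line)) {
      trimws(sub(".*axis_kind:", "", kind_line[1]))
    } else {
      "energy_eV"
    }
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  body <- gsub(",", " ", body)
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  spectrum(m[, 1], m[, 2], axis_kind = axis_kind,
           meta = list(source = path))
}

#' @param s a [spectrum].
#' @rdname read_spectrum
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axis_kind: %s", s$axis_kind), con)
  writeLines(sprintf("%.8g\t%.8g", s$axis, s$intensity), con)
  invisible(path)
}

# trapezoidal integral of a spectrum over an axis interval; the interval end
# points are added by linear interpolation so adjacent bands tile exactly
spectrum_area <- function(s, lo = min(s$axis), hi = max(s$axis)) {
  stopifnot(lo < hi)
  if (lo < min(s$axis) || hi > max(s$axis)) {
    stop(sprintf("interval [%g, %g] lies outside the spectrum axis", lo, hi))
  }
  inner <- s$axis > lo & s$axis < hi
  x <- c(lo, s$axis[inner], hi)
  y <- stats::approx(s$axis, s$intensity, xout = x)$y
  pracma::trapz(x, y)
}
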