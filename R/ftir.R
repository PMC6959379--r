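#' FTIR fingerprinting
#'
#' Total-area normalization, band integrals over six diagnostic vibrational
#' regions of dissolved organic matter, and covariance PCA of spectra or
#' component-abundance tables.
#'
#' @name ftir
NULL

#' Default FTIR band definitions
#'
#' Six diagnostic regions: C-O / C-O-C stretching of carbohydrates
#' (970-1150 cm-1), C-O stretching of phenolics (1150-1250), N-O stretching
#' of nitrate / N-H bending of ammonium (1380-1400), O-H bending and
#' aliphatic C-H deformation (1350-1450), C-C stretching of aromatic rings
#' (1510 cm-1, realized as 1500-1520 since the assignment is a point, not a
#' range), and C=O stretching of carbonyls (1620-1800). The nitrate band is
#' contained in the aliphatic band; overlapping bands are integrated
#' independently and must not be summed.
#'
#' @return data frame with columns `label`, `lo`, `hi` (cm-1).
#' @export
default_ftir_bands <- function() {
  data.frame(
    label = c("carbohydrate", "phenolic", "nitrate-ammonium",
              "aliphatic-OH", "aromatic", "carbonyl"),
    lo = c(970, 1150, 1380, 1350, 1500, 1620),
    hi = c(1150, 1250, 1400, 1450, 1520, 1800),
    stringsAsFactors = FALSE
  )
}

#' Normalize a spectrum to unit total area
#'
#' Divides the intensity by the trapezoidal integral over `range`, so
#' spectra of differing overall signal become comparable before band
#' integration or PCA. Idempotent and scale-invariant.
#'
#' @param s a [spectrum].
#' @param range length-2 interval within the axis; default the full axis.
#' @return the normalized [spectrum].
#' @export
area_normalize <- function(s, range = NULL) {
  stopifnot(is_spectrum(s))
  if (is.null(range)) range <- range(s$axis)
  total <- spectrum_area(s, range[1], range[2])
  if (total <= 0) stop("total area over the range is not positive")
  out <- s
  out$intensity <- s$intensity / total
  out$meta$area_normalized <- list(range = range, total = total)
  out
}

#' Band areas of a spectrum
#'
#' Trapezoidal integral over each band, with the band end points interpolated
#' onto the axis; overlapping bands are integrated independently.
#'
#' @param s a [spectrum] (normalize first with [area_normalize] when
#'   comparing samples).
#' @param bands data frame with `label`, `lo`, `hi`; default
#'   [default_ftir_bands()].
#' @return named numeric vector of areas.
#' @export
band_table <- function(s, bands = default_ftir_bands()) {
  stopifnot(is_spectrum(s))
  out <- numeric(nrow(bands))
  names(out) <- bands$label
  for (i in seq_len(nrow(bands))) {
    if (bands$lo[i] < min(s$axis) || bands$hi[i] > max(s$axis)) {
      stop(sprintf("band '%s' [%g, %g] lies outside the spectrum axis",
                   bands$label[i], bands$lo[i], bands$hi[i]))
    }
    out[i] <- spectrum_area(s, bands$lo[i], bands$hi[i])
  }
  out
}

#' PCA fingerprint of a sample x variable matrix
#'
#' Column-centered (covariance, no variance scaling) principal component
#' analysis via singular value decomposition, matching total-area-normalized
#' input where variables are already on a common scale. Sign convention: the
#' largest-magnitude loading of each component is made positive, so results
#' are deterministic. A matrix with zero total variance is flagged rather
#' than an error.
#'
#' @param X numeric matrix or data frame, samples in rows, >= 2 rows and
#'   columns, no missing values.
#' @return `pca_result` list: `scores` (sample x component), `loadings`
#'   (variable x component), `explained_variance_pct`, `center`,
#'   `zero_variance` flag.
#' @export
pca_fingerprint <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 samples and 2 variables")
  if (any(!is.finite(X))) stop("matrix contains missing or non-finite values")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  zero_variance <- total <= .Machine$double.eps
  expl <- if (zero_variance) rep(0, length(ev)) else 100 * ev / total
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance_pct = expl, center = pc$center,
                 zero_variance = zero_variance),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d variables%s\n",
              nrow(x$scores), nrow(x$loadings),
              if (x$zero_variance) " (zero variance)" else ""))
  ev <- round(x$explained_variance_pct[seq_len(min(4, length(x$explained_variance_pct)))], 1)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "...\n")
  invisible(x)
}
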