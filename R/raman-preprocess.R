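#' Pointwise average of spectra
#'
#' Averages replicate spectra (e.g. the pixels of one Raman map, or a set
#' of map averages) on a common axis.
#'
#' @param x numeric matrix with spectra in rows, or a list of equal-length
#'   numeric vectors.
#' @return numeric vector, the pointwise arithmetic mean.
#' @export
averageSpectra <- function(x) {
  if (is.list(x)) {
    len <- unique(vapply(x, length, integer(1)))
    if (length(len) != 1) stop("spectra are not on a common axis")
    x <- do.call(rbind, x)
  }
  stopifnot(is.matrix(x), nrow(x) >= 1)
  colMeans(x)
}

#' Baseline subtraction for Raman spectra
#'
#' Removes the smooth background (fluorescence, substrate) under the Raman
#' peaks. Two estimators:
#' \describe{
#'   \item{\code{als}}{asymmetric least squares: iteratively reweighted
#'     smoothing with a second-difference penalty, where points above the
#'     current baseline get weight \code{p} and points below get
#'     \code{1 - p}, so the fit hugs the lower envelope. Standard choice
#'     for broad NIR-excited biofluid backgrounds. Defaults
#'     \code{lambda = 1e5}, \code{p = 0.01}, 10 reweighting iterations.}
#'   \item{\code{poly}}{iterative polynomial fitting (default order 5):
#'     the spectrum is repeatedly clipped to the current fit from above and
#'     refit, converging to a polynomial under the peaks.}
#' }
#' Peak positions are untouched; only the estimated baseline is subtracted.
#'
#' @param intensities numeric vector, one spectrum.
#' @param wavenumbers numeric axis (needed for \code{poly}; optional for
#'   \code{als}).
#' @param method \code{"als"} (default) or \code{"poly"}.
#' @param lambda ALS smoothness penalty.
#' @param p ALS asymmetry in (0, 1).
#' @param iter number of reweighting / clipping iterations.
#' @param degree polynomial order for \code{"poly"}.
#' @return numeric vector, baseline-subtracted intensities.
#' @export
subtractBaseline <- function(intensities, wavenumbers = NULL,
                             method = c("als", "poly"),
                             lambda = 1e5, p = 0.01, iter = 10, degree = 5) {
  method <- match.arg(method)
  y <- as.numeric(intensities)
  m <- length(y)
  if (method == "als") {
    if (m < 3) stop("ALS baseline needs at least 3 points")
    y - alsBaseline(y, lambda = lambda, p = p, iter = iter)
  } else {
    if (is.null(wavenumbers)) wavenumbers <- seq_len(m)
    if (m < degree + 1) stop("fewer points than polynomial degree of freedom")
    yc <- y
    base <- y
    for (k in seq_len(iter)) {
      fit <- lm(yc ~ poly(wavenumbers, degree))
      base <- unname(fitted(fit))
      yc <- pmin(yc, base)
    }
    y - base
  }
}

# Eilers-style asymmetric least squares on a sparse banded system.
alsBaseline <- function(y, lambda = 1e5, p = 0.01, iter = 10) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (k in seq_len(iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    wNew <- ifelse(y > z, p, 1 - p)
    if (all(wNew == w) && k > 1) break
    w <- wNew
  }
  z
}

#' Standard normal variate (SNV) normalisation
#'
#' Per-spectrum normalisation: subtract the spectrum's mean and divide by
#' its standard deviation, so every spectrum has mean 0 and SD 1. Removes
#' multiplicative and additive intensity effects (focus, dried-ring
#' thickness) and is invariant under affine transforms \code{a*x + b},
#' \code{a > 0}.
#'
#' @param intensities numeric vector (one spectrum) or matrix (spectra in
#'   rows, normalised row-wise).
#' @return same shape as the input.
#' @export
snvNormalize <- function(intensities) {
  if (is.matrix(intensities))
    return(t(apply(intensities, 1, snvNormalize)))
  s <- sd(intensities)
  if (!is.finite(s) || s == 0) stop("cannot SNV-normalise a constant spectrum")
  (intensities - mean(intensities)) / s
}

#' Difference spectrum between two groups
#'
#' Pointwise mean of group A minus pointwise mean of group B (e.g. the
#' control-subtracted cancer spectrum that exposes depleted bands).
#'
#' @param groupA,groupB numeric matrices with spectra in rows (or vectors)
#'   on one common axis.
#' @return numeric vector.
#' @export
differenceSpectrum <- function(groupA, groupB) {
  a <- if (is.matrix(groupA)) colMeans(groupA) else as.numeric(groupA)
  b <- if (is.matrix(groupB)) colMeans(groupB) else as.numeric(groupB)
  if (length(a) != length(b)) stop("groups are not on a common axis")
  a - b
}

#' Interpolate spectra onto a reference wavenumber axis
#'
#' Spectra whose axis differs from the reference by less than one grid step
#' are linearly interpolated onto it; a larger mismatch is an error.
#'
#' @param wavenumbers,intensities the spectrum to align.
#' @param refAxis target axis.
#' @return numeric vector on \code{refAxis}.
#' @export
alignToAxis <- function(wavenumbers, intensities, refAxis) {
  if (length(wavenumbers) == length(refAxis) &&
      all(wavenumbers == refAxis)) return(as.numeric(intensities))
  step <- min(diff(refAxis))
  if (max(abs(range(wavenumbers) - range(refAxis))) >= step)
    stop("wavenumber axes differ by more than one grid step; cannot align")
  approx(wavenumbers, intensities, xout = refAxis, rule = 2)$y
}

#' Preprocess every spectrum of a dataset
#'
#' Applies the per-spectrum pipeline — baseline subtraction then SNV
#' normalisation — to each row of a \linkS4class{SpectralDataset}. Both
#' steps use no cross-spectrum statistics, so preprocessing cannot leak
#' information between cross-validation folds.
#'
#' @param dataset a \linkS4class{SpectralDataset}.
#' @param baseline \code{"als"}, \code{"poly"} or \code{"none"}.
#' @param snv apply SNV after baseline subtraction? Default \code{TRUE}.
#' @param ... passed to \code{\link{subtractBaseline}}.
#' @return a \linkS4class{SpectralDataset} with transformed intensities.
#' @export
preprocessSpectra <- function(dataset, baseline = c("als", "poly", "none"),
                              snv = TRUE, ...) {
  stopifnot(is(dataset, "SpectralDataset"))
  baseline <- match.arg(baseline)
  mat <- dataset@intensities
  if (baseline != "none")
    mat <- t(apply(mat, 1, subtractBaseline, wavenumbers = dataset@wavenumbers,
                   method = baseline, ...))
  if (snv) mat <- snvNormalize(mat)
  new("SpectralDataset", wavenumbers = dataset@wavenumbers,
      intensities = mat, meta = dataset@meta)
}
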