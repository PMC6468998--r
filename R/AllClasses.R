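#' @import methods
#' @importFrom stats sd median qnorm qt pnorm rnorm rpois runif aov TukeyHSD
#'   prcomp predict setNames approx lm coef pf fitted poly
#' @importFrom utils read.delim write.table packageVersion head tail
#'   modifyList
NULL

## Central S4 containers. All genomic coordinates are 0-based, half-open
## (BED dialect); window indices are 1-based inside R, 0-based on disk.

#' GenomeWindows: an ordered, disjoint tiling of a reference genome
#'
#' Windows are sorted by chromosome (in the input order of the size table)
#' and start, are non-overlapping, and jointly cover every included
#' chromosome end-to-end. They form the coordinate frame for all
#' copy-number math in the package.
#'
#' @slot chrom character, chromosome of each window.
#' @slot start,end numeric, 0-based half-open bounds.
#' @slot spanBp numeric(1), nominal window span in bp (no window is longer).
#' @slot genome character(1), free-text label of the size table used.
#' @exportClass GenomeWindows
setClass("GenomeWindows",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 spanBp = "numeric", genome = "character"))

setValidity("GenomeWindows", function(object) {
  n <- length(object@chrom)
  if (length(object@start) != n || length(object@end) != n)
    return("chrom, start and end must have equal length")
  if (n == 0L) return("empty window set")
  if (any(object@end <= object@start))
    return("every window must satisfy end > start")
  if (any(object@end - object@start > object@spanBp + 0.5))
    return("window longer than nominal spanBp")
  for (ch in unique(object@chrom)) {
    i <- which(object@chrom == ch)
    if (any(diff(i) != 1L)) return("windows of one chromosome must be contiguous rows")
    if (length(i) > 1L && any(object@start[i][-1] != object@end[i][-length(i)]))
      return(sprintf("windows on %s are not a gap-free tiling", ch))
  }
  TRUE
})

#' WindowCounts: per-window read counts for one sample
#'
#' @slot sampleId character(1).
#' @slot counts numeric, non-negative integers, one per window.
#' @slot totalReads numeric(1), equals \code{sum(counts)}.
#' @slot windowSetId character(1), identity token of the window frame.
#' @exportClass WindowCounts
setClass("WindowCounts",
  representation(sampleId = "character", counts = "numeric",
                 totalReads = "numeric", windowSetId = "character"))

setValidity("WindowCounts", function(object) {
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (!isTRUE(all.equal(sum(object@counts), object@totalReads)))
    return("totalReads must equal sum(counts)")
  TRUE
})

#' Log2RatioProfile: per-window log2 read ratios for one sample
#'
#' @slot sampleId character(1).
#' @slot ratios numeric, finite, one per window.
#' @slot pseudocount numeric(1), pseudocount used in the ratio.
#' @slot windowSetId character(1).
#' @exportClass Log2RatioProfile
setClass("Log2RatioProfile",
  representation(sampleId = "character", ratios = "numeric",
                 pseudocount = "numeric", windowSetId = "character"))

setValidity("Log2RatioProfile", function(object) {
  if (any(!is.finite(object@ratios))) return("ratios must be finite")
  TRUE
})

#' ReferencePanel: per-window null mean and SD from normal cfDNA profiles
#'
#' The null model for Z-values: per-window sample mean and standard
#' deviation of log2 ratios across a cohort of normal cfDNA samples.
#'
#' @slot nSamples numeric(1), panel size (>= 2).
#' @slot mu,sigma numeric, per-window mean and SD; sigma strictly positive
#'   after flooring.
#' @slot sigmaFloor numeric(1), lower bound applied to sigma.
#' @slot windowSetId character(1).
#' @exportClass ReferencePanel
setClass("ReferencePanel",
  representation(nSamples = "numeric", mu = "numeric", sigma = "numeric",
                 sigmaFloor = "numeric", windowSetId = "character"))

setValidity("ReferencePanel", function(object) {
  if (object@nSamples < 2) return("a reference panel needs >= 2 samples")
  if (length(object@mu) != length(object@sigma))
    return("mu and sigma must have equal length")
  if (any(object@sigma <= 0)) return("sigma must be strictly positive")
  TRUE
})

#' ZProfile: per-window Z-values of one sample against a reference panel
#'
#' @slot sampleId character(1).
#' @slot z numeric, finite, one per window.
#' @slot panelN numeric(1), size of the panel the Z-values were computed
#'   against (NA when unknown); used for finite-panel calibration of the
#'   rejection threshold in \code{\link{cniScore}}.
#' @slot windowSetId character(1).
#' @exportClass ZProfile
setClass("ZProfile",
  representation(sampleId = "character", z = "numeric", panelN = "numeric",
                 windowSetId = "character"))

setValidity("ZProfile", function(object) {
  if (any(!is.finite(object@z))) return("z values must be finite")
  TRUE
})

#' CNIResult: the copy-number instability score of one sample
#'
#' @slot sampleId character(1).
#' @slot cni numeric(1), non-negative score.
#' @slot alpha numeric(1), per-window false-positive rate.
#' @slot zCritical numeric(1), two-sided rejection threshold on |z|.
#' @slot rejected integer, 1-based indices of rejected windows.
#' @slot convention character(1), "cdf_sum" or "abs_z_sum".
#' @slot z numeric, the per-window z values scored (kept for export).
#' @exportClass CNIResult
setClass("CNIResult",
  representation(sampleId = "character", cni = "numeric", alpha = "numeric",
                 zCritical = "numeric", rejected = "integer",
                 convention = "character", z = "numeric"))

setValidity("CNIResult", function(object) {
  if (object@cni < 0) return("cni must be non-negative")
  if ((object@cni == 0) != (length(object@rejected) == 0L))
    return("cni must be zero exactly when no window is rejected")
  if (length(object@rejected) &&
      any(abs(object@z[object@rejected]) <= object@zCritical))
    return("every rejected window must satisfy |z| > zCritical")
  TRUE
})

#' TissueCNProfile: median-normalised log2 profile with gain/loss flags
#'
#' @slot sampleId character(1).
#' @slot log2VsMedian numeric, per-window log2(count / median count);
#'   -Inf is possible for zero-count windows and flags as loss.
#' @slot gain,loss logical, per-window flags.
#' @slot threshold numeric(1), symmetric log2 flag threshold.
#' @exportClass TissueCNProfile
setClass("TissueCNProfile",
  representation(sampleId = "character", log2VsMedian = "numeric",
                 gain = "logical", loss = "logical", threshold = "numeric"))

setValidity("TissueCNProfile", function(object) {
  if (!identical(object@gain, object@log2VsMedian > object@threshold))
    return("gain flags must equal log2VsMedian > threshold")
  if (!identical(object@loss, object@log2VsMedian < -object@threshold))
    return("loss flags must equal log2VsMedian < -threshold")
  if (any(object@gain & object@loss)) return("a window cannot be both gain and loss")
  TRUE
})

#' SpectralDataset: hierarchical Raman spectra on a common wavenumber axis
#'
#' One row of \code{intensities} is one map-average spectrum. The metadata
#' records the participant / drop / map hierarchy and the class label.
#'
#' @slot wavenumbers numeric, strictly increasing axis in cm^-1.
#' @slot intensities numeric matrix, spectra in rows.
#' @slot meta data.frame with columns participant, class ("cancer" or
#'   "control"), drop, map; one row per spectrum.
#' @exportClass SpectralDataset
setClass("SpectralDataset",
  representation(wavenumbers = "numeric", intensities = "matrix",
                 meta = "data.frame"))

setValidity("SpectralDataset", function(object) {
  if (length(object@wavenumbers) < 2) return("axis needs >= 2 points")
  if (any(diff(object@wavenumbers) <= 0))
    return("wavenumbers must be strictly increasing")
  if (ncol(object@intensities) != length(object@wavenumbers))
    return("intensity columns must match the wavenumber axis")
  if (nrow(object@meta) != nrow(object@intensities))
    return("meta must have one row per spectrum")
  need <- c("participant", "class", "drop", "map")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must contain columns:", paste(need, collapse = ", ")))
  if (!all(object@meta$class %in% c("cancer", "control")))
    return("class labels must be 'cancer' or 'control'")
  TRUE
})

#' ClassifierResult: cross-validated PCA-LDA classification summary
#'
#' @slot predictions data.frame, one row per scored spectrum: participant,
#'   class (truth), drop, map, fold, predicted, score.
#' @slot confusion 2x2 integer matrix, rows = truth, cols = prediction.
#' @slot sensitivity,specificity numeric(1), cancer = positive class.
#' @slot nFolds numeric(1), one fold per participant.
#' @slot pcCounts numeric, PCs retained in each completed fold.
#' @slot skippedFolds character, participants whose fold was skipped.
#' @exportClass ClassifierResult
setClass("ClassifierResult",
  representation(predictions = "data.frame", confusion = "matrix",
                 sensitivity = "numeric", specificity = "numeric",
                 nFolds = "numeric", pcCounts = "numeric",
                 skippedFolds = "character"))

setValidity("ClassifierResult", function(object) {
  if (sum(object@confusion) != nrow(object@predictions))
    return("confusion total must equal the number of scored spectra")
  for (v in c(object@sensitivity, object@specificity))
    if (!is.na(v) && (v < 0 || v > 1)) return("rates must lie in [0, 1]")
  TRUE
})

## -- show methods --------------------------------------------------------

setMethod("show", "GenomeWindows", function(object) {
  cat(sprintf("GenomeWindows: %d windows on %d chromosomes (%s), span <= %.0f bp\n",
              length(object@chrom), length(unique(object@chrom)),
              object@genome, object@spanBp))
})

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d samples x %d windows (sigma floor %g)\n",
              object@nSamples, length(object@mu), object@sigmaFloor))
})

setMethod("show", "CNIResult", function(object) {
  cat(sprintf("CNIResult [%s]: CNI = %.4f (%s), %d/%d windows rejected at |z| > %.4f (alpha = %g)\n",
              object@sampleId, object@cni, object@convention,
              length(object@rejected), length(object@z),
              object@zCritical, object@alpha))
})

setMethod("show", "SpectralDataset", function(object) {
  tab <- table(object@meta$class)
  cat(sprintf("SpectralDataset: %d spectra (%s) x %d wavenumbers [%.0f..%.0f cm^-1], %d participants\n",
              nrow(object@intensities),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(object@wavenumbers), min(object@wavenumbers),
              max(object@wavenumbers), length(unique(object@meta$participant))))
})

setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf("ClassifierResult: %d folds, sensitivity %.3f, specificity %.3f\n",
              object@nFolds, object@sensitivity, object@specificity))
  print(object@confusion)
})

## -- accessors -----------------------------------------------------------

#' Number of windows in a window frame
#' @param x a GenomeWindows object.
#' @return integer(1).
#' @export
nWindows <- function(x) {
  stopifnot(is(x, "GenomeWindows"))
  length(x@chrom)
}

#' Window lengths in bp
#' @param x a GenomeWindows object.
#' @return numeric vector of window lengths.
#' @export
windowLengths <- function(x) {
  stopifnot(is(x, "GenomeWindows"))
  x@end - x@start
}

#' Identity token of a window frame
#'
#' Objects derived from a window frame carry this token so that mismatched
#' frames are rejected instead of silently recycled.
#' @param x a GenomeWindows object.
#' @return character(1).
#' @export
windowSetId <- function(x) {
  stopifnot(is(x, "GenomeWindows"))
  sprintf("%d:%0.0f:%s", length(x@chrom), sum(x@end - x@start),
          paste(unique(x@chrom), collapse = ","))
}

#' Per-window counts of a WindowCounts object
#' @param x a WindowCounts object.
#' @return numeric vector.
#' @export
windowCounts <- function(x) { stopifnot(is(x, "WindowCounts")); x@counts }

#' Log2 ratios of a Log2RatioProfile
#' @param x a Log2RatioProfile.
#' @return numeric vector.
#' @export
log2Ratios <- function(x) { stopifnot(is(x, "Log2RatioProfile")); x@ratios }

#' Z-values of a ZProfile
#' @param x a ZProfile.
#' @return numeric vector.
#' @export
zValues <- function(x) { stopifnot(is(x, "ZProfile")); x@z }

#' The CNI score of a CNIResult
#' @param x a CNIResult.
#' @return numeric(1).
#' @export
cniValue <- function(x) { stopifnot(is(x, "CNIResult")); x@cni }

#' Indices of rejected windows of a CNIResult
#' @param x a CNIResult.
#' @return integer vector (1-based).
#' @export
rejectedWindows <- function(x) { stopifnot(is(x, "CNIResult")); x@rejected }

#' Wavenumber axis of a SpectralDataset
#' @param x a SpectralDataset.
#' @return numeric vector in cm^-1.
#' @export
wavenumbers <- function(x) { stopifnot(is(x, "SpectralDataset")); x@wavenumbers }

#' Intensity matrix of a SpectralDataset (spectra in rows)
#' @param x a SpectralDataset.
#' @return numeric matrix.
#' @export
intensities <- function(x) { stopifnot(is(x, "SpectralDataset")); x@intensities }

#' Spectrum metadata of a SpectralDataset
#' @param x a SpectralDataset.
#' @return data.frame with participant, class, drop, map.
#' @export
spectraMeta <- function(x) { stopifnot(is(x, "SpectralDataset")); x@meta }

#' Coerce a GenomeWindows frame to GRanges
#'
#' Converts the package's 0-based half-open windows to the 1-based closed
#' convention of \linkS4class{GRanges}.
#' @param x a GenomeWindows object.
#' @return a \code{GRanges} with a \code{windowIndex} metadata column.
#' @export
windowsAsGRanges <- function(x) {
  stopifnot(is(x, "GenomeWindows"))
  GenomicRanges::GRanges(
    seqnames = x@chrom,
    ranges = IRanges::IRanges(start = x@start + 1, end = x@end),
    windowIndex = seq_along(x@chrom))
}
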