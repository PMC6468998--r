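#' Log2 read-ratio profile of one sample
#'
#' Transforms binned read counts into per-window log2 ratios of observed
#' over expected counts, where the expectation is proportional to window
#' length: \code{expected_w = totalReads * len_w / total_bp}. A pseudocount
#' (default 0.5) keeps zero-count windows finite.
#'
#' @param counts a \linkS4class{WindowCounts} object.
#' @param windows the \linkS4class{GenomeWindows} frame the counts live on.
#' @param pseudocount numeric(1) added to both numerator and denominator.
#' @return a \linkS4class{Log2RatioProfile}.
#' @export
log2RatioProfile <- function(counts, windows, pseudocount = 0.5) {
  stopifnot(is(counts, "WindowCounts"), is(windows, "GenomeWindows"))
  checkWindowSet(counts@windowSetId, windowSetId(windows))
  if (counts@totalReads <= 0) stop("totalReads must be positive")
  len <- windowLengths(windows)
  expected <- counts@totalReads * len / sum(len)
  r <- log2((counts@counts + pseudocount) / (expected + pseudocount))
  if (any(!is.finite(r)))
    stop("non-finite log2 ratio; use a positive pseudocount for zero-count windows")
  new("Log2RatioProfile", sampleId = counts@sampleId, ratios = r,
      pseudocount = pseudocount, windowSetId = counts@windowSetId)
}

#' Build a reference panel from normal cfDNA log2-ratio profiles
#'
#' Computes the per-window sample mean and standard deviation across a
#' cohort of normal profiles; these are the null model that converts a new
#' sample's log2 ratios into Z-values. The SD is floored (default 1e-4) so
#' a degenerate panel cannot blow up the division.
#'
#' @param profiles list of \linkS4class{Log2RatioProfile} objects on one
#'   window frame.
#' @param sigmaFloor numeric(1), lower bound on the per-window SD.
#' @return a \linkS4class{ReferencePanel}.
#' @export
buildReference <- function(profiles, sigmaFloor = 1e-4) {
  stopifnot(is.list(profiles), length(profiles) >= 2,
            all(vapply(profiles, is, logical(1), "Log2RatioProfile")))
  wsid <- profiles[[1]]@windowSetId
  for (p in profiles) checkWindowSet(p@windowSetId, wsid)
  mat <- vapply(profiles, log2Ratios, numeric(length(profiles[[1]]@ratios)))
  mu <- rowMeans(mat)
  sigma <- pmax(apply(mat, 1, sd), sigmaFloor)
  new("ReferencePanel", nSamples = length(profiles), mu = mu, sigma = sigma,
      sigmaFloor = sigmaFloor, windowSetId = wsid)
}

#' Z-value profile of a sample against a reference panel
#'
#' \code{z_w = (ratio_w - mu_w) / sigma_w}. The panel size is carried along
#' so that downstream scoring can calibrate its rejection threshold for the
#' finite panel.
#'
#' @param profile a \linkS4class{Log2RatioProfile}.
#' @param panel a \linkS4class{ReferencePanel} on the same window frame.
#' @return a \linkS4class{ZProfile}.
#' @export
zProfile <- function(profile, panel) {
  stopifnot(is(profile, "Log2RatioProfile"), is(panel, "ReferencePanel"))
  checkWindowSet(profile@windowSetId, panel@windowSetId)
  if (length(profile@ratios) != length(panel@mu))
    stop("profile and panel have different window counts")
  new("ZProfile", sampleId = profile@sampleId,
      z = (profile@ratios - panel@mu) / panel@sigma,
      panelN = panel@nSamples, windowSetId = profile@windowSetId)
}

#' Copy-number instability (CNI) score
#'
#' Windows whose Z-value rejects the null of equality to the reference at a
#' two-sided per-window false-positive rate \code{alpha} (default 0.002,
#' i.e. 0.2\%) contribute to the score. Under the default \code{cdf_sum}
#' convention the score sums the standard-normal CDF of the absolute
#' Z-values over rejected windows, \eqn{\sum_{w} \Phi(|z_w|)}; the
#' \code{abs_z_sum} convention sums \eqn{|z_w|} instead. Both reflect the
#' number and amplitude of aberrations and grow with the tumour fraction of
#' cfDNA.
#'
#' The rejection threshold is the upper \code{1 - alpha/2} quantile of the
#' null of the Z statistic. When the profile carries the reference-panel
#' size n (the default path through \code{\link{zProfile}}), that null is a
#' scaled Student-t — the panel mean and SD are estimates — and the
#' calibrated threshold \code{sqrt(1 + 1/n) * qt(1 - alpha/2, n - 1)} is
#' used so the realised per-window false-positive rate equals \code{alpha}.
#' With an unknown panel size (\code{panelN = NA}, or
#' \code{panelAdjust = FALSE}) the standard-normal quantile
#' \code{qnorm(1 - alpha/2)} is used.
#'
#' @param z a \linkS4class{ZProfile}, or a bare numeric vector of Z-values.
#' @param alpha two-sided per-window false-positive rate in (0, 1).
#' @param convention \code{"cdf_sum"} (default) or \code{"abs_z_sum"}.
#' @param panelAdjust use the finite-panel t threshold when the panel size
#'   is known? Default \code{TRUE}.
#' @return a \linkS4class{CNIResult}.
#' @examples
#' cniScore(new("ZProfile", sampleId = "s", z = c(0, 4, 0),
#'              panelN = NA_real_, windowSetId = "toy"))
#' @export
cniScore <- function(z, alpha = 0.002,
                     convention = c("cdf_sum", "abs_z_sum"),
                     panelAdjust = TRUE) {
  convention <- match.arg(convention)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (is.numeric(z))
    z <- new("ZProfile", sampleId = "z", z = as.numeric(z),
             panelN = NA_real_, windowSetId = "unspecified")
  stopifnot(is(z, "ZProfile"))
  n <- z@panelN
  zCrit <- if (panelAdjust && !is.na(n) && n >= 2)
    sqrt(1 + 1 / n) * qt(1 - alpha / 2, df = n - 1)
  else
    qnorm(1 - alpha / 2)
  rejected <- which(abs(z@z) > zCrit)
  cni <- switch(convention,
    cdf_sum   = sum(pnorm(abs(z@z[rejected]))),
    abs_z_sum = sum(abs(z@z[rejected])))
  new("CNIResult", sampleId = z@sampleId, cni = cni, alpha = alpha,
      zCritical = zCrit, rejected = as.integer(rejected),
      convention = convention, z = z@z)
}

#' Median-normalised tissue copy-number profile with gain/loss calls
#'
#' Per-window read counts are normalised to the median count over all
#' windows; ratios are reported as log2 values, and windows with log2 above
#' \code{threshold} (default 0.15) are flagged as gains, below
#' \code{-threshold} as losses. Zero-count windows give \code{-Inf} and
#' flag as losses.
#'
#' @param counts a \linkS4class{WindowCounts} object.
#' @param threshold symmetric log2 flag threshold (default 0.15).
#' @return a \linkS4class{TissueCNProfile}.
#' @export
tissueProfile <- function(counts, threshold = 0.15) {
  stopifnot(is(counts, "WindowCounts"), threshold > 0)
  if (counts@totalReads <= 0) stop("totalReads must be positive")
  med <- median(counts@counts)
  if (med <= 0) stop("median window count must be positive")
  l2 <- log2(counts@counts / med)
  new("TissueCNProfile", sampleId = counts@sampleId, log2VsMedian = l2,
      gain = l2 > threshold, loss = l2 < -threshold, threshold = threshold)
}

#' Per-window annotated copy-number table
#'
#' Flattens a \linkS4class{CNIResult} or \linkS4class{TissueCNProfile} onto
#' its window frame: one row per window with chrom, start, end, value and
#' flag. For a CNIResult the value is the window Z and the flag is
#' \code{"rejected"} or \code{""}; for a tissue profile the value is the
#' median-normalised log2 and the flag is \code{"gain"}, \code{"loss"} or
#' \code{""}. The table round-trips losslessly through
#' \code{\link{writeCnTable}} / \code{\link{readCnTable}}.
#'
#' @param result a \linkS4class{CNIResult} or \linkS4class{TissueCNProfile}.
#' @param windows the matching \linkS4class{GenomeWindows} frame.
#' @return data.frame with columns chrom, start, end, value, flag.
#' @export
exportCnTable <- function(result, windows) {
  stopifnot(is(windows, "GenomeWindows"))
  nw <- nWindows(windows)
  if (is(result, "CNIResult")) {
    if (length(result@z) != nw) stop("result and windows have different sizes")
    value <- result@z
    flag <- rep("", nw)
    flag[result@rejected] <- "rejected"
  } else if (is(result, "TissueCNProfile")) {
    if (length(result@log2VsMedian) != nw)
      stop("result and windows have different sizes")
    value <- result@log2VsMedian
    flag <- rep("", nw)
    flag[result@gain] <- "gain"
    flag[result@loss] <- "loss"
  } else stop("result must be a CNIResult or TissueCNProfile")
  data.frame(chrom = windows@chrom, start = windows@start, end = windows@end,
             value = value, flag = flag, stringsAsFactors = FALSE)
}

#' Linear genome plot of a per-window copy-number table
#'
#' A simple whole-genome scatter of per-window values against cumulative
#' genomic position, with gains/rejections in red and losses in purple —
#' a linear stand-in for a circular genome plot.
#'
#' @param cnTable data.frame from \code{\link{exportCnTable}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the cumulative midpoints used as x coordinates.
#' @export
plotGenomeProfile <- function(cnTable, ...) {
  stopifnot(all(c("chrom", "start", "end", "value", "flag") %in% names(cnTable)))
  chroms <- unique(cnTable$chrom)
  offset <- setNames(cumsum(c(0, head(
    vapply(chroms, function(ch) max(cnTable$end[cnTable$chrom == ch]),
           numeric(1)), -1))), chroms)
  x <- offset[cnTable$chrom] + (cnTable$start + cnTable$end) / 2
  col <- ifelse(cnTable$flag %in% c("gain", "rejected"), "red3",
                ifelse(cnTable$flag == "loss", "purple3", "grey40"))
  v <- cnTable$value
  v[!is.finite(v)] <- min(v[is.finite(v)], 0)
  graphics::plot(x, v, col = col, pch = 20, xaxt = "n",
                 xlab = "genome position", ylab = "value", ...)
  graphics::abline(v = offset[-1], col = "grey85")
  invisible(x)
}

checkWindowSet <- function(a, b) {
  if (!identical(a, b))
    stop(sprintf("window-set mismatch: '%s' vs '%s'", a, b))
  invisible(TRUE)
}
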