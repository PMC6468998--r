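#' Partition a genome into equal-sized windows
#'
#' Tiles every included chromosome with ordered, disjoint windows that cover
#' it end-to-end. Two modes:
#' \describe{
#'   \item{\code{nWindows}}{the total window count is authoritative (default
#'     701, the genome-wide binning used for shallow-WGS copy-number
#'     instability scoring). Windows are allocated to chromosomes
#'     proportionally to length by the largest-remainder rule (every
#'     chromosome gets at least one), then each chromosome is tiled with
#'     near-equal integer windows, so exactly \code{nWindows} windows are
#'     emitted and their lengths sum to the included genome length.}
#'   \item{\code{spanBp}}{fixed window span; the last window of each
#'     chromosome may be shorter.}
#' }
#' Sex chromosomes (chrX/chrY, X/Y) are excluded by default because
#' mixed-sex reference panels make their read ratios bimodal;
#' mitochondrial contigs (chrM/MT) are always excluded.
#'
#' @param chromSizes data.frame with columns \code{chrom} and \code{length}
#'   (bp), or a path readable by \code{\link{readChromSizes}}.
#' @param nWindows total number of windows (exactly this many are emitted).
#'   Give exactly one of \code{nWindows} / \code{spanBp}.
#' @param spanBp fixed window span in bp.
#' @param includeSex keep chrX/chrY? Default \code{FALSE}.
#' @return a \linkS4class{GenomeWindows} object.
#' @examples
#' sizes <- data.frame(chrom = "chr1", length = 100)
#' partitionGenome(sizes, spanBp = 10)
#' @export
partitionGenome <- function(chromSizes, nWindows = 701, spanBp = NULL,
                            includeSex = FALSE) {
  if (is.character(chromSizes)) chromSizes <- readChromSizes(chromSizes)
  stopifnot(is.data.frame(chromSizes),
            all(c("chrom", "length") %in% names(chromSizes)))
  if (!is.null(spanBp)) {
    if (!missing(nWindows)) stop("give exactly one of nWindows / spanBp")
    nWindows <- NULL
  }
  if (is.null(nWindows) && is.null(spanBp))
    stop("give exactly one of nWindows / spanBp")

  sizes <- chromSizes[!(chromSizes$chrom %in% c("chrM", "MT", "chrMT")), ,
                      drop = FALSE]
  if (!includeSex)
    sizes <- sizes[!(sizes$chrom %in% c("chrX", "chrY", "X", "Y")), ,
                   drop = FALSE]
  if (nrow(sizes) == 0L) stop("empty chromosome size table")
  if (any(sizes$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(sizes$chrom)) stop("duplicated chromosome in size table")
  lens <- as.numeric(sizes$length)
  total <- sum(lens)

  if (!is.null(spanBp)) {
    if (spanBp <= 0) stop("spanBp must be positive")
    if (spanBp > max(lens))
      stop(sprintf("spanBp (%g) exceeds the longest chromosome (%g bp)",
                   spanBp, max(lens)))
    perChrom <- lapply(seq_len(nrow(sizes)), function(i) {
      starts <- seq(0, lens[i] - 1, by = spanBp)
      data.frame(chrom = sizes$chrom[i], start = starts,
                 end = pmin(starts + spanBp, lens[i]))
    })
    span <- spanBp
  } else {
    if (nWindows < nrow(sizes))
      stop("nWindows must be at least the number of chromosomes")
    nPer <- largestRemainder(lens, nWindows)
    perChrom <- lapply(seq_len(nrow(sizes)), function(i) {
      # integer boundaries floor(len * k / n): near-equal, exact coverage
      b <- floor(lens[i] * (0:nPer[i]) / nPer[i])
      data.frame(chrom = sizes$chrom[i], start = b[-length(b)], end = b[-1])
    })
    span <- max(unlist(lapply(perChrom, function(d) d$end - d$start)))
  }

  tab <- do.call(rbind, perChrom)
  new("GenomeWindows", chrom = as.character(tab$chrom), start = tab$start,
      end = tab$end, spanBp = span,
      genome = paste(sizes$chrom, collapse = ","))
}

# Hamilton apportionment: integer allocation proportional to weights,
# each unit >= 1, summing exactly to n.
largestRemainder <- function(weights, n) {
  m <- length(weights)
  quota <- weights / sum(weights) * (n - m) # reserve 1 per chromosome
  base <- floor(quota)
  left <- (n - m) - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base + 1L)
}

#' Bin aligned fragments into genome windows by midpoint
#'
#' Each fragment is assigned to exactly one window: the window containing
#' its midpoint (\code{floor((start + end) / 2)}; for point input the given
#' position). Fragments on chromosomes absent from the window frame, and
#' malformed intervals with \code{end <= start}, are skipped and counted in
#' a message.
#'
#' @param windows a \linkS4class{GenomeWindows} frame.
#' @param fragments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), or \code{chrom}, \code{pos} midpoints.
#' @param sampleId sample identifier stored in the result.
#' @return a \linkS4class{WindowCounts} object.
#' @export
countReads <- function(windows, fragments, sampleId = "sample") {
  stopifnot(is(windows, "GenomeWindows"), is.data.frame(fragments))
  if (all(c("start", "end") %in% names(fragments))) {
    bad <- fragments$end <= fragments$start
    if (any(bad)) {
      message(sprintf("countReads: skipped %d malformed intervals (end <= start)",
                      sum(bad)))
      fragments <- fragments[!bad, , drop = FALSE]
    }
    mid <- floor((fragments$start + fragments$end) / 2)
  } else if ("pos" %in% names(fragments)) {
    mid <- fragments$pos
  } else stop("fragments need columns chrom,start,end or chrom,pos")

  chrom <- as.character(fragments$chrom)
  counts <- numeric(length(windows@chrom))
  offRef <- 0L
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    wi <- which(windows@chrom == ch)
    if (!length(wi)) { offRef <- offRef + sum(sel); next }
    m <- mid[sel]
    inside <- m >= windows@start[wi[1]] & m < windows@end[wi[length(wi)]]
    offRef <- offRef + sum(!inside)
    idx <- findInterval(m[inside], windows@start[wi])
    tab <- tabulate(idx, nbins = length(wi))
    counts[wi] <- counts[wi] + tab
  }
  if (offRef > 0)
    message(sprintf("countReads: skipped %d fragments outside the window frame",
                    offRef))
  new("WindowCounts", sampleId = sampleId, counts = counts,
      totalReads = sum(counts), windowSetId = windowSetId(windows))
}
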