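# Small in-code fixtures shared across test files.

hg19Sizes <- function() {
  readChromSizes(system.file("extdata", "hg19.chrom.sizes",
                             package = "liquidlens"))
}

hg19Windows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- partitionGenome(hg19Sizes())
    cache
  }
})

# a tiny two-chromosome frame for unit tests
toyWindows <- function() {
  partitionGenome(data.frame(chrom = c("c1", "c2"), length = c(100, 60)),
                  spanBp = 20)
}

toyCounts <- function(counts, windows = toyWindows(), id = "toy") {
  new("WindowCounts", sampleId = id, counts = as.numeric(counts),
      totalReads = sum(counts), windowSetId = windowSetId(windows))
}

toyProfile <- function(ratios, windows = toyWindows(), id = "toy") {
  new("Log2RatioProfile", sampleId = id, ratios = as.numeric(ratios),
      pseudocount = 0.5, windowSetId = windowSetId(windows))
}

# gaussian peak on an axis
gaussPeak <- function(axis, centre, amp, width) {
  amp * exp(-((axis - centre)^2) / (2 * width^2))
}

# swap in a new metadata data.frame (e.g. permuted labels)
withMeta <- function(dataset, meta) {
  new("SpectralDataset", wavenumbers = wavenumbers(dataset),
      intensities = intensities(dataset), meta = meta)
}
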