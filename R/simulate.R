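## Seeded synthetic-data generators. Each emulates the statistical
## structure of one assay of the multi-analyte liquid biopsy and returns
## ground truth alongside the data. All are pure functions of
## (parameters, seed): the same seed reproduces the same object.

#' Simulate binned shallow-WGS cfDNA read counts with a reference panel
#'
#' Per-window expected rates are proportional to window length, modulated
#' by a per-sample lognormal window effect (SD \code{windowNoiseSd} in log2
#' units, the inter-sample biological/technical noise) and, in aberrant
#' windows of the test samples, by the copy-ratio mixture
#' \code{1 + tumourFraction * (copyRatio - 1)}. Counts are Poisson at the
#' requested depth. Panel samples never carry aberrations.
#'
#' Defaults mirror the study design scaled to desk size: a 133-sample
#' normal panel over 701 genome-wide windows; depth defaults to 1e6 reads
#' (the study's ~30e6 is available by argument).
#'
#' @param windows a \linkS4class{GenomeWindows} frame; default: the
#'   packaged hg19 autosomes partitioned into 701 windows.
#' @param panelN reference-panel size (default 133).
#' @param nSamples number of test samples to draw (default 1).
#' @param depthReads sequencing depth per sample (default 1e6).
#' @param windowNoiseSd inter-sample per-window noise SD, log2 scale
#'   (default 0.05).
#' @param aberrations data.frame with columns \code{firstWindow},
#'   \code{lastWindow} (1-based, inclusive), \code{copyRatio}; or NULL.
#' @param tumourFraction tumour fraction of cfDNA in [0, 1].
#' @param seed integer seed.
#' @return list with \code{windows}, \code{panel} (list of
#'   \linkS4class{WindowCounts}), \code{samples} (list of
#'   \linkS4class{WindowCounts}) and \code{truth} (aberrations, tumour
#'   fraction, per-window multiplier).
#' @export
simCfdna <- function(windows = NULL, panelN = 133, nSamples = 1,
                     depthReads = 1e6, windowNoiseSd = 0.05,
                     aberrations = NULL, tumourFraction = 0, seed = 1) {
  if (is.null(windows)) windows <- defaultHg19Windows()
  stopifnot(is(windows, "GenomeWindows"),
            tumourFraction >= 0, tumourFraction <= 1, depthReads > 0)
  set.seed(seed)
  len <- windowLengths(windows)
  nw <- length(len)
  baseRate <- depthReads * len / sum(len)
  mult <- aberrationMultiplier(nw, aberrations, tumourFraction)

  drawSample <- function(id, m) {
    eff <- 2^rnorm(nw, 0, windowNoiseSd)
    counts <- rpois(nw, baseRate * eff * m)
    new("WindowCounts", sampleId = id, counts = as.numeric(counts),
        totalReads = sum(counts), windowSetId = windowSetId(windows))
  }
  panel <- lapply(seq_len(panelN), function(i)
    drawSample(sprintf("panel_%03d", i), rep(1, nw)))
  samples <- lapply(seq_len(nSamples), function(i)
    drawSample(sprintf("sample_%03d", i), mult))
  list(windows = windows, panel = panel, samples = samples,
       truth = list(aberrations = aberrations,
                    tumourFraction = tumourFraction, multiplier = mult))
}

aberrationMultiplier <- function(nw, aberrations, tumourFraction) {
  mult <- rep(1, nw)
  if (!is.null(aberrations) && nrow(aberrations)) {
    stopifnot(all(c("firstWindow", "lastWindow", "copyRatio") %in%
                  names(aberrations)))
    if (any(aberrations$copyRatio <= 0)) stop("copyRatio must be positive")
    for (i in seq_len(nrow(aberrations))) {
      idx <- aberrations$firstWindow[i]:aberrations$lastWindow[i]
      if (any(idx < 1 | idx > nw)) stop("aberration outside the window frame")
      mult[idx] <- mult[idx] *
        (1 + tumourFraction * (aberrations$copyRatio[i] - 1))
    }
  }
  mult
}

#' Noise-free expectation log2-ratio profile of a simulated sample
#'
#' The log2-ratio profile a sample would have if its counts sat exactly at
#' their expectation: \code{log2(m_w / T)} where \code{m_w} is the
#' copy-ratio mixture multiplier and \code{T} renormalises for the change
#' in total depth. With no aberration (or tumour fraction 0) this is the
#' zero profile.
#'
#' @param windows a \linkS4class{GenomeWindows} frame.
#' @param aberrations,tumourFraction as in \code{\link{simCfdna}}.
#' @param sampleId identifier for the returned profile.
#' @return a \linkS4class{Log2RatioProfile} (pseudocount 0).
#' @export
cfdnaExpectedProfile <- function(windows, aberrations = NULL,
                                 tumourFraction = 0,
                                 sampleId = "expectation") {
  stopifnot(is(windows, "GenomeWindows"))
  len <- windowLengths(windows)
  mult <- aberrationMultiplier(length(len), aberrations, tumourFraction)
  total <- sum(len * mult) / sum(len)
  new("Log2RatioProfile", sampleId = sampleId,
      ratios = log2(mult / total), pseudocount = 0,
      windowSetId = windowSetId(windows))
}

defaultHg19Windows <- function(nWindows = 701) {
  partitionGenome(readChromSizes(system.file("extdata", "hg19.chrom.sizes",
                                             package = "liquidlens")),
                  nWindows = nWindows)
}

#' Simulate a hierarchical plasma Raman dataset
#'
#' Emulates drop-coated-deposition plasma spectra: a smooth fluorescence
#' baseline, a fixed set of biological Raman peaks, and three carotenoid
#' bands whose amplitude is depleted in the cancer class by a fractional
#' effect. The hierarchy follows the study design — by default 20 cancer
#' and 10 control participants, 3 drops each, 2 map-average spectra per
#' drop (120 + 60 spectra). Each participant carries a shared lognormal
#' carotenoid-amplitude factor (SD \code{participantSd} on the log scale)
#' and independent lognormal jitter on every other peak; each spectrum has
#' its own global intensity scale (focus/ring-thickness variation, removed
#' by SNV) plus white noise.
#'
#' The band centres 1008/1158/1524 cm^-1 are canonical carotenoid Raman
#' bands adopted as fixture constants.
#'
#' @param nCancer,nControl participants per class (defaults 20 / 10).
#' @param drops drops per participant (default 3).
#' @param maps map-average spectra per drop (default 2).
#' @param axis wavenumber grid in cm^-1 (default 600..1800 step 2).
#' @param bandCentres,bandAmps,bandWidth carotenoid band parameters.
#' @param depletionEffect fractional carotenoid amplitude loss in the
#'   cancer class, in [0, 1] (default 0.3).
#' @param participantSd log-scale SD of the per-participant carotenoid
#'   factor (default 0.08).
#' @param peakJitterSd log-scale SD of per-participant non-carotenoid peak
#'   amplitudes (default 0.05).
#' @param mapNoiseSd additive white-noise SD per spectrum (default 0.01).
#' @param scaleSd log-scale SD of the per-spectrum global intensity scale
#'   (default 0.15).
#' @param baselineAmp amplitude of the fluorescence baseline (default 5).
#' @param seed integer seed.
#' @return a \linkS4class{SpectralDataset}; the class column of its
#'   metadata is the ground truth.
#' @export
simRaman <- function(nCancer = 20, nControl = 10, drops = 3, maps = 2,
                     axis = seq(600, 1800, by = 2),
                     bandCentres = c(1008, 1158, 1524),
                     bandAmps = c(0.8, 0.6, 1.0), bandWidth = 10,
                     depletionEffect = 0.3, participantSd = 0.08,
                     peakJitterSd = 0.05, mapNoiseSd = 0.01,
                     scaleSd = 0.15, baselineAmp = 5, seed = 1) {
  stopifnot(depletionEffect >= 0, depletionEffect <= 1,
            length(bandCentres) == length(bandAmps))
  set.seed(seed)
  gauss <- function(c0, a, w) a * exp(-((axis - c0)^2) / (2 * w^2))
  # fixed biological peaks: phenylalanine, amide III, CH2, amide I, ...
  peakC <- c(853, 937, 1003, 1254, 1317, 1448, 1660)
  peakA <- c(0.25, 0.20, 0.50, 0.30, 0.25, 0.45, 0.60)
  peakW <- c(9, 10, 6, 14, 10, 12, 16)
  baseline <- baselineAmp * exp(-(axis - min(axis)) / 500) + 1.5

  classes <- c(rep("cancer", nCancer), rep("control", nControl))
  ids <- c(sprintf("LC%02d", seq_len(nCancer)),
           sprintf("CT%02d", seq_len(nControl)))
  nSpec <- (nCancer + nControl) * drops * maps
  mat <- matrix(0, nSpec, length(axis))
  meta <- data.frame(participant = character(nSpec), class = character(nSpec),
                     drop = integer(nSpec), map = integer(nSpec),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_along(ids)) {
    carotFactor <- exp(rnorm(1, 0, participantSd)) *
      (if (classes[i] == "cancer") 1 - depletionEffect else 1)
    jitter <- exp(rnorm(length(peakC), 0, peakJitterSd))
    fixedPart <- baseline + Reduce(`+`, lapply(seq_along(peakC), function(k)
      gauss(peakC[k], peakA[k] * jitter[k], peakW[k])))
    carotPart <- Reduce(`+`, lapply(seq_along(bandCentres), function(k)
      gauss(bandCentres[k], bandAmps[k], bandWidth)))
    for (d in seq_len(drops)) for (m in seq_len(maps)) {
      row <- row + 1L
      scale <- exp(rnorm(1, 0, scaleSd))
      mat[row, ] <- scale * (fixedPart + carotFactor * carotPart) +
        rnorm(length(axis), 0, mapNoiseSd)
      meta$participant[row] <- ids[i]
      meta$class[row] <- classes[i]
      meta$drop[row] <- d
      meta$map[row] <- m
    }
  }
  new("SpectralDataset", wavenumbers = axis, intensities = mat, meta = meta)
}

#' Simulate an imaging flow-cytometry event table with planted CTCs
#'
#' Planted CTC rows are drawn from an epithelial population (bright AF488,
#' dim CD45, bright DRAQ5, large area); the background from a leukocyte
#' population (dim AF488, bright CD45, bright DRAQ5, small area). Under the
#' default population parameters and \code{\link{defaultGates}} the two
#' populations are separated by well over 4 SDs on every gated channel.
#' Rows are shuffled; ground-truth flags are returned alongside.
#'
#' @param nCaptured total events (default 10000).
#' @param nPlanted planted CTC count (default 7).
#' @param ctc,background lists of channel means/SDs: \code{af488},
#'   \code{cd45}, \code{draq5}, \code{area} each \code{c(mean, sd)}.
#' @param seed integer seed.
#' @return list with \code{events} (data.frame: event_id, i_af488, i_cd45,
#'   i_draq5, area_px) and \code{truth} (logical planted-CTC flags).
#' @export
simEvents <- function(nCaptured = 10000, nPlanted = 7,
                      ctc = list(af488 = c(800, 50), cd45 = c(40, 15),
                                 draq5 = c(600, 50), area = c(1400, 250)),
                      background = list(af488 = c(60, 20), cd45 = c(600, 60),
                                        draq5 = c(550, 60), area = c(350, 80)),
                      seed = 1) {
  stopifnot(nPlanted <= nCaptured, nPlanted >= 0)
  set.seed(seed)
  drawPop <- function(n, p) data.frame(
    i_af488 = pmax(0, rnorm(n, p$af488[1], p$af488[2])),
    i_cd45 = pmax(0, rnorm(n, p$cd45[1], p$cd45[2])),
    i_draq5 = pmax(0, rnorm(n, p$draq5[1], p$draq5[2])),
    area_px = round(pmax(1, rnorm(n, p$area[1], p$area[2]))))
  tab <- rbind(drawPop(nPlanted, ctc), drawPop(nCaptured - nPlanted, background))
  truth <- c(rep(TRUE, nPlanted), rep(FALSE, nCaptured - nPlanted))
  ord <- sample.int(nCaptured)
  tab <- tab[ord, , drop = FALSE]
  truth <- truth[ord]
  tab <- cbind(event_id = sprintf("e%06d", seq_len(nCaptured)), tab)
  rownames(tab) <- NULL
  list(events = tab, truth = truth)
}

#' Simulate blood and tissue gene-statistics tables with planted sets
#'
#' Builds Cuffdiff-style gene tables for the two compartments with planted
#' differential-expression structure matching the study's set sizes: by
#' default 356 blood DE genes and 293 tissue DE genes sharing 21 genes
#' (so 335 blood-only and 272 tissue-only), and exactly
#' \code{nSignature} (default 18) blood genes that pass every blood
#' signature gate (FPKM > 5, p < 0.05, log2FC > 2) — 16 blood-only plus 2
#' shared up-regulated genes. All other DE genes fail at least one gate
#' (down-regulated, or up-regulated below the FPKM floor), matching the
#' observation that most shared genes are down-regulated; null genes
#' satisfy none of the DE criteria.
#'
#' @param nGenes genes per compartment table (default 2000).
#' @param nSignature planted blood-signature genes (default 18).
#' @param nShared DE genes shared by both compartments (default 21).
#' @param nBloodOnly,nTissueOnly compartment-exclusive DE counts
#'   (defaults 335 / 272).
#' @param seed integer seed.
#' @return list with \code{blood}, \code{tissue} (data.frames: gene_id,
#'   fpkm_case, fpkm_control, log2fc, p, q, compartment) and \code{truth}
#'   (gene-id sets: signature, bloodDE, tissueDE, shared).
#' @export
simExpression <- function(nGenes = 2000, nSignature = 18, nShared = 21,
                          nBloodOnly = 335, nTissueOnly = 272, seed = 1) {
  stopifnot(nSignature >= 0, nShared >= 2,
            nGenes >= nBloodOnly + nShared + nTissueOnly)
  set.seed(seed)
  sharedIds <- sprintf("SH%03d", seq_len(nShared))
  bloodOnlyIds <- sprintf("BL%04d", seq_len(nBloodOnly))
  tissueOnlyIds <- sprintf("TS%04d", seq_len(nTissueOnly))
  nSigShared <- min(2, nSignature)
  sigIds <- c(bloodOnlyIds[seq_len(nSignature - nSigShared)],
              sharedIds[seq_len(nSigShared)])

  deRow <- function(id, up, highFpkm) {
    fc <- runif(1, 2.3, 5.5) * (if (up) 1 else -1)
    fpkm <- if (highFpkm) runif(1, 6, 120) else runif(1, 0.2, 4.5)
    data.frame(gene_id = id, fpkm_case = fpkm,
               fpkm_control = fpkm / 2^fc,
               log2fc = fc, p = runif(1, 1e-8, 1e-3), stringsAsFactors = FALSE)
  }
  nullRows <- function(ids) data.frame(
    gene_id = ids, fpkm_case = exp(rnorm(length(ids), 1.5, 1.2)),
    fpkm_control = exp(rnorm(length(ids), 1.5, 1.2)),
    log2fc = runif(length(ids), -1.9, 1.9),
    p = runif(length(ids), 0.06, 1), stringsAsFactors = FALSE)

  buildTable <- function(deIds, compartment) {
    rows <- lapply(deIds, function(id) {
      sig <- id %in% sigIds && compartment == "blood"
      # non-signature DE genes: mostly down-regulated; up-regulated ones
      # stay under the FPKM floor so only planted genes pass the filter
      up <- sig || runif(1) < 0.15
      deRow(id, up = up, highFpkm = sig || (!up && runif(1) < 0.7))
    })
    de <- do.call(rbind, rows)
    nNull <- nGenes - nrow(de)
    nul <- nullRows(sprintf("%s_null%04d", toupper(substr(compartment, 1, 2)),
                            seq_len(nNull)))
    tab <- rbind(de, nul)
    tab$q <- pmin(1, tab$p * nGenes / rank(tab$p))
    tab$compartment <- compartment
    tab[sample.int(nrow(tab)), , drop = FALSE]
  }
  blood <- buildTable(c(bloodOnlyIds, sharedIds), "blood")
  tissue <- buildTable(c(tissueOnlyIds, sharedIds), "tissue")
  rownames(blood) <- rownames(tissue) <- NULL
  list(blood = blood, tissue = tissue,
       truth = list(signature = sort(sigIds),
                    bloodDE = c(bloodOnlyIds, sharedIds),
                    tissueDE = c(tissueOnlyIds, sharedIds),
                    shared = sharedIds))
}
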