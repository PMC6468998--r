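## Readers and writers for the package's on-disk formats. All genomic
## files use the BED dialect: 0-based, half-open, tab-separated. Reals are
## written at 10 significant digits; integers and identifiers round-trip
## losslessly.

#' Read / write a schema-validated TSV table
#'
#' @param path file path.
#' @param required character vector of column names that must be present;
#'   a missing column produces an error naming it.
#' @param numericCols columns checked/coerced to numeric.
#' @return data.frame.
#' @export
readTsv <- function(path, required = character(0),
                    numericCols = character(0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (col in required)
    if (!col %in% names(tab))
      stop(sprintf("%s: missing required column '%s'", path, col))
  for (col in intersect(numericCols, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v) & !is.na(tab[[col]])))
      stop(sprintf("%s: column '%s' is not numeric", path, col))
    tab[[col]] <- v
  }
  tab
}

#' @rdname readTsv
#' @param tab data.frame to write.
#' @param comments character vector of comment lines (written with a
#'   leading \code{#}).
#' @export
writeTsv <- function(tab, path, comments = character(0)) {
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 10)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns chrom, length (header optional).
#' @return data.frame with columns chrom, length.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (identical(tolower(as.character(tab[1, 1])), "chrom"))
    tab <- tab[-1, , drop = FALSE]
  sizes <- data.frame(chrom = as.character(tab[[1]]),
                      length = suppressWarnings(as.numeric(tab[[2]])),
                      stringsAsFactors = FALSE)
  if (any(is.na(sizes$length))) stop("non-numeric chromosome length")
  sizes
}

#' Write / read a window frame as BED
#'
#' @param windows a \linkS4class{GenomeWindows}.
#' @param path output path.
#' @export
writeWindowsBed <- function(windows, path) {
  stopifnot(is(windows, "GenomeWindows"))
  writeTsv(data.frame(chrom = windows@chrom, start = windows@start,
                      end = windows@end), path,
           comments = sprintf("spanBp=%.0f", windows@spanBp))
}

#' Read BED intervals
#'
#' Rows with \code{end <= start} are rejected with their row number.
#' @param path BED / BED-like TSV with columns chrom, start, end.
#' @return data.frame with chrom, start, end.
#' @export
readBed <- function(path, required = c("chrom", "start", "end")) {
  tab <- readTsv(path, required = required,
                 numericCols = c("start", "end"))
  bad <- which(tab$end <= tab$start)
  if (length(bad))
    stop(sprintf("%s: end <= start at row %s", path,
                 paste(bad, collapse = ", ")))
  tab
}

#' Write / read per-window counts
#'
#' @param counts a \linkS4class{WindowCounts}.
#' @param windows the matching \linkS4class{GenomeWindows}.
#' @param path file path.
#' @export
writeWindowCounts <- function(counts, windows, path) {
  stopifnot(is(counts, "WindowCounts"), is(windows, "GenomeWindows"))
  checkWindowSet(counts@windowSetId, windowSetId(windows))
  writeTsv(data.frame(chrom = windows@chrom, start = windows@start,
                      end = windows@end, count = counts@counts),
           path, comments = sprintf("sample_id=%s", counts@sampleId))
}

#' @rdname writeWindowCounts
#' @param sampleId sample identifier for the read object.
#' @export
readWindowCounts <- function(path, windows, sampleId = NULL) {
  stopifnot(is(windows, "GenomeWindows"))
  if (is.null(sampleId)) {
    hdr <- grep("^# sample_id=", readLines(path, n = 5), value = TRUE)
    sampleId <- if (length(hdr)) sub("^# sample_id=", "", hdr[1]) else "sample"
  }
  tab <- readTsv(path, required = c("chrom", "start", "end", "count"),
                 numericCols = c("start", "end", "count"))
  if (nrow(tab) != nWindows(windows))
    stop("counts table does not match the window frame")
  new("WindowCounts", sampleId = sampleId, counts = tab$count,
      totalReads = sum(tab$count), windowSetId = windowSetId(windows))
}

#' Write / read a reference panel
#'
#' TSV with columns index (0-based), mu, sigma; the panel size and window
#' frame are kept in header comments.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param path file path.
#' @export
writeReferencePanel <- function(panel, path) {
  stopifnot(is(panel, "ReferencePanel"))
  writeTsv(data.frame(index = seq_along(panel@mu) - 1L,
                      mu = panel@mu, sigma = panel@sigma),
           path,
           comments = c(sprintf("n_samples=%d", panel@nSamples),
                        sprintf("sigma_floor=%g", panel@sigmaFloor),
                        sprintf("window_set=%s", panel@windowSetId)))
}

#' @rdname writeReferencePanel
#' @export
readReferencePanel <- function(path) {
  hdr <- grep("^# ", readLines(path, n = 10), value = TRUE)
  getv <- function(key, default) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m)) sub(sprintf("^# %s=", key), "", m[1]) else default
  }
  tab <- readTsv(path, required = c("index", "mu", "sigma"),
                 numericCols = c("index", "mu", "sigma"))
  new("ReferencePanel", nSamples = as.numeric(getv("n_samples", NA)),
      mu = tab$mu, sigma = tab$sigma,
      sigmaFloor = as.numeric(getv("sigma_floor", "1e-4")),
      windowSetId = getv("window_set", "unspecified"))
}

#' Write / read a per-window copy-number table
#'
#' @param cnTable data.frame from \code{\link{exportCnTable}}.
#' @param path file path.
#' @export
writeCnTable <- function(cnTable, path) {
  writeTsv(cnTable, path)
}

#' @rdname writeCnTable
#' @export
readCnTable <- function(path) {
  tab <- readTsv(path, required = c("chrom", "start", "end", "value", "flag"),
                 numericCols = c("start", "end", "value"))
  tab$flag[is.na(tab$flag)] <- ""
  tab
}

#' Read one spectrum file
#'
#' Two-column whitespace- or comma-separated (wavenumber, intensity).
#' @param path file path.
#' @return data.frame with wavenumber, intensity.
#' @export
readSpectrumFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("spectrum file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- read.table(path, header = grepl("[A-Za-z]", first), sep = sep,
                    comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop(sprintf("%s: expected two columns", path))
  out <- data.frame(wavenumber = as.numeric(tab[[1]]),
                    intensity = as.numeric(tab[[2]]))
  if (any(is.na(out))) stop(sprintf("%s: non-numeric spectrum data", path))
  if (any(diff(out$wavenumber) <= 0))
    stop(sprintf("%s: wavenumbers must be strictly increasing", path))
  out
}

#' Load a spectral dataset from a manifest
#'
#' The manifest is a TSV with columns path (relative to the manifest's
#' directory or absolute), participant, class, drop, map. Spectra whose
#' axis differs from the first spectrum's by less than one grid step are
#' interpolated onto it; a larger mismatch is an error.
#'
#' @param manifestPath path to the manifest TSV.
#' @return a \linkS4class{SpectralDataset}.
#' @export
readSpectralDataset <- function(manifestPath) {
  man <- readTsv(manifestPath,
                 required = c("path", "participant", "class", "drop", "map"))
  base <- dirname(manifestPath)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  first <- readSpectrumFile(paths[1])
  axis <- first$wavenumber
  mat <- matrix(0, nrow(man), length(axis))
  mat[1, ] <- first$intensity
  for (i in seq_len(nrow(man))[-1]) {
    s <- readSpectrumFile(paths[i])
    mat[i, ] <- alignToAxis(s$wavenumber, s$intensity, axis)
  }
  new("SpectralDataset", wavenumbers = axis, intensities = mat,
      meta = data.frame(participant = as.character(man$participant),
                        class = as.character(man$class),
                        drop = as.integer(man$drop),
                        map = as.integer(man$map),
                        stringsAsFactors = FALSE))
}

#' Write a spectral dataset as per-spectrum files plus a manifest
#'
#' @param dataset a \linkS4class{SpectralDataset}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeSpectralDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SpectralDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset@meta
  files <- sprintf("%s_d%d_m%d.txt", meta$participant, meta$drop, meta$map)
  for (i in seq_len(nrow(meta)))
    writeTsv(data.frame(wavenumber = dataset@wavenumbers,
                        intensity = dataset@intensities[i, ]),
             file.path(dir, files[i]))
  man <- cbind(path = files, meta)
  manPath <- file.path(dir, "manifest.tsv")
  writeTsv(man, manPath)
  invisible(manPath)
}

#' Read a cytometry event table
#'
#' Accepts the package's column names (i_af488, i_cd45, i_draq5, area_px)
#' directly.
#' @param path TSV/CSV file path.
#' @return data.frame.
#' @export
readEventTable <- function(path) {
  readTsv(path, required = c("i_af488", "i_cd45", "i_draq5", "area_px"),
          numericCols = c("i_af488", "i_cd45", "i_draq5", "area_px"))
}

#' Read a gene-statistics table
#'
#' Accepts either the package's column names (gene_id, fpkm_case,
#' fpkm_control, log2fc, p, q) or Cuffdiff-style names (gene, value_1,
#' value_2, \code{log2(fold_change)}, p_value, q_value), which are
#' renamed on input.
#'
#' @param path TSV file path.
#' @param compartment "blood" or "tissue", stored in the result.
#' @return data.frame with standardised columns.
#' @export
readGeneStats <- function(path, compartment = c("blood", "tissue")) {
  compartment <- match.arg(compartment)
  tab <- readTsv(path)
  ali <- c(gene = "gene_id", value_1 = "fpkm_case", value_2 = "fpkm_control",
           "log2(fold_change)" = "log2fc", p_value = "p", q_value = "q")
  for (old in names(ali))
    if (old %in% names(tab) && !(ali[[old]] %in% names(tab)))
      names(tab)[names(tab) == old] <- ali[[old]]
  for (col in c("gene_id", "fpkm_case", "log2fc", "p"))
    if (!col %in% names(tab))
      stop(sprintf("%s: missing required column '%s'", path, col))
  for (col in intersect(c("fpkm_case", "fpkm_control", "log2fc", "p", "q"),
                        names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  tab$compartment <- compartment
  tab
}
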