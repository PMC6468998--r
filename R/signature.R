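#' Three-tier differential-expression grouping
#'
#' Partitions every gene of a statistics table into three tiers:
#' \describe{
#'   \item{strict}{p < 5e-5 and |log2 fold change| > 2}
#'   \item{moderate}{p < 0.05 and |log2 fold change| > 2, not strict}
#'   \item{unchanged}{everything else}
#' }
#' Rows with missing p or log2fc are dropped with a message.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{log2fc},
#'   \code{p}.
#' @param strictP,moderateP p-value cuts for the two DE tiers.
#' @param minAbsLog2fc absolute fold-change cut shared by both DE tiers.
#' @return data.frame with \code{gene_id} and \code{tier} (factor with
#'   levels strict, moderate, unchanged).
#' @export
tierGenes <- function(genes, strictP = 5e-5, moderateP = 0.05,
                      minAbsLog2fc = 2) {
  need <- c("gene_id", "log2fc", "p")
  if (!all(need %in% names(genes)))
    stop(paste("gene table must contain columns:", paste(need, collapse = ", ")))
  bad <- is.na(genes$p) | is.na(genes$log2fc)
  if (any(bad)) {
    message(sprintf("tierGenes: dropped %d rows with missing p or log2fc", sum(bad)))
    genes <- genes[!bad, , drop = FALSE]
  }
  big <- abs(genes$log2fc) > minAbsLog2fc
  tier <- ifelse(genes$p < strictP & big, "strict",
          ifelse(genes$p < moderateP & big, "moderate", "unchanged"))
  data.frame(gene_id = genes$gene_id,
             tier = factor(tier, levels = c("strict", "moderate", "unchanged")),
             stringsAsFactors = FALSE)
}

#' Blood signature gene filter
#'
#' Selects genes over-expressed in patient blood that pass all three gates:
#' (i) expression above \code{minFpkm} (default 5 FPKM, the minimal level
#' for calling a protein-coding gene transcribed) in the case condition,
#' (ii) significant differential expression (p < \code{alpha}, default
#' 0.05; optionally the q-value instead), and (iii) log2 fold change
#' (tumour vs control) above \code{minLog2fc} (default 2, up-regulation
#' only). Raising any threshold can only shrink the selection.
#'
#' @param blood data.frame of blood-compartment gene statistics with
#'   columns \code{gene_id}, \code{fpkm_case}, \code{log2fc}, \code{p}
#'   (and \code{q} if \code{useQ}).
#' @param minFpkm,minLog2fc,alpha the three gates.
#' @param useQ gate on the q-value instead of the p-value (default FALSE).
#' @return character vector of selected gene ids.
#' @export
selectBloodSignature <- function(blood, minFpkm = 5, minLog2fc = 2,
                                 alpha = 0.05, useQ = FALSE) {
  need <- c("gene_id", "fpkm_case", "log2fc", if (useQ) "q" else "p")
  if (!all(need %in% names(blood)))
    stop(paste("blood table must contain columns:", paste(need, collapse = ", ")))
  stopifnot(minFpkm > 0, minLog2fc > 0, alpha > 0)
  pv <- if (useQ) blood$q else blood$p
  sel <- blood$fpkm_case > minFpkm & pv < alpha & blood$log2fc > minLog2fc
  sel[is.na(sel)] <- FALSE
  as.character(blood$gene_id[sel])
}

#' Two-set Venn counts for tissue and blood gene sets
#'
#' @param tissueSet,bloodSet vectors of gene identifiers (duplicates are
#'   collapsed).
#' @return list with \code{tissue_only}, \code{blood_only}, \code{shared}.
#' @examples
#' venn <- vennCounts(paste0("t", 1:293),
#'                    c(paste0("t", 1:21), paste0("b", 1:335)))
#' venn$shared # 21
#' @export
vennCounts <- function(tissueSet, bloodSet) {
  t <- unique(as.character(tissueSet))
  b <- unique(as.character(bloodSet))
  shared <- length(intersect(t, b))
  list(tissue_only = length(t) - shared,
       blood_only = length(b) - shared,
       shared = shared)
}
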