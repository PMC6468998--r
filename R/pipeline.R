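#' Run the multi-analyte pipeline end to end
#'
#' Orchestrates simulate-then-analyse runs of the four stages — cfDNA
#' copy-number instability, Raman classification, CTC enumeration and the
#' expression signature — from one configuration. Each requested stage is
#' run in the declared order; its artifacts (input tables, result tables)
#' are written under \code{outDir/<stage>/} and a machine-readable summary
#' of all stages, together with the resolved configuration and the package
#' version, is written next to them. Reruns with an identical
#' configuration and seed produce byte-identical summaries.
#'
#' @param config list with elements \code{seed} (integer), \code{stages}
#'   (character vector, any of "cfdna", "raman", "ctc", "expression";
#'   empty = no-op), and optional per-stage parameter lists
#'   (\code{cfdna = list(...)} etc. forwarded to the stage's generator).
#'   Unknown top-level keys are rejected.
#' @param outDir output directory, created if needed.
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(config, outDir) {
  known <- c("seed", "stages", "cfdna", "raman", "ctc", "expression")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) stages <- character(0)
  bad <- setdiff(stages, c("cfdna", "raman", "ctc", "expression"))
  if (length(bad))
    stop(sprintf("unknown stages: %s", paste(bad, collapse = ", ")))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  resolved <- list(seed = seed, stages = as.list(stages),
                   package_version = as.character(packageVersion("liquidlens")))
  for (st in stages) resolved[[st]] <- config[[st]]

  summary <- list()
  for (st in stages) {
    stageDir <- file.path(outDir, st)
    dir.create(stageDir, showWarnings = FALSE)
    params <- if (is.null(config[[st]])) list() else config[[st]]
    summary[[st]] <- tryCatch(
      switch(st,
        cfdna = stageCfdna(params, seed + 101L, stageDir),
        raman = stageRaman(params, seed + 202L, stageDir),
        ctc = stageCtc(params, seed + 303L, stageDir),
        expression = stageExpression(params, seed + 404L, stageDir)),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e))))
  }
  jsonlite::write_json(resolved, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(summary)
}

stageCfdna <- function(params, seed, dir) {
  args <- modifyList(list(seed = seed), params)
  sim <- do.call(simCfdna, args)
  profiles <- lapply(sim$panel, log2RatioProfile, windows = sim$windows)
  panel <- buildReference(profiles)
  writeReferencePanel(panel, file.path(dir, "panel.tsv"))
  writeWindowsBed(sim$windows, file.path(dir, "windows.bed"))
  res <- lapply(sim$samples, function(s) {
    z <- zProfile(log2RatioProfile(s, sim$windows), panel)
    r <- cniScore(z)
    writeCnTable(exportCnTable(r, sim$windows),
                 file.path(dir, sprintf("%s.cn.tsv", s@sampleId)))
    list(sample_id = s@sampleId, cni = r@cni,
         n_rejected = length(r@rejected))
  })
  list(n_windows = nWindows(sim$windows), panel_n = panel@nSamples,
       samples = res)
}

stageRaman <- function(params, seed, dir) {
  args <- modifyList(list(seed = seed), params)
  sim <- do.call(simRaman, args)
  res <- loocvByParticipant(sim)
  writeTsv(res@predictions, file.path(dir, "predictions.tsv"))
  list(n_spectra = nrow(sim@intensities), n_folds = res@nFolds,
       sensitivity = res@sensitivity, specificity = res@specificity,
       confusion = as.list(setNames(as.integer(res@confusion),
                                    c("tp", "fp", "fn", "tn"))))
}

stageCtc <- function(params, seed, dir) {
  args <- modifyList(list(seed = seed), params)
  sim <- do.call(simEvents, args)
  writeTsv(sim$events, file.path(dir, "events.tsv"))
  writeTsv(data.frame(event_id = sim$events$event_id, planted = sim$truth),
           file.path(dir, "events.truth.tsv"))
  cls <- classifyEvents(sim$events)
  list(n_captured = cls$nCaptured, n_ctc = cls$nCtc, per_10k = cls$per10k)
}

stageExpression <- function(params, seed, dir) {
  args <- modifyList(list(seed = seed), params)
  sim <- do.call(simExpression, args)
  writeTsv(sim$blood, file.path(dir, "blood.tsv"))
  writeTsv(sim$tissue, file.path(dir, "tissue.tsv"))
  tiers <- tierGenes(sim$blood)
  sig <- selectBloodSignature(sim$blood)
  writeTsv(data.frame(gene_id = sort(sig)), file.path(dir, "signature.tsv"))
  deSet <- function(tab) tab$gene_id[tab$p < 0.05 & abs(tab$log2fc) > 2]
  venn <- vennCounts(deSet(sim$tissue), deSet(sim$blood))
  list(n_signature = length(sig), tiers = as.list(table(tiers$tier)),
       venn = venn)
}
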