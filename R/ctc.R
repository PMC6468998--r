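#' Gate cytometry events into CTC / non-CTC
#'
#' The positivity rule for a circulating tumour cell: positive for the
#' epithelial stain (AF488 pan-cytokeratin), negative for the leukocyte
#' antigen (CD45) and positive for the nuclear stain (DRAQ5):
#' \code{flag = (i_af488 > t_af488) & (i_cd45 <= t_cd45) & (i_draq5 > t_draq5)}.
#' CD45-negative is inclusive of the threshold so the rule partitions every
#' event. An optional cell-area filter (in pixels) can additionally gate on
#' size; it is off by default. The rule is a pure function of each event
#' row. Counts are normalised per 10,000 captured cells.
#'
#' Numeric thresholds are instrument- and staining-dependent and are not
#' package constants; the defaults in \code{\link{defaultGates}} are
#' calibrated to the synthetic event generator, not to any instrument.
#'
#' @param events data.frame with columns \code{i_af488}, \code{i_cd45},
#'   \code{i_draq5}, \code{area_px}.
#' @param gates list with \code{t_af488}, \code{t_cd45}, \code{t_draq5}
#'   (and optional \code{area_min}, \code{area_max}).
#' @param nCaptured total captured cells (default: number of event rows).
#' @return list with \code{flags} (logical per event), \code{nCtc},
#'   \code{nCaptured} and \code{per10k}.
#' @export
classifyEvents <- function(events, gates = defaultGates(),
                           nCaptured = nrow(events)) {
  need <- c("i_af488", "i_cd45", "i_draq5")
  if (!all(need %in% names(events)))
    stop(paste("event table must contain columns:", paste(need, collapse = ", ")))
  stopifnot(all(c("t_af488", "t_cd45", "t_draq5") %in% names(gates)))
  if (nCaptured <= 0) stop("nCaptured must be positive")
  if (nCaptured < nrow(events)) stop("nCaptured cannot be below the event count")
  flags <- events$i_af488 > gates$t_af488 &
           events$i_cd45 <= gates$t_cd45 &
           events$i_draq5 > gates$t_draq5
  if (!is.null(gates$area_min)) flags <- flags & events$area_px >= gates$area_min
  if (!is.null(gates$area_max)) flags <- flags & events$area_px <= gates$area_max
  nCtc <- sum(flags)
  list(flags = flags, nCtc = nCtc, nCaptured = nCaptured,
       per10k = per10k(nCtc, nCaptured))
}

#' Default gate thresholds for the synthetic event generator
#'
#' Chosen so the generator's planted CTC and leukocyte populations are
#' separated by well over 4 SDs on every gated channel. These are fixture
#' values for synthetic data, not instrument calibrations.
#'
#' @return list with \code{t_af488}, \code{t_cd45}, \code{t_draq5}.
#' @export
defaultGates <- function() list(t_af488 = 400, t_cd45 = 150, t_draq5 = 200)

#' CTC count per 10,000 captured cells
#'
#' @param nCtc CTC-gated event count.
#' @param nCaptured total captured cells (> 0).
#' @return numeric(1), \code{10000 * nCtc / nCaptured}.
#' @examples per10k(13, 52000) # 2.5
#' @export
per10k <- function(nCtc, nCaptured) {
  if (any(nCaptured <= 0)) stop("nCaptured must be positive")
  10000 * nCtc / nCaptured
}

#' Spike-in recovery percentage
#'
#' Fraction of cultured cells spiked into whole blood that the detection
#' pipeline retrieved, as a percentage. Retrieval above 100\% (possible
#' double counting) triggers a warning but is still computed.
#'
#' @param retrieved cells retrieved.
#' @param spiked cells spiked (> 0).
#' @return list with \code{spiked}, \code{retrieved}, \code{percent}.
#' @examples recoveryPercent(2100, 5000) # 42%
#' @export
recoveryPercent <- function(retrieved, spiked) {
  if (spiked <= 0) stop("spiked must be positive")
  if (retrieved > spiked)
    warning("retrieved exceeds spiked: possible double counting")
  list(spiked = spiked, retrieved = retrieved,
       percent = 100 * retrieved / spiked)
}

#' Convert a pixel area to square micrometres
#'
#' Imaging flow-cytometry masks report cell area in pixels; at the
#' instrument's scale 1 pixel = 0.25 um^2.
#'
#' @param areaPx area in pixels (>= 0).
#' @param um2PerPixel scale factor, default 0.25.
#' @return area in um^2.
#' @examples pixelsToArea(1720) # 430
#' @export
pixelsToArea <- function(areaPx, um2PerPixel = 0.25) {
  if (any(areaPx < 0)) stop("pixel area must be non-negative")
  um2PerPixel * areaPx
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every unique value of the score as a decision threshold
#' (prediction positive when \code{value >= threshold}) and reports the
#' true- and false-positive rates along the sweep, with the area under the
#' curve by the trapezoid rule. Tied scores contribute half, so the AUC
#' equals the Mann-Whitney U statistic divided by \code{n1 * n2} and is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param values numeric per-sample scores (higher = more positive).
#' @param labels class labels.
#' @param positive label of the positive class (default \code{"cancer"}
#'   when present, else the second sorted level).
#' @return list with \code{thresholds}, \code{tpr}, \code{fpr} (including
#'   the (0,0) and (1,1) endpoints) and \code{auc}.
#' @export
rocAuc <- function(values, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("both classes must be present")
  if (is.null(positive)) positive <- if ("cancer" %in% lev) "cancer" else lev[2]
  isPos <- labels == positive
  n1 <- sum(isPos); n0 <- sum(!isPos)
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(isPos & values >= t) / n1, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(!isPos & values >= t) / n0, numeric(1)))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc)
}

#' One-way ANOVA with Tukey multiple-comparison contrasts
#'
#' Classical one-way analysis of variance across groups followed by
#' Tukey's honest significant difference test on all pairwise group
#' contrasts, with significance at p < 0.05.
#'
#' @param values numeric observations.
#' @param groups group membership (coerced to factor).
#' @param conf confidence level for the Tukey intervals.
#' @param method \code{"anova"} (default) or \code{"wilcox"}, a
#'   Mann-Whitney rank test for exactly two groups of count-like data.
#' @return for \code{"anova"}: list with \code{F}, \code{p}, \code{tukey}
#'   (data.frame of pairwise contrasts: diff, lwr, upr, p_adj) and the
#'   fitted \code{aov}; for \code{"wilcox"}: list with \code{W} and
#'   \code{p}.
#' @export
groupTest <- function(values, groups, conf = 0.95,
                      method = c("anova", "wilcox")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two values")
  if (method == "wilcox") {
    if (nlevels(groups) != 2) stop("wilcox method needs exactly two groups")
    wt <- stats::wilcox.test(values ~ groups, exact = FALSE)
    return(list(W = unname(wt$statistic), p = wt$p.value))
  }
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], tukey = tukey, fit = fit)
}
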