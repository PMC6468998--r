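#' Fit a PCA model on training spectra
#'
#' Centres the training matrix and computes principal components via
#' \code{\link[stats]{prcomp}}. The number of retained components is the
#' smallest count whose cumulative explained-variance share reaches
#' \code{varianceFraction} (default 0.95), capped at \code{maxK} (default
#' 20) and at the matrix rank; a fixed \code{k} overrides the rule.
#'
#' @param train numeric matrix, training spectra in rows.
#' @param varianceFraction cumulative variance target in (0, 1].
#' @param maxK cap on the retained component count.
#' @param k fixed component count (overrides the variance rule).
#' @return an object of class \code{ramanPCA}: list with \code{center}
#'   (mean spectrum), \code{loadings} (p x k, orthonormal columns),
#'   \code{sdev}, \code{explained} (variance shares, non-increasing) and
#'   \code{k}.
#' @export
fitPca <- function(train, varianceFraction = 0.95, maxK = 20, k = NULL) {
  stopifnot(is.matrix(train), nrow(train) >= 2)
  pc <- prcomp(train, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stop("degenerate (rank 0) training matrix")
  explained <- v / sum(v)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (is.null(k)) {
    k <- which(cumsum(explained) >= varianceFraction)[1]
    if (is.na(k)) k <- rank
    k <- min(k, maxK, rank)
  } else k <- min(k, rank)
  structure(list(center = pc$center,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev[seq_len(k)],
                 explained = explained, k = k),
            class = "ramanPCA")
}

#' Project spectra onto a fitted PCA model
#'
#' @param model a \code{ramanPCA} from \code{\link{fitPca}}.
#' @param x numeric matrix, spectra in rows (or one spectrum as a vector).
#' @return score matrix (n x k).
#' @export
pcaScores <- function(model, x) {
  stopifnot(inherits(model, "ramanPCA"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  sweep(x, 2, model$center) %*% model$loadings
}

#' Fisher linear discriminant for two classes
#'
#' Computes the direction that maximises the ratio of between-class to
#' within-class scatter, \eqn{w = S_w^{-1} (\mu_1 - \mu_0)}, with the
#' within-class scatter regularised by adding
#' \code{reg * trace(Sw) / d} to its diagonal so small folds stay
#' invertible. The decision threshold is the midpoint of the projected
#' class means; a projection strictly above the threshold is called the
#' positive class, and a score exactly at the threshold is called negative
#' (conservative tie-break).
#'
#' @param scores numeric matrix, one row per observation (e.g. PC scores).
#' @param labels vector of class labels with exactly two levels.
#' @param positive label treated as the positive class (default
#'   \code{"cancer"} when present, else the second sorted level).
#' @param reg diagonal regularisation fraction (default 1e-6).
#' @return an object of class \code{fisherLDA}: list with \code{w},
#'   \code{threshold}, \code{positive}, \code{negative}.
#' @export
fitLda <- function(scores, labels, positive = NULL, reg = 1e-6) {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("LDA needs exactly two classes in the training data")
  if (is.null(positive)) positive <- if ("cancer" %in% lev) "cancer" else lev[2]
  if (!positive %in% lev) stop("positive class absent from labels")
  negative <- setdiff(lev, positive)
  d <- ncol(scores)
  mu1 <- colMeans(scores[labels == positive, , drop = FALSE])
  mu0 <- colMeans(scores[labels == negative, , drop = FALSE])
  Sw <- matrix(0, d, d)
  for (g in lev) {
    xg <- scores[labels == g, , drop = FALSE]
    xc <- sweep(xg, 2, colMeans(xg))
    Sw <- Sw + crossprod(xc)
  }
  tr <- sum(diag(Sw))
  if (tr <= 0) tr <- d # all-identical points: fall back to Euclidean direction
  Sw <- Sw + diag(reg * tr / d, d)
  w <- solve(Sw, mu1 - mu0)
  structure(list(w = as.numeric(w),
                 threshold = sum(w * (mu1 + mu0)) / 2,
                 positive = positive, negative = negative),
            class = "fisherLDA")
}

#' Predict class labels from a fitted Fisher discriminant
#'
#' @param model a \code{fisherLDA} from \code{\link{fitLda}}.
#' @param scores numeric matrix of observations in rows.
#' @return data.frame with columns \code{score} (projection) and
#'   \code{predicted}.
#' @export
ldaPredict <- function(model, scores) {
  stopifnot(inherits(model, "fisherLDA"))
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = length(model$w))
  proj <- as.numeric(scores %*% model$w)
  data.frame(score = proj,
             predicted = ifelse(proj > model$threshold,
                                model$positive, model$negative),
             stringsAsFactors = FALSE)
}

#' Leave-one-participant-out cross-validated PCA-LDA classification
#'
#' One fold per participant: all of a participant's spectra (every drop and
#' map) are held out together, the PCA mean/loadings and the discriminant
#' are fitted on the remaining participants only, and the held-out spectra
#' are predicted — so no within-participant information leaks into the
#' model that scores a participant. Baseline subtraction and SNV are
#' per-spectrum operations and are applied once up front. Every spectrum is
#' predicted exactly once; a fold whose training set lacks a class is
#' skipped with a warning and recorded.
#'
#' Sensitivity is the fraction of cancer spectra predicted cancer;
#' specificity the fraction of control spectra predicted control.
#'
#' @param dataset a \linkS4class{SpectralDataset} (raw; preprocessing is
#'   applied internally unless \code{preprocess = FALSE}).
#' @param baseline,snv,... preprocessing options, see
#'   \code{\link{preprocessSpectra}}.
#' @param varianceFraction,maxK,k PCA retention rule, see
#'   \code{\link{fitPca}}.
#' @param reg LDA regularisation, see \code{\link{fitLda}}.
#' @param preprocess set \code{FALSE} if \code{dataset} is already
#'   preprocessed.
#' @param returnModels also return the per-fold fitted PCA and LDA models
#'   (e.g. to verify that a fold's model does not depend on its held-out
#'   participant).
#' @return a \linkS4class{ClassifierResult}; with
#'   \code{returnModels = TRUE}, a list with elements \code{result} and
#'   \code{models} (one \code{list(pca, lda)} per completed fold, named by
#'   participant).
#' @export
loocvByParticipant <- function(dataset, baseline = "als", snv = TRUE,
                               varianceFraction = 0.95, maxK = 20, k = NULL,
                               reg = 1e-6, preprocess = TRUE,
                               returnModels = FALSE, ...) {
  stopifnot(is(dataset, "SpectralDataset"))
  meta <- dataset@meta
  participants <- unique(meta$participant)
  classOf <- vapply(participants, function(p)
    unique(meta$class[meta$participant == p])[1], character(1))
  if (length(unique(classOf)) < 2)
    stop("need participants from both classes")
  if (preprocess)
    dataset <- preprocessSpectra(dataset, baseline = baseline, snv = snv, ...)
  mat <- dataset@intensities

  preds <- vector("list", length(participants))
  models <- list()
  pcCounts <- numeric(0)
  skipped <- character(0)
  for (i in seq_along(participants)) {
    p <- participants[i]
    test <- which(meta$participant == p)
    train <- which(meta$participant != p)
    if (length(unique(meta$class[train])) < 2) {
      warning(sprintf("fold for participant %s skipped: training set has one class", p))
      skipped <- c(skipped, as.character(p))
      next
    }
    pca <- fitPca(mat[train, , drop = FALSE],
                  varianceFraction = varianceFraction, maxK = maxK, k = k)
    lda <- fitLda(pcaScores(pca, mat[train, , drop = FALSE]),
                  meta$class[train], positive = "cancer", reg = reg)
    out <- ldaPredict(lda, pcaScores(pca, mat[test, , drop = FALSE]))
    preds[[i]] <- cbind(meta[test, c("participant", "class", "drop", "map")],
                        fold = i, out)
    pcCounts <- c(pcCounts, pca$k)
    if (returnModels) models[[as.character(p)]] <- list(pca = pca, lda = lda)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(truth = c("cancer", "control"),
                                      predicted = c("cancer", "control")))
  tb <- table(factor(predictions$class, c("cancer", "control")),
              factor(predictions$predicted, c("cancer", "control")))
  confusion[] <- as.integer(tb)
  sens <- confusion["cancer", "cancer"] / sum(confusion["cancer", ])
  spec <- confusion["control", "control"] / sum(confusion["control", ])
  result <- new("ClassifierResult", predictions = predictions,
                confusion = confusion, sensitivity = sens,
                specificity = spec, nFolds = length(participants),
                pcCounts = pcCounts, skippedFolds = skipped)
  if (returnModels) list(result = result, models = models) else result
}
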