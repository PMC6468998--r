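test_that("PCA captures collinear data in one component with orthonormal loadings", {
  set.seed(21)
  direction <- rnorm(40)
  x <- outer(rnorm(12), direction) # rank-1 data
  m <- fitPca(x, varianceFraction = 0.95)
  expect_equal(m$k, 1)
  expect_gt(m$explained[1], 1 - 1e-10)
  full <- fitPca(matrix(rnorm(15 * 40), 15, 40), k = 10)
  expect_equal(crossprod(full$loadings), diag(10),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(diff(full$explained) <= 1e-12))
  expect_error(fitPca(matrix(1, 4, 6)), "degenerate")
})

test_that("PCA scores match a brute-force covariance eigendecomposition", {
  set.seed(22)
  x <- matrix(rnorm(5 * 9), 5, 9) # 5-spectrum toy set
  m <- fitPca(x, k = 4)
  scores <- pcaScores(m, x)
  ev <- eigen(cov(x) * (nrow(x) - 1) / (nrow(x) - 1), symmetric = TRUE)
  centred <- sweep(x, 2, colMeans(x))
  oracle <- centred %*% ev$vectors[, 1:4]
  for (j in 1:4) { # equal up to sign
    same <- max(abs(scores[, j] - oracle[, j]))
    flip <- max(abs(scores[, j] + oracle[, j]))
    expect_lt(min(same, flip), 1e-8)
  }
  # scores reproduce the centred data within reconstruction error
  mFull <- fitPca(x, k = 5)
  recon <- pcaScores(mFull, x) %*% t(mFull$loadings)
  expect_equal(recon, centred, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the Fisher discriminant matches its closed form and separates clouds", {
  set.seed(23)
  # toy 2-D two-class set: w parallel to Sw^-1 (mu1 - mu0)
  a <- cbind(rnorm(20, 0), rnorm(20, 0, 2))
  b <- cbind(rnorm(20, 10), rnorm(20, 1, 2))
  scores <- rbind(a, b)
  labels <- rep(c("control", "cancer"), each = 20)
  m <- fitLda(scores, labels, positive = "cancer", reg = 1e-6)
  mu0 <- colMeans(a); mu1 <- colMeans(b)
  Sw <- crossprod(sweep(a, 2, mu0)) + crossprod(sweep(b, 2, mu1))
  Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / 2, 2)
  wOracle <- solve(Sw, mu1 - mu0)
  expect_equal(m$w, as.numeric(wOracle), tolerance = 1e-8)
  expect_equal(m$threshold, sum(wOracle * (mu1 + mu0)) / 2, tolerance = 1e-8)
  # well-separated clouds classify their own training data perfectly
  pred <- ldaPredict(m, scores)$predicted
  expect_equal(pred, ifelse(labels == "cancer", "cancer", "control"))
  # direction agrees with MASS::lda up to scale
  ml <- MASS::lda(scores, grouping = labels)
  cosine <- sum(m$w * ml$scaling) /
    sqrt(sum(m$w^2) * sum(ml$scaling^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-4)
})

test_that("1-D LDA reduces to the sign of the mean difference", {
  s <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  lab <- rep(c("control", "cancer"), each = 3)
  m <- fitLda(s, lab)
  expect_gt(m$w * (11 - 2), 0)
  # a score exactly at the threshold is called negative (control)
  expect_equal(ldaPredict(m, matrix(m$threshold / m$w, 1, 1))$predicted,
               "control")
  expect_error(fitLda(s, rep("cancer", 6)), "two classes")
})

test_that("participant-level LOOCV predicts each spectrum once with no leakage", {
  ds <- simRaman(nCancer = 6, nControl = 4, drops = 2, maps = 2,
                 axis = seq(600, 1800, by = 4), seed = 51)
  out <- loocvByParticipant(ds, returnModels = TRUE)
  res <- out$result
  expect_equal(res@nFolds, 10)
  expect_equal(nrow(res@predictions), 40) # every spectrum scored once
  expect_equal(sum(res@confusion), 40)
  expect_equal(anyDuplicated(res@predictions[c("participant", "drop", "map")]), 0)
  expect_length(res@pcCounts, 10)

  # corrupting a held-out participant's spectra leaves that fold's model
  # untouched (bitwise-equal parameters)
  victim <- "LC03"
  mat <- intensities(ds)
  mat[spectraMeta(ds)$participant == victim, ] <-
    matrix(rnorm(sum(spectraMeta(ds)$participant == victim) * ncol(mat)),
           ncol = ncol(mat))
  ds2 <- new("SpectralDataset", wavenumbers = wavenumbers(ds),
             intensities = mat, meta = spectraMeta(ds))
  out2 <- loocvByParticipant(ds2, returnModels = TRUE)
  expect_identical(out$models[[victim]], out2$models[[victim]])
})

test_that("clearly separable synthetic classes are classified perfectly", {
  ds <- simRaman(nCancer = 5, nControl = 5, drops = 1, maps = 2,
                 axis = seq(600, 1800, by = 4),
                 depletionEffect = 0.6, participantSd = 0.02, seed = 52)
  res <- loocvByParticipant(ds)
  expect_equal(res@sensitivity, 1)
  expect_equal(res@specificity, 1)
})

test_that("a fold whose training set lacks a class is skipped and recorded", {
  ds <- simRaman(nCancer = 4, nControl = 1, drops = 1, maps = 2,
                 axis = seq(600, 1800, by = 8), seed = 53)
  expect_warning(res <- loocvByParticipant(ds), "skipped")
  expect_equal(res@skippedFolds, "CT01")
  # the skipped participant's spectra are excluded from the confusion total
  expect_equal(sum(res@confusion), 8)
})

test_that("the pipeline is invariant under per-spectrum affine transforms", {
  ds <- simRaman(nCancer = 4, nControl = 4, drops = 1, maps = 2,
                 axis = seq(600, 1800, by = 4), seed = 54)
  set.seed(55)
  mat <- intensities(ds)
  gain <- runif(nrow(mat), 0.5, 3)
  offset <- rnorm(nrow(mat), 0, 10)
  ds2 <- new("SpectralDataset", wavenumbers = wavenumbers(ds),
             intensities = mat * gain + offset, meta = spectraMeta(ds))
  r1 <- loocvByParticipant(ds)
  r2 <- loocvByParticipant(ds2)
  expect_equal(r1@predictions$predicted, r2@predictions$predicted)
  expect_equal(r1@predictions$score, r2@predictions$score, tolerance = 1e-6)
})

test_that("permuted labels give chance-level balanced accuracy", {
  ds <- simRaman(nCancer = 8, nControl = 8, drops = 1, maps = 2,
                 axis = seq(600, 1800, by = 4), seed = 42)
  pp <- preprocessSpectra(ds)
  meta <- spectraMeta(pp)
  parts <- unique(meta$participant)
  trueClass <- vapply(parts, function(p)
    meta$class[meta$participant == p][1], character(1))
  set.seed(99)
  bal <- replicate(50, {
    perm <- setNames(sample(trueClass), parts) # balanced relabelling
    m2 <- meta
    m2$class <- unname(perm[m2$participant])
    r <- loocvByParticipant(withMeta(pp, m2), preprocess = FALSE)
    (r@sensitivity + r@specificity) / 2
  })
  expect_lt(abs(mean(bal) - 0.5), 3 * sd(bal) / sqrt(length(bal)))
})

test_that("sensitivity responds monotonically to the depletion effect size", {
  sens <- vapply(c(0.05, 0.3, 0.6), function(eff) {
    ds <- simRaman(nCancer = 6, nControl = 6, drops = 1, maps = 2,
                   axis = seq(600, 1800, by = 4),
                   depletionEffect = eff, participantSd = 0.15, seed = 60)
    loocvByParticipant(ds)@sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})
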