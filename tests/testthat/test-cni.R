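test_that("log2 ratios follow the observed/expected formula", {
  w <- toyWindows() # 8 equal 20-bp windows
  # counts exactly at expectation -> all ratios zero
  p0 <- log2RatioProfile(toyCounts(rep(100, 8)), w)
  expect_equal(log2Ratios(p0), rep(0, 8))
  # one window at twice its expectation, pseudocount 0 -> ratio 1
  cnt <- rep(100, 8); cnt[3] <- 200
  # expectation uses totalReads, so put the doubled window against it
  p1 <- log2RatioProfile(toyCounts(cnt), w, pseudocount = 0)
  expected3 <- sum(cnt) * 20 / 160
  expect_equal(log2Ratios(p1)[3], log2(200 / expected3))
  # zero count with pseudocount 0.5 stays finite and matches hand formula
  cnt0 <- rep(100, 8); cnt0[5] <- 0
  p2 <- log2RatioProfile(toyCounts(cnt0), w, pseudocount = 0.5)
  e5 <- sum(cnt0) * 20 / 160
  expect_equal(log2Ratios(p2)[5], log2(0.5 / (e5 + 0.5)))
  expect_true(all(is.finite(log2Ratios(p2))))
  expect_error(log2RatioProfile(toyCounts(rep(0, 8)), w), "positive")
})

test_that("reference panels hold per-window mean/SD with a sigma floor", {
  w <- toyWindows()
  p <- toyProfile(c(0.1, -0.2, 0, 0.3, 0, 0, 0.05, -0.1))
  panel <- buildReference(list(p, p))
  expect_equal(panel@mu, p@ratios)
  expect_equal(panel@sigma, rep(1e-4, 8)) # identical profiles -> floor
  zeroPanel <- buildReference(list(toyProfile(rep(0, 8)),
                                   toyProfile(rep(0, 8)),
                                   toyProfile(rep(0, 8))))
  expect_equal(zeroPanel@mu, rep(0, 8))
  # mismatched window sets are rejected
  other <- new("Log2RatioProfile", sampleId = "x", ratios = rep(0, 8),
               pseudocount = 0.5, windowSetId = "elsewhere")
  expect_error(buildReference(list(p, other)), "mismatch")
})

test_that("a 133-profile panel recovers the generator SD", {
  set.seed(5)
  nw <- 200
  trueSd <- 0.1
  profiles <- lapply(1:133, function(i)
    new("Log2RatioProfile", sampleId = paste0("n", i),
        ratios = rnorm(nw, 0, trueSd), pseudocount = 0.5,
        windowSetId = "simset"))
  panel <- buildReference(profiles)
  rel <- abs(panel@sigma - trueSd) / trueSd
  # typical per-window error ~1/sqrt(2*132) ~ 6%; nearly all within 15%
  expect_lt(mean(rel), 0.15)
  expect_gt(mean(rel < 0.15), 0.95)
  expect_lt(max(abs(panel@mu)), 5 * trueSd / sqrt(133) * 4)
})

test_that("z profiles standardise against the panel", {
  w <- toyWindows()
  panel <- new("ReferencePanel", nSamples = 10,
               mu = seq(-0.2, 0.15, length.out = 8), sigma = rep(0.05, 8),
               sigmaFloor = 1e-4, windowSetId = windowSetId(w))
  atMean <- new("Log2RatioProfile", sampleId = "m", ratios = panel@mu,
                pseudocount = 0.5, windowSetId = windowSetId(w))
  expect_equal(zValues(zProfile(atMean, panel)), rep(0, 8))
  up <- atMean; up@ratios[4] <- panel@mu[4] + 2 * panel@sigma[4]
  expect_equal(zValues(zProfile(up, panel))[4], 2)
  expect_equal(zProfile(up, panel)@panelN, 10)
})

test_that("null z values are standard-normal within Monte-Carlo error", {
  w <- hg19Windows()
  sim <- simCfdna(w, panelN = 60, nSamples = 30, seed = 13)
  panel <- buildReference(lapply(sim$panel, log2RatioProfile, windows = w))
  z <- unlist(lapply(sim$samples, function(s)
    zValues(zProfile(log2RatioProfile(s, w), panel))))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 2)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("cniScore applies the two-sided threshold and both conventions", {
  # all-null profile scores zero with an empty rejected set
  r0 <- cniScore(rep(0, 10))
  expect_equal(cniValue(r0), 0)
  expect_length(rejectedWindows(r0), 0)
  expect_equal(r0@zCritical, qnorm(1 - 0.002 / 2))
  # a single clear aberration contributes Phi(|z|)
  r1 <- cniScore(c(rep(0, 9), 4))
  expect_equal(rejectedWindows(r1), 10L)
  expect_equal(cniValue(r1), pnorm(4))
  # abs_z_sum convention sums |z| instead
  r2 <- cniScore(c(rep(0, 9), 4), convention = "abs_z_sum")
  expect_equal(cniValue(r2), 4)
  # finite-panel calibration uses the scaled t quantile
  zp <- new("ZProfile", sampleId = "s", z = rep(0, 5), panelN = 133,
            windowSetId = "x")
  expect_equal(cniScore(zp)@zCritical,
               sqrt(1 + 1 / 133) * qt(1 - 0.001, 132))
  expect_equal(cniScore(zp, panelAdjust = FALSE)@zCritical,
               qnorm(0.999))
  expect_error(cniScore(rep(0, 3), alpha = 1.5), "alpha")
})

test_that("cniScore equals a brute-force normal-CDF loop oracle", {
  # oracle: explicit loop with an erfc-based normal CDF (pracma)
  oracleCni <- function(z, alpha, convention, zCrit) {
    phi <- function(x) 0.5 * pracma::erfc(-x / sqrt(2))
    total <- 0
    for (zi in z) {
      if (abs(zi) > zCrit)
        total <- total + if (convention == "cdf_sum") phi(abs(zi)) else abs(zi)
    }
    total
  }
  set.seed(17)
  for (rep in 1:50) {
    z <- rnorm(sample(5:400, 1), sd = sample(c(0.5, 1, 2, 4), 1))
    for (conv in c("cdf_sum", "abs_z_sum")) {
      r <- cniScore(z, convention = conv)
      expect_equal(cniValue(r),
                   oracleCni(z, 0.002, conv, qnorm(1 - 0.001)),
                   tolerance = 1e-10)
      expect_true(all(abs(z[rejectedWindows(r)]) > r@zCritical))
      expect_true(all(abs(z[-rejectedWindows(r)]) <= r@zCritical) ||
                  length(rejectedWindows(r)) == length(z))
    }
  }
})

test_that("CNI is non-decreasing in the number of aberrant windows", {
  z <- rep(0, 100)
  cnis <- sapply(seq(0, 40, by = 10), function(k) {
    zz <- z; if (k > 0) zz[seq_len(k)] <- 5
    cniValue(cniScore(zz))
  })
  expect_true(all(diff(cnis) > 0))
})

test_that("implanted gains are recovered in nearly all seeded replicates", {
  # 3-window single-copy gain (ratio 1.5) at tumour fraction 0.4:
  # per-window mean z ~ log2(1.2)/0.063 ~ 4.2 under the default noise,
  # so a lesion window is rejected with ~87% power and the lesion with ~99.8%
  w <- hg19Windows()
  ab <- data.frame(firstWindow = 300, lastWindow = 302, copyRatio = 1.5)
  sim <- simCfdna(w, panelN = 133, nSamples = 40, aberrations = ab,
                  tumourFraction = 0.4, seed = 23)
  panel <- buildReference(lapply(sim$panel, log2RatioProfile, windows = w))
  hit <- vapply(sim$samples, function(s) {
    r <- cniScore(zProfile(log2RatioProfile(s, w), panel))
    any(rejectedWindows(r) %in% 300:302)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("tissue profiles flag gains and losses at the log2 threshold", {
  med <- 1000
  cnt <- rep(med, 11)
  cnt[2] <- round(med * 2^0.2)   # log2 ~ +0.2 -> gain
  cnt[3] <- round(med * 2^-0.2)  # log2 ~ -0.2 -> loss
  cnt[4] <- round(med * 2^0.1)   # inside the corridor -> no flag
  tp <- tissueProfile(toyCounts(cnt, id = "t",
                                windows = partitionGenome(
                                  data.frame(chrom = "c", length = 110),
                                  spanBp = 10)))
  expect_equal(tp@threshold, 0.15)
  expect_true(tp@gain[2]);  expect_false(tp@loss[2])
  expect_true(tp@loss[3]);  expect_false(tp@gain[3])
  expect_false(tp@gain[4] || tp@loss[4])
  expect_false(any(tp@gain & tp@loss))
  # uniform counts -> all zero, no flags
  u <- tissueProfile(toyCounts(rep(50, 8)))
  expect_equal(u@log2VsMedian, rep(0, 8))
  expect_false(any(u@gain | u@loss))
  # zero-count window -> -Inf, flagged as loss; all-zero input rejected
  cz <- rep(40, 8); cz[1] <- 0
  tz <- tissueProfile(toyCounts(cz))
  expect_true(is.infinite(tz@log2VsMedian[1]) && tz@loss[1])
  expect_error(tissueProfile(toyCounts(rep(0, 8))), "positive")
})

test_that("copy-number tables export one row per window and round-trip", {
  w <- hg19Windows()
  sim <- simCfdna(w, panelN = 20, nSamples = 1, seed = 3)
  panel <- buildReference(lapply(sim$panel, log2RatioProfile, windows = w))
  r <- cniScore(zProfile(log2RatioProfile(sim$samples[[1]], w), panel))
  tab <- exportCnTable(r, w)
  expect_equal(nrow(tab), 701)
  expect_equal(sum(tab$flag == "rejected"), length(rejectedWindows(r)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCnTable(tab, path)
  back <- readCnTable(path)
  expect_equal(back$value, signif(tab$value, 10))
  expect_identical(back$flag, tab$flag)
  expect_identical(back$start, tab$start)
  # a result with nothing rejected has zero flagged rows
  none <- cniScore(rep(0, 701))
  expect_equal(sum(exportCnTable(none, w)$flag != ""), 0)
})
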