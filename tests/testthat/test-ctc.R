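test_that("the CTC gate is AF488+ / CD45- / DRAQ5+ and a pure row function", {
  g <- list(t_af488 = 400, t_cd45 = 150, t_draq5 = 200)
  ev <- data.frame(
    i_af488 = c(800, 800, 800, 100, 800),
    i_cd45  = c(40, 600, 40, 40, 150),   # row 5 sits exactly on the cut
    i_draq5 = c(600, 600, 100, 600, 600),
    area_px = c(1400, 300, 1400, 300, 1400))
  cls <- classifyEvents(ev, g)
  # CD45-negative is inclusive: a value at the threshold still gates in
  expect_equal(cls$flags, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cls$nCtc, 2)
  expect_equal(cls$per10k, 10000 * 2 / 5)
  # permuting rows permutes flags identically
  perm <- c(3, 5, 1, 2, 4)
  expect_equal(classifyEvents(ev[perm, ], g)$flags, cls$flags[perm])
  # optional size gate
  area <- classifyEvents(ev, c(g, list(area_min = 1000)))
  expect_equal(area$nCtc, 2)
  expect_error(classifyEvents(ev, g, nCaptured = 0), "positive")
  expect_error(classifyEvents(ev[, -1], g), "i_af488")
})

test_that("planted synthetic CTCs are recovered exactly under default gates", {
  sim <- simEvents(nCaptured = 10000, nPlanted = 7, seed = 101)
  cls <- classifyEvents(sim$events)
  expect_equal(cls$nCtc, 7)
  expect_equal(cls$flags, sim$truth)
  expect_equal(cls$per10k, 7)
  none <- simEvents(nCaptured = 2000, nPlanted = 0, seed = 102)
  expect_equal(classifyEvents(none$events)$nCtc, 0)
})

test_that("per-10k normalisation is exact and scale-free", {
  expect_equal(per10k(0, 10000), 0)
  expect_equal(per10k(5, 10000), 5)
  expect_equal(per10k(13, 52000), 2.5)
  expect_equal(per10k(26, 104000), per10k(13, 52000)) # doubling both
  expect_error(per10k(1, 0), "positive")
})

test_that("spike-in recovery and pixel-area conversions match hand values", {
  expect_equal(recoveryPercent(2100, 5000)$percent, 42)
  expect_equal(recoveryPercent(0, 150)$percent, 0)
  expect_equal(recoveryPercent(150, 150)$percent, 100)
  expect_warning(r <- recoveryPercent(160, 150), "double counting")
  expect_equal(r$percent, 100 * 160 / 150)
  expect_error(recoveryPercent(10, 0), "positive")

  expect_equal(pixelsToArea(0), 0)
  expect_equal(pixelsToArea(1720), 430)
  expect_equal(pixelsToArea(4), 1)
  expect_error(pixelsToArea(-1), "non-negative")
})

test_that("ROC/AUC matches the pair-counting U statistic and is monotone", {
  # perfectly separated groups
  sep <- rocAuc(c(1, 2, 3, 10, 11, 12),
                rep(c("control", "cancer"), each = 3))
  expect_equal(sep$auc, 1)
  expect_true(all(diff(sep$tpr) >= 0) && all(diff(sep$fpr) >= 0))

  # toy values vs a brute-force pair-counting oracle (ties count 1/2)
  uOracle <- function(values, labels, positive) {
    pos <- values[labels == positive]; neg <- values[labels != positive]
    s <- 0
    for (p in pos) for (n in neg)
      s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
    s / (length(pos) * length(neg))
  }
  set.seed(33)
  for (rep in 1:20) {
    v <- sample(1:6, 10, replace = TRUE) # forces ties
    lab <- sample(c("cancer", "control"), 10, replace = TRUE,
                  prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    expect_equal(rocAuc(v, lab)$auc, uOracle(v, lab, "cancer"))
    # invariance under a strictly monotone transform
    expect_equal(rocAuc(exp(v / 2), lab)$auc, rocAuc(v, lab)$auc)
  }

  # labels independent of values: AUC near 1/2
  set.seed(34)
  v <- rnorm(2000)
  lab <- sample(rep(c("cancer", "control"), 1000))
  expect_lt(abs(rocAuc(v, lab)$auc - 0.5), 0.04)
  # cross-check against an established implementation
  r <- pROC::roc(response = lab, predictor = v, levels = c("control", "cancer"),
                 direction = "<", quiet = TRUE)
  expect_equal(rocAuc(v, lab)$auc, as.numeric(pROC::auc(r)))
  expect_error(rocAuc(1:3, rep("cancer", 3)), "both classes")
})

test_that("per-10k ranking follows planted CTC fractions", {
  planted <- c(2, 10, 40, 120)
  p10 <- vapply(seq_along(planted), function(i) {
    sim <- simEvents(nCaptured = 5000, nPlanted = planted[i], seed = 200 + i)
    classifyEvents(sim$events)$per10k
  }, numeric(1))
  expect_equal(order(p10), order(planted))
})

test_that("the group test reproduces classical ANOVA and Tukey results", {
  # identical groups: zero between-group variance
  same <- c(1, 2, 3)
  g0 <- groupTest(rep(same, 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(g0$F, 0)
  expect_equal(g0$p, 1)
  expect_true(all(g0$tukey$p_adj > 0.99))

  # two groups: F equals the squared equal-variance t statistic
  set.seed(35)
  x <- rnorm(8, 0); y <- rnorm(9, 1)
  gt <- groupTest(c(x, y), rep(c("a", "b"), c(8, 9)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(gt$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(gt$p, tt$p.value, tolerance = 1e-10)

  # three groups: F from textbook sums of squares
  vals <- c(4.1, 5.2, 4.8, 6.0, 7.1, 6.5, 9.0, 8.2, 8.8)
  grp <- rep(c("a", "b", "c"), each = 3)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  fOracle <- (ssb / 2) / (ssw / 6)
  g3 <- groupTest(vals, grp)
  expect_equal(g3$F, fOracle, tolerance = 1e-10)
  expect_equal(g3$p, pf(fOracle, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(nrow(g3$tukey), 3) # all pairwise contrasts
  expect_error(groupTest(1:4, rep("a", 4)), "two groups")
  expect_error(groupTest(1:3, c("a", "a", "b")), "at least two values")

  # Mann-Whitney alternative for two-group count data
  mw <- groupTest(c(x, y), rep(c("a", "b"), c(8, 9)), method = "wilcox")
  wt <- wilcox.test(x, y, exact = FALSE)
  expect_equal(mw$W, unname(wt$statistic))
  expect_equal(mw$p, wt$p.value)
  expect_error(groupTest(vals, grp, method = "wilcox"), "exactly two")
})
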