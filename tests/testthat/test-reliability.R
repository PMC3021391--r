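mkPanel <- function(valsA, valsB, parameter = "A.PFC->preSMA",
                    group = "OC") {
  n <- length(valsA)
  rbind(
    data.frame(subject = sprintf("s%02d", 1:n), group = group, session = "A",
               parameter = parameter, value = valsA),
    data.frame(subject = sprintf("s%02d", 1:n), group = group, session = "B",
               parameter = parameter, value = valsB))
}

test_that("cross-session correlations report r-squared / rho with the documented edge cases", {
  set.seed(1)
  a <- rnorm(15)
  p <- mkPanel(a, a)
  expect_equal(crossSessionCorrelation(p, "A.PFC->preSMA")$estimate, 1)
  pneg <- mkPanel(a, -a)
  expect_equal(crossSessionCorrelation(pneg, "A.PFC->preSMA", "spearman")$estimate, -1)
  expect_error(crossSessionCorrelation(mkPanel(a, rep(1, 15)), "A.PFC->preSMA"),
               "constant")

  # brute-force rank-correlation oracle on random 15-pair vectors
  b <- rnorm(15)
  sp <- crossSessionCorrelation(mkPanel(a, b), "A.PFC->preSMA", "spearman")
  rankCor <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(sp$estimate, rankCor(a, b), tolerance = 1e-12)
})

test_that("sign-consistency chi-squared reproduces the half-up rounding convention and is symmetric", {
  s1 <- signConsistencyTest(11, 15)
  expect_equal(s1$chiSqReported, 3.3)
  expect_equal(s1$df, 1L)
  expect_equal(roundHalfUp(s1$p, 2), 0.07)

  expect_equal(signConsistencyTest(11, 16)$chiSqReported, 2.3)  # 2.25 rounds up
  expect_equal(signConsistencyTest(8, 16)$chiSq, 0)
  expect_equal(signConsistencyTest(10, 15)$chiSqReported, 1.7)

  # symmetry: preserving k of n is as surprising as preserving n - k
  for (n in c(15, 16)) for (k in 0:n)
    expect_equal(signConsistencyTest(k, n)$chiSq,
                 signConsistencyTest(n - k, n)$chiSq)
  expect_error(signConsistencyTest(12, 11), "0\\.\\.nTotal")
})

test_that("repeated-measures ANOVA recovers injected connection effects and nulls", {
  set.seed(42)
  nSub <- 15
  conns <- paste0("A.c", 1:4)
  base <- expand.grid(subject = sprintf("s%02d", 1:nSub),
                      session = c("A", "B"), parameter = conns,
                      stringsAsFactors = FALSE)
  base$group <- "OC"

  # identical values everywhere -> all F = 0
  base$value <- 1
  av0 <- parameterAnova(base)
  expect_true(all(av0$F == 0))
  expect_true(all(av0$p == 1))

  # a pure connection effect at n = 15 is detected; other effects are not
  eff <- c(0, 0.3, 0.6, 0.9)[match(base$parameter, conns)]
  base$value <- eff + rnorm(nrow(base), 0, 0.1)
  av <- parameterAnova(base)
  pConn <- av$p[av$effect == "connection"]
  expect_lt(pConn, 0.001)
  expect_gt(min(av$p[av$effect %in% c("session", "session:connection")]), 0.05)

  # permuting connection labels within subject x session (balance
  # preserved) abolishes the effect most of the time
  set.seed(7)
  pPerm <- replicate(10, {
    perm <- base
    key <- interaction(perm$subject, perm$session)
    for (ii in split(seq_len(nrow(perm)), key))
      perm$parameter[ii] <- sample(perm$parameter[ii])
    avp <- parameterAnova(perm)
    avp$p[avp$effect == "connection"][1]
  })
  expect_gt(mean(pPerm > 0.05), 0.7)

  # unbalanced panels are rejected
  expect_error(parameterAnova(base[-1, ]), "unbalanced")
})

test_that("Greenhouse-Geisser correction runs and never reports smaller p than uncorrected", {
  skip_if_not_installed("car")
  set.seed(3)
  conns <- paste0("A.c", 1:3)
  d <- expand.grid(subject = sprintf("s%02d", 1:12), session = c("A", "B"),
                   parameter = conns, stringsAsFactors = FALSE)
  d$group <- rep(c("OC", "PD"), each = 6)[match(d$subject,
                                                sprintf("s%02d", 1:12))]
  d$value <- rnorm(nrow(d)) + 0.5 * (d$parameter == "A.c2")
  avGG <- parameterAnova(d, correction = "GG")
  avU <- parameterAnova(d, correction = "none")
  expect_true(all(c("connection", "session") %in% avGG$effect))
  pU <- avU$p[avU$effect == "connection"]
  pG <- avGG$p[avGG$effect == "connection"]
  expect_gte(pG + 1e-12, pU)
})

test_that("posterior-correlation group summaries: means, t-maps, Bonferroni masks, negativity fraction", {
  # all-identity matrices: zero off-diagonal means, nothing significant
  idm <- replicate(5, diag(3), simplify = FALSE)
  s0 <- posteriorCorrGroupSummary(idm)
  expect_true(all(s0$mean[upper.tri(s0$mean)] == 0))
  expect_false(any(s0$bonferroniMask))
  expect_equal(s0$nUnique, 3)

  # constant +0.2 off-diagonal with jitter, n = 15: all elements significant
  set.seed(5)
  mats <- replicate(15, {
    m <- diag(4)
    m[upper.tri(m)] <- 0.2 + rnorm(6, 0, 0.02)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }, simplify = FALSE)
  s1 <- posteriorCorrGroupSummary(mats)
  expect_equal(s1$nUnique, 6)
  expect_true(all(s1$bonferroniMask))
  expect_equal(s1$fractionNegative, 0)

  # closed-form oracle for the constant-shift t statistic
  v <- vapply(mats, function(m) m[1, 2], numeric(1))
  expect_equal(unname(s1$t[1]), mean(v) / (sd(v) / sqrt(15)), tolerance = 1e-12)

  expect_error(posteriorCorrGroupSummary(list(diag(3), diag(4))), "shape")
})

test_that("between-session matrix agreement uses rank correlation over unique elements", {
  m <- matrix(rnorm(16), 4); m <- (m + t(m)) / 2; diag(m) <- 1
  expect_equal(matrixSessionAgreement(m, m)$rho, 1)
  ag <- matrixSessionAgreement(m, m * 2)  # monotone transform
  expect_equal(ag$rho, 1)
  expect_equal(ag$nElements, 6)

  # independent random matrices: |rho| small on average (permutation null)
  set.seed(9)
  rhos <- replicate(50, {
    a <- matrix(rnorm(36), 6); b <- matrix(rnorm(36), 6)
    matrixSessionAgreement(a, b)$rho
  })
  expect_lt(abs(mean(rhos)), 0.15)
  expect_error(matrixSessionAgreement(m, diag(3)), "shape")
})

test_that("bilinear/intrinsic ratios guard against near-zero intrinsic weights", {
  m <- buildModel("E", 2)
  pri <- defaultPriors(m)
  nm <- pri$names
  ep <- setNames(rep(0.2, length(nm)), nm)
  ep["B.PFC->preSMA"] <- 0.06
  ep["B.preSMA->PFC"] <- 0.05
  ep["A.preSMA->PFC"] <- 1e-9  # degenerate denominator
  fit <- new("DcmFit", modelId = "E2", paramNames = nm, Ep = ep,
             Cp = diag(length(nm)), F = 0, accuracy = 0, complexity = 0,
             sigma2 = setNames(rep(1, 4), dcmRegions()), trace = 0,
             nIter = 1L, converged = TRUE)
  rat <- bilinearRatio(fit)
  expect_equal(rat[["B.PFC->preSMA"]], 0.06 / 0.2)
  expect_true(is.na(rat[["B.preSMA->PFC"]]))
})

test_that("KS normality checks pass Gaussian samples and flag gross non-normality", {
  set.seed(2)
  g <- ksNormality(rnorm(62))
  expect_gt(g$p, 0.05)
  e <- ksNormality(rexp(200))
  expect_lt(e$p, 0.05)
  expect_equal(g$n, 62)
})

test_that("reliability statistics are invariant to subject relabelling", {
  set.seed(13)
  a <- rnorm(12); b <- 0.5 * a + rnorm(12, 0, 0.5)
  p1 <- mkPanel(a, b)
  perm <- sample(12)
  p2 <- mkPanel(a[perm], b[perm])
  r1 <- crossSessionCorrelation(p1, "A.PFC->preSMA")
  r2 <- crossSessionCorrelation(p2, "A.PFC->preSMA")
  expect_equal(r1$estimate, r2$estimate)
  expect_equal(r1$p, r2$p)
})
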