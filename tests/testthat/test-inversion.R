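test_that("variational Laplace reproduces the closed-form evidence of a conjugate linear-Gaussian model", {
  set.seed(42)
  n <- 40; p <- 3
  X <- cbind(1, rnorm(n), rnorm(n))
  s2 <- 0.5^2
  m0 <- rep(0, p)
  S0 <- diag(c(1, 0.5, 0.25))
  theta <- c(0.4, -0.3, 0.2)
  y <- as.vector(X %*% theta) + rnorm(n, 0, sqrt(s2))

  fit <- vlFit(function(th) as.vector(X %*% th), y, m0, S0,
               sigma2 = s2, estimateNoise = FALSE)

  # independent conjugate oracle: y ~ N(X m0, X S0 X' + s2 I)
  Sy <- X %*% S0 %*% t(X) + diag(s2, n)
  logEv <- as.numeric(
    -0.5 * n * log(2 * pi) -
      0.5 * determinant(Sy, logarithm = TRUE)$modulus -
      0.5 * t(y - X %*% m0) %*% solve(Sy, y - X %*% m0))
  expect_equal(fit$F, logEv, tolerance = 1e-3)

  # posterior matches the conjugate posterior
  P <- crossprod(X) / s2 + solve(S0)
  expect_equal(fit$Ep, as.vector(solve(P, crossprod(X, y) / s2)),
               tolerance = 1e-6)
  expect_equal(fit$Cp, solve(P), tolerance = 1e-6)
})

test_that("free energy decomposes exactly as accuracy minus complexity, with non-negative complexity", {
  m <- buildModel("C", 2)
  p <- groupMeanParams(m)
  d <- quickDesign(6, nVolumes = 30, seed = 8)
  y <- simulateBold(m, p, d, noiseSd = 0.1, seed = 3)
  fit <- invertSession(m, y, design = d)
  expect_equal(fit@F, fit@accuracy - fit@complexity, tolerance = 1e-10)
  expect_gte(fit@complexity, 0)
  # Cp is a valid covariance: symmetric positive semi-definite
  ev <- eigen(fit@Cp, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("data generated at the prior mean leave the posterior mode at the prior mean", {
  m <- buildModel("C", 2)
  d <- quickDesign(8, nVolumes = 40, seed = 8)
  p <- groupMeanParams(m)
  y <- simulateBold(m, p, d, noiseSd = 0.02, seed = 5)

  # priors centred on the generating parameters: no displacement to learn
  pri <- defaultPriors(m)
  nmC <- modelParamNames(m, hemo = FALSE)
  truth <- c(p$A[which(m@aMask == 1)], p$B[which(m@bMask == 1)],
             p$C[which(m@cMask == 1)])
  pri$mean[nmC] <- truth
  fitMatched <- invertSession(m, y, design = d, priors = pri)
  # the mode stays at the prior mean up to posterior uncertainty (weakly
  # identified directions legitimately wander within their credible range)
  dev <- posteriorMean(fitMatched)[nmC] - truth
  psd <- sqrt(diag(posteriorCov(fitMatched))[nmC])
  expect_lt(max(abs(dev) / psd), 3)
  expect_lt(median(abs(dev)), 0.05)

  # the same data seen from the default zero-centred prior must pay a
  # larger complexity (the posterior has further to travel)
  fitDefault <- invertSession(m, y, design = d)
  expect_lt(fitMatched@complexity, fitDefault@complexity)
})

test_that("the free-energy trace is non-decreasing over accepted iterations", {
  m <- buildModel("E", 1)
  p <- groupMeanParams(m)
  d <- quickDesign(8, nVolumes = 35, seed = 9)
  y <- simulateBold(m, p, d, noiseSd = 0.15, seed = 2)
  fit <- invertSession(m, y, design = d)
  tr <- freeEnergyCurve(fit)
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) >= -1e-6))
  expect_gte(tr[length(tr)], tr[1])
})

test_that("a strong positive bilinear effect is recovered with the right sign", {
  m <- buildModel("C", 2)  # single bilinear term PFC->preSMA
  p <- groupMeanParams(m)
  p$B["preSMA", "PFC"] <- 0.15
  d <- quickDesign(12, nVolumes = 60, seed = 10)
  yClean <- simulateBold(m, p, d, noiseSd = 0)
  noiseSd <- sd(sweep(yClean, 2, colMeans(yClean))) / 2  # SNR 2
  signs <- vapply(1:6, function(s) {
    y <- yClean + matrix(rnorm(length(yClean), 0, noiseSd) , nrow(yClean))
    fit <- invertSession(m, y, design = d)
    sign(posteriorMean(fit)[["B.PFC->preSMA"]])
  }, numeric(1))
  expect_true(mean(signs > 0) >= 5 / 6)
})

test_that("posterior correlation normalises covariance, flags degenerate variances, and counts E2's 78 unique pairs", {
  cp <- matrix(c(4, -2, -2, 4), 2, 2,
               dimnames = list(c("A.x", "A.y"), c("A.x", "A.y")))
  cc <- posteriorCorrelation(cp)
  expect_equal(diag(cc), c(A.x = 1, A.y = 1))
  expect_equal(cc[1, 2], -0.5)

  dg <- diag(c(1, 2, 3))
  dimnames(dg) <- list(c("A.a", "B.b", "C.c"), c("A.a", "B.b", "C.c"))
  expect_equal(posteriorCorrelation(dg), diag(3) + 0,
               ignore_attr = TRUE)

  dg0 <- dg; dg0[2, 2] <- 0
  expect_warning(cc0 <- posteriorCorrelation(dg0), "zero posterior variance")
  expect_true(is.na(cc0[2, 2]))

  # an E2 inversion exposes 13 connectivity parameters = 78 unique pairs
  m <- buildModel("E", 2)
  p <- groupMeanParams(m)
  d <- quickDesign(6, nVolumes = 30, seed = 3)
  y <- simulateBold(m, p, d, noiseSd = 0.1, seed = 1)
  fit <- invertSession(m, y, design = d)
  cc2 <- posteriorCorrelation(fit)
  expect_equal(dim(cc2), c(13, 13))
  expect_equal(sum(upper.tri(cc2)), 78)
  expect_true(all(abs(cc2[is.finite(cc2)]) <= 1 + 1e-10))
})

test_that("evidence discriminates the generating model on short sessions", {
  # E1 vs E2 differ in which pair the context modulates; with strong
  # modulation and moderate noise the truth should win per session
  ms <- buildModelSpace()
  d <- quickDesign(12, nVolumes = 60, seed = 6)
  p <- groupMeanParams(ms$E1)
  p$B[p$B != 0] <- 0.15
  yClean <- simulateBold(ms$E1, p, d, noiseSd = 0)
  noiseSd <- sd(sweep(yClean, 2, colMeans(yClean))) / 2
  dF <- vapply(1:4, function(s) {
    set.seed(100 + s)
    y <- yClean + matrix(rnorm(length(yClean), 0, noiseSd), nrow(yClean))
    invertSession(ms$E1, y, design = d)@F -
      invertSession(ms$E2, y, design = d)@F
  }, numeric(1))
  expect_gt(median(dF), 0)
})
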