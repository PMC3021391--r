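test_that("designs have the right trial counts, span and seeded determinism", {
  d <- buildDesign(40, soa = 2.5, seed = 1)
  expect_length(d$onsets, 120)
  expect_equal(max(d$onsets) + d$soa, 300)
  expect_equal(as.vector(table(d$condition)), c(40, 40, 40))
  expect_true(all(diff(d$onsets) > 0))
  d2 <- buildDesign(40, soa = 2.5, seed = 1)
  expect_identical(d, d2)
  d3 <- buildDesign(1, soa = 2.5, seed = 7)
  expect_length(d3$onsets, 3)
  expect_equal(sum(d3$condition == "chosen"), 1)
})

test_that("microtime inputs are box-cars with the expected duty cycle", {
  d <- buildDesign(40, seed = 2)
  inp <- buildInputs(d, dtMicro = 0.1)
  # 80 active trials x 1 s over 300 s
  expect_equal(mean(inp$u[, 1]), 80 / 300, tolerance = 1e-10)
  expect_equal(sum(inp$u[, 2] > 0) * 0.1, 40, tolerance = 1e-8)
  # u2 nonzero only where u1 active
  expect_true(all(inp$u[inp$u[, 2] != 0, 1] == 1))

  # each 1-s trial occupies exactly 10 bins at dt 0.1
  d1 <- quickDesign(1, nVolumes = 10, seed = 3)
  i1 <- buildInputs(d1, 0.1)
  expect_equal(sum(i1$u[, 1] > 0), 10 * sum(d1$condition != "null"))

  # all-null design produces no deflection
  dn <- quickDesign(2, nVolumes = 10)
  dn$condition[] <- "null"
  expect_true(all(buildInputs(dn, 0.1)$u == 0))

  expect_error(buildInputs(d, -0.1), "positive")
  expect_error(buildInputs(d, 0.3), "divide")
})

test_that("the bilinear state equation has the documented fixed point, input gain and modulation", {
  m <- buildModel("E", 2)
  p <- groupMeanParams(m)
  expect_equal(neuralDerivative(rep(0, 4), c(0, 0), p), rep(0, 4))
  # input injection: dz_PFC = C * u1 at z = 0
  expect_equal(neuralDerivative(rep(0, 4), c(1, 0), p),
               c(0.1, 0, 0, 0))
  # u2 = 1 doubles the effective PFC->preSMA coupling when B = A there
  p2 <- p
  p2$B["preSMA", "PFC"] <- p2$A["preSMA", "PFC"]
  z <- c(1, 0, 0, 0)
  d0 <- neuralDerivative(z, c(0, 0), p2)
  d1 <- neuralDerivative(z, c(0, 1), p2)
  expect_equal(d1[3] - d0[3], p2$A["preSMA", "PFC"], tolerance = 1e-12)
  # finite-difference oracle on the u2 direction of the vector field
  h <- 1e-6
  fd <- (neuralDerivative(z, c(0, h), p2) - d0) / h
  expect_equal(fd, as.vector(p2$B %*% z + p2$C[, 2]), tolerance = 1e-6)
  expect_error(neuralDerivative(c(NA, 0, 0, 0), c(0, 0), p), "non-finite")
})

test_that("simulated BOLD is zero for null designs, seed-deterministic, and mask-checked", {
  m <- buildModel("E", 2)
  p <- groupMeanParams(m)
  dn <- quickDesign(2, nVolumes = 15)
  dn$condition[] <- "null"
  y0 <- simulateBold(m, p, dn, noiseSd = 0)
  expect_true(all(abs(y0) < 1e-12))

  d <- quickDesign(6, nVolumes = 25)
  y1 <- simulateBold(m, p, d, noiseSd = 0.1, seed = 11)
  y2 <- simulateBold(m, p, d, noiseSd = 0.1, seed = 11)
  expect_identical(y1, y2)
  y3 <- simulateBold(m, p, d, noiseSd = 0.1, seed = 12)
  expect_false(identical(y1, y3))

  # parameters outside the masks are rejected
  bad <- p
  bad$B["M1", "PM"] <- 0.1
  expect_error(connectivityParams(m, A = p$A, B = bad$B, C = p$C), "bMask")
})

test_that("halving the integration step changes the output by far less than 1e-3 of signal range", {
  m <- buildModel("E", 2)
  p <- groupMeanParams(m)
  d <- quickDesign(4, nVolumes = 20, seed = 5)
  y1 <- simulateBold(m, p, d, noiseSd = 0, dtMicro = 0.1)
  y2 <- simulateBold(m, p, d, noiseSd = 0, dtMicro = 0.05)
  rng <- diff(range(y1))
  expect_lt(max(abs(y1 - y2)) / rng, 1e-3)
})

test_that("with no bilinear terms the response is linear in the driving input to first order", {
  m <- buildModel("C", 2)
  p <- groupMeanParams(m)
  p$B[] <- 0
  # small driving input so the (weakly nonlinear) haemodynamics stay in
  # their linear range; neural dynamics are exactly linear when B = 0
  p$C <- p$C / 5
  d <- quickDesign(5, nVolumes = 20, seed = 4)
  pHalf <- p; pHalf$C <- p$C / 2
  yFull <- simulateBold(m, p, d, noiseSd = 0)
  yHalf <- simulateBold(m, pHalf, d, noiseSd = 0)
  expect_equal(yFull, 2 * yHalf, tolerance = 0.02)
})

test_that("haemodynamic states return to baseline within 1% by 30 s after the last stimulus", {
  # couplings silenced so the neural state decays at the fast self-decay
  # rate and the tail reflects the haemodynamic (balloon) relaxation
  m <- buildModel("E", 2)
  p <- connectivityParams(m, C = ifelse(m@cMask == 1, 0.1, 0))
  d <- quickDesign(1, nVolumes = 100, seed = 2)
  y <- simulateBold(m, p, d, noiseSd = 0)
  lastOff <- max(d$onsets[d$condition != "null"]) + 1
  tail <- y[seq_len(nrow(y)) * d$tr > lastOff + 30, ]
  expect_lt(max(abs(tail)), 0.01 * max(abs(y)))
})

test_that("divergent parameter sets are reported as unstable", {
  m <- buildModel("E", 2)
  p <- groupMeanParams(m)
  p$A[m@aMask == 1] <- 3  # strongly coupled, positive feedback loops
  p$sigmaSelf <- 1e-3
  p <- connectivityParams(m, A = p$A * m@aMask, B = p$B, C = p$C,
                          sigmaSelf = 1e-3)
  d <- quickDesign(8, nVolumes = 40)
  expect_error(simulateBold(m, p, d, noiseSd = 0), "unstable")
})
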