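# Shared fixtures: small designs and group-mean parameter sets so unit
# tests stay fast (short sessions, few trials).

quickDesign <- function(nPer = 10, nVolumes = 40, seed = 1) {
  buildDesign(nPer, soa = 2.5, seed = seed, duration = 1, tr = 2,
              nVolumes = nVolumes)
}

# group-mean connectivity for a model: forward 0.20, backward 0.10 Hz
# intrinsic; bilinear 0.06 forward / 0.05 backward; driving 0.10 Hz
groupMeanParams <- function(model) {
  rost <- c(PFC = 1, PM = 2, preSMA = 2, M1 = 3)
  rg <- dcmRegions()
  A <- matrix(0, 4, 4, dimnames = list(rg, rg))
  B <- matrix(0, 4, 4, dimnames = list(rg, rg))
  for (i in 1:4) for (j in 1:4) if (model@aMask[i, j] == 1) {
    fw <- if (rost[rg[j]] != rost[rg[i]]) rost[rg[j]] < rost[rg[i]]
          else rg[j] == "preSMA"
    A[i, j] <- if (fw) 0.20 else 0.10
    if (model@bMask[i, j] == 1) B[i, j] <- if (fw) 0.06 else 0.05
  }
  C <- ifelse(model@cMask == 1, 0.10, 0)
  dimnames(C) <- list(rg, c("u1", "u2"))
  connectivityParams(model, A = A, B = B, C = C)
}

# tiny cohort config for pipeline tests (short sessions)
tinyConfig <- function(nYoung = 0, nOC = 2, nPD = 0, snr = 2) {
  defaultStudyConfig(nYoung = nYoung, nOC = nOC, nPD = nPD, snr = snr,
                     nPerCondition = 8, nVolumes = 40)
}

expect_silent_numeric <- function(x) {
  expect_true(all(is.finite(x)))
}

# independent Gibbs-sampling oracle for the hierarchical Dirichlet model:
# alternates model assignments m_n | r and r | counts
gibbsRfx <- function(f, a0 = 1, nSamp = 30000, burn = 3000, seed = 1) {
  set.seed(seed)
  n <- nrow(f); K <- ncol(f)
  r <- rep(1 / K, K)
  acc <- numeric(K)
  for (it in seq_len(nSamp + burn)) {
    lg <- sweep(f, 2, log(r), `+`)
    lg <- lg - apply(lg, 1, max)
    pr <- exp(lg) / rowSums(exp(lg))
    mAssign <- apply(pr, 1, function(p) sample.int(K, 1, prob = p))
    counts <- tabulate(mAssign, K)
    gam <- rgamma(K, a0 + counts)
    r <- gam / sum(gam)
    if (it > burn) acc <- acc + r
  }
  acc / nSamp
}
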