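# Model inversion: shrinkage priors over the masked connectivity and
# haemodynamic scaling parameters, variational-Laplace estimation, and
# posterior summaries.

#' Shrinkage priors for a model's free parameters
#'
#' Masked A, B and C entries get zero-mean Gaussian priors with variances
#' 1/16 (A, off-diagonal), 1/16 (B) and 1/32 (C).  The haemodynamic signal
#' decay and transit time are estimated as log-scaling factors around their
#' defaults with prior variance 1/64.  Observation noise is handled by
#' per-region variance hyperparameters estimated by EM, not by the prior.
#'
#' @param model a [DcmModel-class].
#' @param varA,varB,varC,varH prior variances for the parameter classes.
#' @return list with `mean`, `cov` (diagonal), `names`.
#' @export
defaultPriors <- function(model, varA = 1 / 16, varB = 1 / 16,
                          varC = 1 / 32, varH = 1 / 64) {
  nm <- modelParamNames(model)
  v <- numeric(length(nm))
  v[startsWith(nm, "A.")] <- varA
  v[startsWith(nm, "B.")] <- varB
  v[startsWith(nm, "C.")] <- varC
  v[startsWith(nm, "h.")] <- varH
  list(mean = stats::setNames(numeric(length(nm)), nm),
       cov = diag(v, length(nm)), names = nm)
}

# theta vector <-> connectivity matrices (column-major over mask support,
# same order as modelParamNames)
.thetaToParams <- function(theta, model, sigmaSelf = 0.5) {
  nA <- sum(model@aMask); nB <- sum(model@bMask); nC <- sum(model@cMask)
  A <- matrix(0, 4, 4); B <- matrix(0, 4, 4); C <- matrix(0, 4, 2)
  A[which(model@aMask == 1)] <- theta[seq_len(nA)]
  B[which(model@bMask == 1)] <- theta[nA + seq_len(nB)]
  C[which(model@cMask == 1)] <- theta[nA + nB + seq_len(nC)]
  list(A = A, B = B, C = C, sigmaSelf = sigmaSelf,
       hScale = theta[nA + nB + nC + 1:2])
}

#' Invert one model on one session
#'
#' Estimates the posterior density over the model's free parameters and the
#' free-energy bound on log model evidence, by variational Laplace /
#' expectation maximisation (Gauss-Newton updates of the posterior mode,
#' EM updates of per-region noise variances, Levenberg damping on rejected
#' steps).  A constant and a linear drift are projected out of data and
#' prediction per region before the likelihood is evaluated.
#'
#' @param model a [DcmModel-class].
#' @param session a [DcmSession-class] (or a plain volumes x 4 matrix, in
#'   which case `design` must be given).
#' @param design event design; defaults to the session's own design.
#' @param priors from [defaultPriors()]; NULL = defaults for `model`.
#' @param sigmaSelf fixed self-decay rate (Hz).
#' @param hemo haemodynamic defaults around which the log-scales act.
#' @param dtMicro integration step (s).
#' @param centreU2 contextual-input centring convention (must match the
#'   convention used for simulation).
#' @param maxIter,tol convergence controls passed to [vlFit()].
#' @return a [DcmFit-class].
#' @export
#' @examples
#' \donttest{
#' m <- buildModel("E", 2)
#' d <- buildDesign(10, seed = 1, nVolumes = 40)
#' p <- connectivityParams(m,
#'   A = 0.2 * m@aMask, B = 0.05 * m@bMask, C = 0.1 * m@cMask)
#' y <- simulateBold(m, p, d, noiseSd = 0.02, seed = 2)
#' fit <- invertSession(m, y, design = d)
#' freeEnergy(fit)
#' }
invertSession <- function(model, session, design = NULL, priors = NULL,
                          sigmaSelf = 0.5, hemo = defaultHemoParams(),
                          dtMicro = 0.1, centreU2 = FALSE, maxIter = 64,
                          tol = 1e-2) {
  if (methods::is(session, "DcmSession")) {
    y <- session@y
    if (is.null(design)) design <- session@design
  } else {
    y <- session
    if (is.null(design)) stop("design required when session is a matrix")
  }
  stopifnot(nrow(y) == design$nVolumes)
  if (is.null(priors)) priors <- defaultPriors(model)

  inputs <- buildInputs(design, dtMicro, centreU2)
  nVol <- design$nVolumes
  g <- function(theta) {
    pr <- .thetaToParams(theta, model, sigmaSelf)
    h <- hemo
    h["kappa"] <- h["kappa"] * exp(pr$hScale[1])
    h["tau"] <- h["tau"] * exp(pr$hScale[2])
    as.vector(.integrate(pr, h, inputs, design$tr, nVol))
  }

  region <- factor(rep(dcmRegions(), each = nVol), levels = dcmRegions())
  tcov <- scale(seq_len(nVol))[, 1]
  X <- matrix(0, 4 * nVol, 8)
  for (r in 1:4) {
    rows <- (r - 1) * nVol + seq_len(nVol)
    X[rows, 2 * r - 1] <- 1
    X[rows, 2 * r] <- tcov
  }

  fit <- vlFit(g, as.vector(y), priors$mean, priors$cov, noiseGroup = region,
               confounds = X, maxIter = maxIter, tol = tol)
  methods::new("DcmFit", modelId = model@modelId, paramNames = priors$names,
               Ep = stats::setNames(fit$Ep, priors$names), Cp = (fit$Cp + t(fit$Cp)) / 2,
               F = fit$F, accuracy = fit$accuracy, complexity = fit$complexity,
               sigma2 = stats::setNames(fit$sigma2, dcmRegions()),
               trace = fit$trace, nIter = as.integer(fit$nIter),
               converged = fit$converged)
}

#' Per-iteration free-energy trace of an inversion
#'
#' @param fit a [DcmFit-class].
#' @return numeric vector of accepted free-energy values, one per
#'   iteration (a rejected step repeats the previous value).
#' @export
freeEnergyCurve <- function(fit) {
  stopifnot(methods::is(fit, "DcmFit"))
  fit@trace
}

#' Posterior correlation matrix over connectivity parameters
#'
#' Normalises the posterior covariance to a correlation matrix, restricted
#' by default to the connectivity and input parameters (A, B, C), the basis
#' of the identifiability analysis.
#'
#' @param fit a [DcmFit-class], or a covariance matrix with dimnames.
#' @param which regex of parameter names to keep.
#' @return correlation matrix (unit diagonal, entries in `[-1, 1]`);
#'   zero-variance parameters yield `NA` entries with a warning.
#' @export
posteriorCorrelation <- function(fit, which = "^[ABC]\\.") {
  cp <- if (methods::is(fit, "DcmFit")) posteriorCov(fit) else fit
  keep <- grepl(which, rownames(cp))
  cp <- cp[keep, keep, drop = FALSE]
  s <- sqrt(diag(cp))
  if (any(s <= 0)) warning("zero posterior variance: undefined correlations flagged as NA")
  s[s <= 0] <- NA_real_
  cc <- cp / outer(s, s)
  diag(cc) <- ifelse(is.na(s), NA_real_, 1)
  cc
}
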