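# Forward model: event design -> exogenous inputs -> bilinear neural
# dynamics -> balloon haemodynamics -> sampled noisy BOLD.

#' Default balloon-model haemodynamic parameters
#'
#' Canonical values for the haemodynamic transform: signal decay `kappa`
#' (1/s), autoregulatory feedback `gamma` (1/s), mean transit time `tau`
#' (s), vessel stiffness exponent `alpha`, resting oxygen extraction
#' fraction `E0` and resting venous blood volume fraction `V0`.
#'
#' @return named numeric vector of the six parameters.
#' @export
defaultHemoParams <- function() {
  c(kappa = 0.64, gamma = 0.32, tau = 2.0, alpha = 0.32, E0 = 0.32, V0 = 0.04)
}

#' Build a randomly intermixed event design
#'
#' Emulates the action-selection paradigm: equal numbers of "specified",
#' "chosen" and null trials presented at a fixed stimulus onset asynchrony
#' in a seeded random order.  Null trials produce no input deflection.
#'
#' @param nPerCondition trials per condition (study value: 40).
#' @param soa stimulus onset asynchrony, seconds (study value: 2.5).
#' @param seed integer RNG seed for the trial order.
#' @param duration cue duration, seconds (study value: 1).
#' @param tr repetition time, seconds (study value: 2).
#' @param nVolumes retained volumes (study value: 150).
#' @return a `StimDesign`: list with `onsets`, `durations`, `condition`
#'   (factor specified/chosen/null), `soa`, `tr`, `nVolumes`.
#' @export
#' @examples
#' d <- buildDesign(40, seed = 1)
#' table(d$condition)
buildDesign <- function(nPerCondition, soa = 2.5, seed = 1, duration = 1,
                        tr = 2, nVolumes = 150) {
  stopifnot(nPerCondition >= 1, soa > 0, duration > 0, tr > 0)
  # seeded permutation without disturbing the global RNG stream
  cond <- rep(c("specified", "chosen", "null"), each = nPerCondition)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  cond <- sample(cond)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  n <- length(cond)
  list(onsets = (seq_len(n) - 1) * soa,
       durations = rep(duration, n),
       condition = factor(cond, levels = c("specified", "chosen", "null")),
       soa = soa, tr = tr, nVolumes = nVolumes)
}

#' Expand an event design into microtime input functions
#'
#' Input 1 is a box-car indicating any non-null trial; input 2 indicates
#' chosen trials (the psychological context).  By default input 2 is a 0/1
#' indicator; `centreU2 = TRUE` subtracts its mean over active bins of u1.
#'
#' @param design a `StimDesign` from [buildDesign()].
#' @param dtMicro microtime bin width in seconds; must divide `tr`.
#' @param centreU2 mean-centre the contextual input (default FALSE).
#' @return list with `u` (nSteps x 2 matrix), `dtMicro`, `times`.
#' @export
buildInputs <- function(design, dtMicro = 0.1, centreU2 = FALSE) {
  if (dtMicro <= 0) stop("dtMicro must be positive")
  ratio <- design$tr / dtMicro
  if (abs(ratio - round(ratio)) > 1e-8) stop("dtMicro must divide tr")
  nSteps <- design$nVolumes * round(ratio)
  times <- (seq_len(nSteps) - 1) * dtMicro
  u <- matrix(0, nSteps, 2, dimnames = list(NULL, c("u1", "u2")))
  active <- design$condition != "null"
  for (i in which(active)) {
    on <- design$onsets[i]
    bins <- which(times >= on - 1e-9 & times < on + design$durations[i] - 1e-9)
    u[bins, 1] <- 1
    if (design$condition[i] == "chosen") u[bins, 2] <- 1
  }
  if (centreU2 && any(u[, 1] > 0)) u[, 2] <- u[, 2] - mean(u[u[, 1] > 0, 2])
  list(u = u, dtMicro = dtMicro, times = times)
}

#' Default connectivity parameter container
#'
#' @param model a [DcmModel-class]; matrices are zero outside its masks.
#' @param A,B,C numeric matrices of coupling rates (Hz) with support equal
#'   to the model masks (A off-diagonal).
#' @param sigmaSelf positive self-decay rate (Hz) placed on the diagonal of
#'   the effective A matrix; fixed, not estimated.
#' @return list with elements `A`, `B`, `C`, `sigmaSelf`.
#' @export
connectivityParams <- function(model, A = NULL, B = NULL, C = NULL,
                               sigmaSelf = 0.5) {
  stopifnot(sigmaSelf > 0)
  z4 <- matrix(0, 4, 4, dimnames = list(dcmRegions(), dcmRegions()))
  if (is.null(A)) A <- z4
  if (is.null(B)) B <- z4
  if (is.null(C)) C <- matrix(0, 4, 2, dimnames = list(dcmRegions(), c("u1", "u2")))
  if (any(A[model@aMask == 0] != 0) || any(diag(A) != 0))
    stop("A has entries outside the model's aMask")
  if (any(B[model@bMask == 0] != 0))
    stop("B has entries outside the model's bMask")
  if (any(C[model@cMask == 0] != 0))
    stop("C has entries outside the model's cMask")
  list(A = A, B = B, C = C, sigmaSelf = sigmaSelf)
}

#' Bilinear neural state equation
#'
#' Evaluates `dz/dt = (A_eff + u2 B) z + C u` where `A_eff` is the intrinsic
#' coupling matrix with `-sigmaSelf` on the diagonal.
#'
#' @param z neural state, length-4 vector.
#' @param u exogenous input, length-2 vector `(u1, u2)`.
#' @param params a `connectivityParams()` list.
#' @return length-4 vector of state derivatives (Hz).
#' @export
neuralDerivative <- function(z, u, params) {
  if (!all(is.finite(z)) || !all(is.finite(u))) stop("non-finite inputs")
  Aeff <- params$A - diag(params$sigmaSelf, 4)
  as.vector((Aeff + u[2] * params$B) %*% z + params$C %*% u)
}

.integrate <- function(params, hemo, inputs, tr, nVolumes) {
  sampleEvery <- round(tr / inputs$dtMicro)
  Aeff <- params$A - diag(params$sigmaSelf, 4)
  res <- .dcm_integrate(Aeff, params$B, params$C, inputs$u, inputs$dtMicro,
                        as.integer(sampleEvery), as.integer(nVolumes),
                        as.numeric(hemo[c("kappa", "gamma", "tau", "alpha",
                                          "E0", "V0")]))
  if (!res$ok)
    stop("unstable dynamics: integration diverged (A diag ",
         paste(round(diag(Aeff), 3), collapse = ", "), "; max |A| ",
         round(max(abs(params$A)), 3), ")")
  y <- res$y
  colnames(y) <- dcmRegions()
  y
}

#' Simulate a noisy BOLD session from a model and parameters
#'
#' Integrates the bilinear neural dynamics and balloon haemodynamics on the
#' microtime grid (fixed-step RK4), samples the BOLD observation at the TR,
#' and adds i.i.d. Gaussian noise.  Deterministic given `seed`.
#'
#' @param model a [DcmModel-class].
#' @param params a `connectivityParams()` list respecting the model masks.
#' @param design a `StimDesign` from [buildDesign()].
#' @param noiseSd observation noise standard deviation (signal units).
#' @param seed integer RNG seed for the noise.
#' @param hemo haemodynamic parameters ([defaultHemoParams()]).
#' @param dtMicro integration step, seconds.
#' @param centreU2 passed to [buildInputs()].
#' @return numeric matrix, `nVolumes` x 4 regions, percent signal change.
#' @export
simulateBold <- function(model, params, design, noiseSd = 0, seed = 1,
                         hemo = defaultHemoParams(), dtMicro = 0.1,
                         centreU2 = FALSE) {
  inputs <- buildInputs(design, dtMicro, centreU2)
  y <- .integrate(params, hemo, inputs, design$tr, design$nVolumes)
  if (noiseSd > 0) {
    oldseed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    y <- y + matrix(stats::rnorm(length(y), 0, noiseSd), nrow(y), ncol(y))
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }
  y
}
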