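#' Canonical region order of the frontal motor network
#'
#' All connectivity matrices in the package are indexed in this fixed order:
#' dorsolateral prefrontal cortex (PFC), lateral premotor cortex (PM),
#' pre-supplementary motor area (preSMA) and primary motor cortex (M1).
#' Entry `[i, j]` of a connectivity matrix is the influence of region `j`
#' (column, source) on region `i` (row, target).
#'
#' @return Character vector of the four region labels, in canonical order.
#' @export
#' @examples
#' dcmRegions()
dcmRegions <- function() c("PFC", "PM", "preSMA", "M1")

.checkMask <- function(m, nr, nc, what) {
  if (!is.matrix(m) || nrow(m) != nr || ncol(m) != nc)
    return(sprintf("%s must be a %d x %d matrix", what, nr, nc))
  if (!all(m %in% c(0, 1)))
    return(sprintf("%s must be binary (0/1)", what))
  NULL
}

#' DcmModel: one model of the 48-model space
#'
#' A bilinear DCM structure over the four-region network: binary masks for
#' intrinsic connections (`aMask`, off-diagonal, directed), contextual
#' bilinear modulation (`bMask`, must be a subset of `aMask`) and driving
#' inputs (`cMask`, 4 x 2; input 1 = onset of any non-null trial, input 2 =
#' chosen-vs-specified context).
#'
#' @slot modelId character, e.g. `"E2"`.
#' @slot structureSet one of `"A"`..`"F"` (intrinsic connectivity structure).
#' @slot pattern integer 1..8 (contextual modulation pattern).
#' @slot aMask,bMask 4 x 4 binary matrices in canonical region order.
#' @slot cMask 4 x 2 binary matrix.
#'
#' @seealso [buildModel()], [buildModelSpace()], [countParameters()]
#' @export
setClass("DcmModel",
  representation(modelId = "character", structureSet = "character",
                 pattern = "integer", aMask = "matrix", bMask = "matrix",
                 cMask = "matrix"),
  validity = function(object) {
    errs <- c(.checkMask(object@aMask, 4, 4, "aMask"),
              .checkMask(object@bMask, 4, 4, "bMask"),
              .checkMask(object@cMask, 4, 2, "cMask"))
    if (length(errs)) return(errs)
    if (any(diag(object@aMask) != 0))
      errs <- c(errs, "aMask diagonal must be zero (self-decay is implicit)")
    if (any(object@bMask > object@aMask))
      errs <- c(errs, "bMask must be a subset of aMask")
    if (object@cMask[1, 1] != 1)
      errs <- c(errs, "every model drives PFC with the trial-onset input")
    if (length(errs)) errs else TRUE
  })

setMethod("show", "DcmModel", function(object) {
  np <- countParameters(object)
  cat(sprintf("DcmModel %s (set %s, pattern %d): %d intrinsic, %d bilinear, %d driving\n",
              object@modelId, object@structureSet, object@pattern,
              np[["nIntrinsic"]], np[["nBilinear"]], np[["nDriving"]]))
})

#' DcmSession: region time series plus event design for one subject-session
#'
#' @slot y numeric matrix, volumes x 4 regions (canonical order), BOLD signal
#'   in percent-signal-change units.
#' @slot tr repetition time in seconds.
#' @slot design a `StimDesign` (see [buildDesign()]).
#' @slot subjectId,group,session character labels (`group` in
#'   young/OC/PD, `session` in A/B/on/off).
#' @export
setClass("DcmSession",
  representation(y = "matrix", tr = "numeric", design = "list",
                 subjectId = "character", group = "character",
                 session = "character"),
  validity = function(object) {
    if (ncol(object@y) != 4) return("y must have 4 columns (regions)")
    if (!all(is.finite(object@y))) return("y must be finite")
    if (object@tr <= 0) return("tr must be positive")
    TRUE
  })

setMethod("show", "DcmSession", function(object) {
  cat(sprintf("DcmSession %s/%s/%s: %d volumes x 4 regions, TR %g s, %d trials\n",
              object@subjectId, object@group, object@session,
              nrow(object@y), object@tr, length(object@design$onsets)))
})

#' DcmFit: posterior density and free-energy decomposition of one inversion
#'
#' @slot modelId model inverted.
#' @slot paramNames names of the free parameters, e.g. `"A.PFC->preSMA"`,
#'   `"B.preSMA->PFC"`, `"C.PFC.u1"`, `"h.kappa"`.
#' @slot Ep posterior means (named).
#' @slot Cp posterior covariance over the free parameters.
#' @slot F,accuracy,complexity free-energy bound on log evidence (nats) and
#'   its decomposition `F = accuracy - complexity`.
#' @slot sigma2 per-region noise variances (ReML point estimates).
#' @slot trace accepted free-energy values per iteration.
#' @slot nIter,converged iteration count and convergence flag.
#' @export
setClass("DcmFit",
  representation(modelId = "character", paramNames = "character",
                 Ep = "numeric", Cp = "matrix", F = "numeric",
                 accuracy = "numeric", complexity = "numeric",
                 sigma2 = "numeric", trace = "numeric",
                 nIter = "integer", converged = "logical"),
  validity = function(object) {
    p <- length(object@Ep)
    if (!isTRUE(all.equal(dim(object@Cp), c(p, p))))
      return("Cp dimensions must match Ep")
    if (max(abs(object@Cp - t(object@Cp))) > 1e-8)
      return("Cp must be symmetric")
    TRUE
  })

setMethod("show", "DcmFit", function(object) {
  cat(sprintf("DcmFit of %s: F = %.2f (accuracy %.2f, complexity %.2f), %d iter%s\n",
              object@modelId, object@F, object@accuracy, object@complexity,
              object@nIter, if (object@converged) "" else " (not converged)"))
})

#' FfxResult: fixed-effects group model comparison
#'
#' @slot models model ids compared.
#' @slot sumF summed log-evidence per model (nats).
#' @slot deltaF `sumF` relative to the best model (best has 0).
#' @slot postProb posterior model probabilities (softmax of `sumF`, uniform
#'   model prior).
#' @slot ranking model ids from most to least likely.
#' @export
setClass("FfxResult",
  representation(models = "character", sumF = "numeric", deltaF = "numeric",
                 postProb = "numeric", ranking = "character"))

setMethod("show", "FfxResult", function(object) {
  cat("Fixed-effects group model comparison\n")
  df <- data.frame(model = object@models, sumF = round(object@sumF, 2),
                   deltaF = round(object@deltaF, 2),
                   postProb = round(object@postProb, 4))
  print(df[order(-df$sumF), ], row.names = FALSE)
})

#' RfxResult: hierarchical (random-effects) group model comparison
#'
#' @slot models model ids compared.
#' @slot alpha fitted Dirichlet concentration per model.
#' @slot expectedProb expected posterior model probabilities
#'   (`alpha / sum(alpha)`).
#' @slot exceedance exceedance probability per model (Monte-Carlo).
#' @slot mcse Monte-Carlo standard error of each exceedance probability.
#' @slot nMc number of Dirichlet draws; @slot seed RNG seed used.
#' @slot nIter,converged variational iterations and convergence flag.
#' @export
setClass("RfxResult",
  representation(models = "character", alpha = "numeric",
                 expectedProb = "numeric", exceedance = "numeric",
                 mcse = "numeric", nMc = "integer", seed = "integer",
                 nIter = "integer", converged = "logical"))

setMethod("show", "RfxResult", function(object) {
  cat("Random-effects (hierarchical Dirichlet) group model comparison\n")
  df <- data.frame(model = object@models, alpha = round(object@alpha, 2),
                   expectedProb = round(object@expectedProb, 4),
                   exceedance = round(object@exceedance, 4))
  print(df[order(-df$exceedance), ], row.names = FALSE)
})

#' @describeIn DcmModel model identifier accessor
#' @param object a `DcmModel`
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @export
setMethod("modelId", "DcmModel", function(object) object@modelId)
#' @export
setMethod("modelId", "DcmFit", function(object) object@modelId)

#' Free-energy bound accessor
#' @param object a `DcmFit`
#' @return the free energy (nats)
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @export
setMethod("freeEnergy", "DcmFit", function(object) object@F)

#' Posterior mean / covariance accessors
#' @param object a `DcmFit`
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))
#' @export
setMethod("posteriorMean", "DcmFit",
          function(object) stats::setNames(object@Ep, object@paramNames))

#' @rdname posteriorMean
#' @export
setGeneric("posteriorCov", function(object) standardGeneric("posteriorCov"))
#' @export
setMethod("posteriorCov", "DcmFit", function(object) {
  cp <- object@Cp
  dimnames(cp) <- list(object@paramNames, object@paramNames)
  cp
})
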