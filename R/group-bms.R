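# Group-level Bayesian model selection: fixed effects (summed log
# evidences / Group Bayes Factor) and random effects (hierarchical
# Dirichlet model with exceedance probabilities).

.metaCols <- c("session_id", "subject_id", "group", "session")

#' Assemble an evidence table from inversions
#'
#' The evidence table is a data.frame with one row per subject-session:
#' metadata columns `session_id`, `subject_id`, `group`, `session`, then
#' one column per model id holding the free-energy log-evidence estimate
#' (nats).  This layout matches its CSV serialisation
#' ([writeEvidenceCsv()]).
#'
#' @param fits list of [DcmFit-class] objects.
#' @param meta data.frame with one row per session (columns `session_id`,
#'   `subject_id`, `group`, `session`) aligned with the outer order of
#'   `fits`, or NULL when `fits` is a flat named structure.
#' @param sessionOf integer vector mapping each fit to a row of `meta`.
#' @return evidence data.frame.
#' @export
evidenceTable <- function(fits, meta, sessionOf) {
  stopifnot(length(fits) == length(sessionOf))
  models <- unique(vapply(fits, modelId, character(1)))
  tab <- meta[, .metaCols]
  for (m in models) tab[[m]] <- NA_real_
  for (k in seq_along(fits))
    tab[sessionOf[k], modelId(fits[[k]])] <- freeEnergy(fits[[k]])
  tab
}

.modelCols <- function(table, models = NULL) {
  cand <- setdiff(colnames(table), .metaCols)
  if (is.null(models)) return(cand)
  missing <- setdiff(models, cand)
  if (length(missing))
    stop("models not in evidence table: ", paste(missing, collapse = ", "))
  models
}

.evidenceMatrix <- function(table, models) {
  f <- as.matrix(table[, models, drop = FALSE])
  if (anyNA(f)) stop("missing evidence cells for the compared model set")
  storage.mode(f) <- "double"
  f
}

#' Fixed-effects group model comparison
#'
#' Sums log evidences over sessions per model (the log Group Bayes Factor
#' between two models is the difference of these sums) and converts them to
#' posterior model probabilities under a uniform model prior.
#'
#' @param table evidence table (see [evidenceTable()]).
#' @param models model ids to compare; default = all model columns.
#' @return an [FfxResult-class].
#' @export
fixedEffects <- function(table, models = NULL) {
  models <- .modelCols(table, models)
  if (length(models) < 2) stop("need at least 2 models to compare")
  if (nrow(table) < 1) stop("need at least 1 session")
  f <- .evidenceMatrix(table, models)
  sumF <- colSums(f)
  dF <- sumF - max(sumF)
  post <- exp(dF) / sum(exp(dF))
  methods::new("FfxResult", models = models, sumF = sumF, deltaF = dF,
               postProb = post, ranking = models[order(-sumF)])
}

#' Bayes factor from a log-evidence difference
#'
#' `BF = exp(F_a - F_b)`; by the conventional thresholds, BF 3-20 is
#' positive evidence, 20-150 strong, and >150 very strong (log-evidence
#' differences of about 1.1-3, 3-5 and >5).
#'
#' @param Fa,Fb log evidences (nats) of models A and B.
#' @return list with `bf`, `logBf` and `category` (evidence for A over B;
#'   `"none"` below the positive threshold).
#' @export
#' @examples
#' bayesFactor(1.0986, 0)   # BF 3, boundary of positive evidence
bayesFactor <- function(Fa, Fb) {
  stopifnot(is.finite(Fa), is.finite(Fb))
  bf <- exp(Fa - Fb)
  category <- if (bf > 150) "very strong" else if (bf >= 20) "strong"
    else if (bf >= 3) "positive" else "none"
  list(bf = bf, logBf = Fa - Fb, category = category)
}

#' Random-effects (hierarchical Dirichlet) group model comparison
#'
#' Treats the generating model as a subject-level random variable with
#' Dirichlet-distributed model probabilities.  A variational update loop
#' alternates per-subject model responsibilities (softmax of the log
#' evidence plus digamma terms) with Dirichlet count updates; exceedance
#' probabilities -- the belief that each model is more likely than any
#' other -- are computed by Monte-Carlo sampling of the fitted Dirichlet.
#'
#' @param table evidence table; each row is treated as one exchangeable
#'   subject.  With `perSubject = TRUE`, rows are first averaged within
#'   `subject_id`.
#' @param models model ids to compare; default = all model columns.
#' @param priorAlpha Dirichlet prior concentration per model (default 1,
#'   uniform).
#' @param nMc Monte-Carlo draws for the exceedance probability (>= 1000).
#' @param seed RNG seed for the Monte-Carlo step.
#' @param perSubject average sessions within subject before fitting.
#' @param tol,maxIter convergence controls for the variational loop.
#' @return an [RfxResult-class].
#' @export
randomEffects <- function(table, models = NULL, priorAlpha = 1, nMc = 1e5,
                          seed = 1, perSubject = FALSE, tol = 1e-6,
                          maxIter = 256) {
  if (nMc < 1e3) stop("nMc must be at least 1000")
  models <- .modelCols(table, models)
  if (length(models) < 2) stop("need at least 2 models to compare")
  if (perSubject) {
    f <- rowsum(as.matrix(table[, models, drop = FALSE]), table$subject_id)
    f <- f / as.vector(table(table$subject_id)[rownames(f)])
  } else {
    f <- .evidenceMatrix(table, models)
  }
  if (nrow(f) < 2) stop("need at least 2 subject rows")
  K <- ncol(f)
  n <- nrow(f)

  alpha <- rep(priorAlpha, K)
  converged <- FALSE
  iter <- 0
  while (iter < maxIter) {
    iter <- iter + 1
    lg <- sweep(f, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    gnk <- exp(lg) / rowSums(exp(lg))
    alphaNew <- priorAlpha + colSums(gnk)
    if (max(abs(alphaNew - alpha)) < tol) { alpha <- alphaNew; converged <- TRUE; break }
    alpha <- alphaNew
  }
  if (!converged) warning("random-effects variational loop did not converge")

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  draws <- matrix(stats::rgamma(nMc * K, shape = rep(alpha, each = nMc)), nMc, K)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  win <- max.col(draws, ties.method = "first")
  xp <- tabulate(win, K) / nMc

  methods::new("RfxResult", models = models, alpha = stats::setNames(alpha, models),
               expectedProb = stats::setNames(alpha / sum(alpha), models),
               exceedance = stats::setNames(xp, models),
               mcse = sqrt(xp * (1 - xp) / nMc), nMc = as.integer(nMc),
               seed = as.integer(seed), nIter = as.integer(iter),
               converged = converged)
}

#' Compare fixed- and random-effects model rankings
#'
#' Tabulates both rankings over the same model subset and flags any rank
#' disagreements between the two procedures.
#'
#' @param ffx an [FfxResult-class]; @param rfx an [RfxResult-class] over
#'   the same models.
#' @return list with `table` (model, ffxRank, rfxRank, sumF, exceedance),
#'   `agreement` (logical), `flags` (character description of any
#'   disagreements).
#' @export
selectionReport <- function(ffx, rfx) {
  if (length(ffx@models) == 0) stop("empty model subset")
  if (!setequal(ffx@models, rfx@models))
    stop("fixed- and random-effects results cover different model subsets")
  m <- ffx@models
  ffxRank <- rank(-ffx@sumF, ties.method = "first")
  rfxRank <- rank(-rfx@exceedance[m], ties.method = "first")
  tab <- data.frame(model = m, ffxRank = ffxRank, rfxRank = rfxRank,
                    sumF = ffx@sumF, postProb = ffx@postProb,
                    expectedProb = rfx@expectedProb[m],
                    exceedance = rfx@exceedance[m], row.names = NULL)
  dis <- tab$model[tab$ffxRank != tab$rfxRank]
  flags <- if (length(dis)) {
    sprintf("rank disagreement for %s: FFX order %s vs RFX order %s",
            paste(dis, collapse = ", "),
            paste(m[order(ffxRank)], collapse = " > "),
            paste(m[order(rfxRank)], collapse = " > "))
  } else character(0)
  list(table = tab[order(tab$ffxRank), ], agreement = length(dis) == 0,
       flags = flags)
}
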