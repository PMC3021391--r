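# Parameter-level reliability battery: cross-session correlations, sign
# consistency, repeated-measures ANOVA, and posterior-correlation
# (identifiability) summaries.

#' Round half away from zero
#'
#' Reported statistics are rounded half-up to a fixed number of decimals
#' (so 2.25 -> 2.3), unlike R's banker's rounding.
#'
#' @param x numeric; @param digits decimals.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Build a parameter panel from fits
#'
#' Long-format table of posterior-mean parameter values: one row per
#' subject x session x parameter, the layout used by the reliability
#' statistics and their CSV serialisation.
#'
#' @param fits list of [DcmFit-class]; @param meta data.frame aligned with
#'   `fits` (columns `subject_id`, `group`, `session`).
#' @param which regex of parameter names to keep (default: connectivity
#'   and input parameters).
#' @return data.frame with columns subject, group, session, parameter,
#'   value.
#' @export
paramPanel <- function(fits, meta, which = "^[ABC]\\.") {
  stopifnot(length(fits) == nrow(meta))
  do.call(rbind, lapply(seq_along(fits), function(k) {
    ep <- posteriorMean(fits[[k]])
    ep <- ep[grepl(which, names(ep))]
    data.frame(subject = meta$subject_id[k], group = meta$group[k],
               session = meta$session[k], parameter = names(ep),
               value = unname(ep), row.names = NULL)
  }))
}

.pairSessions <- function(panel, parameter) {
  d <- panel[panel$parameter == parameter, ]
  sess <- sort(unique(d$session))
  if (length(sess) != 2) stop("need exactly two sessions; got ",
                              paste(sess, collapse = ", "))
  a <- d[d$session == sess[1], ]
  b <- d[d$session == sess[2], ]
  common <- intersect(a$subject, b$subject)
  if (length(common) < 3) stop("need at least 3 paired subjects")
  list(a = a$value[match(common, a$subject)],
       b = b$value[match(common, b$subject)], subjects = common)
}

#' Cross-session correlation of one parameter
#'
#' Correlates a parameter's posterior means across the two sessions of the
#' paired subjects.  Pearson reports r-squared (the convention for these
#' test-retest summaries) alongside r; Spearman reports rho.
#'
#' @param panel from [paramPanel()] (two sessions).
#' @param parameter parameter name, e.g. `"A.PFC->preSMA"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate` (r2 or rho), `r` (pearson only), `p`, `n`.
#' @export
crossSessionCorrelation <- function(panel, parameter,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pr <- .pairSessions(panel, parameter)
  if (stats::sd(pr$a) == 0 || stats::sd(pr$b) == 0)
    stop("constant parameter vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(pr$a, pr$b, method = method))
  if (method == "pearson")
    list(estimate = unname(ct$estimate^2), r = unname(ct$estimate),
         p = ct$p.value, n = length(pr$a))
  else
    list(estimate = unname(ct$estimate), p = ct$p.value, n = length(pr$a))
}

#' Sign-consistency chi-squared test
#'
#' Tests whether the sign of a parameter is preserved across two sessions
#' more often than the chance expectation of half, with
#' `chi^2 = 2 (nSame - n/2)^2 / (n/2)` on 1 degree of freedom.
#'
#' @param nSame subjects with the same sign on both sessions.
#' @param nTotal total paired subjects.
#' @return list with `nSame`, `nTotal`, `chiSq`, `df`, `p` and
#'   `chiSqReported` (rounded half-up to 1 decimal).
#' @export
#' @examples
#' signConsistencyTest(11, 15)  # chi-squared 3.3, p = 0.07
signConsistencyTest <- function(nSame, nTotal) {
  stopifnot(nTotal >= 1)
  if (nSame > nTotal || nSame < 0) stop("nSame must lie in 0..nTotal")
  e <- nTotal / 2
  chi <- 2 * (nSame - e)^2 / e
  list(nSame = nSame, nTotal = nTotal, chiSq = chi, df = 1L,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       chiSqReported = roundHalfUp(chi, 1))
}

#' Repeated-measures ANOVA on a parameter panel
#'
#' Decomposes parameter values by a between-subjects group factor and
#' within-subject session and connection (parameter) factors, as a
#' group x session x connection repeated-measures ANOVA.  The panel must
#' be balanced (every subject observed in every session x connection
#' cell).  `correction = "GG"` applies Greenhouse-Geisser-corrected
#' p-values to within-subject effects (requires the car package).
#'
#' @param panel from [paramPanel()].
#' @param correction `"none"` or `"GG"`.
#' @return data.frame with columns effect, dfN, dfD, F, p (effects with
#'   zero sum of squares report F = 0).
#' @export
parameterAnova <- function(panel, correction = c("none", "GG")) {
  correction <- match.arg(correction)
  d <- panel
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$session <- factor(d$session); d$connection <- factor(d$parameter)
  counts <- table(d$subject, d$session, d$connection)
  if (any(counts != 1))
    stop("unbalanced panel: every subject needs exactly one value per ",
         "session x connection cell")

  if (correction == "GG") {
    if (!requireNamespace("car", quietly = TRUE))
      stop("Greenhouse-Geisser correction requires the car package")
    d$cell <- interaction(d$session, d$connection, sep = "_|_")
    mat <- tapply(d$value, list(d$subject, d$cell), mean)
    grp <- d$group[match(rownames(mat), d$subject)]
    idata <- do.call(rbind, strsplit(colnames(mat), "_|_", fixed = TRUE))
    idata <- data.frame(session = factor(idata[, 1]),
                        connection = factor(idata[, 2]))
    fit <- if (nlevels(grp) >= 2) stats::lm(mat ~ grp) else stats::lm(mat ~ 1)
    av <- car::Anova(fit, idata = idata, idesign = ~ session * connection,
                     type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    uni <- s$univariate.tests
    gg <- s$pval.adjustments
    eff <- rownames(uni)[rownames(uni) != "(Intercept)"]
    out <- data.frame(effect = gsub("grp", "group", eff),
                      dfN = uni[eff, "num Df"], dfD = uni[eff, "den Df"],
                      F = uni[eff, "F value"], p = uni[eff, "Pr(>F)"],
                      row.names = NULL)
    if (!is.null(gg)) {
      idx <- match(eff, rownames(gg))
      pgg <- gg[idx, "Pr(>F[GG])"]
      out$p <- ifelse(is.na(pgg), out$p, pgg)
    }
    out$F[!is.finite(out$F) | uni[eff, "Sum Sq"] < 1e-12] <- 0
    out$p[!is.finite(out$p)] <- 1
    return(out)
  }

  form <- if (nlevels(d$group) >= 2)
    value ~ group * session * connection else
    value ~ session * connection
  av <- stats::aov(stats::update(form,
    . ~ . + Error(subject / (session * connection))), data = d)
  s <- summary(av)
  out <- do.call(rbind, lapply(s, function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    resid <- tab[eff == "Residuals", , drop = FALSE]
    data.frame(effect = eff[keep], dfN = tab$Df[keep],
               dfD = if (nrow(resid)) resid$Df[1] else NA_real_,
               F = ifelse(tab[keep, "Sum Sq"] < 1e-12, 0,
                          tab[keep, "F value"]),
               p = tab[keep, "Pr(>F)"], row.names = NULL)
  }))
  out$p[out$F == 0] <- 1
  rownames(out) <- NULL
  out
}

#' Group summary of posterior correlation matrices
#'
#' Element-wise mean of per-subject posterior correlation matrices, with a
#' two-tailed one-sample t-test per unique off-diagonal element against
#' zero mean, Bonferroni correction over the number of unique elements,
#' and the fraction of negative mean elements.
#'
#' @param matrices list of same-shaped correlation matrices (one per
#'   subject).
#' @return list with `mean` matrix, `t` and `p` vectors (named by element
#'   pair), `bonferroniMask` (p < 0.05 / nUnique), `nUnique`,
#'   `fractionNegative`.
#' @export
posteriorCorrGroupSummary <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  dims <- vapply(matrices, dim, numeric(2))
  if (any(dims != dims[, 1])) stop("shape mismatch across subjects")
  arr <- simplify2array(matrices)
  meanM <- apply(arr, c(1, 2), mean)
  ut <- which(upper.tri(meanM), arr.ind = TRUE)
  nm <- rownames(meanM)
  elemNames <- if (is.null(nm)) sprintf("[%d,%d]", ut[, 1], ut[, 2]) else
    paste(nm[ut[, 1]], nm[ut[, 2]], sep = " ~ ")
  n <- length(matrices)
  tt <- apply(ut, 1, function(ij) {
    v <- arr[ij[1], ij[2], ]
    s <- stats::sd(v)
    if (s == 0) { if (mean(v) == 0) c(0, 1) else c(Inf, 0) }
    else { tv <- mean(v) / (s / sqrt(n))
           c(tv, 2 * stats::pt(-abs(tv), df = n - 1)) }
  })
  nUnique <- nrow(ut)
  p <- stats::setNames(tt[2, ], elemNames)
  list(mean = meanM, t = stats::setNames(tt[1, ], elemNames), p = p,
       bonferroniMask = p < 0.05 / nUnique, nUnique = nUnique,
       fractionNegative = mean(meanM[upper.tri(meanM)] < 0))
}

#' Between-session agreement of mean posterior-correlation matrices
#'
#' Spearman rank correlation over the vectorised unique off-diagonal
#' elements of two mean matrices.
#'
#' @param matA,matB same-shaped matrices.
#' @return list with `rho`, `p`, `nElements`.
#' @export
matrixSessionAgreement <- function(matA, matB) {
  if (!all(dim(matA) == dim(matB))) stop("shape mismatch")
  a <- matA[upper.tri(matA)]
  b <- matB[upper.tri(matB)]
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, nElements = length(a))
}

#' Ratio of bilinear to intrinsic connection weight
#'
#' For each modulated connection, `B/A`; undefined (NA, excluded) when
#' `|A| < 1e-6`.
#'
#' @param fit a [DcmFit-class].
#' @return named numeric vector of ratios, one per bilinear parameter.
#' @export
bilinearRatio <- function(fit) {
  ep <- posteriorMean(fit)
  bnames <- names(ep)[startsWith(names(ep), "B.")]
  out <- vapply(bnames, function(bn) {
    an <- sub("^B\\.", "A.", bn)
    a <- ep[[an]]
    if (!is.finite(a) || abs(a) < 1e-6) NA_real_ else ep[[bn]] / a
  }, numeric(1))
  stats::setNames(out, bnames)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests a sample against a normal distribution with the sample's own mean
#' and standard deviation.
#'
#' @param x numeric sample.
#' @return list with `z` (KS statistic times sqrt(n)), `D`, `p`, `n`.
#' @export
ksNormality <- function(x) {
  x <- x[is.finite(x)]
  ct <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(z = unname(ct$statistic) * sqrt(length(x)), D = unname(ct$statistic),
       p = ct$p.value, n = length(x))
}
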