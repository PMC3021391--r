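# Synthetic study cohorts with known ground truth: healthy young (one
# session), healthy older controls (two sessions) and Parkinson's disease
# patients (on/off medication), generated from the bilinear forward model.

.edgeMeans <- function(model, aForward, aBackward, bForward, bBackward,
                       cDrive) {
  regions <- dcmRegions()
  rostral <- c(PFC = 1, PM = 2, preSMA = 2, M1 = 3)
  isForward <- function(from, to) {
    if (rostral[from] != rostral[to]) rostral[from] < rostral[to]
    else from == "preSMA"  # lateral pair: preSMA -> PM is the forward link
  }
  nm <- modelParamNames(model, hemo = FALSE)
  vals <- vapply(nm, function(x) {
    if (startsWith(x, "C.")) return(cDrive)
    ft <- strsplit(sub("^[AB]\\.", "", x), "->", fixed = TRUE)[[1]]
    fw <- isForward(ft[1], ft[2])
    if (startsWith(x, "A.")) { if (fw) aForward else aBackward }
    else { if (fw) bForward else bBackward }
  }, numeric(1))
  stats::setNames(vals, nm)
}

#' Default study configuration
#'
#' The study roster: 28 healthy young subjects (one session, generating
#' model E2), 15 healthy older controls (two sessions, both E2, session
#' labels randomly assigned A/B), 16 Parkinson's disease patients (two
#' sessions: "on" generated by E2, "off" by E1; on/off order
#' counterbalanced within blocks of six) -- 90 sessions in total.  Group
#' mean driving input 0.10 Hz; group mean bilinear (contextual) terms 0.06
#' (forward) and 0.05 (backward); intrinsic means 0.20 Hz forward and 0.10
#' Hz backward; between-subject SD 0.05 Hz, within-subject session jitter
#' SD 0.02 Hz; observation noise set per session to give a time-series
#' SNR of about 2.
#'
#' @param nYoung,nOC,nPD group sizes.
#' @param snr target ratio of signal SD to noise SD (0 = noiseless).
#' @param betweenSd,jitterSd between-subject and within-subject
#'   (session-to-session) SDs of the connectivity parameters (Hz).
#' @param nPerCondition trials per condition.
#' @param nVolumes volumes per session.
#' @return a `CohortConfig` list consumed by [generateCohort()].
#' @export
defaultStudyConfig <- function(nYoung = 28, nOC = 15, nPD = 16, snr = 2,
                               betweenSd = 0.05, jitterSd = 0.02,
                               nPerCondition = 40, nVolumes = 150) {
  list(
    groups = list(
      list(label = "young", n = nYoung, sessions = c(A = "E2")),
      list(label = "OC", n = nOC, sessions = c(A = "E2", B = "E2"),
           randomiseLabels = TRUE),
      list(label = "PD", n = nPD, sessions = c(on = "E2", off = "E1"),
           counterbalanceBlocks = 6)
    ),
    means = list(aForward = 0.20, aBackward = 0.10, bForward = 0.06,
                 bBackward = 0.05, cDrive = 0.10),
    betweenSd = betweenSd, jitterSd = jitterSd, snr = snr,
    sigmaSelf = 0.5,
    design = list(nPerCondition = nPerCondition, soa = 2.5, duration = 1,
                  tr = 2, nVolumes = nVolumes),
    dtMicro = 0.1, centreU2 = FALSE
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' For every subject, connectivity parameters are drawn as group mean plus
#' a between-subject deviation (shared across that subject's sessions);
#' each session adds independent within-subject jitter, a freshly
#' randomised event design, and observation noise scaled to the configured
#' SNR.  Sessions whose parameter draw produces unstable dynamics are
#' redrawn (bounded retries).  Fully reproducible from `config` + `seed`.
#'
#' @param config from [defaultStudyConfig()].
#' @param seed master integer seed; all per-session seeds derive from it.
#' @return list with `sessions` (list of [DcmSession-class]), `roster`
#'   (data.frame: session_id, subject_id, group, session, truth_model,
#'   noise_sd, seed) and `truth` (long data.frame: session_id, parameter,
#'   value -- the true generating parameters).
#' @export
generateCohort <- function(config = defaultStudyConfig(), seed = 1) {
  models <- buildModelSpace()
  for (g in config$groups)
    if (!all(g$sessions %in% names(models)))
      stop("unknown truth model id: ",
           paste(setdiff(g$sessions, names(models)), collapse = ", "))

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)

  sessions <- list()
  roster <- NULL
  truth <- NULL
  sid <- 0
  for (g in config$groups) {
    # counterbalancing / label randomisation bookkeeping per group
    labOrder <- lapply(seq_len(g$n), function(i) names(g$sessions))
    if (isTRUE(g$randomiseLabels)) {
      labOrder <- lapply(seq_len(g$n), function(i) sample(names(g$sessions)))
    } else if (!is.null(g$counterbalanceBlocks) && length(g$sessions) == 2) {
      bs <- g$counterbalanceBlocks
      labOrder <- list()
      for (b in seq_len(ceiling(g$n / bs))) {
        k <- min(bs, g$n - (b - 1) * bs)
        first <- sample(rep_len(c(TRUE, FALSE), k))
        labOrder <- c(labOrder, lapply(first, function(f)
          if (f) names(g$sessions) else rev(names(g$sessions))))
      }
    }
    for (i in seq_len(g$n)) {
      subjId <- sprintf("%s%02d", g$label, i)
      # subject-level deviations over the union of this subject's truth params
      allNames <- unique(unlist(lapply(g$sessions, function(mid)
        modelParamNames(models[[mid]], hemo = FALSE))))
      dev <- stats::setNames(stats::rnorm(length(allNames), 0,
                                          config$betweenSd), allNames)
      for (lab in labOrder[[i]]) {
        mid <- g$sessions[[lab]]
        model <- models[[mid]]
        nm <- modelParamNames(model, hemo = FALSE)
        mu <- .edgeMeans(model, config$means$aForward, config$means$aBackward,
                         config$means$bForward, config$means$bBackward,
                         config$means$cDrive)
        designSeed <- sample.int(.Machine$integer.max, 1)
        ok <- FALSE
        for (try in 1:5) {
          jit <- stats::rnorm(length(nm), 0, config$jitterSd)
          theta <- mu + dev[nm] + jit
          params <- .thetaToParams(c(theta, 0, 0), model, config$sigmaSelf)
          des <- buildDesign(config$design$nPerCondition, config$design$soa,
                             seed = designSeed,
                             duration = config$design$duration,
                             tr = config$design$tr,
                             nVolumes = config$design$nVolumes)
          yClean <- tryCatch(
            simulateBold(model, params, des, noiseSd = 0,
                         dtMicro = config$dtMicro,
                         centreU2 = config$centreU2),
            error = function(e) NULL)
          if (!is.null(yClean)) { ok <- TRUE; break }
          message("unstable parameter draw for ", subjId, "/", lab,
                  "; redrawing (", try, ")")
        }
        if (!ok) stop("could not draw stable parameters for ", subjId)
        noiseSd <- if (config$snr > 0)
          stats::sd(sweep(yClean, 2, colMeans(yClean))) / config$snr else 0
        y <- if (noiseSd > 0)
          yClean + matrix(stats::rnorm(length(yClean), 0, noiseSd),
                          nrow(yClean)) else yClean
        colnames(y) <- dcmRegions()
        sid <- sid + 1
        sessId <- sprintf("S%03d", sid)
        sessions[[sessId]] <- methods::new("DcmSession", y = y,
          tr = config$design$tr, design = des, subjectId = subjId,
          group = g$label, session = lab)
        roster <- rbind(roster, data.frame(
          session_id = sessId, subject_id = subjId, group = g$label,
          session = lab, truth_model = mid, noise_sd = noiseSd,
          seed = designSeed))
        truth <- rbind(truth, data.frame(
          session_id = sessId, parameter = nm, value = unname(theta),
          row.names = NULL))
      }
    }
  }
  list(sessions = sessions, roster = roster, truth = truth)
}
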