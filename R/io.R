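# Format round-tripping: TSV time series, CSV designs and evidence
# tables, JSON inversion results and cohort manifests.  All numeric
# fields survive a write/read round trip at 15 significant digits.

.fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Write / read a region time-series TSV
#'
#' Columns: `time_s`, then one column per region in canonical order.
#'
#' @param y volumes x 4 matrix; @param tr repetition time (s).
#' @param path file path.
#' @return `readSessionSeries` returns list(y, tr).
#' @export
writeSessionSeries <- function(y, tr, path) {
  df <- data.frame(time_s = .fmt(seq_len(nrow(y)) * tr))
  for (r in seq_len(ncol(y))) df[[dcmRegions()[r]]] <- .fmt(y[, r])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSessionSeries
#' @export
readSessionSeries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  y <- as.matrix(df[, dcmRegions()])
  tr <- df$time_s[2] - df$time_s[1]
  list(y = y, tr = tr)
}

#' Write / read an event design CSV
#'
#' Columns: `onset_s`, `duration_s`, `condition`.
#'
#' @param design a `StimDesign`; @param path file path.
#' @param tr,nVolumes sampling metadata used when reading back.
#' @export
writeDesign <- function(design, path) {
  df <- data.frame(onset_s = .fmt(design$onsets),
                   duration_s = .fmt(design$durations),
                   condition = as.character(design$condition))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path, tr = 2, nVolumes = 150) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ons <- as.numeric(df$onset_s)
  soa <- if (length(ons) > 1) min(diff(ons)) else NA_real_
  list(onsets = ons, durations = as.numeric(df$duration_s),
       condition = factor(df$condition,
                          levels = c("specified", "chosen", "null")),
       soa = soa, tr = tr, nVolumes = nVolumes)
}

#' Write / read an evidence table CSV
#'
#' Layout: `session_id`, `subject_id`, `group`, `session`, then one column
#' per model id (free energies in nats).
#'
#' @param table evidence data.frame; @param path file path.
#' @export
writeEvidenceCsv <- function(table, path) {
  out <- table
  for (cc in setdiff(colnames(out), .metaCols)) out[[cc]] <- .fmt(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEvidenceCsv
#' @export
readEvidenceCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in setdiff(colnames(df), .metaCols)) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Serialise an inversion result to JSON
#'
#' Records model id, session id, the free-energy decomposition, posterior
#' means named by connection, and the posterior covariance as a nested
#' array in the same name order.
#'
#' @param fit a [DcmFit-class]; @param sessionId session label.
#' @param path file path.
#' @export
writeFitJson <- function(fit, sessionId, path) {
  rec <- list(model_id = fit@modelId, session_id = sessionId,
              F = fit@F, accuracy = fit@accuracy, complexity = fit@complexity,
              converged = fit@converged, n_iter = fit@nIter,
              sigma2 = as.list(fit@sigma2),
              Ep = as.list(posteriorMean(fit)),
              param_names = fit@paramNames,
              Cp = unname(fit@Cp))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFitJson
#' @export
readFitJson <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- rec$param_names
  methods::new("DcmFit", modelId = rec$model_id, paramNames = nm,
               Ep = stats::setNames(unlist(rec$Ep)[nm], nm),
               Cp = {
                 cp <- as.matrix(rec$Cp); (cp + t(cp)) / 2
               },
               F = rec$F, accuracy = rec$accuracy,
               complexity = rec$complexity,
               sigma2 = stats::setNames(unlist(rec$sigma2), dcmRegions()),
               trace = numeric(0), nIter = as.integer(rec$n_iter),
               converged = rec$converged)
}

#' Write / read a cohort directory
#'
#' A cohort directory holds `manifest.json` (roster and seeds),
#' `truth.json` (true generating parameters per session), and per session
#' a time-series TSV plus a design CSV.
#'
#' @param cohort from [generateCohort()]; @param dir directory path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cohort$roster, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (sessId in names(cohort$sessions)) {
    s <- cohort$sessions[[sessId]]
    writeSessionSeries(s@y, s@tr, file.path(dir, paste0(sessId, "_bold.tsv")))
    writeDesign(s@design, file.path(dir, paste0(sessId, "_design.csv")))
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  roster <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else NULL
  sessions <- list()
  for (k in seq_len(nrow(roster))) {
    sessId <- roster$session_id[k]
    ts <- readSessionSeries(file.path(dir, paste0(sessId, "_bold.tsv")))
    des <- readDesign(file.path(dir, paste0(sessId, "_design.csv")),
                      tr = ts$tr, nVolumes = nrow(ts$y))
    sessions[[sessId]] <- methods::new("DcmSession", y = ts$y, tr = ts$tr,
      design = des, subjectId = roster$subject_id[k],
      group = roster$group[k], session = roster$session[k])
  }
  list(sessions = sessions, roster = roster, truth = truth)
}
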