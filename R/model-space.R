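# Model space: 48 bilinear DCMs over the PFC / PM / preSMA / M1 network,
# grouped by intrinsic structure (sets A-F) and contextual modulation
# pattern (1-8).

# The anatomical skeleton: five region pairs; no direct PFC-M1 connection.
# "Forward" is the rostro-caudal direction (PFC most rostral); for the
# lateral preSMA-PM pair the forward direction is preSMA -> PM.
.dcmPairs <- function() {
  list(c("PFC", "PM"), c("PFC", "preSMA"), c("PM", "M1"),
       c("preSMA", "M1"), c("preSMA", "PM"))
}

# Modulation patterns: which pairs carry the chosen-vs-specified bilinear
# effect.  1-4 single pairs, 5 = rostral (1 u 2), 6 = caudal (3 u 4),
# 7 = rostral u caudal, 8 = all five pairs including preSMA-PM.  The
# assignment of pattern 3 to PM-M1 and 4 to preSMA-M1 is a convention and
# can be overridden by passing a custom pattern table.
.defaultPatternTable <- function() {
  list(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 4L,
       `5` = c(1L, 2L), `6` = c(3L, 4L), `7` = 1:4, `8` = 1:5)
}

.maskFromEdges <- function(edges) {
  regions <- dcmRegions()
  m <- matrix(0, 4, 4, dimnames = list(regions, regions))
  for (e in edges) m[e[2L], e[1L]] <- 1  # m[to, from]: column = source
  m
}

# Directed intrinsic edges (from, to) for a structure set.
.intrinsicEdges <- function(bidirectional) {
  fwd <- lapply(.dcmPairs(), function(p) c(p[1L], p[2L]))
  if (!bidirectional) return(fwd)
  c(fwd, lapply(.dcmPairs(), function(p) c(p[2L], p[1L])))
}

#' Build one model of the 48-model space
#'
#' Constructs the binary connectivity masks for one bilinear DCM, identified
#' by its intrinsic-structure set and contextual-modulation pattern.
#'
#' Structure sets: `A` = unidirectional rostro-caudal connections only;
#' `C`, `E` = bidirectional connections over the same five region pairs
#' (PFC-PM, PFC-preSMA, PM-M1, preSMA-M1, preSMA-PM); `B`, `D`, `F` = as
#' `A`, `C`, `E` plus the chosen-vs-specified context as a second direct
#' driving input to PFC.  Contextual modulation applies to the forward
#' direction only in sets A-D and to both directions of each modulated pair
#' in sets E and F (so `C2` is nested in `E2`, differing only by the
#' feedback modulation).  Patterns select the modulated pairs: 1 = PFC-PM,
#' 2 = PFC-preSMA, 3 = PM-M1, 4 = preSMA-M1, 5 = rostral (1 and 2),
#' 6 = caudal (3 and 4), 7 = rostral and caudal, 8 = all five pairs.
#'
#' @param structureSet one of `"A"`..`"F"`.
#' @param pattern integer 1..8.
#' @param patternTable optional named list mapping pattern id to indices of
#'   modulated pairs (see `Details`); the default encodes the conventions
#'   above.
#' @return a [DcmModel-class] object.
#' @export
#' @examples
#' e2 <- buildModel("E", 2)
#' countParameters(e2)  # 10 intrinsic, 2 bilinear, 1 driving
buildModel <- function(structureSet, pattern, patternTable = NULL) {
  sets <- LETTERS[1:6]
  if (!is.character(structureSet) || length(structureSet) != 1L ||
      !structureSet %in% sets)
    stop("structureSet must be one of ", paste(sets, collapse = ", "))
  pattern <- suppressWarnings(as.integer(pattern))
  if (is.na(pattern) || pattern < 1L || pattern > 8L)
    stop("pattern must be an integer in 1..8")
  if (is.null(patternTable)) patternTable <- .defaultPatternTable()

  bidir <- structureSet %in% c("C", "D", "E", "F")
  aMask <- .maskFromEdges(.intrinsicEdges(bidir))

  pairs <- .dcmPairs()[patternTable[[as.character(pattern)]]]
  bothDirs <- structureSet %in% c("E", "F")
  bEdges <- list()
  for (p in pairs) {
    bEdges <- c(bEdges, list(c(p[1L], p[2L])))
    if (bothDirs) bEdges <- c(bEdges, list(c(p[2L], p[1L])))
  }
  bMask <- .maskFromEdges(bEdges) * aMask  # only existing connections

  cMask <- matrix(0, 4, 2, dimnames = list(dcmRegions(), c("u1", "u2")))
  cMask["PFC", "u1"] <- 1
  if (structureSet %in% c("B", "D", "F")) cMask["PFC", "u2"] <- 1

  methods::new("DcmModel", modelId = paste0(structureSet, pattern),
               structureSet = structureSet, pattern = pattern,
               aMask = aMask, bMask = bMask, cMask = cMask)
}

#' Enumerate the full 48-model space
#'
#' All combinations of structure sets A-F and modulation patterns 1-8.
#'
#' @inheritParams buildModel
#' @return named list of 48 [DcmModel-class] objects, names = model ids.
#' @export
#' @examples
#' length(buildModelSpace())  # 48
buildModelSpace <- function(patternTable = NULL) {
  ids <- as.vector(outer(LETTERS[1:6], 1:8, paste0))
  models <- lapply(ids, function(id)
    buildModel(substr(id, 1, 1), as.integer(substr(id, 2, 2)), patternTable))
  stats::setNames(models, ids)
}

#' Count the user-specified connection parameters of a model
#'
#' Self-connections (the decay on the diagonal of A) are fixed, not
#' user-specified, and are never counted.
#'
#' @param model a [DcmModel-class].
#' @return named integer vector `nIntrinsic`, `nBilinear`, `nDriving`.
#' @export
countParameters <- function(model) {
  stopifnot(methods::is(model, "DcmModel"))
  c(nIntrinsic = sum(model@aMask), nBilinear = sum(model@bMask),
    nDriving = sum(model@cMask))
}

#' Names of the free parameters of a model
#'
#' Connectivity parameters are named `A.<from>-><to>`, `B.<from>-><to>`,
#' `C.<region>.u<j>`; the haemodynamic log-scaling factors are `h.kappa`
#' and `h.tau`.  Mask entries are enumerated column-major (source region
#' varies slowest), matching the parameter vector used by [invertSession()].
#'
#' @param model a [DcmModel-class].
#' @param hemo include the haemodynamic scaling parameters (default TRUE).
#' @return character vector of parameter names.
#' @export
modelParamNames <- function(model, hemo = TRUE) {
  regions <- dcmRegions()
  nameEdges <- function(mask, tag) {
    idx <- which(mask == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
    sprintf("%s.%s->%s", tag, regions[idx[, "col"]], regions[idx[, "row"]])
  }
  idxC <- which(model@cMask == 1, arr.ind = TRUE)
  idxC <- idxC[order(idxC[, "col"], idxC[, "row"]), , drop = FALSE]
  nm <- c(nameEdges(model@aMask, "A"), nameEdges(model@bMask, "B"),
          sprintf("C.%s.u%d", regions[idxC[, "row"]], idxC[, "col"]))
  if (hemo) nm <- c(nm, "h.kappa", "h.tau")
  nm
}

#' Serialise a model space to JSON
#'
#' Masks are written as nested 0/1 arrays in canonical region order.
#'
#' @param models list of [DcmModel-class] (e.g. from [buildModelSpace()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelSpaceJson <- function(models, path) {
  recs <- lapply(models, function(m) list(
    model_id = m@modelId, structure_set = m@structureSet,
    pattern = m@pattern, regions = dcmRegions(),
    a_mask = unname(m@aMask), b_mask = unname(m@bMask),
    c_mask = unname(m@cMask)))
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
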