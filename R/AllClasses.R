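#' @import methods
NULL

#' MotifProfile: position-specific scoring model for a PPR motif class
#'
#' A log-odds profile built from an alignment of motif instances. Scores are
#' in bits (base-2 log-odds against the background). The P-class motif is
#' 35 residues long; L and S variants may differ in length.
#'
#' @slot classLabel one of \code{"P"}, \code{"L"}, \code{"S"}.
#' @slot motifLen motif length in residues (35 for P).
#' @slot logOdds numeric matrix \code{motifLen x 20}, columns in
#'   \code{Biostrings::AA_STANDARD} order.
#' @slot background length-20 background residue frequencies (sums to 1).
#' @slot hitThreshold minimum bit score for a motif hit.
#'
#' @export
setClass("MotifProfile",
  representation(
    classLabel = "character",
    motifLen = "integer",
    logOdds = "matrix",
    background = "numeric",
    hitThreshold = "numeric"
  )
)

setValidity("MotifProfile", function(object) {
  msgs <- character()
  if (!object@classLabel %in% c("P", "L", "S"))
    msgs <- c(msgs, "classLabel must be one of P, L, S")
  if (object@classLabel == "P" && object@motifLen != 35L)
    msgs <- c(msgs, "P-class motifs are 35 residues long")
  if (!all(dim(object@logOdds) == c(object@motifLen, 20L)))
    msgs <- c(msgs, "logOdds must be motifLen x 20")
  if (!all(is.finite(object@logOdds)))
    msgs <- c(msgs, "logOdds entries must be finite")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9)
    msgs <- c(msgs, "background must be 20 frequencies summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MotifProfile-class display a short summary
#' @param object a \code{MotifProfile}
#' @export
setMethod("show", "MotifProfile", function(object) {
  cat("MotifProfile (class ", object@classLabel, ", ",
      object@motifLen, " aa, hit threshold ",
      format(object@hitThreshold), " bits)\n", sep = "")
  cat("  consensus: ", profileConsensus(object), "\n", sep = "")
})

#' ProteinAnnotation: tiled PPR motif chain for one protein
#'
#' The non-overlapping, score-maximal set of motif hits selected by the
#' tiling dynamic programme, together with per-class counts and the
#' retention classification. Hits record the residues at motif positions 5
#' and 35 (1-based), the base-specifying positions of the PPR code.
#'
#' @slot proteinId protein identifier.
#' @slot hits \code{data.frame} with columns \code{start} (0-based offset),
#'   \code{width}, \code{classLabel}, \code{score}, \code{aa5}, \code{aa35},
#'   sorted by \code{start}.
#' @slot nP,nL,nS counts of P, L and S motif hits.
#' @slot totalScore sum of hit scores (bits).
#' @slot classification one of \code{"P-class"}, \code{"PLS-class"},
#'   \code{"other"}.
#'
#' @export
setClass("ProteinAnnotation",
  representation(
    proteinId = "character",
    hits = "data.frame",
    nP = "integer",
    nL = "integer",
    nS = "integer",
    totalScore = "numeric",
    classification = "character"
  )
)

setValidity("ProteinAnnotation", function(object) {
  msgs <- character()
  h <- object@hits
  need <- c("start", "width", "classLabel", "score", "aa5", "aa35")
  if (!all(need %in% names(h)))
    msgs <- c(msgs, paste("hits must have columns:", paste(need, collapse = ", ")))
  if (nrow(h) > 1) {
    if (is.unsorted(h$start, strictly = TRUE))
      msgs <- c(msgs, "hits must be sorted by strictly increasing start")
    if (any(h$start[-1] < (h$start + h$width)[-nrow(h)]))
      msgs <- c(msgs, "hits must be non-overlapping")
  }
  if (nrow(h) && all(need %in% names(h))) {
    if (sum(h$classLabel == "P") != object@nP ||
        sum(h$classLabel == "L") != object@nL ||
        sum(h$classLabel == "S") != object@nS)
      msgs <- c(msgs, "class counts must equal label tallies")
  }
  if (!object@classification %in% c("P-class", "PLS-class", "other"))
    msgs <- c(msgs, "classification must be P-class, PLS-class or other")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProteinAnnotation-class display a short summary
#' @param object a \code{ProteinAnnotation}
#' @export
setMethod("show", "ProteinAnnotation", function(object) {
  cat("ProteinAnnotation for ", object@proteinId, ": ",
      nrow(object@hits), " motifs (P=", object@nP, ", L=", object@nL,
      ", S=", object@nS, "), total score ",
      format(round(object@totalScore, 1)), " bits, ",
      object@classification, "\n", sep = "")
})

#' Accessors for ProteinAnnotation
#'
#' @param x a \code{ProteinAnnotation}.
#' @return \code{motifHits} returns the hit table; \code{classification}
#'   the class label; \code{nPMotifs} the number of P motifs;
#'   \code{totalScore} the summed hit score; \code{proteinId} the id.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
motifHits <- function(x) x@hits

#' @rdname annotation-accessors
#' @export
classification <- function(x) x@classification

#' @rdname annotation-accessors
#' @export
nPMotifs <- function(x) x@nP

#' @rdname annotation-accessors
#' @export
totalScore <- function(x) x@totalScore

#' @rdname annotation-accessors
#' @export
proteinId <- function(x) x@proteinId
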