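#' Build a position-specific scoring profile from a motif alignment
#'
#' Turns an alignment of motif instances into a bit-scaled log-odds
#' profile. For residue \eqn{a} at column \eqn{i},
#' \deqn{\mathrm{logOdds}[i][a] = \log_2 \frac{(c_{ia} + \kappa\, b_a) /
#'   (n_i + \kappa)}{b_a}}
#' where \eqn{c_{ia}} is the residue count, \eqn{n_i} the number of
#' non-gap residues in the column, \eqn{\kappa} the pseudocount mass and
#' \eqn{b_a} the background frequency. Gaps (\code{-} or \code{.}) and
#' \code{X} are treated as missing observations; any column with less than
#' 50\% occupancy is rejected.
#'
#' @param alignment equal-length aligned motif sequences: a character
#'   vector, \code{AAStringSet}, or path to an aligned FASTA file.
#' @param classLabel motif class, one of \code{"P"}, \code{"L"}, \code{"S"}.
#' @param pseudocount total pseudocount mass \eqn{\kappa} (default 1).
#' @param background length-20 background frequencies in
#'   \code{Biostrings::AA_STANDARD} order; default uniform.
#' @param hitThreshold bit-score cutoff for motif hits (default 8).
#' @return A \code{\linkS4class{MotifProfile}}.
#' @examples
#' # a synthetic example alignment ships with the package
#' fa <- system.file("extdata", "synthetic_p_motif_alignment.fasta",
#'                   package = "RFLfinder")
#' buildProfile(fa, "P")
#' @param motifLen expected motif length; defaults to 35 for class P and
#'   to the alignment width otherwise.
#' @export
buildProfile <- function(alignment, classLabel = "P", pseudocount = 1,
                         background = NULL, hitThreshold = 8,
                         motifLen = NULL) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  seqs <- asProteinVector(alignment)
  if (length(seqs) < 2L)
    stageStop("ppr_motifs", "an alignment of at least 2 sequences is required")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    off <- which(nchar(seqs) != nchar(seqs)[1L])[1L]
    nm <- if (!is.null(names(seqs))) names(seqs)[off] else paste0("#", off)
    stageStop("ppr_motifs", "ragged alignment: sequence '", nm,
              "' has length ", nchar(seqs)[off], ", expected ",
              nchar(seqs)[1L])
  }
  if (is.null(motifLen))
    motifLen <- if (classLabel == "P") 35L else w
  if (w != motifLen)
    stageStop("ppr_motifs", "alignment width ", w,
              " does not match motif length ", motifLen)
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (abs(sum(background) - 1) > 1e-9)
    stageStop("ppr_motifs", "background frequencies must sum to 1")
  chars <- do.call(rbind, strsplit(seqs, ""))
  lo <- matrix(0, nrow = w, ncol = 20L, dimnames = list(NULL, AA20))
  for (i in seq_len(w)) {
    col <- chars[, i]
    obs <- col[col %in% AA20]
    if (length(obs) < length(col) / 2)
      stageStop("ppr_motifs", "column ", i, " has less than 50% occupancy")
    cnt <- table(factor(obs, levels = AA20))
    neff <- length(obs)
    lo[i, ] <- log2((as.numeric(cnt) + pseudocount * background) /
                    (neff + pseudocount) / background)
  }
  new("MotifProfile", classLabel = classLabel, motifLen = as.integer(w),
      logOdds = lo, background = as.numeric(background),
      hitThreshold = hitThreshold)
}

#' Consensus sequence of a profile
#'
#' @param profile a \code{MotifProfile}.
#' @return The string of per-column maximal-scoring residues.
#' @export
profileConsensus <- function(profile) {
  paste(AA20[apply(profile@logOdds, 1L, which.max)], collapse = "")
}

#' Score every offset of a protein against a profile
#'
#' Residues outside the 20 standard amino acids (e.g. X from N-containing
#' codons) take the minimum score of their column, i.e. they score as
#' mismatches.
#'
#' @param protein a protein string or \code{AAString}.
#' @param profile a \code{MotifProfile}.
#' @return Numeric vector of bit scores, one per 0-based offset
#'   \code{0 .. nchar(protein) - motifLen}; length 0 if the protein is
#'   shorter than the motif.
#' @export
scoreOffsets <- function(protein, profile) {
  p <- toupper(as.character(protein))
  L <- nchar(p)
  w <- profile@motifLen
  if (L < w) return(numeric(0))
  ext <- cbind(profile@logOdds, apply(profile@logOdds, 1L, min))
  idx <- match(strsplit(p, "")[[1L]], AA20)
  idx[is.na(idx)] <- 21L
  noff <- L - w + 1L
  pos <- outer(seq_len(w), 0L:(noff - 1L), `+`)   # w x noff residue positions
  sc <- matrix(ext[cbind(rep(seq_len(w), noff), idx[pos])], nrow = w)
  colSums(sc)
}

# class priority for tie-breaking: P over L over S
.classRank <- c(P = 1L, L = 2L, S = 3L)

#' Scan a protein and tile non-overlapping motif hits
#'
#' Generates candidate hits at every offset of every profile, keeps those
#' scoring at or above each profile's \code{hitThreshold}, and selects the
#' non-overlapping subset maximising total score by weighted-interval
#' scheduling. Score ties are broken in favour of earlier starts, then
#' P over L over S. The protein is classified as \code{"P-class"} when it
#' carries 10 or more P motifs (and at most 2 L/S), \code{"PLS-class"}
#' when it contains at least two consecutive P,L,S triplets, else
#' \code{"other"}.
#'
#' @param protein protein string or \code{AAString}.
#' @param profiles a \code{MotifProfile} or list of profiles.
#' @param proteinId id recorded in the annotation.
#' @return A \code{\linkS4class{ProteinAnnotation}}. For P hits,
#'   \code{aa5}/\code{aa35} are the protein residues at motif positions 5
#'   and 35 (1-based within the motif).
#' @export
scanAndTile <- function(protein, profiles, proteinId = "protein") {
  if (is(profiles, "MotifProfile")) profiles <- list(profiles)
  p <- toupper(as.character(protein))
  cand <- do.call(rbind, lapply(profiles, function(pr) {
    sc <- scoreOffsets(p, pr)
    keep <- which(sc >= pr@hitThreshold)
    if (!length(keep)) return(NULL)
    data.frame(start = keep - 1L, width = pr@motifLen,
               classLabel = pr@classLabel, score = sc[keep],
               stringsAsFactors = FALSE)
  }))
  sel <- tileHits(cand)
  buildAnnotation(proteinId, p, sel)
}

# weighted-interval scheduling over candidate hits; returns selected rows.
# Candidates are ordered by (start, class rank, -score); on equal total
# score the earlier-start (then higher-priority class) candidate is kept.
tileHits <- function(cand) {
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.frame(start = integer(), width = integer(),
                      classLabel = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  ord <- order(cand$start, .classRank[cand$classLabel], -cand$score)
  cand <- cand[ord, , drop = FALSE]
  n <- nrow(cand)
  ends <- cand$start + cand$width            # exclusive end
  # nxt[i]: first candidate starting at or after ends[i]
  nxt <- vapply(seq_len(n), function(i) {
    j <- which(cand$start >= ends[i])
    if (length(j)) min(j) else n + 1L
  }, integer(1))
  best <- numeric(n + 1L)
  for (i in n:1)
    best[i] <- max(best[i + 1L], cand$score[i] + best[min(nxt[i], n + 1L)])
  take <- logical(n)
  i <- 1L
  while (i <= n) {
    with_i <- cand$score[i] + best[min(nxt[i], n + 1L)]
    if (with_i >= best[i + 1L] - 1e-12) {
      take[i] <- TRUE
      i <- nxt[i]
    } else {
      i <- i + 1L
    }
  }
  cand[take, , drop = FALSE]
}

# assemble a ProteinAnnotation from selected hits
buildAnnotation <- function(proteinId, protein, sel) {
  if (nrow(sel)) {
    sel <- sel[order(sel$start), , drop = FALSE]
    sel$aa5 <- ifelse(sel$classLabel == "P",
                      substr(rep(protein, nrow(sel)),
                             sel$start + 5L, sel$start + 5L), NA)
    sel$aa35 <- ifelse(sel$classLabel == "P",
                       substr(rep(protein, nrow(sel)),
                              sel$start + 35L, sel$start + 35L), NA)
    rownames(sel) <- NULL
  } else {
    sel$aa5 <- character(0)
    sel$aa35 <- character(0)
  }
  nP <- sum(sel$classLabel == "P")
  nL <- sum(sel$classLabel == "L")
  nS <- sum(sel$classLabel == "S")
  cls <- classifyMotifChain(sel$classLabel)
  new("ProteinAnnotation", proteinId = proteinId, hits = sel,
      nP = as.integer(nP), nL = as.integer(nL), nS = as.integer(nS),
      totalScore = sum(sel$score), classification = cls)
}

# classification rules: P-class needs >=10 P motifs and at most 2 L/S;
# PLS-class needs >=2 consecutive (P,L,S) triplets; else "other"
classifyMotifChain <- function(labels) {
  nP <- sum(labels == "P"); nL <- sum(labels == "L"); nS <- sum(labels == "S")
  if (nP >= 10L && (nL + nS) <= 2L) return("P-class")
  if (length(labels) >= 6L) {
    s <- paste(labels, collapse = "")
    if (grepl("PLSPLS", s, fixed = TRUE)) return("PLS-class")
  }
  "other"
}

#' Summarise motif-count and score distributions across groups
#'
#' Produces the per-protein table and per-group summary statistics behind
#' motif-count and score-distribution comparisons (e.g. RFL versus other
#' P-class proteins): motifs per protein, per-motif scores and total
#' protein scores.
#'
#' @param annotations list of \code{ProteinAnnotation}.
#' @param groups character vector of group labels, one per annotation.
#' @return List with \code{perProtein} (protein id, group, n_motifs,
#'   total_score) and \code{groupSummary} (per-group n, median/mean motif
#'   count, median per-motif score, median total score). Empty groups are
#'   dropped with a warning.
#' @export
scoreSummaries <- function(annotations, groups) {
  stopifnot(length(annotations) == length(groups), length(annotations) > 0L)
  per <- data.frame(
    protein_id = vapply(annotations, proteinId, character(1)),
    group = as.character(groups),
    n_motifs = vapply(annotations, function(a) nrow(a@hits), integer(1)),
    total_score = vapply(annotations, totalScore, numeric(1)),
    stringsAsFactors = FALSE)
  gs <- lapply(split(seq_along(annotations), per$group), function(ix) {
    ms <- unlist(lapply(annotations[ix], function(a) a@hits$score))
    data.frame(
      n_proteins = length(ix),
      median_motifs = stats::median(per$n_motifs[ix]),
      mean_motifs = mean(per$n_motifs[ix]),
      median_motif_score = if (length(ms)) stats::median(ms) else NA_real_,
      median_total_score = stats::median(per$total_score[ix]))
  })
  gsum <- cbind(group = names(gs), do.call(rbind, gs))
  rownames(gsum) <- NULL
  keep <- gsum$n_proteins > 0
  if (any(!keep))
    warning("empty group(s) omitted: ",
            paste(gsum$group[!keep], collapse = ", "))
  list(perProtein = per, groupSummary = gsum[keep, , drop = FALSE])
}

#' Annotation hit table as TSV-ready data.frame
#'
#' @param annotations list of \code{ProteinAnnotation}.
#' @return data.frame with columns protein_id, start, class, score, aa5,
#'   aa35 (one row per motif hit).
#' @export
annotationTable <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a@hits) == 0L) return(NULL)
    data.frame(protein_id = a@proteinId, start = a@hits$start,
               class = a@hits$classLabel, score = a@hits$score,
               aa5 = a@hits$aa5, aa35 = a@hits$aa35,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      class = character(), score = numeric(),
                      aa5 = character(), aa35 = character())
  out
}
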