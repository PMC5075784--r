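#' Tally (position-5, position-35) amino-acid combinations
#'
#' Counts the amino-acid pair at motif positions 5 and 35 (1-based) across
#' all P motifs of the given annotations. These two positions specify the
#' RNA base recognised by each motif under the PPR code.
#'
#' @param annotations list of \code{ProteinAnnotation}.
#' @param group group label stored in the table (e.g. \code{"RFL"} or
#'   \code{"P-class"}).
#' @return A \code{CombinationTable}: list with \code{group},
#'   \code{counts} (data.frame aa5, aa35, count, sorted by decreasing
#'   count then combo) and \code{total}.
#' @export
extractCombos <- function(annotations, group = "group") {
  pairs <- do.call(rbind, lapply(annotations, function(a) {
    h <- a@hits[a@hits$classLabel == "P", , drop = FALSE]
    if (!nrow(h)) return(NULL)
    data.frame(aa5 = h$aa5, aa35 = h$aa35, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    counts <- data.frame(aa5 = character(), aa35 = character(),
                         count = integer(), stringsAsFactors = FALSE)
  } else {
    key <- paste0(pairs$aa5, pairs$aa35)
    tab <- table(key)
    counts <- data.frame(aa5 = substr(names(tab), 1L, 1L),
                         aa35 = substr(names(tab), 2L, 2L),
                         count = as.integer(tab), stringsAsFactors = FALSE)
    counts <- counts[order(-counts$count, counts$aa5, counts$aa35), ]
    rownames(counts) <- NULL
  }
  structure(list(group = group, counts = counts,
                 total = sum(counts$count)),
            class = "CombinationTable")
}

#' Construct a CombinationTable from counts
#'
#' @param counts named integer vector; names are two-letter combos
#'   (aa5 then aa35), e.g. \code{c(TD = 60, TN = 40)}.
#' @param group group label.
#' @return A \code{CombinationTable}.
#' @export
combinationTable <- function(counts, group = "group") {
  stopifnot(!is.null(names(counts)), all(nchar(names(counts)) == 2L))
  df <- data.frame(aa5 = substr(names(counts), 1L, 1L),
                   aa35 = substr(names(counts), 2L, 2L),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$aa5, df$aa35), ]
  rownames(df) <- NULL
  structure(list(group = group, counts = df, total = sum(df$count)),
            class = "CombinationTable")
}

#' @export
print.CombinationTable <- function(x, ...) {
  cat("CombinationTable [", x$group, "]: ", nrow(x$counts),
      " combos, ", x$total, " motifs\n", sep = "")
  invisible(x)
}

#' Combination enrichment between RFL and P-class motif sets
#'
#' For each of the \code{topN} most frequent combinations in the P-class
#' table, tests the 2x2 contingency (combo vs rest, RFL vs P-class) with a
#' two-sided Fisher exact test. No multiple-testing correction is applied;
#' significance is the bare p < \code{alpha} rule.
#'
#' @param rfl,pclass \code{CombinationTable}s with positive totals.
#' @param alpha significance level (default 0.01).
#' @param topN number of top P-class combinations tested (default 25).
#' @return data.frame with columns combo, count_rfl, count_p, freq_rfl,
#'   freq_p, p_value, significant, enriched_in_rfl.
#' @export
comboEnrichment <- function(rfl, pclass, alpha = 0.01, topN = 25L) {
  stopifnot(rfl$total > 0L, pclass$total > 0L)
  pc <- pclass$counts
  top <- utils::head(pc, topN)
  combo <- paste0(top$aa5, top$aa35)
  rkey <- paste0(rfl$counts$aa5, rfl$counts$aa35)
  res <- lapply(seq_along(combo), function(i) {
    a <- rfl$counts$count[match(combo[i], rkey)]
    if (is.na(a)) a <- 0L
    cpc <- top$count[i]
    tab <- matrix(c(a, rfl$total - a, cpc, pclass$total - cpc), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    fr <- a / rfl$total
    fp <- cpc / pclass$total
    data.frame(combo = combo[i], count_rfl = a, count_p = cpc,
               freq_rfl = fr, freq_p = fp, p_value = p,
               significant = p < alpha, enriched_in_rfl = fr > fp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default PPR code table
#'
#' Ships the base assignments for the canonical purine-recognising pairs
#' TD (G), TN (A), SD (G), SN (A) and the C-recognising pairs NS and NT,
#' plus widely used extensions (ND -> U, GD -> G, GN -> A) flagged in the
#' \code{extended} column. Unlisted combinations fall back to \code{"N"}.
#'
#' @return data.frame with columns aa5, aa35, base, extended.
#' @export
defaultCodeTable <- function() {
  data.frame(
    aa5 = c("T", "T", "S", "S", "N", "N", "N", "G", "G"),
    aa35 = c("D", "N", "D", "N", "S", "T", "D", "D", "N"),
    base = c("G", "A", "G", "A", "C", "C", "U", "G", "A"),
    extended = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Read a PPR code table from TSV
#'
#' @param path TSV with columns aa5, aa35, base (and optionally extended).
#' @return data.frame usable as a code table.
#' @export
readCodeTable <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("aa5", "aa35", "base")
  if (!all(need %in% names(ct)))
    stageStop("ppr_code_stats", "code table must have columns: ",
              paste(need, collapse = ", "))
  if (!all(ct$base %in% c("A", "C", "G", "U", "N")))
    stageStop("ppr_code_stats", "code table bases must be A, C, G, U or N")
  if (is.null(ct$extended)) ct$extended <- FALSE
  ct
}

# lookup vector combo -> base
codeLookup <- function(code) {
  stats::setNames(code$base, paste0(code$aa5, code$aa35))
}

#' Predict the recognised RNA sequence of a PPR protein
#'
#' Maps each P motif, from the amino terminus (which contacts the 5' end
#' of the RNA target) to the carboxy terminus, to its predicted base via
#' the PPR code table; unknown combinations yield \code{"N"}.
#'
#' @param annotation a \code{ProteinAnnotation}.
#' @param code a code table (default \code{\link{defaultCodeTable}}).
#' @return A single string over \{A, C, G, U, N\} of length equal to the
#'   number of P motifs.
#' @examples
#' # TD,TN,SD,SN -> "GAGA"; NS,NT -> "CC"
#' @export
predictTargets <- function(annotation, code = defaultCodeTable()) {
  h <- annotation@hits[annotation@hits$classLabel == "P", , drop = FALSE]
  if (!nrow(h)) return("")
  lk <- codeLookup(code)
  bases <- lk[paste0(h$aa5, h$aa35)]
  bases[is.na(bases)] <- "N"
  paste(bases, collapse = "")
}

#' Predicted base composition of a motif set
#'
#' Takes combinations in decreasing frequency until their cumulative
#' frequency reaches \code{massCutoff} ("the set of combinations that add
#' up to at least 50\% of all combinations"), maps them to bases via the
#' code table, drops unknowns (\code{N}) and renormalises.
#'
#' @param tab a \code{CombinationTable} with positive total.
#' @param code a code table.
#' @param massCutoff cumulative frequency cutoff (default 0.5).
#' @return Named numeric vector of proportions over A, C, G, U (sums to 1).
#' @export
baseComposition <- function(tab, code = defaultCodeTable(),
                            massCutoff = 0.5) {
  stopifnot(tab$total > 0L)
  cnt <- tab$counts  # already sorted by decreasing count then combo
  freq <- cnt$count / tab$total
  k <- which(cumsum(freq) >= massCutoff - 1e-12)[1L]
  if (is.na(k)) k <- nrow(cnt)
  used <- cnt[seq_len(k), , drop = FALSE]
  lk <- codeLookup(code)
  bases <- lk[paste0(used$aa5, used$aa35)]
  bases[is.na(bases)] <- "N"
  keep <- bases != "N"
  if (!any(keep))
    stageStop("ppr_code_stats",
              "all retained combinations map to N under the code table")
  w <- tapply(used$count[keep], factor(bases[keep],
                                       levels = c("A", "C", "G", "U")), sum)
  w[is.na(w)] <- 0
  prop <- as.numeric(w) / sum(w)
  stats::setNames(prop, c("A", "C", "G", "U"))
}

#' Write a combination table as TSV
#'
#' @param tab a \code{CombinationTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeComboTable <- function(tab, path) {
  utils::write.table(tab$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
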