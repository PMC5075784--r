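# Shared constants and small helpers.

# The 20 standard amino acids, in Biostrings::AA_STANDARD order. All profile
# matrices and background vectors are indexed in this order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Codon table for the standard nuclear genetic code, used by the synthetic
# generator's reverse translation (Biostrings handles forward translation).
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

# Synonymous codons per amino acid (stops excluded).
SYNONYMOUS_CODONS <- split(names(CODON_TABLE), CODON_TABLE)[
  setdiff(unique(CODON_TABLE), "*")]

#' Canonical P-type PPR motif consensus
#'
#' A 35-residue consensus for the P-class pentatricopeptide-repeat motif,
#' used as the seed sequence for the synthetic generator and for building
#' example scoring profiles. Positions 5 and 35 (1-based) are the
#' base-specifying positions of the PPR code.
#'
#' @return A single 35-character string.
#' @export
pprPConsensus <- function() {
  "VVTYNTLISGLCKAGRVDEALELFREMKEKGIRPD"
}

# round half away from zero, for integer percentages
roundHalfUp <- function(x) floor(x + 0.5)

# deterministic label sequence: A..Z, then AA, AB, ...
labelSeq <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- n - 26L
  pairs <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, pairs[seq_len(extra)])
}

# split a label string into a label vector; pass vectors through
asLabels <- function(x) {
  if (length(x) == 1L && is.character(x) && nchar(x) > 1L &&
      !grepl(" ", x, fixed = TRUE)) {
    strsplit(x, "")[[1]]
  } else {
    as.character(x)
  }
}

# identity substitution matrix over the 20 standard residues plus X;
# X matches nothing, including itself
identitySubMatrix <- function() {
  letters21 <- c(AA20, "X")
  m <- diag(1, length(letters21))
  dimnames(m) <- list(letters21, letters21)
  m["X", "X"] <- 0
  m
}

# uppercase character coercion that keeps names (as.character drops them)
asProteinVector <- function(x) {
  nm <- names(x)
  out <- toupper(as.character(x))
  names(out) <- nm
  out
}

# stop with a consistent prefix so pipeline stages can be identified
stageStop <- function(stage, ...) {
  stop("[", stage, "] ", ..., call. = FALSE)
}
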