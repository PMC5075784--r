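#' Read a multi-contig genome FASTA
#'
#' Reads genomic DNA, normalises residues to uppercase and validates the
#' alphabet (A, C, G, T, N only). Record order is preserved; the id of each
#' contig is the first whitespace-delimited token of its header.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param species optional species tag stored in the metadata of the result.
#' @return A \code{\link[Biostrings]{DNAStringSet}} named by contig id, with
#'   \code{metadata(x)$species} set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT", ">chr2", "NNACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path, species = NA_character_) {
  if (!file.exists(path))
    stageStop("seqio", "file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stageStop("seqio", "empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stageStop("seqio", "duplicate contig id(s): ",
              paste(unique(dup), collapse = ", "))
  up <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stageStop("seqio", "non-DNA character '",
              substr(up[i], bad[i], bad[i]), "' in contig '", ids[i],
              "' at position ", bad[i])
  }
  if (any(nchar(up) == 0L))
    stageStop("seqio", "empty sequence for contig '",
              ids[which(nchar(up) == 0L)[1L]], "'")
  out <- Biostrings::DNAStringSet(up)
  names(out) <- ids
  S4Vectors::metadata(out)$species <- species
  out
}

# translate a DNAString(Set slice) with N-containing codons rendered as X
translateX <- function(dna) {
  as.character(Biostrings::translate(dna, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Extract ORFs from six-frame translations
#'
#' Scans all six reading frames of each contig for maximal stop-free codon
#' runs (stop-to-stop; runs truncated by the contig edge are included) and
#' returns those of at least \code{minCodons} codons. There is no
#' start-codon requirement: the target gene family is essentially intronless
#' and is annotated directly from genomic six-frame translations. Codons
#' containing N translate to X; X never terminates a run.
#'
#' @param genome a \code{DNAStringSet} (e.g. from \code{\link{readGenome}})
#'   or a single \code{DNAString}.
#' @param minCodons minimum ORF length in codons. The default 93 retains
#'   ORFs strictly longer than 92 codons.
#' @return A \code{\link[GenomicRanges]{GRanges}} (1-based, closed
#'   intervals on the forward strand) with metadata columns \code{frame}
#'   (0, 1 or 2: the offset of the reading frame on the reading strand),
#'   \code{n_codons}, \code{aa} (the translated protein) and
#'   \code{orf_id}. Contigs shorter than one codon yield no ranges.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ATG", 120), collapse = "")))
#' sixFrameOrfs(gen, minCodons = 93)
#' @export
sixFrameOrfs <- function(genome, minCodons = 93L) {
  if (is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(stats::setNames(list(genome), "seq"))
  stopifnot(minCodons >= 1L)
  res <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    dna <- genome[[ci]]
    L <- length(dna)
    if (L < 3L) next
    for (str in c("+", "-")) {
      rs <- if (str == "+") dna else Biostrings::reverseComplement(dna)
      for (f in 0:2) {
        ncod <- (L - f) %/% 3L
        if (ncod < 1L) next
        aa <- translateX(Biostrings::subseq(rs, f + 1L, f + 3L * ncod))
        runs <- gregexpr("[^*]+", aa)[[1L]]
        if (runs[1L] == -1L) next
        lens <- attr(runs, "match.length")
        keep <- lens >= minCodons
        if (!any(keep)) next
        for (k in which(keep)) {
          c0 <- runs[k] - 1L            # 0-based codon offset on reading strand
          nc <- lens[k]
          rd_start <- f + 3L * c0 + 1L  # 1-based on reading strand
          rd_end <- f + 3L * (c0 + nc)
          if (str == "+") {
            gstart <- rd_start; gend <- rd_end
          } else {
            gstart <- L - rd_end + 1L; gend <- L - rd_start + 1L
          }
          res[[length(res) + 1L]] <- data.frame(
            contig = contig, start = gstart, end = gend, strand = str,
            frame = f, n_codons = nc,
            aa = substr(aa, runs[k], runs[k] + nc - 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) {
    gr <- GenomicRanges::GRanges(seqlengths =
      stats::setNames(nchar(as.character(genome)), names(genome)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      frame = integer(), n_codons = integer(), aa = character(),
      orf_id = character())
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    frame = df$frame, n_codons = df$n_codons, aa = df$aa,
    seqlengths = stats::setNames(nchar(as.character(genome)), names(genome)))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr$orf_id <- paste0(GenomicRanges::seqnames(gr), "|",
                      GenomicRanges::strand(gr), "|", gr$frame, "|",
                      GenomicRanges::start(gr), "-", GenomicRanges::end(gr))
  names(gr) <- gr$orf_id
  gr
}

#' ORF proteins as an AAStringSet
#'
#' @param orfs a \code{GRanges} from \code{\link{sixFrameOrfs}}.
#' @return An \code{AAStringSet} named by \code{orf_id}.
#' @export
orfProteins <- function(orfs) {
  aa <- Biostrings::AAStringSet(orfs$aa)
  names(aa) <- orfs$orf_id
  aa
}

#' Write ORFs as protein FASTA
#'
#' Headers encode contig, strand, frame and 1-based coordinates as
#' \code{contig|strand|frame|start-end}.
#'
#' @param orfs a \code{GRanges} from \code{\link{sixFrameOrfs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOrfFasta <- function(orfs, path) {
  Biostrings::writeXStringSet(orfProteins(orfs), path)
  invisible(path)
}

#' Write ranges as GFF3
#'
#' A plain GFF3 writer for ORF and gene-locus ranges. Internal coordinates
#' are GRanges 1-based closed intervals, which match the GFF3 convention
#' directly.
#'
#' @param gr a \code{GRanges}; metadata columns are emitted as attributes.
#' @param path output path.
#' @param type GFF3 type column (default \code{"ORF"}).
#' @param source GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(gr, path, type = "ORF", source = "RFLfinder") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(gr) == 0L) return(invisible(path))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  keep <- setdiff(names(mc), "aa")  # protein sequence stays in FASTA output
  attrs <- vapply(seq_len(nrow(mc)), function(i) {
    kv <- vapply(keep, function(k) paste0(k, "=", mc[i, k]), character(1))
    paste(kv, collapse = ";")
  }, character(1))
  lines <- paste(
    as.character(GenomicRanges::seqnames(gr)), source, type,
    GenomicRanges::start(gr), GenomicRanges::end(gr), ".",
    as.character(GenomicRanges::strand(gr)), ".", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
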