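#' Build a gene-locus GRanges
#'
#' Convenience constructor for the locus table used by the genomic-cluster
#' statistics: a \code{GRanges} with metadata columns \code{gene_id},
#' \code{species}, \code{is_rfl} and \code{n_motifs}.
#'
#' @param gene_id,chromosome,start,end,strand,species,is_rfl,n_motifs
#'   per-gene vectors; \code{start}/\code{end} are 1-based closed.
#' @return A \code{GRanges}.
#' @export
geneLoci <- function(gene_id, chromosome, start, end, strand = "+",
                     species = "unknown", is_rfl = TRUE, n_motifs = NA_integer_) {
  stopifnot(all(start <= end), all(nzchar(chromosome)))
  n <- length(gene_id)
  GenomicRanges::GRanges(
    seqnames = chromosome,
    ranges = IRanges::IRanges(start, end),
    strand = rep(strand, length.out = n),
    gene_id = gene_id,
    species = rep(species, length.out = n),
    is_rfl = rep(is_rfl, length.out = n),
    n_motifs = rep(n_motifs, length.out = n))
}

#' Call genomic RFL clusters versus singlets
#'
#' Per chromosome, RFL loci are sorted by start and chained while the gap
#' between consecutive loci (start of next minus end of current) is at most
#' \code{maxGap}. Chains of two or more genes are clusters ("two or more
#' genes at one chromosomal location"); chains of one are singlets.
#'
#' @param loci a \code{GRanges} of gene loci (see \code{\link{geneLoci}});
#'   only rows with \code{is_rfl == TRUE} are considered. Should contain a
#'   single species.
#' @param maxGap maximum intergenic gap in bp within a cluster
#'   (default 300000; genomic windows of ~500 kbp hold one cluster).
#' @return List with \code{clusters} (list of \code{ClusterCall}s: species,
#'   chromosome, members ordered by start, span \code{c(start, end)}) and
#'   \code{singlets} (character vector of gene ids).
#' @export
callClusters <- function(loci, maxGap = 300000) {
  rfl <- loci[loci$is_rfl]
  clusters <- list()
  singlets <- character(0)
  if (length(rfl) == 0L)
    return(list(clusters = clusters, singlets = singlets))
  sp <- unique(rfl$species)
  if (length(sp) > 1L)
    stageStop("genome_clusters", "loci must come from one species, got: ",
              paste(sp, collapse = ", "))
  for (chr in unique(as.character(GenomicRanges::seqnames(rfl)))) {
    sub <- rfl[as.character(GenomicRanges::seqnames(rfl)) == chr]
    sub <- sub[order(GenomicRanges::start(sub))]
    st <- GenomicRanges::start(sub)
    en <- GenomicRanges::end(sub)
    gap_ok <- if (length(sub) > 1L) (st[-1L] - en[-length(sub)]) <= maxGap
              else logical(0)
    chain <- cumsum(c(TRUE, !gap_ok))
    for (k in unique(chain)) {
      ix <- which(chain == k)
      if (length(ix) >= 2L) {
        clusters[[length(clusters) + 1L]] <- structure(list(
          species = sp, chromosome = chr,
          members = sub$gene_id[ix],
          span = c(min(st[ix]), max(en[ix]))), class = "ClusterCall")
      } else {
        singlets <- c(singlets, sub$gene_id[ix])
      }
    }
  }
  list(clusters = clusters, singlets = singlets)
}

#' @export
print.ClusterCall <- function(x, ...) {
  cat("ClusterCall [", x$species, " ", x$chromosome, ":",
      x$span[1], "-", x$span[2], "]: ",
      length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Per-species cluster/singlet statistics
#'
#' Counts clustered and singlet RFL genes and the integer percentage of
#' genes in clusters (nearest integer, half away from zero).
#'
#' @param clusters list of \code{ClusterCall} from \code{\link{callClusters}}.
#' @param singlets character vector of singlet gene ids.
#' @param species species label; taken from the clusters when omitted.
#' @return data.frame with columns species, n_total, n_clustered,
#'   n_singlets, pct_clustered.
#' @examples
#' # 5 clustered + 2 singlets -> 71% of genes in clusters
#' @export
clusterStats <- function(clusters, singlets, species = NULL) {
  if (is.null(species)) {
    species <- if (length(clusters)) clusters[[1L]]$species else "unknown"
  }
  if (length(clusters)) {
    sp <- unique(vapply(clusters, function(cl) cl$species, character(1)))
    if (length(sp) > 1L)
      stageStop("genome_clusters", "clusters span multiple species")
  }
  n_clustered <- sum(vapply(clusters, function(cl) length(cl$members),
                            integer(1)))
  n_singlets <- length(singlets)
  n_total <- n_clustered + n_singlets
  if (n_total == 0L) {
    warning("no RFL loci; percentage set to 0")
    pct <- 0L
  } else {
    pct <- as.integer(roundHalfUp(100 * n_clustered / n_total))
  }
  data.frame(species = species, n_total = n_total,
             n_clustered = n_clustered, n_singlets = n_singlets,
             pct_clustered = pct, stringsAsFactors = FALSE)
}

#' Assign RFL loci to anchored Rf regions
#'
#' Labels a locus with a region name when it lies strictly between the two
#' flanking anchor genes of that region on the same chromosome (e.g. the
#' Rf-region 1 / Rf-region 2 intervals bounded by conserved genes on rice
#' chromosome 10); otherwise \code{"unassigned"}.
#'
#' @param loci a \code{GRanges} of gene loci.
#' @param anchors data.frame with one row per region: columns
#'   \code{region}, \code{chromosome}, \code{left_start}, \code{left_end},
#'   \code{right_start}, \code{right_end} (1-based closed anchor-gene
#'   coordinates; the left anchor must end before the right anchor starts).
#' @return Named character vector: gene_id -> region label.
#' @export
regionAssign <- function(loci, anchors) {
  need <- c("region", "chromosome", "left_start", "left_end",
            "right_start", "right_end")
  if (!all(need %in% names(anchors)))
    stageStop("genome_clusters", "anchors must have columns: ",
              paste(need, collapse = ", "))
  if (any(anchors$left_end >= anchors$right_start))
    stageStop("genome_clusters", "overlapping or unordered anchor pair for ",
              "region(s): ",
              paste(anchors$region[anchors$left_end >= anchors$right_start],
                    collapse = ", "))
  out <- stats::setNames(rep("unassigned", length(loci)), loci$gene_id)
  for (i in seq_len(nrow(anchors))) {
    hit <- as.character(GenomicRanges::seqnames(loci)) == anchors$chromosome[i] &
      GenomicRanges::start(loci) > anchors$left_end[i] &
      GenomicRanges::end(loci) < anchors$right_start[i]
    out[hit] <- anchors$region[i]
  }
  out
}
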