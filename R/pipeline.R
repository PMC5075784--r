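#' Pipeline configuration
#'
#' Collects and validates the thresholds of every stage.
#'
#' @param minCodons minimum ORF length in codons (default 93: ORFs
#'   strictly longer than 92 codons are kept).
#' @param hitThreshold motif bit-score cutoff (default 8).
#' @param identityThreshold greedy-clustering identity cutoff (default
#'   0.40).
#' @param minCoverage greedy-clustering coverage of the shorter sequence
#'   (default 0.10).
#' @param pruneBelow orthogroup similarity pruning threshold (default 0.25).
#' @param inflation Markov-clustering inflation (default 1.5).
#' @param maxGap genomic-cluster chaining gap in bp (default 300000).
#' @param alpha enrichment significance level (default 0.01).
#' @param topN number of top combinations tested (default 25).
#' @param massCutoff cumulative-frequency cutoff for base composition
#'   (default 0.5).
#' @param codeTable PPR code table (default \code{\link{defaultCodeTable}}).
#' @param seed RNG seed recorded in the run manifest.
#' @return A validated \code{PipelineConfig} (list).
#' @export
pipelineConfig <- function(minCodons = 93L, hitThreshold = 8,
                           identityThreshold = 0.40, minCoverage = 0.10,
                           pruneBelow = 0.25, inflation = 1.5,
                           maxGap = 300000, alpha = 0.01, topN = 25L,
                           massCutoff = 0.5, codeTable = defaultCodeTable(),
                           seed = 1L) {
  cfg <- list(minCodons = as.integer(minCodons), hitThreshold = hitThreshold,
              identityThreshold = identityThreshold,
              minCoverage = minCoverage, pruneBelow = pruneBelow,
              inflation = inflation, maxGap = maxGap, alpha = alpha,
              topN = as.integer(topN), massCutoff = massCutoff,
              codeTable = codeTable, seed = as.integer(seed))
  if (cfg$minCodons < 1L)
    stageStop("pipeline", "minCodons must be >= 1")
  if (cfg$identityThreshold <= 0 || cfg$identityThreshold > 1)
    stageStop("pipeline", "identityThreshold must be in (0, 1]")
  for (p in c("minCoverage", "pruneBelow", "alpha", "massCutoff")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stageStop("pipeline", p, " must be in [0, 1]")
  }
  if (cfg$inflation <= 1)
    stageStop("pipeline", "inflation must exceed 1")
  if (cfg$maxGap < 0)
    stageStop("pipeline", "maxGap must be non-negative")
  if (!all(c("aa5", "aa35", "base") %in% names(cfg$codeTable)))
    stageStop("pipeline", "codeTable must have columns aa5, aa35, base")
  structure(cfg, class = "PipelineConfig")
}

#' Run the genome-to-RFL-catalogue pipeline
#'
#' Executes every stage end to end: six-frame ORF extraction, P-motif
#' profile scanning and tiling, retention of P-class proteins (10 or more
#' P motifs), RFL identification by the three strategies (greedy identity
#' clustering, orthogroup Markov clustering, and neighbor-joining clade
#' extraction anchored on the reference RFLs), the Venn consensus across
#' methods, genomic cluster statistics, position-5/35 combination
#' statistics with enrichment, predicted base composition and RNA targets,
#' and the motif-evolution analysis of the largest genomic cluster.
#'
#' @param genome a \code{DNAStringSet} or path to a genome FASTA.
#' @param motifAlignment aligned P-motif instances (character vector,
#'   \code{AAStringSet}, or FASTA path) used to build the scanning
#'   profile.
#' @param references reference RFL proteins (named character vector,
#'   \code{AAStringSet}, or FASTA path).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, all stage outputs are
#'   written there as FASTA/GFF3/TSV/newick plus a run manifest.
#' @param species species tag for the cluster statistics.
#' @return List with elements \code{orfs}, \code{annotations} (P-motif
#'   bearing ORFs), \code{pclassIds}, \code{methods} (list of
#'   \code{MethodResult}), \code{consensus}, \code{rflIds} (ids identified
#'   by every method), \code{loci}, \code{genomicClusters},
#'   \code{clusterStats}, \code{combos}, \code{enrichment},
#'   \code{baseComposition}, \code{targets}, \code{motifEvolution} and
#'   \code{funnel} (ORF / PPR / P-class / per-method counts).
#' @export
runPipeline <- function(genome, motifAlignment, references,
                        config = pipelineConfig(), outDir = NULL,
                        species = "synthetic") {
  if (is.character(genome)) genome <- readGenome(genome, species = species)
  if (is.character(references) && length(references) == 1L &&
      file.exists(references))
    references <- Biostrings::readAAStringSet(references)
  refs <- stats::setNames(toupper(as.character(references)),
                          names(references))
  if (is.null(names(refs)) || any(names(refs) == ""))
    stageStop("pipeline", "reference sequences must be named")

  # stage 1: ORFs
  orfs <- sixFrameOrfs(genome, minCodons = config$minCodons)
  nOrfs <- length(orfs)

  # stage 2: motif annotation
  profile <- buildProfile(motifAlignment, classLabel = "P",
                          hitThreshold = config$hitThreshold)
  proteins <- orfProteins(orfs)
  annotations <- lapply(seq_along(proteins), function(i)
    scanAndTile(proteins[[i]], profile, proteinId = names(proteins)[i]))
  names(annotations) <- names(proteins)
  hasMotif <- vapply(annotations, function(a) nrow(a@hits) > 0L, logical(1))
  annotations <- annotations[hasMotif]
  nPpr <- sum(hasMotif)
  pclassIds <- names(annotations)[vapply(annotations, classification,
                                         character(1)) == "P-class"]
  nPclass <- length(pclassIds)

  pseqs <- stats::setNames(as.character(proteins[pclassIds]), pclassIds)
  pool <- c(pseqs, refs)

  methods <- list()
  consensus <- NULL
  rflIds <- character(0)
  if (nPclass >= 1L) {
    greedy <- greedyIdentityCluster(pool,
                                    identityThreshold = config$identityThreshold,
                                    minCoverage = config$minCoverage)
    methods$greedy_identity <- rflFromClusters(
      greedy, names(refs), "greedy_identity",
      list(identityThreshold = config$identityThreshold,
           minCoverage = config$minCoverage))
    ortho <- orthogroupCluster(pool, pruneBelow = config$pruneBelow,
                               inflation = config$inflation)
    methods$orthogroup <- rflFromClusters(
      ortho, names(refs), "orthogroup",
      list(pruneBelow = config$pruneBelow, inflation = config$inflation))
    if (length(pool) >= 3L) {
      tree <- njTree(identityDistanceMatrix(pool))
      clade <- extractRflClade(tree, names(refs))
      methods$phylo_clade <- methodResult(
        "phylo_clade", setdiff(clade$rflIds, names(refs)),
        clade$params)
    }
    if (length(methods) >= 2L) {
      consensus <- consensusReport(methods)
      allSig <- paste(sort(vapply(methods, `[[`, character(1), "method")),
                      collapse = "+")
      core <- consensus$partition[[allSig]]
      rflIds <- if (is.null(core)) character(0) else core
    } else if (length(methods) == 1L) {
      rflIds <- methods[[1L]]$rflIds
    }
  }

  # stage 4: genomic clusters of the identified RFL loci
  loci <- orfs[names(orfs) %in% names(annotations)]
  loci <- geneLoci(loci$orf_id,
                   as.character(GenomicRanges::seqnames(loci)),
                   GenomicRanges::start(loci), GenomicRanges::end(loci),
                   as.character(GenomicRanges::strand(loci)),
                   species = species,
                   is_rfl = loci$orf_id %in% rflIds,
                   n_motifs = vapply(annotations[loci$orf_id], nPMotifs,
                                     integer(1)))
  gclust <- callClusters(loci, maxGap = config$maxGap)
  gstats <- clusterStats(gclust$clusters, gclust$singlets, species = species)

  # stage 5: position-5/35 statistics
  rflAnn <- annotations[intersect(rflIds, pclassIds)]
  otherAnn <- annotations[setdiff(pclassIds, rflIds)]
  combos <- list(RFL = extractCombos(rflAnn, "RFL"),
                 P = extractCombos(otherAnn, "P-class"))
  enrichment <- NULL
  baseComp <- list()
  if (combos$RFL$total > 0L && combos$P$total > 0L) {
    enrichment <- comboEnrichment(combos$RFL, combos$P,
                                  alpha = config$alpha, topN = config$topN)
    baseComp <- list(
      RFL = baseComposition(combos$RFL, config$codeTable, config$massCutoff),
      P = baseComposition(combos$P, config$codeTable, config$massCutoff))
  }
  targets <- vapply(rflAnn, predictTargets, character(1),
                    code = config$codeTable)

  # stage 6: motif evolution within the largest genomic cluster
  motifEvo <- NULL
  sizes <- vapply(gclust$clusters, function(cl) length(cl$members), integer(1))
  if (length(sizes) && max(sizes) >= 2L) {
    big <- gclust$clusters[[which.max(sizes)]]
    ids <- intersect(big$members, names(rflAnn))
    if (length(ids) >= 2L) {
      inst <- motifInstances(annotations[ids],
                             stats::setNames(as.character(proteins[ids]), ids))
      if (nrow(inst) >= 3L) {
        labeling <- labelMotifs(inst)
        archs <- lapply(ids, function(id) architectureOf(labeling, id))
        names(archs) <- ids
        diffs <- list()
        if (length(ids) >= 2L) {
          for (i in seq_len(length(ids) - 1L)) {
            key <- paste0(ids[i], "->", ids[i + 1L])
            diffs[[key]] <- diffArchitectures(archs[[ids[i]]],
                                              archs[[ids[i + 1L]]])
          }
        }
        motifEvo <- list(cluster = big, instances = inst,
                         tree = motifDistanceTree(inst),
                         labeling = labeling, architectures = archs,
                         diffs = diffs)
      }
    }
  }

  funnel <- list(nOrfs = nOrfs, nPpr = nPpr, nPclass = nPclass,
                 methodCounts = vapply(methods, function(m)
                   length(m$rflIds), integer(1)))
  result <- list(orfs = orfs, annotations = annotations,
                 pclassIds = pclassIds, methods = methods,
                 consensus = consensus, rflIds = rflIds, loci = loci,
                 genomicClusters = gclust, clusterStats = gstats,
                 combos = combos, enrichment = enrichment,
                 baseComposition = baseComp, targets = targets,
                 motifEvolution = motifEvo, funnel = funnel,
                 config = config)
  if (!is.null(outDir)) writeReportBundle(result, outDir)
  result
}

# write all stage outputs as plain-text files plus a run manifest
writeReportBundle <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeOrfFasta(result$orfs, file.path(outDir, "orfs.fasta"))
  writeGff3(result$orfs, file.path(outDir, "orfs.gff3"), type = "ORF")
  utils::write.table(annotationTable(result$annotations),
                     file.path(outDir, "motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(result$pclassIds, file.path(outDir, "pclass_ids.txt"))
  for (m in names(result$methods))
    writeLines(result$methods[[m]]$rflIds,
               file.path(outDir, paste0("rfl_", m, ".txt")))
  if (!is.null(result$consensus)) {
    blocks <- result$consensus$partition
    df <- data.frame(signature = rep(names(blocks),
                                     vapply(blocks, length, integer(1))),
                     id = unlist(blocks, use.names = FALSE))
    utils::write.table(df, file.path(outDir, "consensus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$clusterStats,
                     file.path(outDir, "cluster_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in names(result$combos))
    writeComboTable(result$combos[[g]],
                    file.path(outDir, paste0("combos_", g, ".tsv")))
  if (!is.null(result$enrichment))
    utils::write.table(result$enrichment,
                       file.path(outDir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (length(result$baseComposition)) {
    bc <- do.call(rbind, lapply(names(result$baseComposition), function(g)
      data.frame(group = g, t(result$baseComposition[[g]]))))
    utils::write.table(bc, file.path(outDir, "base_composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(result$targets))
    utils::write.table(data.frame(protein_id = names(result$targets),
                                  target = unname(result$targets)),
                       file.path(outDir, "targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(result$motifEvolution)) {
    ape::write.tree(result$motifEvolution$tree,
                    file.path(outDir, "motif_tree.nwk"))
    utils::write.table(eventTable(result$motifEvolution$diffs),
                       file.path(outDir, "motif_events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- result$config
  manifest <- c(
    paste0("package: RFLfinder ",
           as.character(utils::packageVersion("RFLfinder"))),
    paste0("R: ", R.version.string),
    paste0("seed: ", cfg$seed),
    vapply(setdiff(names(cfg), c("codeTable", "seed")), function(k)
      paste0(k, ": ", format(cfg[[k]])), character(1)))
  writeLines(manifest, file.path(outDir, "manifest.txt"))
  invisible(outDir)
}
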