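# Synthetic genomes with planted RFL clusters and full ground truth.
#
# The generator emulates the structure of the real inputs: multi-hundred-kbp
# chromosomes carrying clustered, intronless RFL genes built from tandem
# 35-aa P motifs (15-20 per gene), dispersed background P-class PPR genes
# (10-14 motifs), and non-PPR background ORFs, diverging by point mutation
# plus motif-level duplication / deletion / insertion / transposition /
# unequal-crossover events.
#
# Motif positions fall into three tiers: a structurally conserved core
# (never mutated by family divergence, so every PPR gene stays detectable
# by the scoring profile), the base-specifying code positions 5 and 35
# (drawn from group-specific combination biases, modelling diversifying
# selection), and variable positions (carrying family- and motif-level
# divergence, so unrelated families fall below clustering thresholds).

PPR_CORE_POS <- c(2L, 6L, 13L, 20L, 27L, 31L)
PPR_CODE_POS <- c(5L, 35L)
PPR_VAR_POS <- setdiff(1:35, c(PPR_CORE_POS, PPR_CODE_POS))

#' Default (aa5, aa35) combination biases
#'
#' Group-specific distributions over position-5/35 amino-acid pairs. The
#' P-class background is dominated by TD (G) and TN (A) with common
#' C-recognising NS/NT; the RFL bias doubles SD and SN, makes GD/GN
#' unusually common and NS/NT rare, reproducing the purine shift of RFL
#' proteins relative to other P-class proteins.
#'
#' @return Named list with elements \code{RFL} and \code{P}, each a named
#'   probability vector over two-letter combos.
#' @export
defaultComboBias <- function() {
  filler <- c("AD", "AN", "TS", "TT", "SS", "MD", "LN", "VD")
  p <- c(TD = 0.14, TN = 0.12, NS = 0.10, NT = 0.08, ND = 0.08,
         SD = 0.05, SN = 0.05, GD = 0.03, GN = 0.03)
  p <- c(p, stats::setNames(rep((1 - sum(p)) / length(filler),
                                length(filler)), filler))
  r <- c(SD = 0.10, SN = 0.10, TD = 0.10, TN = 0.09, ND = 0.08,
         GD = 0.06, GN = 0.06, NS = 0.02, NT = 0.02)
  r <- c(r, stats::setNames(rep((1 - sum(r)) / length(filler),
                                length(filler)), filler))
  list(RFL = r, P = p)
}

#' Specification for a synthetic genome
#'
#' Collects and validates all generator parameters. Defaults define the
#' reference study conditions: five 160-kbp chromosomes, three RFL
#' clusters of 3-5 intronless genes plus two singlet RFL genes (each
#' cluster or singlet on its own chromosome), six dispersed background
#' P-class PPR genes and a light scatter of non-PPR ORFs.
#'
#' @param seed integer RNG seed.
#' @param nChromosomes,chromosomeLength chromosome count and length (bp).
#' @param nClusters number of planted RFL clusters.
#' @param genesPerCluster integer range \code{c(min, max)} of genes per
#'   cluster.
#' @param nSingletRfl number of dispersed singlet RFL genes.
#' @param nBackgroundPpr number of dispersed background P-class PPR genes.
#' @param motifsPerRfl motif-count range for RFL genes (default 15-20).
#' @param motifsPerBackgroundPpr motif-count range for background PPR
#'   genes (default 10-14).
#' @param motifDivergence per-residue substitution probability applied to
#'   variable motif positions of every placed gene.
#' @param motifHeterogeneity per-residue divergence between the motifs of
#'   one ancestral architecture (makes tandem motifs distinguishable).
#' @param familyDivergence per-residue divergence of each background PPR
#'   family's motif flavour from the consensus (variable positions only).
#' @param comboRefresh probability per motif per placed gene of redrawing
#'   the (aa5, aa35) pair from the group bias (diversifying selection at
#'   the code positions).
#' @param eventRates named probabilities per gene for
#'   \code{duplication}, \code{deletion}, \code{insertion},
#'   \code{transposition}, \code{unequal_crossover}.
#' @param comboBias list with elements \code{RFL} and \code{P}: named
#'   probability vectors over two-letter (aa5, aa35) combos.
#' @param backgroundOrfDensity non-PPR background ORFs per kbp.
#' @param orfLength length range (aa) of background ORFs.
#' @param intergenicGap,clusterGap sampled gap ranges (bp) between items
#'   and between genes within a cluster.
#' @return A validated \code{SyntheticSpec} (list).
#' @export
syntheticSpec <- function(seed = 1L,
                          nChromosomes = 5L,
                          chromosomeLength = 160000L,
                          nClusters = 3L,
                          genesPerCluster = c(3L, 5L),
                          nSingletRfl = 2L,
                          nBackgroundPpr = 6L,
                          motifsPerRfl = c(15L, 20L),
                          motifsPerBackgroundPpr = c(10L, 14L),
                          motifDivergence = 0.05,
                          motifHeterogeneity = 0.15,
                          familyDivergence = 1,
                          comboRefresh = 1,
                          eventRates = c(duplication = 0.15,
                                         deletion = 0.15,
                                         insertion = 0.05,
                                         transposition = 0.05,
                                         unequal_crossover = 0.10),
                          comboBias = defaultComboBias(),
                          backgroundOrfDensity = 0.02,
                          orfLength = c(100L, 200L),
                          intergenicGap = c(4000L, 12000L),
                          clusterGap = c(2000L, 8000L)) {
  spec <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
               chromosomeLength = as.integer(chromosomeLength),
               nClusters = as.integer(nClusters),
               genesPerCluster = as.integer(genesPerCluster),
               nSingletRfl = as.integer(nSingletRfl),
               nBackgroundPpr = as.integer(nBackgroundPpr),
               motifsPerRfl = as.integer(motifsPerRfl),
               motifsPerBackgroundPpr = as.integer(motifsPerBackgroundPpr),
               motifDivergence = motifDivergence,
               motifHeterogeneity = motifHeterogeneity,
               familyDivergence = familyDivergence,
               comboRefresh = comboRefresh,
               eventRates = eventRates,
               comboBias = comboBias,
               backgroundOrfDensity = backgroundOrfDensity,
               orfLength = as.integer(orfLength),
               intergenicGap = as.integer(intergenicGap),
               clusterGap = as.integer(clusterGap))
  probs <- c(spec$motifDivergence, spec$motifHeterogeneity,
             spec$familyDivergence, spec$comboRefresh, spec$eventRates)
  if (any(probs < 0 | probs > 1))
    stageStop("synthetic_data", "probabilities must lie in [0, 1]")
  need <- c("duplication", "deletion", "insertion", "transposition",
            "unequal_crossover")
  if (!all(need %in% names(spec$eventRates)))
    stageStop("synthetic_data", "eventRates must name: ",
              paste(need, collapse = ", "))
  for (rg in list(spec$genesPerCluster, spec$motifsPerRfl,
                  spec$motifsPerBackgroundPpr, spec$orfLength,
                  spec$intergenicGap, spec$clusterGap)) {
    if (length(rg) != 2L || rg[1L] > rg[2L] || rg[1L] < 1L)
      stageStop("synthetic_data", "ranges must be non-empty c(min, max)")
  }
  for (g in c("RFL", "P")) {
    bias <- spec$comboBias[[g]]
    if (is.null(bias) || abs(sum(bias) - 1) > 1e-6 ||
        any(nchar(names(bias)) != 2L))
      stageStop("synthetic_data", "comboBias$", g,
                " must be a named probability vector over 2-letter combos")
  }
  if (spec$chromosomeLength < 1000L || spec$nChromosomes < 1L)
    stageStop("synthetic_data", "chromosomes must be at least 1 kbp")
  structure(spec, class = "SyntheticSpec")
}

# ---- internal helpers -----------------------------------------------------

sampleRange <- function(rg) if (rg[1L] == rg[2L]) rg[1L] else
  sample(rg[1L]:rg[2L], 1L)

# substitute residues at the given positions with probability rate
mutateChars <- function(chars, rate, positions = seq_along(chars)) {
  if (rate <= 0) return(chars)
  hit <- positions[stats::runif(length(positions)) < rate]
  for (i in hit)
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  chars
}

drawCombo <- function(bias) {
  combo <- sample(names(bias), 1L, prob = bias)
  c(substr(combo, 1L, 1L), substr(combo, 2L, 2L))
}

# a motif is a list(label, chars (35 residues incl. code positions))
newMotif <- function(flavorChars, label, heterogeneity, bias) {
  chars <- mutateChars(flavorChars, heterogeneity, PPR_VAR_POS)
  ab <- drawCombo(bias)
  chars[PPR_CODE_POS] <- ab
  list(label = label, chars = chars)
}

motifResidues <- function(motif) paste(motif$chars, collapse = "")

# reverse-translate a protein, sampling uniformly among synonymous codons
reverseTranslate <- function(protein) {
  aas <- strsplit(protein, "")[[1L]]
  paste(vapply(aas, function(a) {
    cods <- SYNONYMOUS_CODONS[[a]]
    if (is.null(cods))
      stageStop("synthetic_data", "cannot reverse-translate residue: ", a)
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1)), collapse = "")
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

REV_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
revcompString <- function(s) {
  paste(rev(REV_BASE[strsplit(s, "")[[1L]]]), collapse = "")
}

# apply motif-level events to a motif list; returns list(motifs, events)
applyMotifEvents <- function(motifs, ancestor, rates, freshLabel,
                             minMotifs = 10L, maxMotifs = 25L) {
  events <- character(0)
  n <- function() length(motifs)
  if (stats::runif(1) < rates[["duplication"]] && n() < maxMotifs) {
    i <- sample(n(), 1L)
    motifs <- append(motifs, motifs[i], after = i)
    events <- c(events, paste0("duplication@", i))
  }
  if (stats::runif(1) < rates[["deletion"]] && n() > minMotifs) {
    i <- sample(n(), 1L)
    motifs <- motifs[-i]
    events <- c(events, paste0("deletion@", i))
  }
  if (stats::runif(1) < rates[["insertion"]] && n() < maxMotifs) {
    i <- sample(n() + 1L, 1L)
    motifs <- append(motifs, list(freshLabel()), after = i - 1L)
    events <- c(events, paste0("insertion@", i))
  }
  if (stats::runif(1) < rates[["transposition"]] && n() >= 4L) {
    len <- sample(1:2, 1L)
    i <- sample(n() - len + 1L, 1L)
    j <- sample(setdiff(seq_len(n() - len + 1L), i), 1L)
    blk <- motifs[i:(i + len - 1L)]
    motifs <- append(motifs[-(i:(i + len - 1L))], blk, after = j - 1L)
    events <- c(events, paste0("transposition@", i, ">", j))
  }
  if (stats::runif(1) < rates[["unequal_crossover"]]) {
    for (try in 1:10) {
      i <- sample(n(), 1L)
      j <- sample(length(ancestor), 1L)
      cand <- c(motifs[seq_len(i)],
                if (j < length(ancestor)) ancestor[(j + 1L):length(ancestor)])
      if (length(cand) >= minMotifs && length(cand) <= maxMotifs) {
        motifs <- cand
        events <- c(events, paste0("unequal_crossover@", i, "x", j))
        break
      }
    }
  }
  list(motifs = motifs, events = events)
}

# derive a placed gene from its ancestral motif list
deriveGene <- function(ancestor, spec, bias, freshLabel, applyEvents = TRUE) {
  motifs <- ancestor
  events <- character(0)
  if (applyEvents) {
    ev <- applyMotifEvents(motifs, ancestor, spec$eventRates, freshLabel)
    motifs <- ev$motifs
    events <- ev$events
  }
  motifs <- lapply(motifs, function(m) {
    m$chars <- mutateChars(m$chars, spec$motifDivergence, PPR_VAR_POS)
    if (stats::runif(1) < spec$comboRefresh)
      m$chars[PPR_CODE_POS] <- drawCombo(bias)
    m
  })
  list(motifs = motifs, events = events)
}

geneFromMotifs <- function(motifs) {
  paste0("M", paste(vapply(motifs, motifResidues, character(1)),
                    collapse = ""))
}

#' Generate a synthetic genome with ground truth
#'
#' Builds the genome described by a \code{\link{syntheticSpec}}: each RFL
#' cluster is grown from a sampled ancestral architecture by tandem
#' duplication of the gene within a genomic window, followed by motif-level
#' events and point mutations in each copy; singlet RFL genes, background
#' P-class PPR genes and non-PPR ORFs are dispersed across the
#' chromosomes. Proteins are reverse-translated with uniformly sampled
#' synonymous codons (in-frame stops are impossible by construction) and
#' placed on either strand with probability 1/2. Deterministic for a
#' fixed seed.
#'
#' @param spec a \code{SyntheticSpec}.
#' @return List with \code{genome} (\code{DNAStringSet}), \code{truth}
#'   (list: \code{genes} data.frame with 1-based coordinates, strand,
#'   family, cluster_id, n_motifs, architecture, events, protein;
#'   \code{motifs} data.frame with per-motif label, aa5, aa35, residues;
#'   \code{references} named character vector of the cluster-ancestor
#'   proteins) and \code{spec}.
#' @export
generateGenome <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  consensus <- strsplit(pprPConsensus(), "")[[1L]]

  genes <- list()     # each: list(kind, id, cluster, protein, motifs, events)
  items <- list()     # placement items: list(kind, gene_ids)
  references <- character(0)

  # RFL clusters
  labCounter <- new.env()
  for (cl in seq_len(spec$nClusters)) {
    labCounter$n <- 0L
    freshLabel <- function() {
      labCounter$n <- labCounter$n + 1L
      newMotif(consensus, paste0("x", labCounter$n),
               spec$motifHeterogeneity, spec$comboBias$RFL)
    }
    nm <- sampleRange(spec$motifsPerRfl)
    anc <- lapply(seq_len(nm), function(i)
      newMotif(consensus, labelSeq(nm)[i], spec$motifHeterogeneity,
               spec$comboBias$RFL))
    ancProt <- geneFromMotifs(anc)
    references[paste0("RFLref_", cl)] <- ancProt
    k <- sampleRange(spec$genesPerCluster)
    ids <- paste0("RFL_c", cl, "_g", seq_len(k))
    for (g in seq_len(k)) {
      d <- deriveGene(anc, spec, spec$comboBias$RFL, freshLabel)
      genes[[ids[g]]] <- list(kind = "RFL", id = ids[g],
                              cluster = paste0("C", cl),
                              motifs = d$motifs, events = d$events,
                              protein = geneFromMotifs(d$motifs))
    }
    items[[length(items) + 1L]] <- list(kind = "cluster", gene_ids = ids)
  }

  # singlet RFL genes, derived from a sampled cluster ancestor
  for (sg in seq_len(spec$nSingletRfl)) {
    cl <- sample(spec$nClusters, 1L)
    # rebuild the ancestor motif list from the stored reference protein
    prot <- references[[paste0("RFLref_", cl)]]
    nm <- (nchar(prot) - 1L) / 35L
    anc <- lapply(seq_len(nm), function(i) list(
      label = labelSeq(nm)[i],
      chars = strsplit(substr(prot, 2L + (i - 1L) * 35L, 1L + i * 35L),
                       "")[[1L]]))
    labCounter$n <- 100L * sg
    freshLabel <- function() {
      labCounter$n <- labCounter$n + 1L
      newMotif(consensus, paste0("x", labCounter$n),
               spec$motifHeterogeneity, spec$comboBias$RFL)
    }
    id <- paste0("RFL_s", sg)
    d <- deriveGene(anc, spec, spec$comboBias$RFL, freshLabel)
    genes[[id]] <- list(kind = "RFL", id = id, cluster = NA_character_,
                        motifs = d$motifs, events = d$events,
                        protein = geneFromMotifs(d$motifs))
    items[[length(items) + 1L]] <- list(kind = "single", gene_ids = id)
  }

  # background P-class PPR genes: one divergent family flavour each
  for (bg in seq_len(spec$nBackgroundPpr)) {
    flavor <- mutateChars(consensus, spec$familyDivergence, PPR_VAR_POS)
    nm <- sampleRange(spec$motifsPerBackgroundPpr)
    anc <- lapply(seq_len(nm), function(i)
      newMotif(flavor, labelSeq(nm)[i], spec$motifHeterogeneity,
               spec$comboBias$P))
    id <- paste0("BGPPR_", bg)
    d <- deriveGene(anc, spec, spec$comboBias$P,
                    freshLabel = function() newMotif(
                      flavor, "x", spec$motifHeterogeneity, spec$comboBias$P),
                    applyEvents = FALSE)
    genes[[id]] <- list(kind = "background", id = id, cluster = NA_character_,
                        motifs = d$motifs, events = character(0),
                        protein = geneFromMotifs(d$motifs))
    items[[length(items) + 1L]] <- list(kind = "single", gene_ids = id)
  }

  # non-PPR background ORFs
  nOrfs <- round(spec$backgroundOrfDensity *
                 spec$nChromosomes * spec$chromosomeLength / 1000)
  for (o in seq_len(nOrfs)) {
    len <- sampleRange(spec$orfLength)
    id <- paste0("ORF_", o)
    genes[[id]] <- list(kind = "orf", id = id, cluster = NA_character_,
                        motifs = list(), events = character(0),
                        protein = paste(sample(AA20, len, replace = TRUE),
                                        collapse = ""))
    items[[length(items) + 1L]] <- list(kind = "single", gene_ids = id)
  }

  # reverse-translate and assign strands
  for (id in names(genes)) {
    genes[[id]]$dna <- reverseTranslate(genes[[id]]$protein)
    genes[[id]]$strand <- if (stats::runif(1) < 0.5) "+" else "-"
  }

  # place items across chromosomes. Each RFL item (cluster or singlet)
  # gets its own chromosome, mirroring the one-cluster-per-chromosome
  # organisation of the real genomes and keeping distinct planted clusters
  # from chaining into one called cluster; other items are placed
  # first-fit in shuffled order.
  chromNames <- paste0("chr", seq_len(spec$nChromosomes))
  cursor <- stats::setNames(rep(1L, spec$nChromosomes), chromNames)
  placements <- list()  # gene_id -> list(chrom, start, end)
  isRflItem <- vapply(items, function(it)
    genes[[it$gene_ids[1L]]]$kind == "RFL", logical(1))
  if (sum(isRflItem) > spec$nChromosomes)
    stageStop("synthetic_data", "infeasible packing: ", sum(isRflItem),
              " RFL clusters/singlets need as many chromosomes, got ",
              spec$nChromosomes)
  placeItem <- function(it, allowed) {
    gl <- lapply(it$gene_ids, function(id) genes[[id]])
    gaps <- if (length(gl) > 1L)
      vapply(seq_len(length(gl) - 1L), function(i)
        sampleRange(spec$clusterGap), integer(1)) else integer(0)
    span <- sum(vapply(gl, function(g) nchar(g$dna), integer(1))) + sum(gaps)
    pre <- sampleRange(spec$intergenicGap)
    for (chrom in allowed) {
      if (cursor[chrom] + pre + span - 1L <= spec$chromosomeLength) {
        pos <- cursor[chrom] + pre
        for (i in seq_along(gl)) {
          id <- gl[[i]]$id
          w <- nchar(gl[[i]]$dna)
          placements[[id]] <<- list(chrom = chrom, start = pos,
                                    end = pos + w - 1L)
          pos <- pos + w + (if (i < length(gl)) gaps[i] else 0L)
        }
        cursor[chrom] <<- pos
        return(TRUE)
      }
    }
    FALSE
  }
  rflItems <- which(isRflItem)
  for (k in seq_along(rflItems)) {
    if (!placeItem(items[[rflItems[k]]], chromNames[k]))
      stageStop("synthetic_data", "infeasible packing: RFL item does not ",
                "fit on chromosome ", k, "; increase chromosomeLength")
  }
  for (it in items[sample(length(items))]) {
    if (genes[[it$gene_ids[1L]]]$kind == "RFL") next
    if (!placeItem(it, chromNames))
      stageStop("synthetic_data", "infeasible packing: item does not fit ",
                "on any chromosome; increase chromosomeLength or reduce ",
                "gene counts")
  }

  # assemble chromosomes: random background overwritten by gene DNA
  chromSeq <- stats::setNames(
    vapply(chromNames, function(ch) randomDnaString(spec$chromosomeLength),
           character(1)), chromNames)
  for (id in names(placements)) {
    pl <- placements[[id]]
    dna <- genes[[id]]$dna
    if (genes[[id]]$strand == "-") dna <- revcompString(dna)
    substr(chromSeq[[pl$chrom]], pl$start, pl$end) <- dna
  }
  genome <- Biostrings::DNAStringSet(chromSeq)
  S4Vectors::metadata(genome)$species <- "synthetic"

  # ground-truth tables
  placedIds <- names(placements)
  truthGenes <- do.call(rbind, lapply(placedIds, function(id) {
    g <- genes[[id]]
    pl <- placements[[id]]
    data.frame(gene_id = id, species = "synthetic", chromosome = pl$chrom,
               start = pl$start, end = pl$end, strand = g$strand,
               family = g$kind, cluster_id = g$cluster,
               n_motifs = length(g$motifs),
               architecture = paste(vapply(g$motifs, `[[`, character(1),
                                           "label"), collapse = ","),
               events = paste(g$events, collapse = ";"),
               protein = g$protein, stringsAsFactors = FALSE)
  }))
  if (is.null(truthGenes))
    truthGenes <- data.frame(gene_id = character(), species = character(),
                             chromosome = character(), start = integer(),
                             end = integer(), strand = character(),
                             family = character(), cluster_id = character(),
                             n_motifs = integer(), architecture = character(),
                             events = character(), protein = character(),
                             stringsAsFactors = FALSE)
  truthGenes <- truthGenes[order(truthGenes$chromosome, truthGenes$start), ]
  rownames(truthGenes) <- NULL
  truthMotifs <- do.call(rbind, lapply(placedIds, function(id) {
    g <- genes[[id]]
    if (!length(g$motifs)) return(NULL)
    data.frame(gene_id = id, index = seq_along(g$motifs),
               label = vapply(g$motifs, `[[`, character(1), "label"),
               aa5 = vapply(g$motifs, function(m) m$chars[5L], character(1)),
               aa35 = vapply(g$motifs, function(m) m$chars[35L], character(1)),
               residues = vapply(g$motifs, motifResidues, character(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truthMotifs))
    truthMotifs <- data.frame(gene_id = character(), index = integer(),
                              label = character(), aa5 = character(),
                              aa35 = character(), residues = character(),
                              stringsAsFactors = FALSE)
  rownames(truthMotifs) <- NULL
  list(genome = genome,
       truth = list(genes = truthGenes, motifs = truthMotifs,
                    references = references),
       spec = spec)
}

#' Simulate a P-motif training alignment
#'
#' Samples motif instances around the P consensus with high conservation
#' at the structural core, family-level diversity at variable positions
#' and code positions drawn from a mixture of the RFL and P-class biases.
#' Used to build the scanning profile.
#'
#' @param n number of aligned motifs (default 150).
#' @param coreConservation per-residue consensus probability at core
#'   positions (default 0.95).
#' @param variableDivergence per-residue substitution probability at
#'   variable positions (default 0.80, emulating the diversity of a
#'   family-wide motif collection).
#' @param comboBias combination bias list (mixed 50/50 across groups).
#' @param seed optional RNG seed.
#' @return Named character vector of aligned 35-aa motif sequences.
#' @export
simulateMotifAlignment <- function(n = 150L, coreConservation = 0.95,
                                   variableDivergence = 0.80,
                                   comboBias = defaultComboBias(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  consensus <- strsplit(pprPConsensus(), "")[[1L]]
  mix <- (comboBias$RFL + comboBias$P[names(comboBias$RFL)]) / 2
  out <- vapply(seq_len(n), function(i) {
    chars <- mutateChars(consensus, 1 - coreConservation, PPR_CORE_POS)
    chars <- mutateChars(chars, variableDivergence, PPR_VAR_POS)
    chars[PPR_CODE_POS] <- drawCombo(mix)
    paste(chars, collapse = "")
  }, character(1))
  stats::setNames(out, paste0("motif_", seq_len(n)))
}

#' Write ground truth to plain-text files
#'
#' Emits the gene table as GFF3 (1-based inclusive coordinates) and TSV,
#' the per-motif architecture/combination table as TSV, and the gene and
#' reference proteins as FASTA. All outputs are re-parsable by the other
#' modules.
#'
#' @param truth the \code{truth} element of \code{\link{generateGenome}}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gff = file.path(dir, "genes.gff3"),
             genes = file.path(dir, "genes.tsv"),
             motifs = file.path(dir, "motifs.tsv"),
             proteins = file.path(dir, "proteins.fasta"),
             references = file.path(dir, "references.fasta"))
  g <- truth$genes
  if (nrow(g)) {
    gr <- geneLoci(g$gene_id, g$chromosome, g$start, g$end, g$strand,
                   species = g$species, is_rfl = g$family == "RFL",
                   n_motifs = g$n_motifs)
    writeGff3(gr, paths["gff"], type = "gene")
  } else {
    writeLines("##gff-version 3", paths["gff"])
  }
  utils::write.table(g[, setdiff(names(g), "protein"), drop = FALSE],
                     paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$motifs, paths["motifs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prot <- Biostrings::AAStringSet(
    stats::setNames(g$protein, g$gene_id))
  Biostrings::writeXStringSet(prot, paths["proteins"])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(truth$references), paths["references"])
  invisible(paths)
}
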