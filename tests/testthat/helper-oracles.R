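# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity from first principles and do
# not call the implementation paths they check.

# --- six-frame ORF enumeration --------------------------------------------

# codon -> amino acid, from the standard code table (data, not translate())
.GC <- Biostrings::GENETIC_CODE

oracleTranslate <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  cods <- substring(dna, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(.GC[cods])
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

oracleRevcomp <- function(dna) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(dna, "")[[1L]]]), collapse = "")
}

# every maximal stop-free run of >= minCodons codons in all six frames,
# as a data.frame with 1-based forward-strand coordinates
oracleSixFrameOrfs <- function(dna, minCodons) {
  L <- nchar(dna)
  out <- list()
  for (str in c("+", "-")) {
    rs <- if (str == "+") dna else oracleRevcomp(dna)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < 1L) next
      aa <- oracleTranslate(substr(rs, f + 1L, f + 3L * ncod))
      chars <- strsplit(aa, "")[[1L]]
      run_start <- NULL
      for (i in seq_len(length(chars) + 1L)) {
        stop_here <- i > length(chars) || chars[i] == "*"
        if (!stop_here && is.null(run_start)) run_start <- i
        if (stop_here && !is.null(run_start)) {
          len <- i - run_start
          if (len >= minCodons) {
            rd_start <- f + 3L * (run_start - 1L) + 1L
            rd_end <- f + 3L * (i - 1L)
            if (str == "+") {
              gs <- rd_start; ge <- rd_end
            } else {
              gs <- L - rd_end + 1L; ge <- L - rd_start + 1L
            }
            out[[length(out) + 1L]] <- data.frame(
              start = gs, end = ge, strand = str, frame = f,
              n_codons = len,
              aa = substr(aa, run_start, i - 1L),
              stringsAsFactors = FALSE)
          }
          run_start <- NULL
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      n_codons = integer(), aa = character()))
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand, df$frame), ]
}

# --- Gotoh global alignment (affine gaps) ---------------------------------

# optimal global alignment score under match +1 / mismatch 0 /
# gap of length k costing open + k * ext
oracleAlignScore <- function(a, b, open = 10, ext = 0.5) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in aligned pair
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in b (x aligned to -)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in a
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -open - ext * i
  for (j in seq_len(m)) Y[1L, j + 1L] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) 1 else 0
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# --- weighted interval scheduling -----------------------------------------

# exhaustive maximum over all non-overlapping subsets of candidate hits
oracleBestTiling <- function(cand) {
  n <- nrow(cand)
  if (n == 0L) return(0)
  best <- 0
  for (mask in 0:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) < 2L) {
      sc <- sum(cand$score[sel])
    } else {
      o <- sel[order(cand$start[sel])]
      if (any(cand$start[o][-1L] <
              (cand$start[o] + cand$width[o])[-length(o)])) next
      sc <- sum(cand$score[sel])
    }
    if (sc > best) best <- sc
  }
  best
}

# --- Fisher exact (two-sided) by hypergeometric enumeration ---------------

oracleFisherP <- function(a, b, c, d) {
  # margins: row1 = a + b, col1 = a + c, total n
  n <- a + b + c + d
  k1 <- a + b
  m1 <- a + c
  lo <- max(0L, k1 + m1 - n)
  hi <- min(k1, m1)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m1, x) + lchoose(n - m1, k1 - x) - lchoose(n, k1)),
    numeric(1))
  pobs <- probs[a - lo + 1L]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# --- indel-only edit distance ---------------------------------------------

# minimal number of single-label insertions+deletions (no substitution)
oracleIndelDistance <- function(a, b) {
  a <- if (length(a) == 1L && nchar(a) > 1L) strsplit(a, "")[[1L]] else a
  b <- if (length(b) == 1L && nchar(b) > 1L) strsplit(b, "")[[1L]] else b
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j + 1L] + 1L,
        D[i + 1L, j] + 1L,
        if (a[i] == b[j]) D[i, j] else 1e9L)
    }
  }
  D[n + 1L, m + 1L]
}

# --- genomic gap chaining --------------------------------------------------

# brute-force neighbour scan: gene ids grouped with any neighbour within
# maxGap on the same chromosome, via transitive closure
oracleGapChains <- function(df, maxGap) {
  out <- list()
  for (chr in unique(df$chromosome)) {
    s <- df[df$chromosome == chr, ]
    s <- s[order(s$start), ]
    n <- nrow(s)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      gap <- max(s$start[j] - s$end[i], s$start[i] - s$end[j])
      adj[i, j] <- gap <= maxGap
    }
    comp <- rep(NA_integer_, n); nc <- 0L
    for (v in seq_len(n)) {
      if (!is.na(comp[v])) next
      nc <- nc + 1L
      q <- v
      while (length(q)) {
        u <- q[1L]; q <- q[-1L]
        if (!is.na(comp[u])) next
        comp[u] <- nc
        q <- c(q, which(adj[u, ] & is.na(comp)))
      }
    }
    out[[chr]] <- split(s$gene_id, comp)
  }
  out
}

# --- base composition cutoff rule -----------------------------------------

oracleBaseComposition <- function(counts, code, massCutoff) {
  df <- data.frame(combo = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$combo), ]
  freq <- df$count / sum(df$count)
  k <- which(cumsum(freq) >= massCutoff - 1e-12)[1L]
  used <- df[seq_len(k), ]
  lk <- stats::setNames(code$base, paste0(code$aa5, code$aa35))
  bases <- lk[used$combo]
  bases[is.na(bases)] <- "N"
  keep <- bases != "N"
  w <- tapply(used$count[keep],
              factor(bases[keep], levels = c("A", "C", "G", "U")), sum)
  w[is.na(w)] <- 0
  stats::setNames(as.numeric(w) / sum(w), c("A", "C", "G", "U"))
}

# --- shared fixtures -------------------------------------------------------

# deterministic scanning profile and its consensus, shared across tests
testProfile <- local({
  prof <- NULL
  function() {
    if (is.null(prof))
      prof <<- buildProfile(simulateMotifAlignment(seed = 17), "P")
    prof
  }
})

# the reference study conditions (default spec, seed 1), run once and
# shared by the pipeline and acceptance tests
defaultRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generateGenome(syntheticSpec(seed = 1))
      aln <- simulateMotifAlignment(seed = 17)
      res <- runPipeline(sim$genome, aln, sim$truth$references,
                         pipelineConfig(seed = 1))
      cache <<- list(sim = sim, aln = aln, res = res)
    }
    cache
  }
})

# larger generator conditions used for the combination-frequency and
# enrichment checks (>= 500 motifs in both groups)
# group sizes target ~1400 motifs per group: a two-proportion power
# calculation at alpha 0.01 for the doubled SD/SN frequencies (0.05 ->
# 0.10; SE = sqrt((p1 q1 + p2 q2)/n)) needs ~1320 per group for
# power 0.99
bigSpec <- function(seed = 1) {
  syntheticSpec(seed = seed, nChromosomes = 16L,
                chromosomeLength = 250000L,
                nClusters = 16L, genesPerCluster = c(5L, 6L),
                nSingletRfl = 0L, nBackgroundPpr = 115L,
                backgroundOrfDensity = 0)
}

bigSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateGenome(bigSpec(seed = 1))
    cache
  }
})

# ids of the P-class ORFs overlapping the planted RFL genes
plantedRflOrfs <- function(sim, res) {
  tg <- sim$truth$genes
  rfl <- tg[tg$family == "RFL", ]
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(rfl$chromosome,
                           IRanges::IRanges(rfl$start, rfl$end)),
    res$loci, ignore.strand = TRUE)
  list(genes = rfl,
       hit_genes = unique(S4Vectors::queryHits(ov)),
       orf_ids = unique(res$loci$gene_id[S4Vectors::subjectHits(ov)]))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

writeTempFasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}
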