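# helper: annotation built directly from a list of (aa5, aa35) pairs
annotationFromCombos <- function(combos, id = "prot", classLabel = "P") {
  n <- length(combos)
  hits <- data.frame(start = 35L * (seq_len(n) - 1L), width = 35L,
                     classLabel = classLabel, score = 10,
                     aa5 = vapply(combos, `[`, character(1), 1L),
                     aa35 = vapply(combos, `[`, character(1), 2L),
                     stringsAsFactors = FALSE)
  new("ProteinAnnotation", proteinId = id, hits = hits,
      nP = sum(hits$classLabel == "P"), nL = sum(hits$classLabel == "L"),
      nS = sum(hits$classLabel == "S"), totalScore = sum(hits$score),
      classification = if (sum(hits$classLabel == "P") >= 10L)
        "P-class" else "other")
}

test_that("profile log-odds match the hand-computed formula", {
  # single column {A, A, C}, pseudocount 1, uniform background
  prof <- buildProfile(c("A", "A", "C"), classLabel = "S", pseudocount = 1)
  lo <- prof@logOdds
  expect_equal(unname(lo[1, "A"]), log2((2 + 0.05) / 4 / 0.05))
  expect_equal(unname(lo[1, "C"]), log2((1 + 0.05) / 4 / 0.05))
  expect_equal(unname(lo[1, "W"]), log2(0.05 / 4 / 0.05))
  expect_true(validObject(prof))
})

test_that("a degenerate alignment scores its consensus maximally", {
  seqs <- rep("ACDEF", 2)
  prof <- buildProfile(seqs, classLabel = "S")
  expect_equal(profileConsensus(prof), "ACDEF")
  maxScore <- sum(apply(prof@logOdds, 1L, max))
  expect_equal(unname(scoreOffsets("ACDEF", prof)), maxScore)
  # every aligned residue carries its column's maximum
  chars <- strsplit("ACDEF", "")[[1]]
  for (i in 1:5)
    expect_equal(unname(prof@logOdds[i, chars[i]]),
                 max(prof@logOdds[i, ]))
})

test_that("profile building rejects bad alignments", {
  expect_error(buildProfile(c("AC", "ACD"), "S"), "ragged.*#2")
  expect_error(buildProfile(c(s1 = "AC", s2 = "ACD"), "S"), "s2")
  expect_error(buildProfile(c("A-", "A-", "AC"), "S"),
               "column 2.*occupancy")
  expect_error(buildProfile("ACDEF", "S"), "at least 2")
})

test_that("tandem consensus copies are tiled at offsets 0, 35, 70, ...", {
  prof <- testProfile()
  unit <- profileConsensus(prof)
  ann12 <- scanAndTile(strrep(unit, 12), prof, "p12")
  expect_equal(nrow(motifHits(ann12)), 12L)
  expect_equal(motifHits(ann12)$start, 35L * (0:11))
  expect_equal(nPMotifs(ann12), 12L)
  expect_equal(classification(ann12), "P-class")
  # 9 copies fail the >= 10 P-motif retention rule
  ann9 <- scanAndTile(strrep(unit, 9), prof, "p9")
  expect_equal(nPMotifs(ann9), 9L)
  expect_equal(classification(ann9), "other")
})

test_that("tiling DP equals the exhaustive non-overlapping optimum", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:12, 1)
    cand <- data.frame(start = sample(0:60, n, replace = TRUE),
                       width = sample(c(10L, 20L, 35L), n, replace = TRUE),
                       classLabel = sample(c("P", "L", "S"), n,
                                           replace = TRUE),
                       score = round(runif(n, 1, 20), 2),
                       stringsAsFactors = FALSE)
    sel <- RFLfinder:::tileHits(cand)
    if (nrow(sel) > 1L) {
      expect_true(all(sel$start[-1] >=
                      (sel$start + sel$width)[-nrow(sel)]))
    }
    expect_equal(sum(sel$score), oracleBestTiling(cand), tolerance = 1e-9)
  }
})

test_that("raising the hit threshold never increases the P-motif count", {
  set.seed(7)
  prof <- testProfile()
  unit <- profileConsensus(prof)
  protein <- paste0(
    paste(sample(RFLfinder:::AA20, 30, replace = TRUE), collapse = ""),
    strrep(unit, 11))
  counts <- vapply(c(2, 5, 8, 15, 30, 60), function(th) {
    p <- prof; p@hitThreshold <- th
    nPMotifs(scanAndTile(protein, p))
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("implanted motifs are recovered at their planted offsets", {
  prof <- testProfile()
  unit <- strsplit(profileConsensus(prof), "")[[1]]
  set.seed(99)
  total <- 0L; found <- 0L
  for (rep in 1:30) {
    nm <- sample(10:15, 1)
    motifs <- vapply(seq_len(nm), function(i) {
      m <- RFLfinder:::mutateChars(unit, 0.10)  # <= 10% substitution
      paste(m, collapse = "")
    }, character(1))
    lead <- sample(0:20, 1)
    protein <- paste0(paste(sample(RFLfinder:::AA20, lead, replace = TRUE),
                            collapse = ""),
                      paste(motifs, collapse = ""))
    planted <- lead + 35L * (seq_len(nm) - 1L)
    got <- motifHits(scanAndTile(protein, prof))$start
    total <- total + nm
    found <- found + sum(planted %in% got)
  }
  expect_gte(found / total, 0.95)
})

test_that("aa5/aa35 of every P hit equal direct string indexing", {
  prof <- testProfile()
  set.seed(5)
  unit <- strsplit(profileConsensus(prof), "")[[1]]
  protein <- paste(vapply(1:12, function(i)
    paste(RFLfinder:::mutateChars(unit, 0.08), collapse = ""),
    character(1)), collapse = "")
  ann <- scanAndTile(protein, prof)
  h <- motifHits(ann)
  expect_gt(nrow(h), 0L)
  expect_equal(h$aa5, substring(protein, h$start + 5L, h$start + 5L))
  expect_equal(h$aa35, substring(protein, h$start + 35L, h$start + 35L))
})

test_that("PLS-class and short proteins classify as documented", {
  # two consecutive P,L,S triplets
  expect_equal(RFLfinder:::classifyMotifChain(
    c("P", "L", "S", "P", "L", "S")), "PLS-class")
  expect_equal(RFLfinder:::classifyMotifChain(rep("P", 10)), "P-class")
  expect_equal(RFLfinder:::classifyMotifChain(
    c(rep("P", 10), "L", "S", "S")), "other")
  expect_equal(RFLfinder:::classifyMotifChain(character(0)), "other")
  # a protein shorter than the motif yields an empty "other" annotation
  ann <- scanAndTile("MKV", testProfile(), "tiny")
  expect_equal(nrow(motifHits(ann)), 0L)
  expect_equal(classification(ann), "other")
})

test_that("score summaries are symmetric and ordered by generator design", {
  a15 <- annotationFromCombos(rep(list(c("T", "D")), 15), id = "a")
  b15 <- annotationFromCombos(rep(list(c("T", "D")), 15), id = "b")
  s <- scoreSummaries(list(a15, b15), c("g1", "g2"))
  expect_equal(s$perProtein$n_motifs, c(15L, 15L))
  g <- s$groupSummary
  expect_equal(g$median_motifs[g$group == "g1"],
               g$median_motifs[g$group == "g2"])
  # RFL proteins carry more motifs than background by construction
  rfl <- lapply(1:6, function(i)
    annotationFromCombos(rep(list(c("S", "D")), 15 + (i %% 5)),
                         id = paste0("r", i)))
  bg <- lapply(1:6, function(i)
    annotationFromCombos(rep(list(c("T", "D")), 10 + (i %% 4)),
                         id = paste0("b", i)))
  s2 <- scoreSummaries(c(rfl, bg), rep(c("RFL", "other"), each = 6))
  gs <- s2$groupSummary
  expect_gt(gs$median_motifs[gs$group == "RFL"],
            gs$median_motifs[gs$group == "other"])
})
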