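mkInstances <- function(residues, protein_id = "p") {
  data.frame(protein_id = protein_id, index = seq_along(residues),
             start = 35L * (seq_along(residues) - 1L),
             residues = residues, stringsAsFactors = FALSE)
}

randomMotif <- function() paste(sample(RFLfinder:::AA20, 35, replace = TRUE),
                                collapse = "")

test_that("motif instances are extracted in amino-terminal order", {
  prof <- testProfile()
  unit <- profileConsensus(prof)
  protein <- strrep(unit, 11)
  ann <- scanAndTile(protein, prof, "p1")
  inst <- motifInstances(list(ann), c(p1 = protein))
  expect_equal(nrow(inst), 11L)
  expect_equal(inst$index, 1:11)
  expect_true(all(inst$residues == unit))
  expect_error(motifInstances(list(ann), c(other = protein)), "missing")
})

test_that("identical motifs form a zero-length cherry in the distance tree", {
  set.seed(191)
  m1 <- randomMotif()
  m3 <- randomMotif()
  inst <- mkInstances(c(m1, m1, m3))
  tr <- motifDistanceTree(inst)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd["p.1", "p.2"], 0, tolerance = 1e-12)
  expect_gt(pd["p.1", "p.3"], 0.5)
  expect_true(all(tr$edge.length >= 0))
})

test_that("ragged motif lengths are rejected", {
  inst <- mkInstances(c(strrep("A", 35), strrep("A", 34), strrep("A", 35)))
  expect_error(motifDistanceTree(inst), "ragged")
})

test_that("motif families are monophyletic at the planted scale", {
  # 69 motifs from 5 proteins, in 5 divergent families
  set.seed(201)
  sizes <- c(14, 14, 14, 14, 13)
  fams <- lapply(1:5, function(f) {
    anc <- strsplit(randomMotif(), "")[[1]]
    vapply(seq_len(sizes[f]), function(i)
      paste(RFLfinder:::mutateChars(anc, 0.05), collapse = ""),
      character(1))
  })
  inst <- do.call(rbind, lapply(1:5, function(f)
    mkInstances(fams[[f]], protein_id = paste0("prot", f))))
  inst$index <- ave(seq_len(nrow(inst)), inst$protein_id, FUN = seq_along)
  expect_equal(nrow(inst), 69L)
  tr <- phangorn::midpoint(motifDistanceTree(inst))
  for (f in 1:5) {
    tips <- paste0("prot", f, ".", seq_len(sizes[f]))
    expect_true(ape::is.monophyletic(tr, tips))
  }
  # the same families drive the labelling
  lab <- labelMotifs(inst)
  expect_length(unique(lab$labels), 5L)
  fam_of <- rep(1:5, sizes)
  expect_equal(length(unique(paste(fam_of, lab$labels))), 5L)
})

test_that("motif labelling honours thresholds and identity of residues", {
  m <- randomMotif()
  inst <- mkInstances(c(m, m, m))
  expect_equal(unique(labelMotifs(inst)$labels), "A")

  set.seed(211)
  ancA <- strsplit(randomMotif(), "")[[1]]
  ancB <- RFLfinder:::mutateChars(ancA, 0.5)  # ~50% cross identity
  fam <- c(vapply(1:3, function(i)
             paste(RFLfinder:::mutateChars(ancA, 0.04), collapse = ""),
             character(1)),
           vapply(1:3, function(i)
             paste(RFLfinder:::mutateChars(ancB, 0.04), collapse = ""),
             character(1)))
  lab <- labelMotifs(mkInstances(fam))
  expect_equal(lab$labels[1:3], rep(lab$labels[1], 3))
  expect_equal(lab$labels[4:6], rep(lab$labels[4], 3))
  expect_false(lab$labels[1] == lab$labels[4])

  # threshold 1.0 degenerates to one label per distinct residue string
  mixed <- mkInstances(c(m, m, randomMotif(), randomMotif()))
  lab1 <- labelMotifs(mixed, identityThreshold = 1.0)
  expect_equal(length(unique(lab1$labels)), 3L)
})

test_that("architecture diffs match the worked examples", {
  d0 <- diffArchitectures("ABCD", "ABCD")
  expect_length(d0$events, 0L)

  d1 <- diffArchitectures("ABCD", "ABBCD")
  expect_length(d1$events, 1L)
  expect_equal(d1$events[[1]]$type, "duplication")
  expect_equal(d1$events[[1]]$label, "B")

  d2 <- diffArchitectures("ABCD", "ACBD")
  expect_length(d2$events, 1L)
  expect_equal(d2$events[[1]]$type, "transposition")

  d3 <- diffArchitectures("ABCD", "AXBCD")
  expect_length(d3$events, 1L)
  expect_equal(d3$events[[1]]$type, "insertion")
})

test_that("event scripts replay to the target architecture", {
  set.seed(221)
  for (rep in 1:40) {
    labs <- LETTERS[1:6]
    a <- sample(labs, sample(3:9, 1), replace = TRUE)
    b <- sample(labs, sample(3:9, 1), replace = TRUE)
    d <- diffArchitectures(a, b)
    expect_equal(applyEvents(a, d$events), b)
  }
  # including permutation pairs handled by transpositions
  for (rep in 1:15) {
    a <- sample(LETTERS[1:7], 7)
    b <- sample(a, 7)
    d <- diffArchitectures(a, b)
    expect_equal(applyEvents(a, d$events), b)
  }
})

test_that("indel event count equals the brute-force edit distance", {
  set.seed(231)
  for (rep in 1:40) {
    a <- sample(LETTERS[1:5], sample(2:12, 1), replace = TRUE)
    b <- sample(LETTERS[1:5], sample(2:12, 1), replace = TRUE)
    if (length(a) == length(b) && identical(sort(a), sort(b))) next
    d <- diffArchitectures(a, b)
    nIndel <- sum(vapply(d$events, function(e)
      e$type %in% c("insertion", "deletion", "duplication"), logical(1)))
    expect_equal(nIndel, as.integer(oracleIndelDistance(a, b)))
  }
})

test_that("planted single events are recovered by type", {
  set.seed(241)
  for (rep in 1:12) {
    n <- sample(8:14, 1)
    a <- labelSeqLocal <- LETTERS[seq_len(n)]
    # duplication
    i <- sample(n, 1)
    b <- append(a, a[i], after = i)
    d <- diffArchitectures(a, b)
    expect_equal(vapply(d$events, `[[`, character(1), "type"),
                 "duplication")
    # deletion
    b2 <- a[-sample(n, 1)]
    d2 <- diffArchitectures(a, b2)
    expect_equal(vapply(d2$events, `[[`, character(1), "type"), "deletion")
    # adjacent transposition
    i <- sample(n - 1, 1)
    b3 <- a; b3[c(i, i + 1)] <- b3[c(i + 1, i)]
    d3 <- diffArchitectures(a, b3)
    expect_equal(vapply(d3$events, `[[`, character(1), "type"),
                 "transposition")
  }
})

test_that("event tables flatten diffs for TSV output", {
  d <- diffArchitectures("ABCD", "ABBCD")
  tab <- eventTable(list(pair1 = d))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$type, "duplication")
  expect_equal(tab$pair, "pair1")
  expect_equal(nrow(eventTable(diffArchitectures("AB", "AB"))), 0L)
})
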