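# build a protein family: n mutated copies of a base sequence
mkFamily <- function(base, n, rate, prefix) {
  chars <- strsplit(base, "")[[1]]
  out <- vapply(seq_len(n), function(i)
    paste(RFLfinder:::mutateChars(chars, rate), collapse = ""),
    character(1))
  stats::setNames(out, paste0(prefix, seq_len(n)))
}

test_that("pairwise identity matches hand-countable cases", {
  m <- pairwiseIdentity("MKVLMKVL", "MKVLMKVL")
  expect_equal(m[["identity"]], 1)
  expect_equal(m[["coverage"]], 1)
  expect_equal(pairwiseIdentity("AAAA", "AATA")[["identity"]], 0.75)
  expect_equal(pairwiseIdentity("AAAA", "AATA")[["coverage"]], 1)
})

test_that("global alignment score equals the affine-gap Gotoh oracle", {
  set.seed(61)
  for (rep in 1:20) {
    a <- paste(sample(RFLfinder:::AA20, sample(5:30, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(RFLfinder:::AA20, sample(5:30, 1), replace = TRUE),
               collapse = "")
    m <- pairwiseIdentity(a, b)
    expect_equal(attr(m, "score"), oracleAlignScore(a, b),
                 tolerance = 1e-9)
  }
})

test_that("greedy clustering follows the representative rule", {
  same <- stats::setNames(rep("MKVAPLLE", 4), paste0("s", 1:4))
  expect_length(greedyIdentityCluster(same), 1L)

  set.seed(71)
  base1 <- paste(sample(RFLfinder:::AA20, 80, replace = TRUE), collapse = "")
  base2 <- paste(sample(RFLfinder:::AA20, 80, replace = TRUE), collapse = "")
  fams <- c(mkFamily(base1, 4, 0.05, "a"), mkFamily(base2, 4, 0.05, "b"))
  cl <- greedyIdentityCluster(fams)
  expect_length(cl, 2L)
  expect_setequal(
    lapply(cl, sort),
    list(sort(paste0("a", 1:4)), sort(paste0("b", 1:4))))
})

test_that("per-species clustering groups RFLs that a pooled run separates", {
  # two species whose RFLs fall below the 40% cross-species identity
  set.seed(81)
  spA <- mkFamily(paste(sample(RFLfinder:::AA20, 100, replace = TRUE),
                        collapse = ""), 3, 0.05, "spA_")
  spB <- mkFamily(paste(sample(RFLfinder:::AA20, 100, replace = TRUE),
                        collapse = ""), 3, 0.05, "spB_")
  pooled <- greedyIdentityCluster(c(spA, spB))
  expect_gte(length(pooled), 2L)  # one 40% run fails to merge the species
  expect_length(greedyIdentityCluster(spA), 1L)
  expect_length(greedyIdentityCluster(spB), 1L)
})

test_that("lowering the identity threshold never increases cluster count", {
  set.seed(91)
  seqs <- c(mkFamily(paste(sample(RFLfinder:::AA20, 60, replace = TRUE),
                           collapse = ""), 3, 0.15, "x"),
            mkFamily(paste(sample(RFLfinder:::AA20, 60, replace = TRUE),
                           collapse = ""), 3, 0.15, "y"))
  ns <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(th)
    length(greedyIdentityCluster(seqs, identityThreshold = th)), integer(1))
  expect_true(all(diff(ns) <= 0L))
})

test_that("orthogroup clustering resolves planted families and edge cases", {
  set.seed(101)
  bases <- replicate(3, paste(sample(RFLfinder:::AA20, 90, replace = TRUE),
                              collapse = ""))
  seqs <- c(mkFamily(bases[1], 4, 0.05, "f1_"),
            mkFamily(bases[2], 3, 0.05, "f2_"),
            mkFamily(bases[3], 3, 0.05, "f3_"))
  cl <- orthogroupCluster(seqs)
  expect_length(cl, 3L)
  got <- unname(lapply(cl, sort))
  expect_setequal(got, list(sort(paste0("f1_", 1:4)),
                            sort(paste0("f2_", 1:3)),
                            sort(paste0("f3_", 1:3))))
  # single sequence -> one singleton cluster
  expect_equal(orthogroupCluster(c(only = "MKVL"))[[1]], "only")
  # permutation invariance after the documented ordering
  cl2 <- orthogroupCluster(seqs[sample(length(seqs))])
  expect_setequal(unname(lapply(cl2, sort)), got)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- njTree(d3)
  pd3 <- ape::cophenetic.phylo(tr3)
  expect_equal(pd3[c("a", "b", "c"), c("a", "b", "c")], d3,
               tolerance = 1e-9)

  # 4 taxa from a known topology ((a,b),(c,d))
  tree4 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0);")
  d4 <- ape::cophenetic.phylo(tree4)
  tr4 <- njTree(d4)
  # topology: identical unrooted topology to the generating tree
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4),
                                         ape::unroot(tree4))), 0)
  # path lengths reproduce the additive input distances
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)],
               d4, tolerance = 1e-9)

  # ultrametric 4-taxon input is also reproduced
  du <- matrix(c(0, 2, 8, 8,  2, 0, 8, 8,  8, 8, 0, 4,  8, 8, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(ape::cophenetic.phylo(njTree(du))[letters[1:4], letters[1:4]],
               du, tolerance = 1e-9)

  expect_error(njTree(matrix(c(0, NA, NA, 0), 2)), "non-finite|3 leaves")
  dInf <- d3; dInf[1, 2] <- dInf[2, 1] <- Inf
  expect_error(njTree(dInf), "non-finite")
})

test_that("negative NJ branch lengths are clamped to zero", {
  # a distance matrix known to induce negative NJ branch estimates
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0) + 0.0, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "d"] <- d["d", "a"] <- 3   # break additivity
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("clade extraction returns the smallest clade holding all references", {
  tree <- ape::read.tree(
    text = "(((r1:1,r2:1):1,(x1:1,x2:1):1):2,((y1:1,y2:1):1,(y3:1,y4:1):1):2);")
  res <- extractRflClade(tree, c("r1", "r2"))
  expect_s3_class(res, "MethodResult")
  expect_setequal(res$rflIds, c("r1", "r2"))
  # references spanning both sides of the clade pull in the in-betweens
  res2 <- extractRflClade(tree, c("r1", "x1"))
  expect_setequal(res2$rflIds, c("r1", "r2", "x1", "x2"))
  # single reference -> the leaf alone
  expect_equal(extractRflClade(tree, "y3")$rflIds, "y3")
  expect_error(extractRflClade(tree, c("r1", "zz", "qq")), "zz, qq")
})

test_that("synthetic RFL family is monophyletic and extracted exactly", {
  set.seed(111)
  # one RFL family with two subfamilies (as two genomic clusters would
  # be), anchored by one reference ancestor per subfamily
  anc1 <- paste(sample(RFLfinder:::AA20, 120, replace = TRUE),
                collapse = "")
  anc2 <- paste(RFLfinder:::mutateChars(strsplit(anc1, "")[[1]], 0.18),
                collapse = "")
  rfl <- c(mkFamily(anc1, 3, 0.06, "rflA"), mkFamily(anc2, 3, 0.06, "rflB"))
  refs <- c(ref1 = anc1, ref2 = anc2)
  bg <- do.call(c, lapply(1:4, function(i)
    mkFamily(paste(sample(RFLfinder:::AA20, 120, replace = TRUE),
                   collapse = ""), 2, 0.08, paste0("bg", i, "_"))))
  pool <- c(rfl, refs, bg)
  tr <- njTree(identityDistanceMatrix(pool))
  res <- extractRflClade(tr, names(refs))
  expect_setequal(setdiff(res$rflIds, names(refs)), names(rfl))
})

test_that("consensus partitions are disjoint and count the union", {
  r1 <- methodResult("m1", c("a", "b", "c"))
  r2 <- methodResult("m2", c("a", "b", "c"))
  cons <- consensusReport(list(r1, r2))
  expect_length(cons$partition, 1L)
  expect_equal(cons$unionCount, 3L)

  set.seed(121)
  for (rep in 1:10) {
    sets <- lapply(1:4, function(i)
      methodResult(paste0("m", i),
                   sample(letters, sample(3:15, 1))))
    cons <- consensusReport(sets)
    ids <- unlist(cons$partition, use.names = FALSE)
    expect_equal(length(ids), length(unique(ids)))  # disjoint blocks
    expect_equal(cons$unionCount,
                 length(Reduce(union, lapply(sets, `[[`, "rflIds"))))
    expect_equal(cons$unionCount, length(ids))
  }
})
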