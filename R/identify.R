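#' Global pairwise identity and coverage
#'
#' Needleman-Wunsch global alignment on an identity scoring scheme
#' (match +1, mismatch 0, affine gaps: open -10, extend -0.5). Identity is
#' matches over the aligned columns in which both sequences have a residue
#' (gap columns are excluded, so a motif-level deletion does not dilute
#' the identity of the remaining aligned repeats). Coverage is the
#' fraction of the
#' shorter sequence aligned opposite a residue (not a gap) of the longer.
#' These mirror the CD-Hit criteria \code{-c} (identity, computed over
#' aligned residues under \code{-G0}) and \code{-aS} (coverage of the
#' shorter sequence).
#'
#' @param a,b protein strings or \code{AAString}s; non-empty.
#' @return Named numeric vector \code{c(identity=, coverage=)}.
#' @examples
#' pairwiseIdentity("AAAA", "AATA")  # identity 0.75
#' @export
pairwiseIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = identitySubMatrix(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- which(ap != "-" & as != "-")
  if (!length(both))
    return(c(identity = 0, coverage = 0))
  matches <- sum(ap[both] == as[both])
  out <- c(identity = matches / length(both),
           coverage = length(both) / min(nchar(a), nchar(b)))
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Greedy identity clustering (CD-Hit style)
#'
#' Sequences are processed by decreasing length (ties broken by
#' lexicographic id); each joins the first existing cluster whose founding
#' representative it matches at \code{>= identityThreshold} global identity
#' with \code{>= minCoverage} coverage of the shorter sequence, otherwise
#' it founds a new cluster. Defaults mirror the published CD-Hit settings
#' \code{-c 0.4 -aS 0.1}; single-species input is recommended, as a single
#' run across divergent species fails to group their RFLs.
#'
#' @param seqs named character vector or \code{AAStringSet}.
#' @param identityThreshold global identity cutoff in (0, 1]; default 0.40.
#' @param minCoverage minimum coverage of the shorter sequence; default 0.10.
#' @return List of character vectors of ids; each element is named by its
#'   representative (founder) id.
#' @export
greedyIdentityCluster <- function(seqs, identityThreshold = 0.40,
                                  minCoverage = 0.10) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  s <- asProteinVector(seqs)
  if (is.null(names(s)) || any(names(s) == ""))
    stageStop("rfl_identify", "sequences must be named")
  ord <- order(-nchar(s), names(s))
  s <- s[ord]
  reps <- character(0)
  clusters <- list()
  for (id in names(s)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      m <- pairwiseIdentity(s[[id]], s[[reps[k]]])
      if (m["identity"] >= identityThreshold &&
          m["coverage"] >= minCoverage) {
        clusters[[k]] <- c(clusters[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      clusters[[length(clusters) + 1L]] <- id
    }
  }
  names(clusters) <- reps
  clusters
}

#' Orthogroup clustering by Markov clustering of a similarity graph
#'
#' Builds the all-vs-all similarity graph with edge weight
#' identity x coverage (edges below \code{pruneBelow} removed, self loops
#' added), then runs Markov clustering: alternately square the
#' column-stochastic matrix (expansion) and raise entries to
#' \code{inflation} with renormalisation, until the matrix changes by less
#' than \code{tol} or \code{maxIter} iterations. Clusters are the connected
#' components of the converged matrix's non-zero structure. Deterministic.
#'
#' @param seqs named character vector or \code{AAStringSet} (length >= 1).
#' @param pruneBelow similarity pruning threshold (default 0.25).
#' @param inflation MCL inflation exponent (default 1.5).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @param maxIter iteration cap (default 100).
#' @return List of character vectors of ids (clusters, by first member).
#' @export
orthogroupCluster <- function(seqs, pruneBelow = 0.25, inflation = 1.5,
                              tol = 1e-6, maxIter = 100L) {
  s <- asProteinVector(seqs)
  ids <- names(s)
  if (is.null(ids) || any(ids == ""))
    stageStop("rfl_identify", "sequences must be named")
  n <- length(s)
  if (n == 1L) return(stats::setNames(list(ids), ids))
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- pairwiseIdentity(s[[i]], s[[j]])
      w <- m[["identity"]] * m[["coverage"]]
      if (w >= pruneBelow) sim[i, j] <- sim[j, i] <- w
    }
  }
  diag(sim) <- 1
  M <- sweep(sim, 2L, colSums(sim), "/")
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  adj <- (M > 1e-9) | t(M > 1e-9)
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    nc <- nc + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- nc
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  out <- split(ids, comp)
  names(out) <- vapply(out, `[`, character(1), 1L)
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor-joining (via \code{\link[ape]{nj}}) with negative
#' branch lengths clamped to zero. Distances must be finite.
#'
#' @param dm a \code{dist} object or symmetric numeric matrix with
#'   dimnames; at least 3 leaves.
#' @return An unrooted \code{\link[ape]{phylo}} tree.
#' @export
njTree <- function(dm) {
  m <- as.matrix(dm)
  if (!all(is.finite(m)))
    stageStop("rfl_identify", "non-finite distances in matrix")
  if (nrow(m) < 3L)
    stageStop("rfl_identify", "at least 3 leaves are required")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise distance matrix from protein sequences
#'
#' Distance is 1 - global pairwise identity, suitable for intronless,
#' same-family proteins that align globally.
#'
#' @param seqs named character vector or \code{AAStringSet}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
identityDistanceMatrix <- function(seqs) {
  s <- asProteinVector(seqs)
  ids <- names(s)
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m <- pairwiseIdentity(s[[i]], s[[j]])
        d[i, j] <- d[j, i] <- 1 - m[["identity"]]
      }
    }
  }
  d
}

#' Extract the RFL clade anchored on reference sequences
#'
#' Midpoint-roots the tree, finds the most recent common ancestor of the
#' reference leaves and returns every leaf of that smallest containing
#' clade. A single reference returns just that leaf.
#'
#' @param tree a \code{phylo} tree.
#' @param referenceIds character vector of reference leaf labels (>= 1).
#' @return A \code{MethodResult}: list with \code{method}
#'   (\code{"phylo_clade"}), \code{rflIds} and \code{params}.
#' @export
extractRflClade <- function(tree, referenceIds) {
  referenceIds <- unique(as.character(referenceIds))
  if (length(referenceIds) < 1L)
    stageStop("rfl_identify", "at least one reference id is required")
  missing <- setdiff(referenceIds, tree$tip.label)
  if (length(missing))
    stageStop("rfl_identify", "reference id(s) absent from tree: ",
              paste(missing, collapse = ", "))
  if (length(referenceIds) == 1L) {
    return(methodResult("phylo_clade", referenceIds,
                        list(references = referenceIds)))
  }
  rooted <- phangorn::midpoint(tree)
  mrca <- ape::getMRCA(rooted, referenceIds)
  leaves <- if (mrca == ape::Ntip(rooted) + 1L) {
    rooted$tip.label  # MRCA is the root
  } else {
    ape::extract.clade(rooted, mrca)$tip.label
  }
  methodResult("phylo_clade", leaves, list(references = referenceIds))
}

#' Construct a MethodResult
#'
#' @param method method label, e.g. \code{"greedy_identity"},
#'   \code{"orthogroup"}, \code{"phylo_clade"}.
#' @param rflIds character vector of identified RFL ids.
#' @param params list of parameters used.
#' @return An object of class \code{MethodResult}.
#' @export
methodResult <- function(method, rflIds, params = list()) {
  structure(list(method = method, rflIds = unique(as.character(rflIds)),
                 params = params),
            class = "MethodResult")
}

#' @export
print.MethodResult <- function(x, ...) {
  cat("MethodResult [", x$method, "]: ", length(x$rflIds),
      " RFL ids\n", sep = "")
  invisible(x)
}

#' RFL set from clusters containing reference sequences
#'
#' The RFL set of a clustering-based method is the union of all clusters
#' containing at least one reference RFL, minus the references themselves.
#'
#' @param clusters list of character vectors of ids.
#' @param referenceIds reference RFL ids present in the clustering input.
#' @param method method label for the result.
#' @param params parameter record.
#' @return A \code{MethodResult}.
#' @export
rflFromClusters <- function(clusters, referenceIds, method, params = list()) {
  hit <- vapply(clusters, function(cl) any(referenceIds %in% cl), logical(1))
  ids <- setdiff(unlist(clusters[hit], use.names = FALSE), referenceIds)
  methodResult(method, ids, params)
}

#' Venn consensus across identification methods
#'
#' Partitions the union of all methods' RFL sets into disjoint blocks by
#' membership signature (which methods identified each id).
#'
#' @param results list of \code{MethodResult} (>= 2).
#' @return A \code{ConsensusReport}: list with \code{partition} (named list
#'   of id vectors, names are "+"-joined method signatures) and
#'   \code{unionCount}.
#' @examples
#' r1 <- methodResult("a", c("x", "y"))
#' r2 <- methodResult("b", c("y", "z"))
#' consensusReport(list(r1, r2))
#' @export
consensusReport <- function(results) {
  stopifnot(length(results) >= 2L)
  methods <- vapply(results, function(r) r$method, character(1))
  if (anyDuplicated(methods))
    stageStop("rfl_identify", "duplicate method labels in results")
  univ <- sort(unique(unlist(lapply(results, `[[`, "rflIds"))))
  sig <- vapply(univ, function(id) {
    paste(sort(methods[vapply(results, function(r) id %in% r$rflIds,
                              logical(1))]),
          collapse = "+")
  }, character(1))
  part <- split(univ, sig)
  structure(list(partition = part, unionCount = length(univ)),
            class = "ConsensusReport")
}

#' @export
print.ConsensusReport <- function(x, ...) {
  cat("ConsensusReport: union of", x$unionCount, "ids in",
      length(x$partition), "blocks\n")
  for (s in names(x$partition))
    cat("  ", s, ": ", length(x$partition[[s]]), "\n", sep = "")
  invisible(x)
}
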