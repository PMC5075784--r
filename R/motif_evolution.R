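#' Extract motif instances from annotated proteins
#'
#' Collects the 35-residue P-motif sequences of each protein, numbered
#' from the amino terminus.
#'
#' @param annotations list of \code{ProteinAnnotation}.
#' @param proteins named character vector (or \code{AAStringSet}) of the
#'   annotated protein sequences.
#' @return data.frame with columns protein_id, index (1-based from the
#'   amino terminus), start (0-based offset) and residues.
#' @export
motifInstances <- function(annotations, proteins) {
  proteins <- asProteinVector(proteins)
  rows <- lapply(annotations, function(a) {
    h <- a@hits[a@hits$classLabel == "P", , drop = FALSE]
    if (!nrow(h)) return(NULL)
    p <- unname(proteins[a@proteinId][1L])
    if (is.null(p) || is.na(p))
      stageStop("motif_evolution", "missing protein sequence for ",
                a@proteinId)
    data.frame(protein_id = a@proteinId,
               index = seq_len(nrow(h)),
               start = h$start,
               residues = substr(rep(p, nrow(h)), h$start + 1L,
                                 h$start + h$width),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), index = integer(),
                      start = integer(), residues = character())
  rownames(out) <- NULL
  out
}

# Hamming distance fraction between equal-length strings
hammingFrac <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  sum(ca != cb) / length(ca)
}

# pairwise p-distance matrix for equal-length motif residues
motifPDist <- function(instances) {
  res <- instances$residues
  lens <- unique(nchar(res))
  if (length(lens) != 1L)
    stageStop("motif_evolution", "ragged motif lengths: ",
              paste(lens, collapse = ", "))
  ids <- paste0(instances$protein_id, ".", instances$index)
  n <- length(res)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    chars <- do.call(rbind, strsplit(res, ""))
    for (i in seq_len(n - 1L)) {
      cmp <- chars[rep(i, n - i), , drop = FALSE] !=
             chars[(i + 1L):n, , drop = FALSE]
      d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- rowSums(cmp) / lens
    }
  }
  d
}

#' Neighbor-joining tree of PPR motif instances
#'
#' Pairwise p-distance (Hamming fraction over the 35 positions) between
#' motifs, followed by neighbor-joining. Leaf labels are
#' \code{protein_id.index}.
#'
#' @param instances data.frame from \code{\link{motifInstances}} (>= 3
#'   rows, equal-length residues).
#' @return A \code{phylo} tree.
#' @export
motifDistanceTree <- function(instances) {
  if (nrow(instances) < 3L)
    stageStop("motif_evolution", "at least 3 motif instances are required")
  njTree(motifPDist(instances))
}

#' Label motif instances by single-linkage identity clustering
#'
#' Single-linkage clustering of motif instances, cut so that instances
#' join a group when linked by identity at or above
#' \code{identityThreshold}. Labels are assigned A, B, C, ... in order of
#' first occurrence along the input; identical residues always share a
#' label.
#'
#' @param instances data.frame from \code{\link{motifInstances}}.
#' @param identityThreshold identity for joining a group (default 0.80,
#'   high enough that recent duplicates share labels, low enough that
#'   anciently diverged motifs do not).
#' @return A \code{MotifLabeling}: list with \code{labels} (character
#'   vector parallel to \code{instances}), \code{instances} (the input
#'   with a label column) and \code{threshold}.
#' @export
labelMotifs <- function(instances, identityThreshold = 0.80) {
  n <- nrow(instances)
  if (n == 0L)
    return(structure(list(labels = character(0), instances = instances,
                          threshold = identityThreshold),
                     class = "MotifLabeling"))
  if (n == 1L) {
    grp <- 1L
  } else {
    d <- stats::as.dist(motifPDist(instances))
    hc <- stats::hclust(d, method = "single")
    grp <- stats::cutree(hc, h = 1 - identityThreshold + 1e-12)
  }
  first <- !duplicated(grp)
  lab_of_grp <- stats::setNames(labelSeq(sum(first)), unique(grp))
  labels <- unname(lab_of_grp[as.character(grp)])
  inst <- instances
  inst$label <- labels
  structure(list(labels = labels, instances = inst,
                 threshold = identityThreshold),
            class = "MotifLabeling")
}

#' @export
print.MotifLabeling <- function(x, ...) {
  cat("MotifLabeling: ", length(x$labels), " motifs, ",
      length(unique(x$labels)), " labels (threshold ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Architecture label string of one protein
#'
#' @param labeling a \code{MotifLabeling}.
#' @param protein_id protein to extract.
#' @return Character vector of labels ordered by motif index.
#' @export
architectureOf <- function(labeling, protein_id) {
  inst <- labeling$instances
  sub <- inst[inst$protein_id == protein_id, , drop = FALSE]
  sub$label[order(sub$index)]
}

# longest common subsequence DP table for label vectors
lcsTable <- function(a, b) {
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n))
    for (j in seq_len(m))
      L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L
                           else max(L[i, j + 1L], L[i + 1L, j])
  L
}

# single block move: remove len elements at i, reinsert before position j
# (j indexes the shortened vector, 1..length-len+1)
blockMove <- function(x, i, len, j) {
  blk <- x[i:(i + len - 1L)]
  rest <- x[-(i:(i + len - 1L))]
  append(rest, blk, after = j - 1L)
}

# find a single block move turning a into b; NULL if none exists
findBlockMove <- function(a, b) {
  n <- length(a)
  for (len in seq_len(n - 1L)) {
    for (i in seq_len(n - len + 1L)) {
      for (j in seq_len(n - len + 1L)) {
        if (j == i) next
        if (identical(blockMove(a, i, len, j), b))
          return(list(i = i, len = len, j = j))
      }
    }
  }
  NULL
}

#' Minimal motif-architecture edit script between two proteins
#'
#' Computes the event script transforming label string \code{a} into
#' \code{b}. If the two architectures are permutations of each other with
#' displaced blocks, block moves are reported as \emph{transposition}
#' events first. Remaining differences are resolved by a minimal
#' insertion/deletion script (unit costs, via longest-common-subsequence
#' alignment); an insertion adjacent to an identical label is reported as
#' a \emph{duplication}. Replaying the script with
#' \code{\link{applyEvents}} reproduces \code{b} exactly.
#'
#' @param a,b label vectors (or single strings of one-character labels)
#'   from one \code{MotifLabeling}.
#' @return An \code{ArchitectureDiff}: list with \code{a}, \code{b} and
#'   \code{events}, a list of events, each a list with \code{type}
#'   (duplication, deletion, insertion or transposition), \code{position}
#'   (1-based, in the evolving string) and \code{label} (for
#'   transpositions: \code{labels}, \code{from}, \code{to}, \code{length}).
#' @examples
#' diffArchitectures("ABCD", "ABBCD")  # one duplication of B
#' diffArchitectures("ABCD", "ACBD")   # one transposition
#' @export
diffArchitectures <- function(a, b) {
  a <- asLabels(a); b <- asLabels(b)
  events <- list()
  cur <- a
  # transposition pre-pass: only for permutations with displaced content
  if (length(cur) == length(b) &&
      identical(sort(cur), sort(b)) && !identical(cur, b)) {
    guard <- 0L
    while (!identical(cur, b) && guard < length(b)) {
      mv <- findBlockMove(cur, b)
      if (is.null(mv)) break
      events[[length(events) + 1L]] <- list(
        type = "transposition", position = mv$i,
        labels = cur[mv$i:(mv$i + mv$len - 1L)],
        from = mv$i, to = mv$j, length = mv$len)
      cur <- blockMove(cur, mv$i, mv$len, mv$j)
      guard <- guard + 1L
    }
  }
  if (!identical(cur, b)) {
    L <- lcsTable(cur, b)
    # walk the alignment left to right, emitting events with positions in
    # the evolving string so the script replays deterministically
    ops <- list()
    i <- length(cur); j <- length(b)
    while (i > 0L || j > 0L) {
      if (i > 0L && j > 0L && cur[i] == b[j] &&
          L[i + 1L, j + 1L] == L[i, j] + 1L) {
        ops[[length(ops) + 1L]] <- list(op = "M"); i <- i - 1L; j <- j - 1L
      } else if (j > 0L && (i == 0L || L[i + 1L, j] >= L[i, j + 1L])) {
        ops[[length(ops) + 1L]] <- list(op = "I", label = b[j]); j <- j - 1L
      } else {
        ops[[length(ops) + 1L]] <- list(op = "D", label = cur[i]); i <- i - 1L
      }
    }
    ops <- rev(ops)
    pos <- 1L
    work <- cur
    for (o in ops) {
      if (o$op == "M") {
        pos <- pos + 1L
      } else if (o$op == "D") {
        events[[length(events) + 1L]] <- list(
          type = "deletion", position = pos, label = o$label)
        work <- work[-pos]
      } else {
        neighbour_same <-
          (pos > 1L && work[pos - 1L] == o$label) ||
          (pos <= length(work) && work[pos] == o$label)
        events[[length(events) + 1L]] <- list(
          type = if (neighbour_same) "duplication" else "insertion",
          position = pos, label = o$label)
        work <- append(work, o$label, after = pos - 1L)
        pos <- pos + 1L
      }
    }
  }
  structure(list(a = a, b = b, events = events), class = "ArchitectureDiff")
}

#' Replay an architecture event script
#'
#' @param a starting label vector (or single string).
#' @param events event list from \code{\link{diffArchitectures}}.
#' @return The transformed label vector.
#' @export
applyEvents <- function(a, events) {
  x <- asLabels(a)
  for (e in events) {
    if (e$type == "deletion") {
      x <- x[-e$position]
    } else if (e$type %in% c("insertion", "duplication")) {
      x <- append(x, e$label, after = e$position - 1L)
    } else if (e$type == "transposition") {
      x <- blockMove(x, e$from, e$length, e$to)
    } else {
      stageStop("motif_evolution", "unknown event type: ", e$type)
    }
  }
  x
}

#' @export
print.ArchitectureDiff <- function(x, ...) {
  cat("ArchitectureDiff: ", paste(x$a, collapse = ""), " -> ",
      paste(x$b, collapse = ""), " (", length(x$events), " events)\n",
      sep = "")
  for (e in x$events) {
    if (e$type == "transposition") {
      cat("  transposition of ", paste(e$labels, collapse = ""),
          " from ", e$from, " to ", e$to, "\n", sep = "")
    } else {
      cat("  ", e$type, " of ", e$label, " at ", e$position, "\n", sep = "")
    }
  }
  invisible(x)
}

#' Event list as a TSV-ready data.frame
#'
#' @param diffs list of \code{ArchitectureDiff} (optionally named by pair).
#' @return data.frame with columns pair, type, position, label.
#' @export
eventTable <- function(diffs) {
  if (inherits(diffs, "ArchitectureDiff")) diffs <- list(diffs)
  nm <- names(diffs)
  if (is.null(nm))
    nm <- vapply(diffs, function(d)
      paste0(paste(d$a, collapse = ""), "->", paste(d$b, collapse = "")),
      character(1))
  rows <- lapply(seq_along(diffs), function(i) {
    ev <- diffs[[i]]$events
    if (!length(ev))
      return(NULL)
    data.frame(pair = nm[i],
               type = vapply(ev, `[[`, character(1), "type"),
               position = vapply(ev, `[[`, integer(1), "position"),
               label = vapply(ev, function(e)
                 if (e$type == "transposition")
                   paste(e$labels, collapse = "") else e$label,
                 character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pair = character(), type = character(),
                      position = integer(), label = character())
  out
}
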