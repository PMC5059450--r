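#' @title MRP matrix of source-tree clades
#'
#' @description Matrix representation with parsimony (MRP): every
#' informative internal node of every source tree becomes one binary
#' character. Taxa subtended by the node are scored 1, taxa present in that
#' source tree but not subtended are 0, taxa absent from the source tree
#' are `NA` (the '?' state). The matrix is rooted by a hypothetical
#' all-zero outgroup row, `MRP_Outgroup`.
#'
#' @slot mat integer matrix, rows = taxa (outgroup first), entries 0/1/NA.
#' @slot provenance data.frame with one row per character: `source`
#'   (source-tree index) and `node` (node number within that tree).
#' @export
setClass("MRPMatrix",
         representation(mat = "matrix", provenance = "data.frame"))

setValidity("MRPMatrix", function(object) {
  m <- object@mat
  if (!(OUTGROUP_LABEL %in% rownames(m)))
    return("outgroup row missing")
  og <- m[OUTGROUP_LABEL, ]
  if (length(og) && any(is.na(og) | og != 0L))
    return("outgroup row must be all zero")
  real <- m[setdiff(rownames(m), OUTGROUP_LABEL), , drop = FALSE]
  if (ncol(m)) {
    ones <- colSums(real == 1L, na.rm = TRUE)
    zeros <- colSums(real == 0L, na.rm = TRUE)
    if (any(ones < 2L | zeros < 1L))
      return("every character must have >=2 ones and >=1 zero among real taxa")
  }
  if (nrow(object@provenance) != ncol(m))
    return("provenance must have one row per character")
  TRUE
})

#' @describeIn MRPMatrix-class taxon names (outgroup included)
#' @param x,object an `MRPMatrix`
#' @export
mrpTaxa <- function(x) rownames(x@mat)

#' @describeIn MRPMatrix-class the underlying 0/1/NA matrix
#' @export
mrpMatrix <- function(x) x@mat

#' @describeIn MRPMatrix-class per-character provenance
#' @export
mrpProvenance <- function(x) x@provenance

setMethod("show", "MRPMatrix", function(object) {
  cat("MRPMatrix:", nrow(object@mat) - 1L, "taxa (+ outgroup),",
      ncol(object@mat), "characters from",
      length(unique(object@provenance$source)), "source tree(s)\n")
})

#' @title Taxonomic overlap between source trees
#' @description Pairwise shared-taxon counts and the connectivity of the
#' overlap graph whose edges join trees sharing at least two taxa. A source
#' set is usable for MRP only when that graph is connected.
#' @slot shared symmetric integer matrix of shared-taxon counts
#'   (diagonal = tree size).
#' @slot connected logical flag.
#' @export
setClass("OverlapReport",
         representation(shared = "matrix", connected = "logical"))

setMethod("show", "OverlapReport", function(object) {
  cat("OverlapReport:", nrow(object@shared), "source trees;",
      if (object@connected) "connected" else "NOT connected",
      "(>=2 shared taxa edges)\n")
})

#' @describeIn OverlapReport-class is the dataset valid for MRP?
#' @param x an `OverlapReport`
#' @export
isConnected <- function(x) x@connected

#' Check taxonomic overlap between source trees
#'
#' @param trees list of `phylo` source trees (or a `multiPhylo`).
#' @return An [OverlapReport-class] object.
#' @export
checkOverlap <- function(trees) {
  trees <- as.list(trees)
  if (!length(trees)) stop("need at least one source tree")
  k <- length(trees)
  tipsets <- lapply(trees, `[[`, "tip.label")
  shared <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    shared[i, j] <- length(intersect(tipsets[[i]], tipsets[[j]]))
  # BFS on the >=2-shared-taxa graph
  seen <- logical(k)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(shared[v, ] >= 2L & !seen)
    nb <- setdiff(nb, v)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  new("OverlapReport", shared = shared, connected = all(seen))
}

#' Encode source trees as an MRP matrix
#'
#' Standard Baum–Ragan coding. The root node of each source tree is
#' excluded (uninformative given the all-zero outgroup), as is any node
#' whose character would have fewer than two 1s or no 0 among the taxa of
#' its own source tree. Source trees with fewer than three tips contribute
#' no characters (a message is emitted).
#'
#' @param trees list of rooted `phylo` source trees.
#' @return An [MRPMatrix-class].
#' @export
mrpEncode <- function(trees) {
  trees <- as.list(trees)
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  allnames <- c(OUTGROUP_LABEL, taxa)
  cols <- list(); src <- integer(0); nd <- integer(0)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    ntip <- ape::Ntip(tr)
    if (ntip < 3L) {
      message("source tree ", i, " has <3 tips; contributes no characters")
      next
    }
    root <- ntip + 1L
    internals <- setdiff(root:(ntip + tr$Nnode), root)
    for (v in internals) {
      sub <- cladeTips(tr, v)
      if (length(sub) < 2L || length(sub) >= ntip) next   # uninformative
      col <- rep(NA_integer_, length(allnames))
      names(col) <- allnames
      col[tr$tip.label] <- 0L
      col[sub] <- 1L
      col[OUTGROUP_LABEL] <- 0L
      cols[[length(cols) + 1L]] <- col
      src <- c(src, i); nd <- c(nd, v)
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(0), nrow = length(allnames),
           dimnames = list(allnames, NULL))
  rownames(mat) <- allnames
  colnames(mat) <- NULL
  new("MRPMatrix", mat = mat,
      provenance = data.frame(source = src, node = nd))
}

# tip-state matrix (Ntip x nchar) for a tree against an MRP matrix
.tipStates <- function(tree, m) {
  mat <- m@mat
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing))
    stop("tip(s) absent from matrix: ", paste(missing, collapse = ", "))
  mat[tree$tip.label, , drop = FALSE]
}

#' Parsimony length of a tree on an MRP matrix
#'
#' Minimum number of unordered state changes summed over characters
#' (computed by Sankoff dynamic programming, so polytomies and missing data
#' are scored exactly). When the tree does not itself carry the
#' `MRP_Outgroup` tip, the all-zero outgroup is adjoined above the root, so
#' rooted candidate supertrees over the real taxa are scored as in a
#' standard rooted MRP analysis.
#'
#' @param tree a rooted `phylo`; tips must be matrix taxa.
#' @param m an [MRPMatrix-class].
#' @param implicitOutgroup force or suppress the adjoined outgroup; by
#'   default it is adjoined iff the outgroup is not among the tree's tips.
#' @return Integer parsimony length.
#' @export
fitchScore <- function(tree, m,
                       implicitOutgroup = !(OUTGROUP_LABEL %in% tree$tip.label)) {
  if (ncol(m@mat) == 0L) return(0L)
  tr <- ape::reorder.phylo(tree, "postorder")
  st <- .tipStates(tr, m)
  as.integer(sankoffScoreCpp(tr$edge, ape::Ntip(tr),
                             ape::Ntip(tr) + tr$Nnode, st, implicitOutgroup))
}

## ---- enumeration of rooted binary trees (nested-list representation) ----

# all positions to insert `tip` into nested tree `tr`
.insertAll <- function(tr, tip) {
  out <- list(list(tr, tip))                    # graft above this node
  if (is.list(tr)) {
    for (i in 1:2) {
      for (v in .insertAll(tr[[i]], tip)) {
        nt <- tr
        nt[[i]] <- v
        out[[length(out) + 1L]] <- nt
      }
    }
  }
  out
}

.allNested <- function(labels) {
  trees <- list(list(labels[[1L]], labels[[2L]]))
  for (tip in labels[-(1:2)])
    trees <- unlist(lapply(trees, .insertAll, tip = tip), recursive = FALSE)
  trees
}

.nestedNewick <- function(tr) {
  rec <- function(x)
    if (is.list(x)) paste0("(", rec(x[[1L]]), ",", rec(x[[2L]]), ")") else x
  paste0(rec(tr), ";")
}

# postorder edge matrix + tip labels, directly from a nested list
.nestedEdges <- function(tr) {
  tips <- NULL      # character labels or generic integer tip ids
  edges <- integer(0)
  count <- function(x) if (is.list(x)) 1L + count(x[[1L]]) + count(x[[2L]]) else 0L
  nInt <- count(tr)
  nextTip <- 0L; nextInt <- 0L
  rec <- function(x) {
    if (!is.list(x)) {
      nextTip <<- nextTip + 1L
      tips[nextTip] <<- x
      return(nextTip)
    }
    a <- rec(x[[1L]]); b <- rec(x[[2L]])
    nextInt <<- nextInt + 1L
    me <- nTipTotal + nextInt
    edges <<- c(edges, me, a, me, b)
    me
  }
  nTipTotal <- length(unlist(tr))
  rec(tr)
  em <- matrix(edges, ncol = 2L, byrow = TRUE)
  # renumber internals so the root is nTip+1 (ape convention not required
  # for scoring; postorder with root-last suffices)
  list(edge = em, tips = tips, nTip = nTipTotal, nNode = nTipTotal + nInt)
}

.canonicalKeyNested <- function(tr) {
  rec <- function(x) {
    if (!is.list(x)) return(list(key = x, txt = x))
    a <- rec(x[[1L]]); b <- rec(x[[2L]])
    if (a$key > b$key) { tmp <- a; a <- b; b <- tmp }
    list(key = a$key, txt = paste0("(", a$txt, ",", b$txt, ")"))
  }
  rec(tr)$txt
}

.scoreNested <- function(tr, m, implicitOutgroup = TRUE) {
  ne <- .nestedEdges(tr)
  st <- m@mat[ne$tips, , drop = FALSE]
  sankoffScoreCpp(ne$edge, ne$nTip, ne$nNode, st, implicitOutgroup)
}

#' Exhaustive most-parsimonious-tree search
#'
#' Enumerates every rooted binary topology over the matrix's real taxa
#' (the all-zero outgroup is adjoined above each candidate root for
#' scoring) and returns all trees attaining the minimum parsimony length.
#' Intended as the oracle for [heuristicSearch()] at small sizes.
#'
#' @param m an [MRPMatrix-class].
#' @param maxTaxa refuse matrices larger than this (default 9; there are
#'   2,027,025 rooted topologies at 9 taxa).
#' @return list with `trees` (a `multiPhylo` of MPTs) and `length`
#'   (the shared minimum parsimony length).
#' @export
exhaustiveSearch <- function(m, maxTaxa = 9L) {
  taxa <- sort(setdiff(mrpTaxa(m), OUTGROUP_LABEL))
  n <- length(taxa)
  if (n > maxTaxa) stop(n, " taxa exceed maxTaxa = ", maxTaxa)
  if (n < 2L) stop("need at least 2 real taxa")
  mat <- m@mat[taxa, , drop = FALSE]
  enum <- .enumTopologies(n)
  scores <- vapply(enum$edges, function(ne)
    sankoffScoreCpp(ne$edge, ne$nTip, ne$nNode,
                    mat[ne$tips, , drop = FALSE], TRUE), 0)
  best <- min(scores)
  mpts <- enum$trees[scores == best]
  nwk <- vapply(mpts, function(tr) .nestedNewick(rapply(
    tr, function(i) taxa[i], how = "replace")), "")
  trees <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)  # multiPhylo of length 1
  list(trees = trees, length = as.integer(best))
}

# enumerated rooted binary topologies over generic tip indices 1..n,
# with precomputed postorder edge structures; cached for n <= 7
.topoCache <- new.env(parent = emptyenv())
.enumTopologies <- function(n) {
  key <- as.character(n)
  if (!is.null(.topoCache[[key]])) return(.topoCache[[key]])
  trees <- .allNested(as.list(seq_len(n)))
  edges <- lapply(trees, .nestedEdges)
  out <- list(trees = trees, edges = edges)
  if (n <= 7L) .topoCache[[key]] <- out
  out
}

# rooted NNI neighbours of a nested binary tree
.nniNeighbors <- function(tr) {
  out <- list()
  rec <- function(x) {
    if (!is.list(x)) return(list())
    res <- list()
    L <- x[[1L]]; R <- x[[2L]]
    if (is.list(L)) {
      res[[length(res) + 1L]] <- list(list(L[[1L]], R), L[[2L]])
      res[[length(res) + 1L]] <- list(list(L[[2L]], R), L[[1L]])
    }
    if (is.list(R)) {
      res[[length(res) + 1L]] <- list(R[[1L]], list(R[[2L]], L))
      res[[length(res) + 1L]] <- list(R[[2L]], list(R[[1L]], L))
    }
    for (v in rec(L)) res[[length(res) + 1L]] <- list(v, R)
    for (v in rec(R)) res[[length(res) + 1L]] <- list(L, v)
    res
  }
  rec(tr)
}

#' Heuristic most-parsimonious-tree search
#'
#' Random-addition starting trees (greedy stepwise insertion at the
#' best-scoring position) refined by rooted-NNI hill climbing, repeated
#' over independent replicates; all distinct topologies attaining the best
#' length found are returned. Reproducible for a fixed seed.
#'
#' @param m an [MRPMatrix-class].
#' @param replicates number of random-addition replicates (the source
#'   analysis used 1,000).
#' @param seed integer RNG seed.
#' @param maxNNI cap on hill-climbing passes per replicate.
#' @return list with `trees` (multiPhylo of distinct best trees) and
#'   `length` (their parsimony length).
#' @export
heuristicSearch <- function(m, replicates = 10L, seed = 1L, maxNNI = 100L) {
  stopifnot(replicates >= 1L)
  taxa <- setdiff(mrpTaxa(m), OUTGROUP_LABEL)
  if (length(taxa) < 2L) stop("need at least 2 real taxa")
  set.seed(seed)
  bestScore <- Inf
  bestTrees <- list()  # canonical key -> nested tree
  for (rep in seq_len(replicates)) {
    ord <- sample(taxa)
    tr <- list(ord[1L], ord[2L])
    for (tip in ord[-(1:2)]) {
      cands <- .insertAll(tr, tip)
      sc <- vapply(cands, .scoreNested, 0, m = m)
      tr <- cands[[which.min(sc)]]
    }
    cur <- .scoreNested(tr, m)
    for (pass in seq_len(maxNNI)) {
      nb <- .nniNeighbors(tr)
      sc <- vapply(nb, .scoreNested, 0, m = m)
      if (!length(sc) || min(sc) >= cur) break
      tr <- nb[[which.min(sc)]]
      cur <- min(sc)
    }
    if (cur < bestScore) {
      bestScore <- cur
      bestTrees <- list()
    }
    if (cur == bestScore)
      bestTrees[[.canonicalKeyNested(tr)]] <- tr
  }
  trees <- ape::read.tree(text = paste(vapply(bestTrees, .nestedNewick, ""),
                                       collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  list(trees = trees, length = as.integer(bestScore))
}

#' Consensus of a set of trees
#'
#' Strict (clades present in all trees) or majority-rule (clades in more
#' than half) consensus; the result may be polytomous.
#'
#' @param trees a `multiPhylo` or list of `phylo` with identical tip sets.
#' @param kind `"strict"` or `"majority"`.
#' @return A `phylo`.
#' @export
consensusTree <- function(trees, kind = c("strict", "majority")) {
  kind <- match.arg(kind)
  trees <- as.list(trees)
  tips <- trees[[1L]]$tip.label
  for (t in trees)
    if (!setequal(t$tip.label, tips)) stop("trees have mismatched tip sets")
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = if (kind == "strict") 1 else 0.5, rooted = TRUE)
}

# elementwise lexicographic comparison of sorted label vectors
.lexLess <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Maximum agreement subtree of two rooted binary trees
#'
#' Dynamic programming over node pairs; returns a maximum-cardinality tip
#' subset on which the two restricted trees are topologically identical,
#' as the restriction of `tree1` to that subset. Among equal-size
#' agreement sets the lexicographically smallest sorted taxon set is
#' chosen, so the result is deterministic and symmetric in its arguments.
#'
#' @param tree1,tree2 rooted binary `phylo` trees with overlapping tips.
#' @return A `phylo` restricted to the agreement set, with attribute
#'   `"tips"`; `NULL` (with a warning) when the agreement set has < 2 tips.
#' @export
mastPair <- function(tree1, tree2) {
  shared <- intersect(tree1$tip.label, tree2$tip.label)
  if (length(shared) < 2L) {
    warning("tip sets share fewer than 2 taxa; empty agreement subtree")
    return(NULL)
  }
  t1 <- ape::keep.tip(tree1, shared)
  t2 <- ape::keep.tip(tree2, shared)
  k1 <- childrenList(t1); k2 <- childrenList(t2)
  if (any(lengths(k1)[lengths(k1) > 0] != 2L) ||
      any(lengths(k2)[lengths(k2) > 0] != 2L))
    stop("mastPair requires binary trees")
  n1 <- ape::Ntip(t1) + t1$Nnode
  n2 <- ape::Ntip(t2) + t2$Nnode
  tips1 <- lapply(seq_len(n1), function(v) sort(cladeTips(t1, v)))
  tips2 <- lapply(seq_len(n2), function(v) sort(cladeTips(t2, v)))
  po1 <- c(unique(ape::reorder.phylo(t1, "postorder")$edge[, 2L]),
           ape::Ntip(t1) + 1L)
  po2 <- c(unique(ape::reorder.phylo(t2, "postorder")$edge[, 2L]),
           ape::Ntip(t2) + 1L)
  M <- vector("list", n1 * n2)
  idx <- function(u, v) (u - 1L) * n2 + v
  pick <- function(cands) {
    sz <- lengths(cands)
    mx <- max(sz)
    ties <- cands[sz == mx]
    best <- ties[[1L]]
    for (s in ties[-1L]) if (.lexLess(s, best)) best <- s
    best
  }
  ntip1 <- ape::Ntip(t1); ntip2 <- ape::Ntip(t2)
  for (u in po1) for (v in po2) {
    if (u <= ntip1 && v <= ntip2) {
      lab <- t1$tip.label[u]
      M[[idx(u, v)]] <- if (lab == t2$tip.label[v]) lab else character(0)
    } else if (u <= ntip1) {
      lab <- t1$tip.label[u]
      M[[idx(u, v)]] <- if (lab %in% tips2[[v]]) lab else character(0)
    } else if (v <= ntip2) {
      lab <- t2$tip.label[v]
      M[[idx(u, v)]] <- if (lab %in% tips1[[u]]) lab else character(0)
    } else {
      u1 <- k1[[u]][1L]; u2 <- k1[[u]][2L]
      v1 <- k2[[v]][1L]; v2 <- k2[[v]][2L]
      cands <- list(
        sort(c(M[[idx(u1, v1)]], M[[idx(u2, v2)]])),
        sort(c(M[[idx(u1, v2)]], M[[idx(u2, v1)]])),
        M[[idx(u, v1)]], M[[idx(u, v2)]],
        M[[idx(u1, v)]], M[[idx(u2, v)]])
      M[[idx(u, v)]] <- pick(cands)
    }
  }
  best <- M[[idx(ntip1 + 1L, ntip2 + 1L)]]
  if (length(best) < 2L) {
    warning("agreement subtree has fewer than 2 tips")
    return(NULL)
  }
  out <- ape::keep.tip(t1, best)
  attr(out, "tips") <- best
  out
}

#' Write an MRP matrix as a NEXUS DATA block or TNT xread file
#'
#' @param m an [MRPMatrix-class].
#' @param file output path.
#' @param format `"nexus"` or `"tnt"`.
#' @return `file`, invisibly.
#' @export
writeMRP <- function(m, file, format = c("nexus", "tnt")) {
  format <- match.arg(format)
  mat <- m@mat
  rows <- apply(mat, 1L, function(r) {
    r <- as.character(r); r[is.na(r)] <- "?"; paste(r, collapse = "")
  })
  if (format == "nexus") {
    txt <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), ncol(mat)),
             "FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";",
             "MATRIX",
             paste0("  ", rownames(mat), "  ", rows),
             ";", "END;")
  } else {
    txt <- c(sprintf("xread %d %d", ncol(mat), nrow(mat)),
             paste0(rownames(mat), " ", rows), ";")
  }
  writeLines(txt, file)
  invisible(file)
}
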