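#' @useDynLib thermodiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rexp runif rnorm rbinom rpois setNames approx cor t.test
#'   sd dexp dpois lm residuals median quantile
#' @importFrom utils head tail read.csv write.csv
NULL

OUTGROUP_LABEL <- "MRP_Outgroup"

#' Parse a phylogenetic tree from Newick or NEXUS text
#'
#' Thin, validating wrapper around the ape readers. Trees are represented
#' throughout the package as [ape::read.tree()] `phylo` objects (rooted;
#' polytomies preserved; edge lengths, when present, in Myr).
#'
#' @param text Character scalar holding Newick text or a NEXUS TREES block.
#' @param file Path to a file to read instead of `text`.
#' @param format `"newick"` or `"nexus"`.
#' @return A `phylo` object, or a `multiPhylo` list when the input contains
#'   several trees.
#' @examples
#' parseTree("((A,B),C);")
#' @export
parseTree <- function(text = NULL, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  tr <- if (format == "newick") {
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file)
  } else {
    if (!is.null(text)) {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      writeLines(text, tf)
      ape::read.nexus(tf)
    } else ape::read.nexus(file)
  }
  if (is.null(tr)) stop("malformed tree input: parser returned nothing")
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, validateTree)
    return(tr)
  }
  validateTree(tr)
  tr
}

#' Write a tree to Newick or NEXUS text
#'
#' @param tree A `phylo` (or `multiPhylo`) object.
#' @param format `"newick"` or `"nexus"`.
#' @param file Optional path; when `NULL` the text is returned.
#' @return The serialized text (invisibly when written to `file`).
#' @export
writeTree <- function(tree, format = c("newick", "nexus"), file = NULL) {
  format <- match.arg(format)
  if (format == "newick") {
    txt <- ape::write.tree(tree)
  } else {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    ape::write.nexus(tree, file = tf)
    txt <- paste(readLines(tf), collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Validate the package's tree invariants
#'
#' Checks rootedness, unique tip labels and (when edge lengths are present
#' and the tree is dated) non-negative branch durations. Called by all
#' entry points that accept externally produced trees.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1L]
    stop("duplicate tip label: '", dup, "'")
  }
  # trees are treated as rooted as written; a basal polytomy is legal
  # (consensus trees), so ape::is.rooted is deliberately not enforced
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-9))
    stop("negative branch duration")
  invisible(tree)
}

#' Node ages of a dated tree
#'
#' Ages are measured in Ma before present (present = 0, increasing into the
#' past). The tree must be extant-only and (numerically) ultrametric: every
#' tip sits at age 0.
#'
#' @param tree A dated `phylo` with branch lengths in Myr.
#' @param tol Tolerance for declaring tip ages zero.
#' @return Numeric vector of ages indexed by node number
#'   (tips `1..Ntip`, internals `Ntip+1 ..`).
#' @export
nodeAges <- function(tree, tol = 1e-6) {
  if (is.null(tree$edge.length)) stop("tree is not dated (no branch lengths)")
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth[seq_len(ape::Ntip(tree))])
  age <- root_age - depth
  tips <- seq_len(ape::Ntip(tree))
  if (any(abs(age[tips]) > tol * max(root_age, 1)))
    stop("tree is not ultrametric: tips do not all sit at age 0")
  age[tips] <- 0
  age
}

#' Age of the root node
#' @param tree A dated `phylo`.
#' @return Root age in Ma.
#' @export
rootAge <- function(tree) {
  nodeAges(tree)[ape::Ntip(tree) + 1L]
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo`.
#' @param taxa Character vector of >= 1 tip labels (a clade identifier).
#' @return The node number of the MRCA (the tip itself for a single label).
#' @export
mrcaNode <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown tip label(s): ", paste(missing, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Tip labels subtended by a node
#' @param tree A `phylo`.
#' @param node A node number.
#' @return Character vector of tip labels.
#' @export
cladeTips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- childrenList(tree)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- kids[[v]]
    tipch <- ch[ch <= ntip]
    tips <- c(tips, tipch)
    stack <- c(stack, ch[ch > ntip])
  }
  tree$tip.label[tips]
}

# children of every node, as a list indexed by node number
childrenList <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

#' Branches crossing a given age
#'
#' A branch with child age \eqn{a_c} and parent age \eqn{a_p} crosses age
#' `age` iff \eqn{a_c \le age < a_p} (half-open at the old end, so bin
#' counting at node ages is unambiguous). At `age = 0` on an extant-only
#' tree every pendant branch crosses.
#'
#' @param tree A dated `phylo`.
#' @param age Age in Ma, within `[0, rootAge(tree)]`.
#' @param ages Optional precomputed [nodeAges()] vector.
#' @return Integer vector of edge indices (rows of `tree$edge`).
#' @export
branchesCrossing <- function(tree, age, ages = nodeAges(tree)) {
  ra <- ages[ape::Ntip(tree) + 1L]
  if (age < 0 || age > ra)
    stop("age ", age, " outside [0, ", ra, "]")
  child_age <- ages[tree$edge[, 2L]]
  parent_age <- ages[tree$edge[, 1L]]
  which(child_age <= age & age < parent_age)
}

# canonical Newick: children sorted by smallest descendant label; used to
# deduplicate topologies without depending on a tree-distance package
canonicalNewick <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- childrenList(tree)
  rec <- function(v) {
    if (v <= ntip) {
      lab <- tree$tip.label[v]
      return(list(key = lab, txt = lab))
    }
    parts <- lapply(kids[[v]], rec)
    ord <- order(vapply(parts, `[[`, "", "key"))
    parts <- parts[ord]
    list(key = parts[[1L]]$key,
         txt = paste0("(", paste(vapply(parts, `[[`, "", "txt"), collapse = ","), ")"))
  }
  paste0(rec(ntip + 1L)$txt, ";")
}

# TRUE iff two rooted trees have identical labelled topology
sameTopology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  identical(canonicalNewick(a), canonicalNewick(b))
}
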