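#' Read a fossil calibration table
#'
#' Calibration CSV dialect: columns `clade_taxa` (semicolon-separated tip
#' labels identifying a clade by its MRCA), `placement` (`stem` or
#' `crown`) and `age_ma` (fossil first-occurrence age in Ma, a hard
#' minimum).
#'
#' @param path CSV file path.
#' @return A calibration data.frame (class kept plain for easy editing).
#' @export
readCalibrations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("clade_taxa", "placement", "age_ma")
  if (!all(need %in% names(df)))
    stop("calibration file must have columns: ", paste(need, collapse = ", "))
  validateCalibrations(df)
}

#' Validate a calibration set
#' @param cals calibration data.frame (`clade_taxa`, `placement`, `age_ma`).
#' @return `cals`, invisibly checked.
#' @export
validateCalibrations <- function(cals) {
  stopifnot(is.data.frame(cals))
  if (!all(cals$placement %in% c("stem", "crown")))
    stop("placement must be 'stem' or 'crown'")
  if (any(!is.finite(cals$age_ma) | cals$age_ma <= 0))
    stop("calibration ages must be positive and finite")
  cals
}

#' Resolve calibrations to node minimum ages
#'
#' Crown calibrations attach to the MRCA of the listed taxa; stem
#' calibrations to its parent (the MRCA itself when it is the root, with a
#' warning). When several calibrations resolve to one node the oldest age
#' is kept, with a warning.
#'
#' @param tree a rooted `phylo`.
#' @param cals calibration data.frame (see [readCalibrations()]).
#' @return Named numeric vector: minimum age per node number.
#' @export
resolveCalibrations <- function(tree, cals) {
  validateCalibrations(cals)
  root <- ape::Ntip(tree) + 1L
  parent <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  ages <- numeric(0)
  for (i in seq_len(nrow(cals))) {
    taxa <- strsplit(cals$clade_taxa[i], ";", fixed = TRUE)[[1L]]
    taxa <- trimws(taxa)
    node <- mrcaNode(tree, taxa)
    if (cals$placement[i] == "stem") {
      if (node == root) {
        warning("stem calibration on the root clade kept at the root")
      } else node <- parent[node]
    }
    key <- as.character(node)
    if (!is.null(ages[key]) && !is.na(ages[key])) {
      warning("two calibrations resolve to node ", node,
              "; keeping the older age")
      ages[key] <- max(ages[key], cals$age_ma[i])
    } else ages[key] <- cals$age_ma[i]
  }
  ages
}

#' Time-scale a tree with the 'equal' method
#'
#' Fossil ages are hard minima. Calibrated nodes are fixed at their minimum
#' ages, pushed older only where a calibrated descendant plus the minimum
#' branch length forces it (so a parent and child both calibrated at 50 Ma
#' become 50.1 and 50 with the default floor). Each maximal chain of
#' uncalibrated nodes between an assigned ancestor and its oldest
#' calibrated (or tip) descendant divides the free interval equally among
#' the chain's branches; individual node lower bounds are still respected.
#' The root, when uncalibrated, sits at its lower bound. Deterministic.
#'
#' @param tree a rooted `phylo` (existing branch lengths ignored).
#' @param node_ages named numeric from [resolveCalibrations()].
#' @param min_bl minimum branch duration in Myr (default 0.1).
#' @return A dated `phylo` with branch lengths in Myr, tips at age 0.
#' @export
equalScale <- function(tree, node_ages, min_bl = 0.1) {
  if (!length(node_ages)) stop("need at least one calibrated node")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  cal <- rep(NA_real_, nnode)
  cal[as.integer(names(node_ages))] <- node_ages
  if (any(!is.na(cal[seq_len(ntip)])))
    stop("calibrations may not sit on tips (extant-only trees)")
  kids <- childrenList(tree)
  po <- c(unique(ape::reorder.phylo(tree, "postorder")$edge[, 2L]), root)

  # hard lower bound per node: descendants + min_bl, then the calibration
  lb <- numeric(nnode)
  for (v in po) {
    if (v <= ntip) { lb[v] <- 0; next }
    lb[v] <- max(lb[kids[[v]]] + min_bl)
    if (!is.na(cal[v])) lb[v] <- max(lb[v], cal[v])
  }

  age <- rep(NA_real_, nnode)
  age[seq_len(ntip)] <- 0
  age[root] <- lb[root]            # root: its own calibration or forced bound

  # preorder: walk chains of uncalibrated nodes and space them equally
  assignBelow <- function(p) {
    for (c0 in kids[[p]]) {
      if (c0 <= ntip) next
      if (!is.na(cal[c0])) {
        age[c0] <<- lb[c0]
        assignBelow(c0)
        next
      }
      # chain of uncalibrated internals following the max-lower-bound child
      chain <- integer(0)
      v <- c0
      while (v > ntip && is.na(cal[v])) {
        chain <- c(chain, v)
        ch <- kids[[v]]
        v <- ch[which.max(lb[ch])]
      }
      anchorAge <- if (v <= ntip) 0 else lb[v]
      step <- (age[p] - anchorAge) / (length(chain) + 1L)
      for (i in seq_along(chain)) {
        node <- chain[i]
        age[node] <<- max(age[p] - i * step, lb[node])
      }
      if (v > ntip) age[v] <<- lb[v]
      for (node in chain) assignBelow(node)
      if (v > ntip) assignBelow(v)
    }
  }
  assignBelow(root)

  out <- tree
  out$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  validateTree(out)
  out
}

#' Perturb fossil calibrations for robustness runs
#'
#' Moves `ceiling(fraction * n)` calibration entries, chosen uniformly
#' without replacement, to an adjacent node: with equal probability the
#' parent node or a uniformly chosen internal child of the currently
#' resolved node (always a child at the root; always the parent when the
#' node has no internal children). The fossil age is unchanged; moved
#' entries become crown calibrations on their new node. Reproducible given
#' `seed`. The study design re-ran the full analysis with 10, 15 and 20%
#' of dates moved this way.
#'
#' @param tree a rooted `phylo`.
#' @param cals calibration data.frame.
#' @param fraction proportion of entries to move, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A calibration data.frame of the same size.
#' @export
perturbCalibrations <- function(tree, cals, fraction, seed = 1L) {
  validateCalibrations(cals)
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0 || nrow(cals) == 0L) return(cals)
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  kids <- childrenList(tree)
  n <- nrow(cals)
  m <- ceiling(fraction * n)
  moved <- sort(sample.int(n, m))
  out <- cals
  for (i in moved) {
    taxa <- trimws(strsplit(cals$clade_taxa[i], ";", fixed = TRUE)[[1L]])
    node <- mrcaNode(tree, taxa)
    if (cals$placement[i] == "stem" && node != root) node <- parent[node]
    internalKids <- kids[[node]][kids[[node]] > ntip]
    target <-
      if (node == root) {
        if (!length(internalKids)) stop("root has no internal children")
        internalKids[sample.int(length(internalKids), 1L)]
      } else if (!length(internalKids)) {
        parent[node]
      } else if (runif(1) < 0.5) {
        parent[node]
      } else {
        internalKids[sample.int(length(internalKids), 1L)]
      }
    out$clade_taxa[i] <- paste(sort(cladeTips(tree, target)), collapse = ";")
    out$placement[i] <- "crown"
  }
  attr(out, "moved") <- moved
  out
}
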