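# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: brute-force enumeration, direct summation, or
# numerical ODE integration.

# MRCA by intersecting root paths
bruteMrca <- function(tree, taxa) {
  pathToRoot <- function(tip) {
    parent <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    v <- match(tip, tree$tip.label)
    path <- v
    while (!is.na(parent[v])) { v <- parent[v]; path <- c(path, v) }
    path
  }
  paths <- lapply(taxa, pathToRoot)
  common <- Reduce(intersect, paths)
  common[1]  # paths are tip->root ordered, so first common = deepest
}

# lineages alive at an age, by sorting node ages (binary extant trees)
lttCount <- function(tree, age) {
  ages <- thermodiv::nodeAges(tree)
  internals <- ages[(ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)]
  if (age >= max(internals)) return(0L)
  1L + sum(internals > age)
}

# minimal state changes for one 0/1/NA column by exhaustive assignment
# enumeration over internal nodes (and free tips); optionally adjoin the
# all-zero outgroup above the root
bruteColumnScore <- function(tree, col, implicitOutgroup = TRUE) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1
  freeTips <- which(is.na(col[tree$tip.label]))
  internals <- (ntip + 1):nn
  vars <- c(freeTips, internals)
  best <- Inf
  for (mask in 0:(2^length(vars) - 1)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- col[tree$tip.label]
    bits <- as.integer(intToBits(mask))[seq_along(vars)]
    st[vars] <- bits
    changes <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    if (implicitOutgroup) changes <- changes + (st[root] != 0)
    best <- min(best, changes)
  }
  best
}

bruteMatrixScore <- function(tree, m, implicitOutgroup = TRUE) {
  mat <- thermodiv::mrpMatrix(m)
  sum(vapply(seq_len(ncol(mat)), function(j)
    bruteColumnScore(tree, mat[, j], implicitOutgroup), 0))
}

# rooted-topology equality via clade sets (independent of the package's
# canonical-newick machinery)
cladeSets <- function(tree) {
  ntip <- ape::Ntip(tree)
  sets <- lapply((ntip + 1):(ntip + tree$Nnode), function(v)
    paste(sort(ape::extract.clade(tree, v)$tip.label), collapse = "|"))
  sort(unlist(sets))
}
sameRootedTopology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) && identical(cladeSets(a), cladeSets(b))
}

# maximum agreement subtree by subset enumeration (small trees only)
bruteMast <- function(t1, t2) {
  shared <- sort(intersect(t1$tip.label, t2$tip.label))
  n <- length(shared)
  bestSize <- 0; bestSets <- list()
  for (mask in 1:(2^n - 1)) {
    keep <- shared[as.logical(intToBits(mask))[seq_len(n)]]
    if (length(keep) < 2 || length(keep) < bestSize) next
    r1 <- ape::keep.tip(t1, keep); r2 <- ape::keep.tip(t2, keep)
    if (sameRootedTopology(r1, r2)) {
      if (length(keep) > bestSize) { bestSize <- length(keep); bestSets <- list() }
      bestSets[[length(bestSets) + 1]] <- keep
    }
  }
  list(size = bestSize, sets = bestSets)
}

# direct-summation DCCA (explicit normal-equation regressions, loops)
dccaDirect <- function(x, y, s) {
  N <- length(x)
  X <- numeric(N); Y <- numeric(N)
  mx <- sum(x) / N; my <- sum(y) / N
  accx <- 0; accy <- 0
  for (i in 1:N) { accx <- accx + x[i] - mx; X[i] <- accx
                   accy <- accy + y[i] - my; Y[i] <- accy }
  nwin <- N - s
  Fxy <- 0; Fxx <- 0; Fyy <- 0
  for (i in 1:nwin) {
    idx <- i:(i + s)
    t <- seq_along(idx)
    st <- sum(t); stt <- sum(t * t)
    det <- (s + 1) * stt - st * st
    fitres <- function(z) {
      sz <- sum(z); stz <- sum(t * z)
      bslope <- ((s + 1) * stz - st * sz) / det
      bint <- (sz - bslope * st) / (s + 1)
      z - bint - bslope * t
    }
    rx <- fitres(X[idx]); ry <- fitres(Y[idx])
    Fxy <- Fxy + sum(rx * ry) / (s + 1)
    Fxx <- Fxx + sum(rx * rx) / (s + 1)
    Fyy <- Fyy + sum(ry * ry) / (s + 1)
  }
  (Fxy / nwin) / sqrt((Fxx / nwin) * (Fyy / nwin))
}

# constant-rate birth-death log-likelihood by numerical ODE integration
# (deSolve), same node-join and conditioning conventions as the analytic
# implementation but an entirely numerical path
odeBdLoglik <- function(tree, lambda, mu, f = 1) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ages <- thermodiv::nodeAges(phy)
  ntip <- ape::Ntip(phy)
  fv <- if (length(f) == 1) rep(f, ntip) else unname(f[phy$tip.label])
  deriv <- function(t, state, parms) {
    E <- state[1]; D <- state[2]
    list(c(parms$mu - (parms$lambda + parms$mu) * E + parms$lambda * E^2,
           -(parms$lambda + parms$mu) * D + 2 * parms$lambda * E * D))
  }
  nn <- ntip + phy$Nnode
  Es <- numeric(nn); logDs <- numeric(nn); cnt <- integer(nn)
  Eacc <- numeric(nn)
  propagate <- function(E0, logD0, t0, t1) {
    if (t1 - t0 < 1e-12) return(c(E0, logD0))
    # integrate D on a log scale via scaling: track D from 1 and add log
    out <- deSolve::lsoda(c(E = E0, D = 1), c(t0, t1), deriv,
                          list(lambda = lambda, mu = mu),
                          rtol = 1e-10, atol = 1e-12)
    c(out[nrow(out), "E"], logD0 + log(out[nrow(out), "D"]))
  }
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c0 <- phy$edge[e, 2]
    if (c0 <= ntip) {
      E0 <- 1 - fv[c0]; logD0 <- log(fv[c0])
    } else {
      E0 <- Eacc[c0] / 2
      logD0 <- logDs[c0] + log(lambda)
    }
    res <- propagate(E0, logD0, ages[c0], ages[p])
    Eacc[p] <- Eacc[p] + res[1]
    logDs[p] <- logDs[p] + res[2]
  }
  root <- ntip + 1
  Eroot <- Eacc[root] / 2
  logDs[root] + log(lambda) - 2 * log(1 - Eroot)
}

# random MRP-style matrix over given taxa: characters from random clades
# of random source topologies, with '?' for randomly absent taxa
randomMRPMatrix <- function(taxa, nTrees = 3, seed = 1) {
  set.seed(seed)
  trees <- lapply(seq_len(nTrees), function(i) {
    k <- sample(seq(max(3, length(taxa) - 2), length(taxa)), 1)
    tr <- ape::rtree(k, tip.label = sample(taxa, k))
    tr$edge.length <- NULL
    tr
  })
  thermodiv::mrpEncode(trees)
}
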