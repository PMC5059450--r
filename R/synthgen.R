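## Synthetic-data generators: every pipeline input with known ground truth.

# Convert forward-time lineage records to a pruned, dated phylo.
# parent[i], birth[i]: lineage i's parent lineage and birth time (forward
# time, origin = 0); end[i]: death time or horizon T; retained[i]: lineage
# is a sampled extant tip. Extinct and unsampled parts are pruned and
# unary nodes collapsed. Returns NULL when < 2 tips survive.
.recordsToTree <- function(parent, birth, end, retained, T) {
  n <- length(parent)
  childOf <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(parent[i]))
    childOf[[parent[i]]] <- c(childOf[[parent[i]]], i)
  for (i in seq_len(n)) {
    ch <- childOf[[i]]
    if (length(ch) > 1L) childOf[i] <- list(ch[order(birth[ch])])
  }
  # subtree rooted on lineage `lin`'s path strictly after time `from`
  rep1 <- function(lin, from) {
    ch <- childOf[[lin]]
    ch <- ch[birth[ch] > from]
    if (!length(ch)) {
      if (retained[lin])
        return(list(txt = paste0("t", lin), len = end[lin] - from))
      return(NULL)
    }
    nxt <- ch[1L]
    tb <- birth[nxt]
    A <- rep1(lin, tb)       # continuation of this lineage past the split
    B <- rep1(nxt, tb)       # the daughter lineage
    seg <- tb - from
    if (!is.null(A) && !is.null(B))
      return(list(txt = paste0("(", A$txt, ":", format(A$len, digits = 12),
                               ",", B$txt, ":", format(B$len, digits = 12), ")"),
                  len = seg))
    if (!is.null(A)) return(list(txt = A$txt, len = A$len + seg))
    if (!is.null(B)) return(list(txt = B$txt, len = B$len + seg))
    NULL
  }
  top <- rep1(1L, -1)
  if (is.null(top) || !grepl(",", top$txt)) return(NULL)
  tr <- ape::read.tree(text = paste0(top$txt, ";"))
  tr
}

#' Simulate a birth-death tree with known shift regimes
#'
#' Forward (Gillespie) birth-death simulation from a single origin
#' lineage, with an optional plan of rate shifts: at each planned age one
#' uniformly chosen extant lineage switches to a new regime, inherited by
#' its later descendants. Extinct lineages are pruned; extant tips are
#' retained with probability `f`. Returns the realized dated tree and the
#' true shift configuration restricted to surviving branches.
#'
#' @param lambda,mu root-regime rates (events/lineage/Myr).
#' @param T stopping age (Ma): the simulation runs from age `T` to 0.
#'   Exclusive with `n`.
#' @param n stop at the moment the `n`-th extant lineage appears
#'   (exclusive with `T`; no shift plan allowed).
#' @param f per-tip sampling probability in (0, 1].
#' @param shifts optional data.frame (`age`, `lambda`, `mu`) of planned
#'   shifts (requires `T`).
#' @param seed integer RNG seed.
#' @param maxRetry resimulation cap when everything goes extinct or
#'   fewer than 2 tips survive.
#' @return list: `tree` (dated `phylo`), `config` (true
#'   [ShiftConfig-class] on that tree), `lostShifts` (planned shifts with
#'   no surviving descendants), `nGenerated` (extant lineages before
#'   sampling).
#' @export
simulateBDTree <- function(lambda, mu = 0, T = NULL, n = NULL, f = 1,
                           shifts = NULL, seed = 1L, maxRetry = 100L) {
  if (is.null(T) == is.null(n)) stop("supply exactly one of T or n")
  if (!is.null(shifts) && is.null(T)) stop("shift plans require T-stopping")
  stopifnot(lambda > 0, mu >= 0, f > 0, f <= 1)
  set.seed(seed)
  if (!is.null(shifts)) shifts <- shifts[order(-shifts$age), , drop = FALSE]

  for (attempt in seq_len(maxRetry)) {
    parent <- NA_integer_; birth <- 0; death <- NA_real_
    regime <- 1L
    regLam <- lambda; regMu <- mu
    applied <- list()     # (tau, lineage, regimeIndex)
    alive <- 1L
    tau <- 0
    shiftQueue <- if (!is.null(shifts)) T - shifts$age else numeric(0)
    shiftIdx <- 1L
    horizon <- if (!is.null(T)) T else Inf
    ok <- TRUE
    repeat {
      rates <- regLam[regime[alive]] + regMu[regime[alive]]
      tot <- sum(rates)
      dt <- if (tot > 0) rexp(1, tot) else Inf
      nextEv <- tau + dt
      if (shiftIdx <= length(shiftQueue) && shiftQueue[shiftIdx] <= nextEv &&
          shiftQueue[shiftIdx] <= horizon) {
        tau <- shiftQueue[shiftIdx]
        lin <- alive[sample.int(length(alive), 1L)]
        regLam <- c(regLam, shifts$lambda[shiftIdx])
        regMu <- c(regMu, shifts$mu[shiftIdx])
        regime[lin] <- length(regLam)
        applied[[length(applied) + 1L]] <-
          list(tau = tau, lineage = lin, reg = length(regLam))
        shiftIdx <- shiftIdx + 1L
        next
      }
      if (nextEv >= horizon) { tau <- horizon; break }
      tau <- nextEv
      lin <- alive[sample.int(length(alive), 1L, prob = rates / tot)]
      if (runif(1) < regLam[regime[lin]] / (regLam[regime[lin]] + regMu[regime[lin]])) {
        parent <- c(parent, lin); birth <- c(birth, tau)
        death <- c(death, NA_real_)
        regime <- c(regime, regime[lin])
        alive <- c(alive, length(parent))
        if (!is.null(n) && length(alive) == n) { horizon <- tau; break }
      } else {
        death[lin] <- tau
        alive <- setdiff(alive, lin)
        if (!length(alive)) { ok <- FALSE; break }
      }
    }
    if (!ok || length(alive) < 2L) next
    retained <- rep(FALSE, length(parent))
    retained[alive] <- runif(length(alive)) <= f
    if (sum(retained) < 2L) next
    end <- ifelse(is.na(death), horizon, death)
    tr <- .recordsToTree(parent, birth, end, retained, horizon)
    if (is.null(tr)) next

    # map surviving planned shifts onto the pruned tree
    ages <- nodeAges(tr)
    par2 <- rep(NA_integer_, ape::Ntip(tr) + tr$Nnode)
    par2[tr$edge[, 2L]] <- tr$edge[, 1L]
    rootNode <- ape::Ntip(tr) + 1L
    ev <- data.frame(child = integer(0), age = numeric(0),
                     lambda = numeric(0), mu = numeric(0))
    lost <- list()
    for (ap in applied) {
      # lineage ids are in birth order, so parents precede children
      aff <- logical(length(parent))
      aff[ap$lineage] <- TRUE
      if (length(parent) > 1L)
        for (j in seq.int(2L, length(parent)))
          if (aff[parent[j]] &&
              (parent[j] != ap$lineage || birth[j] > ap$tau))
            aff[j] <- TRUE
      affIdx <- which(aff)
      tipsAff <- intersect(paste0("t", affIdx[retained[affIdx]]),
                           tr$tip.label)
      shiftAge <- horizon - ap$tau
      if (!length(tipsAff)) {
        lost[[length(lost) + 1L]] <- ap
        next
      }
      node <- if (length(tipsAff) >= 2L) mrcaNode(tr, tipsAff)
              else match(tipsAff, tr$tip.label)
      while (node != rootNode && ages[par2[node]] <= shiftAge)
        node <- par2[node]
      if (node == rootNode) { lost[[length(lost) + 1L]] <- ap; next }
      ev <- rbind(ev, data.frame(child = node, age = shiftAge,
                                 lambda = regLam[ap$reg], mu = regMu[ap$reg]))
    }
    return(list(tree = tr,
                config = shiftConfig(lambda, mu, if (nrow(ev)) ev else NULL),
                lostShifts = lost, nGenerated = length(alive)))
  }
  stop("simulation failed ", maxRetry, " times (total extinction?)")
}

#' Simulate an autocorrelated isotope-like series
#'
#' Stationary AR(1) noise around an optional linear trend, on a uniform
#' age grid. The long-term rise of benthic oxygen-isotope values toward
#' the present (global cooling) can be emulated with a negative `trend`.
#'
#' @param phi AR(1) coefficient, in (-1, 1).
#' @param sd innovation standard deviation.
#' @param span `c(age_min, age_max)` in Ma.
#' @param step grid step in Myr (default 0.1).
#' @param mean series mean level.
#' @param trend change in value per Myr of age (value at age a includes
#'   `trend * a`; a negative trend makes values larger toward the present).
#' @param seed integer RNG seed.
#' @return An [IsotopeSeries-class].
#' @export
simulateProxy <- function(phi, sd, span, step = 0.1, mean = 0, trend = 0,
                          seed = 1L) {
  stopifnot(phi > -1, phi < 1, sd >= 0)
  set.seed(seed)
  age <- seq(span[1L], span[2L], by = step)
  n <- length(age)
  v <- numeric(n)
  v[1L] <- if (sd > 0) rnorm(1, 0, sd / sqrt(1 - phi^2)) else 0
  if (n > 1L) {
    eps <- if (sd > 0) rnorm(n - 1L, 0, sd) else numeric(n - 1L)
    for (i in 2:n) v[i] <- phi * v[i - 1L] + eps[i - 1L]
  }
  isotopeSeries(age, mean + trend * age + v)
}

#' Simulate a temperature-coupled diversification history
#'
#' Time-inhomogeneous pure-birth simulation in which the speciation rate
#' tracks the temperature proxy: `lambda(age) = exp(a + b * temp(age))`
#' with `temp = -value` of the generated isotope-like series (so higher
#' temp means warmer). `b < 0` makes speciation faster when cooler — the
#' relationship the correlation stage is meant to detect; `b = 0` reduces
#' to a constant-rate simulation.
#'
#' @param a,b intercept and slope on the log-speciation-rate scale.
#' @param T origin age (Ma).
#' @param seriesSpec list of [simulateProxy()] arguments (`phi`, `sd`,
#'   `step`, `mean`, `trend`); the span is `c(0, T)`.
#' @param seed integer RNG seed.
#' @param maxExpectedTips refuse runaway specifications whose expected tip
#'   count exceeds this.
#' @param maxRetry resimulation cap.
#' @return list: `tree` (dated `phylo`), `series` (the
#'   [IsotopeSeries-class]), `b`, `lambdaGrid` (lambda on the age grid).
#' @export
simulateCoupledHistory <- function(a, b, T,
                                   seriesSpec = list(phi = 0.9, sd = 0.15,
                                                     trend = -0.05),
                                   seed = 1L, maxExpectedTips = 1e5,
                                   maxRetry = 100L) {
  spec <- utils::modifyList(list(phi = 0.9, sd = 0.15, step = 0.1,
                                 mean = 0, trend = 0), seriesSpec)
  series <- simulateProxy(spec$phi, spec$sd, span = c(0, T),
                          step = spec$step, mean = spec$mean,
                          trend = spec$trend, seed = seed)
  temp <- -series@value
  lamGrid <- exp(a + b * temp)
  expTips <- exp(sum(lamGrid) * spec$step)
  if (expTips > maxExpectedTips)
    stop("runaway growth: expected ", format(expTips), " tips")
  lamAt <- function(age)
    approx(series@age, lamGrid, xout = age, rule = 2)$y
  lamMax <- max(lamGrid)
  set.seed(seed + 1L)
  for (attempt in seq_len(maxRetry)) {
    parent <- NA_integer_; birth <- 0
    nAlive <- 1L
    tau <- 0
    repeat {
      tau <- tau + rexp(1, nAlive * lamMax)
      if (tau >= T) break
      if (runif(1) <= lamAt(T - tau) / lamMax) {
        # pure birth: every lineage is extant, so choose uniformly
        lin <- sample.int(length(parent), 1L)
        parent <- c(parent, lin); birth <- c(birth, tau)
        nAlive <- nAlive + 1L
      }
    }
    if (nAlive < 2L) next
    retained <- rep(TRUE, length(parent))
    end <- rep(T, length(parent))
    tr <- .recordsToTree(parent, birth, end, retained, T)
    if (!is.null(tr))
      return(list(tree = tr, series = series, b = b, lambdaGrid = lamGrid))
  }
  stop("coupled simulation failed ", maxRetry, " times")
}

#' Decompose a model tree into overlapping source trees
#'
#' Draws `k` random tip subsets of size `tipsPerTree`, takes the induced
#' (restricted) subtrees, and rejection-samples until the two-shared-taxa
#' overlap graph is connected, so the set is valid MRP input by
#' construction.
#'
#' @param tree a `phylo` model tree.
#' @param k number of source trees (>= 2).
#' @param tipsPerTree tips per source tree (>= 4).
#' @param seed integer RNG seed.
#' @param maxTry rejection cap.
#' @return list of `phylo` source trees.
#' @export
decomposeToSourceTrees <- function(tree, k, tipsPerTree, seed = 1L,
                                   maxTry = 200L) {
  stopifnot(k >= 2L, tipsPerTree >= 4L)
  ntip <- ape::Ntip(tree)
  if (tipsPerTree > ntip) stop("tipsPerTree exceeds the model tree size")
  set.seed(seed)
  for (attempt in seq_len(maxTry)) {
    subs <- lapply(seq_len(k), function(i)
      sample(tree$tip.label, tipsPerTree))
    if (length(unique(unlist(subs))) < ntip && attempt < maxTry / 2) next
    trees <- lapply(subs, function(s) ape::keep.tip(tree, s))
    if (isConnected(checkOverlap(trees))) return(trees)
  }
  stop("could not draw a connected source-tree set in ", maxTry, " tries")
}

#' Sample fossil-like minimum-age calibrations with known truth
#'
#' Picks `n` distinct internal nodes of a dated tree and assigns each a
#' calibration age `true_age * (1 - |eps|)`, `eps ~ Normal(0, sd)`, so
#' every emitted age is a valid minimum (fossil first occurrences
#' underestimate clade ages). The study this emulates used 27 calibrated
#' nodes.
#'
#' @param tree dated `phylo`.
#' @param n number of calibrations (<= internal node count).
#' @param underestimateSd relative underestimation SD.
#' @param seed integer RNG seed.
#' @return Calibration data.frame (crown placements, full clade tip
#'   lists), with the sampled node numbers as attribute `"nodes"`.
#' @export
sampleFossilCalibrations <- function(tree, n, underestimateSd = 0.1,
                                     seed = 1L) {
  ntip <- ape::Ntip(tree)
  internals <- (ntip + 1L):(ntip + tree$Nnode)
  if (n > length(internals)) stop("n exceeds the internal node count")
  set.seed(seed)
  ages <- nodeAges(tree)
  nodes <- sort(internals[sample.int(length(internals), n)])
  eps <- abs(rnorm(n, 0, underestimateSd))
  calAge <- ages[nodes] * pmax(1 - eps, 0.05)
  df <- data.frame(
    clade_taxa = vapply(nodes, function(v)
      paste(sort(cladeTips(tree, v)), collapse = ";"), ""),
    placement = "crown",
    age_ma = calAge)
  attr(df, "nodes") <- nodes
  df
}
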