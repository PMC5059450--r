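#' @title Birth-death shift configuration
#'
#' @description A compound-Poisson rate-shift model state: one root regime
#' (speciation rate `lambda`, extinction rate `mu`, both per lineage per
#' Myr) plus zero or more shift events. Each event sits strictly inside a
#' branch (identified by its child node number) at a given age and starts
#' a new constant-rate regime inherited by all descendants until
#' overridden by a younger event.
#'
#' @slot lambda0,mu0 root-regime rates.
#' @slot events data.frame with columns `child`, `age`, `lambda`, `mu`.
#' @export
setClass("ShiftConfig",
         representation(lambda0 = "numeric", mu0 = "numeric",
                        events = "data.frame"))

setValidity("ShiftConfig", function(object) {
  if (object@lambda0 <= 0) return("lambda0 must be > 0")
  if (object@mu0 < 0) return("mu0 must be >= 0")
  ev <- object@events
  need <- c("child", "age", "lambda", "mu")
  if (!all(need %in% names(ev))) return("events need child/age/lambda/mu")
  if (nrow(ev) && (any(ev$lambda <= 0) || any(ev$mu < 0)))
    return("event rates invalid (lambda > 0, mu >= 0)")
  TRUE
})

#' Construct a ShiftConfig
#' @param lambda,mu root-regime speciation and extinction rates.
#' @param events optional data.frame (`child`, `age`, `lambda`, `mu`).
#' @return A [ShiftConfig-class].
#' @export
shiftConfig <- function(lambda, mu = 0, events = NULL) {
  if (is.null(events))
    events <- data.frame(child = integer(0), age = numeric(0),
                         lambda = numeric(0), mu = numeric(0))
  new("ShiftConfig", lambda0 = lambda, mu0 = mu, events = events)
}

#' @describeIn ShiftConfig-class number of shift events
#' @param x a `ShiftConfig`
#' @export
nShifts <- function(x) nrow(x@events)

#' @describeIn ShiftConfig-class the shift-event table
#' @export
shiftEvents <- function(x) x@events

setMethod("show", "ShiftConfig", function(object) {
  cat(sprintf("ShiftConfig: root lambda=%.4g mu=%.4g, %d shift(s)\n",
              object@lambda0, object@mu0, nrow(object@events)))
})

#' Per-tip sampling probabilities
#'
#' Expands a sampling specification to one probability per tip: a single
#' number, a named per-tip vector, or a clade table (`clade_taxa`
#' semicolon-separated, `fraction`) whose MRCA clades are filled in; tips
#' not covered default to 1.
#'
#' @param tree a `phylo`.
#' @param sampling numeric scalar, named numeric, or data.frame.
#' @return Numeric vector of length `Ntip(tree)`, ordered by tip number.
#' @export
expandSampling <- function(tree, sampling = 1) {
  ntip <- ape::Ntip(tree)
  f <- rep(1, ntip)
  names(f) <- tree$tip.label
  if (is.data.frame(sampling)) {
    stopifnot(all(c("clade_taxa", "fraction") %in% names(sampling)))
    for (i in seq_len(nrow(sampling))) {
      taxa <- trimws(strsplit(sampling$clade_taxa[i], ";", fixed = TRUE)[[1L]])
      node <- mrcaNode(tree, taxa)
      f[cladeTips(tree, node)] <- sampling$fraction[i]
    }
  } else if (length(sampling) == 1L && is.null(names(sampling))) {
    f[] <- sampling
  } else {
    stopifnot(!is.null(names(sampling)))
    f[names(sampling)] <- sampling
  }
  if (any(f <= 0 | f > 1)) stop("sampling fractions must lie in (0, 1]")
  f
}

# shared precomputation for likelihood calls
.bdPrep <- function(tree) {
  phy <- ape::reorder.phylo(tree, "postorder")
  deg <- tabulate(phy$edge[, 1L], nbins = ape::Ntip(phy) + phy$Nnode)
  if (any(deg[deg > 0] != 2L))
    stop("tree must be binary (resolve polytomies first)")
  list(phy = phy, ages = nodeAges(phy), ntip = ape::Ntip(phy))
}

#' Log-likelihood of a shift configuration on a dated tree
#'
#' Reconstructed-process birth-death density with per-tip sampling
#' fractions: extinction probability E and density D are propagated
#' tipward-to-rootward with tip conditions `E = 1 - f`, `D = f`, closed
#' -form constant-rate solutions within each regime segment, a factor
#' lambda at every internal node, and conditioning on survival of both
#' root-descendant lineages.
#'
#' @param tree dated binary `phylo`.
#' @param config a [ShiftConfig-class].
#' @param sampling see [expandSampling()].
#' @param prep internal precomputation (for repeated calls).
#' @return Log-likelihood (scalar; `-Inf` when degenerate).
#' @export
bdLogLik <- function(tree, config, sampling = 1, prep = NULL) {
  validObject(config)
  if (is.null(prep)) prep <- .bdPrep(tree)
  ev <- config@events
  if (nrow(ev)) {
    parent <- rep(NA_integer_, length(prep$ages))
    parent[prep$phy$edge[, 2L]] <- prep$phy$edge[, 1L]
    bad <- ev$age < prep$ages[ev$child] | ev$age >= prep$ages[parent[ev$child]]
    if (any(is.na(bad)) || any(bad))
      stop("shift event age outside its branch's age interval")
  }
  f <- expandSampling(prep$phy, sampling)
  bdLoglikCpp(prep$phy$edge, prep$ntip, prep$ages, f,
              c(config@lambda0, ev$lambda), c(config@mu0, ev$mu),
              as.integer(ev$child), as.numeric(ev$age))
}

#' @title Posterior sample set from the rate-shift sampler
#' @description Stored reversible-jump MCMC samples plus the fixed tree and
#' run settings. Each sample is a [ShiftConfig-class] with its
#' log-likelihood, log-prior and generation index.
#' @slot samples list of samples.
#' @slot tree the dated tree (`phylo`).
#' @slot settings run settings (priors, seeds, chain layout).
#' @export
setClass("BDPosterior",
         representation(samples = "list", tree = "ANY", settings = "list"))

setMethod("show", "BDPosterior", function(object) {
  k <- vapply(object@samples, function(s) nrow(s$events), 0L)
  cat(sprintf(
    "BDPosterior: %d samples on a %d-tip tree; shifts per sample %d-%d (median %g)\n",
    length(object@samples), ape::Ntip(object@tree), min(k), max(k), median(k)))
})

#' @describeIn BDPosterior-class stored samples
#' @param x a `BDPosterior`
#' @export
posteriorSamples <- function(x) x@samples

#' @describeIn BDPosterior-class number of stored samples
#' @export
nSamples <- function(x) length(x@samples)

#' @describeIn BDPosterior-class convert one stored sample to a ShiftConfig
#' @param i sample index
#' @export
sampleConfig <- function(x, i) {
  s <- x@samples[[i]]
  shiftConfig(s$lambda[1L], s$mu[1L],
              if (nrow(s$events)) s$events else NULL)
}

# log-prior of a state under the compound-Poisson model
.bdLogPrior <- function(lam, mu, k, gamma, lambdaMean, muMean, totLen) {
  dpois(k, gamma, log = TRUE) +
    sum(dexp(lam, rate = 1 / lambdaMean, log = TRUE)) +
    sum(dexp(mu, rate = 1 / muMean, log = TRUE)) -
    k * log(totLen)
}

#' Reversible-jump MCMC over shift configurations
#'
#' Moves: log-scale multiplier updates of a regime's lambda or mu; shift
#' birth (branch chosen proportional to duration, age uniform on the
#' branch, regime rates drawn from the prior); shift death; and a shift
#' position move. Dimension changes use the standard compound-Poisson
#' acceptance ratios (`gamma/(k+1)` for birth, `k/gamma` for death; the
#' regime-proposal and position densities cancel against the prior).
#' Optional Metropolis coupling runs `chains` chains with inverse
#' temperatures `1/(1 + heatDelta * (j-1))` applied to the likelihood and
#' periodic adjacent-pair swap proposals; samples are stored from the cold
#' chain. The likelihood term can be disabled (`useLikelihood = FALSE`)
#' for prior-recovery checks.
#'
#' @param tree dated binary `phylo`.
#' @param sampling see [expandSampling()].
#' @param priors list: `gamma` (expected shifts per tree, default 1),
#'   `lambdaMean`, `muMean` (exponential prior means; defaults are the
#'   tree's Yule point estimate `(Ntip - 1) / total branch length` and a
#'   tenth of it). Centering regime proposals on the Yule estimate keeps
#'   prior-drawn shift regimes on the scale the data support; the light
#'   extinction prior avoids turnover-driven inflation of the speciation
#'   rate on extant-only trees, where extinction is weakly identified.
#' @param generations total generations per chain.
#' @param chains number of Metropolis-coupled chains (1 = plain MCMC).
#' @param store number of evenly spaced cold-chain samples to keep before
#'   burn-in removal.
#' @param burninFraction fraction of stored samples discarded (default 0.1,
#'   so `store = 10000` leaves 9,000).
#' @param seed integer RNG seed.
#' @param heatDelta increment of the heating ladder.
#' @param swapEvery generations between swap proposals.
#' @param useLikelihood set `FALSE` to sample the prior.
#' @return A [BDPosterior-class].
#' @export
rjmcmcRun <- function(tree, sampling = 1, priors = list(),
                      generations = 20000L, chains = 1L, store = 1000L,
                      burninFraction = 0.1, seed = 1L,
                      heatDelta = 0.1, swapEvery = 50L,
                      useLikelihood = TRUE) {
  stopifnot(generations >= store, store >= 1L, chains >= 1L)
  prep <- .bdPrep(tree)
  phy <- prep$phy; ages <- prep$ages; ntip <- prep$ntip
  f <- expandSampling(phy, sampling)
  edgeChild <- phy$edge[, 2L]
  edgeLen <- ages[phy$edge[, 1L]] - ages[edgeChild]
  totLen <- sum(edgeLen)
  edgeProb <- edgeLen / totLen
  rootA <- ages[ntip + 1L]
  lamHeur <- (ntip - 1) / totLen      # Yule point estimate of lambda
  gamma <- priors$gamma %||% 1
  lambdaMean <- priors$lambdaMean %||% lamHeur
  muMean <- priors$muMean %||% (lamHeur / 10)
  set.seed(seed)

  loglik <- function(st) {
    if (!useLikelihood) return(0)
    bdLoglikCpp(phy$edge, ntip, ages, f, st$lam, st$mu,
                st$evChild, st$evAge)
  }
  logprior <- function(st)
    .bdLogPrior(st$lam, st$mu, length(st$evChild), gamma,
                lambdaMean, muMean, totLen)

  initState <- function() {
    for (try in seq_len(100L)) {
      st <- list(lam = rexp(1, 1 / lambdaMean),
                 mu = rexp(1, 1 / muMean) * 0.1,
                 evChild = integer(0), evAge = numeric(0))
      st$ll <- loglik(st)
      if (is.finite(st$ll)) { st$lp <- logprior(st); return(st) }
    }
    stop("could not initialize a finite-likelihood state in 100 attempts")
  }

  beta <- 1 / (1 + heatDelta * (seq_len(chains) - 1L))
  states <- replicate(chains, initState(), simplify = FALSE)

  recordAt <- unique(round(seq(1, generations, length.out = store)))
  samples <- vector("list", length(recordAt))
  nextRec <- 1L
  mul <- 1.0   # multiplier window for rate updates

  for (gen in seq_len(generations)) {
    for (ci in seq_len(chains)) {
      st <- states[[ci]]
      k <- length(st$evChild)
      u <- runif(1)
      if (u < 0.3) {                      # lambda update
        i <- sample.int(k + 1L, 1L)
        new <- st
        fac <- exp(mul * (runif(1) - 0.5))
        new$lam[i] <- st$lam[i] * fac
        new$ll <- loglik(new)
        la <- beta[ci] * (new$ll - st$ll) +
          dexp(new$lam[i], 1 / lambdaMean, log = TRUE) -
          dexp(st$lam[i], 1 / lambdaMean, log = TRUE) + log(fac)
      } else if (u < 0.5) {               # mu update
        i <- sample.int(k + 1L, 1L)
        new <- st
        fac <- exp(mul * (runif(1) - 0.5))
        new$mu[i] <- st$mu[i] * fac
        new$ll <- loglik(new)
        la <- beta[ci] * (new$ll - st$ll) +
          dexp(new$mu[i], 1 / muMean, log = TRUE) -
          dexp(st$mu[i], 1 / muMean, log = TRUE) + log(fac)
      } else if (u < 0.7) {               # birth of a shift
        e <- sample.int(length(edgeChild), 1L, prob = edgeProb)
        child <- edgeChild[e]
        age <- runif(1, ages[child], ages[child] + edgeLen[e])
        new <- st
        new$evChild <- c(st$evChild, child)
        new$evAge <- c(st$evAge, age)
        new$lam <- c(st$lam, rexp(1, 1 / lambdaMean))
        new$mu <- c(st$mu, rexp(1, 1 / muMean))
        new$ll <- loglik(new)
        la <- beta[ci] * (new$ll - st$ll) + log(gamma) - log(k + 1)
      } else if (u < 0.9) {               # death of a shift
        if (k == 0L) next
        i <- sample.int(k, 1L)
        new <- st
        new$evChild <- st$evChild[-i]
        new$evAge <- st$evAge[-i]
        new$lam <- st$lam[-(i + 1L)]
        new$mu <- st$mu[-(i + 1L)]
        new$ll <- loglik(new)
        la <- beta[ci] * (new$ll - st$ll) + log(k) - log(gamma)
      } else {                            # move a shift's position
        if (k == 0L) next
        i <- sample.int(k, 1L)
        child <- st$evChild[i]
        e <- match(child, edgeChild)
        new <- st
        new$evAge[i] <- runif(1, ages[child], ages[child] + edgeLen[e])
        new$ll <- loglik(new)
        la <- beta[ci] * (new$ll - st$ll)
      }
      if (is.finite(new$ll) && log(runif(1)) < la) {
        new$lp <- logprior(new)
        states[[ci]] <- new
      }
    }
    if (chains > 1L && gen %% swapEvery == 0L) {
      a <- sample.int(chains - 1L, 1L)
      b <- a + 1L
      la <- (beta[a] - beta[b]) * (states[[b]]$ll - states[[a]]$ll)
      if (log(runif(1)) < la) {
        tmp <- states[[a]]; states[[a]] <- states[[b]]; states[[b]] <- tmp
      }
    }
    if (nextRec <= length(recordAt) && gen == recordAt[nextRec]) {
      st <- states[[1L]]
      k <- length(st$evChild)
      samples[[nextRec]] <- list(
        lambda = st$lam, mu = st$mu,
        events = data.frame(child = st$evChild, age = st$evAge,
                            lambda = if (k) st$lam[-1L] else numeric(0),
                            mu = if (k) st$mu[-1L] else numeric(0)),
        logLik = st$ll, logPrior = st$lp, generation = gen)
      nextRec <- nextRec + 1L
    }
  }
  burn <- floor(burninFraction * length(samples))
  samples <- samples[seq.int(burn + 1L, length(samples))]
  new("BDPosterior", samples = samples, tree = phy,
      settings = list(gamma = gamma, lambdaMean = lambdaMean,
                      muMean = muMean, generations = generations,
                      chains = chains, store = store,
                      burninFraction = burninFraction, seed = seed,
                      totLen = totLen, sampling = f,
                      useLikelihood = useLikelihood))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize significant rate shifts from a posterior
#'
#' Per-branch marginal shift probabilities with a Bayes-factor
#' significance criterion: posterior odds of at least one shift on the
#' branch divided by the prior odds under the compound-Poisson prior
#' (events on a branch of duration `l` are a priori Poisson with mean
#' `gamma * l / totLen`). Branches subtending fewer than `minCladeSize`
#' tips are excluded from the report; ties are broken oldest-branch first.
#'
#' @param post a [BDPosterior-class].
#' @param minCladeSize exclude branches subtending fewer tips (default 5).
#' @param bfThreshold Bayes-factor significance threshold (default 5).
#' @return list with `shifts` (per-branch data.frame) and
#'   `configurations` (most frequent event-branch signatures).
#' @export
shiftSummary <- function(post, minCladeSize = 5L, bfThreshold = 5) {
  samples <- post@samples
  if (!length(samples)) stop("empty sample list")
  phy <- post@tree
  ages <- nodeAges(phy)
  edgeChild <- phy$edge[, 2L]
  edgeLen <- ages[phy$edge[, 1L]] - ages[edgeChild]
  nTips <- vapply(edgeChild, function(v) length(cladeTips(phy, v)), 0L)
  hit <- matrix(FALSE, length(samples), length(edgeChild))
  for (i in seq_along(samples)) {
    ev <- samples[[i]]$events
    if (nrow(ev)) hit[i, match(unique(ev$child), edgeChild)] <- TRUE
  }
  prob <- colMeans(hit)
  gamma <- post@settings$gamma
  p0 <- 1 - exp(-gamma * edgeLen / post@settings$totLen)
  eps <- 1 / (2 * length(samples))           # continuity guard for odds
  pAdj <- pmin(pmax(prob, eps), 1 - eps)
  bf <- (pAdj / (1 - pAdj)) / (p0 / (1 - p0))
  keep <- nTips >= minCladeSize
  df <- data.frame(child = edgeChild, nTips = nTips,
                   branchAge = ages[edgeChild],
                   prob = prob, priorProb = p0, bayesFactor = bf,
                   significant = bf >= bfThreshold)[keep, , drop = FALSE]
  df <- df[order(-df$prob, -df$branchAge), , drop = FALSE]
  sig <- vapply(samples, function(s) {
    ev <- s$events
    if (!nrow(ev)) "" else paste(sort(unique(ev$child)), collapse = ",")
  }, "")
  tab <- sort(table(sig), decreasing = TRUE)
  cfg <- data.frame(signature = names(tab),
                    count = as.integer(tab),
                    freq = as.numeric(tab) / length(samples))
  list(shifts = df, configurations = cfg)
}

#' @title Speciation rate-through-time curve
#' @description Mean speciation rate over the branches of a focal clade
#' crossing each point of a uniform age grid (0.1 Myr default step),
#' spanning clade origin down to the present.
#' @slot age grid ages (Ma, ascending from 0).
#' @slot rate mean speciation rate at each grid age.
#' @slot clade tip labels of the focal clade, or `"whole_tree"`.
#' @export
setClass("RateCurve",
         representation(age = "numeric", rate = "numeric", clade = "character"))

setValidity("RateCurve", function(object) {
  if (length(object@age) != length(object@rate))
    return("age and rate lengths differ")
  if (any(object@rate < 0, na.rm = TRUE)) return("rates must be >= 0")
  TRUE
})

setMethod("show", "RateCurve", function(object) {
  cat(sprintf("RateCurve [%s]: %d points, %.1f-%.1f Ma, mean rate %.4g\n",
              paste(object@clade, collapse = ","), length(object@age),
              min(object@age), max(object@age), mean(object@rate)))
})

#' @describeIn RateCurve-class grid ages
#' @param x a `RateCurve`
#' @export
curveAges <- function(x) x@age

#' @describeIn RateCurve-class rates on the grid
#' @export
curveRates <- function(x) x@rate

# edges of the clade subtree (clade = NULL: whole tree) + origin age
.cladeEdges <- function(phy, ages, clade) {
  if (is.null(clade)) {
    node <- ape::Ntip(phy) + 1L
  } else {
    node <- mrcaNode(phy, clade)
    if (node <= ape::Ntip(phy)) stop("clade must cover >= 2 tips")
  }
  # edges whose child lies within the clade subtree
  kids <- childrenList(phy)
  desc <- rep(FALSE, ape::Ntip(phy) + phy$Nnode)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    desc[v] <- TRUE
    stack <- c(stack, kids[[v]])
  }
  edges <- which(desc[phy$edge[, 2L]] & phy$edge[, 2L] != node)
  list(node = node, edges = edges, origin = ages[node])
}

#' Rate-through-time curve for one shift configuration
#'
#' @param tree dated binary `phylo`.
#' @param config a [ShiftConfig-class].
#' @param clade character vector of tip labels identifying the focal clade
#'   by MRCA, or `NULL` for the whole tree.
#' @param step grid step in Myr (default 0.1).
#' @return A [RateCurve-class].
#' @export
rttCurve <- function(tree, config, clade = NULL, step = 0.1) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ages <- nodeAges(phy)
  ce <- .cladeEdges(phy, ages, clade)
  top <- floor(ce$origin / step) * step
  if (top >= ce$origin) top <- top - step
  if (top < 0) stop("clade is younger than one grid step")
  grid <- seq(0, top, by = step)
  ev <- config@events
  lamMat <- branchLambdaAtCpp(phy$edge, ages, c(config@lambda0, ev$lambda),
                              as.integer(ev$child), as.numeric(ev$age), grid)
  rate <- colMeans(lamMat[ce$edges, , drop = FALSE], na.rm = TRUE)
  new("RateCurve", age = grid, rate = rate,
      clade = if (is.null(clade)) "whole_tree" else clade)
}

#' Rate-through-time curves for every posterior sample
#'
#' @param post a [BDPosterior-class].
#' @param clade focal clade tips (NULL = whole tree).
#' @param step grid step in Myr.
#' @return matrix (samples x grid ages) with the grid ages as an
#'   attribute `"age"` and colnames.
#' @export
rttCurves <- function(post, clade = NULL, step = 0.1) {
  phy <- post@tree
  ages <- nodeAges(phy)
  ce <- .cladeEdges(phy, ages, clade)
  top <- floor(ce$origin / step) * step
  if (top >= ce$origin) top <- top - step
  if (top < 0) stop("clade is younger than one grid step")
  grid <- seq(0, top, by = step)
  out <- matrix(NA_real_, length(post@samples), length(grid))
  for (i in seq_along(post@samples)) {
    s <- post@samples[[i]]
    lamMat <- branchLambdaAtCpp(phy$edge, ages, s$lambda,
                                as.integer(s$events$child),
                                as.numeric(s$events$age), grid)
    out[i, ] <- colMeans(lamMat[ce$edges, , drop = FALSE], na.rm = TRUE)
  }
  colnames(out) <- sprintf("%.1f", grid)
  attr(out, "age") <- grid
  attr(out, "clade") <- if (is.null(clade)) "whole_tree" else clade
  out
}

#' Posterior-mean rate-through-time curve
#' @param post a [BDPosterior-class].
#' @param clade focal clade tips (NULL = whole tree).
#' @param step grid step in Myr.
#' @return A [RateCurve-class] of pointwise posterior means.
#' @export
rttMeanCurve <- function(post, clade = NULL, step = 0.1) {
  m <- rttCurves(post, clade, step)
  new("RateCurve", age = attr(m, "age"), rate = unname(colMeans(m)),
      clade = attr(m, "clade"))
}
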