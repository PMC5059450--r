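test_that("likelihood matches closed forms for pure-birth trees", {
  T <- 4; lam <- 0.3
  two <- parseTree(sprintf("(A:%g,B:%g);", T, T))
  expect_equal(bdLogLik(two, shiftConfig(lam, 0)),
               log(lam) - 2 * lam * T, tolerance = 1e-10)

  set.seed(1)
  for (i in 1:5) {
    tr <- ape::rcoal(sample(5:30, 1))
    yule <- (ape::Ntip(tr) - 1) * log(lam) - lam * sum(tr$edge.length)
    expect_equal(bdLogLik(tr, shiftConfig(lam, 0)), yule, tolerance = 1e-8)
  }

  # continuity as the sampling fraction approaches 1
  tr <- ape::rcoal(12)
  expect_lt(abs(bdLogLik(tr, shiftConfig(lam, 0), sampling = 1 - 1e-9) -
                bdLogLik(tr, shiftConfig(lam, 0))), 1e-6)

  expect_error(bdLogLik(parseTree("(A:1,B:1,C:1);"), shiftConfig(0.1)),
               "binary")
  expect_error(shiftConfig(-0.1), "lambda0")
})

test_that("likelihood agrees with numerical ODE integration", {
  set.seed(2)
  for (i in 1:10) {
    tr <- ape::rcoal(sample(5:50, 1))
    lam <- runif(1, 0.1, 1); mu <- runif(1, 0, 0.9) * lam
    f <- runif(1, 0.3, 1)
    expect_equal(bdLogLik(tr, shiftConfig(lam, mu), sampling = f),
                 odeBdLoglik(tr, lam, mu, f), tolerance = 1e-6)
    # heterogeneous per-tip sampling, same node convention both routes
    fv <- setNames(runif(ape::Ntip(tr), 0.2, 1), tr$tip.label)
    expect_equal(bdLogLik(tr, shiftConfig(lam, mu), sampling = fv),
                 odeBdLoglik(tr, lam, mu, fv), tolerance = 1e-6)
  }
})

test_that("sampler retains 9000 of 10000 stored samples at 10% burn-in", {
  set.seed(3)
  tr <- ape::rcoal(8)
  post <- rjmcmcRun(tr, generations = 10000, store = 10000,
                    burninFraction = 0.1, seed = 4, useLikelihood = FALSE)
  expect_equal(nSamples(post), 9000L)
  gens <- vapply(posteriorSamples(post), `[[`, 0, "generation")
  expect_true(all(diff(gens) > 0))
})

test_that("prior recovery: shift counts follow the Poisson prior", {
  set.seed(5)
  tr <- ape::rcoal(10)
  gamma <- 1
  post <- rjmcmcRun(tr, generations = 60000, store = 6000,
                    burninFraction = 1 / 6, seed = 6,
                    priors = list(gamma = gamma), useLikelihood = FALSE)
  k <- vapply(posteriorSamples(post), function(s) nrow(s$events), 0L)
  kmax <- max(3L, max(k))
  obs <- tabulate(k + 1L, nbins = kmax + 1L)
  p <- dpois(0:kmax, gamma)
  p[kmax + 1L] <- p[kmax + 1L] + ppois(kmax, gamma, lower.tail = FALSE)
  # merge sparse tail bins for a valid chi-square test
  keep <- p * length(k) >= 5
  if (any(!keep)) {
    obs2 <- c(obs[keep], sum(obs[!keep]))
    p2 <- c(p[keep], sum(p[!keep]))
  } else { obs2 <- obs; p2 <- p }
  gof <- suppressWarnings(stats::chisq.test(obs2, p = p2))
  expect_gt(gof$p.value, 0.01)
})

test_that("posterior recovers the generating speciation rate", {
  sim <- simulateBDTree(0.1, 0, n = 100, seed = 31)
  post <- rjmcmcRun(sim$tree, generations = 20000, store = 2000, seed = 32)
  lam <- vapply(posteriorSamples(post), function(s) s$lambda[1], 0)
  mu <- vapply(posteriorSamples(post), function(s) s$mu[1], 0)
  ci <- quantile(lam, c(0.025, 0.975))
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
  # lambda absorbs the weakly identified extinction mass, so the net
  # diversification rate is the sharply recovered quantity
  expect_lt(abs(mean(lam - mu) - 0.1) / 0.1, 0.2)
  k <- vapply(posteriorSamples(post), function(s) nrow(s$events), 0L)
  expect_equal(as.integer(names(which.max(table(k)))), 0L)
})

test_that("shift summary computes hand-checkable Bayes factors", {
  set.seed(7)
  tr <- ape::rcoal(12)
  prep <- ape::reorder.phylo(tr, "postorder")
  ages <- nodeAges(prep)
  edgeLen <- ages[prep$edge[, 1]] - ages[prep$edge[, 2]]
  totLen <- sum(edgeLen)
  # choose a branch subtending >= 5 tips
  sizes <- vapply(prep$edge[, 2], function(v) length(cladeTips(prep, v)), 0L)
  e <- which(sizes >= 5)[1]
  child <- prep$edge[e, 2]
  mkSample <- function(withShift) {
    ev <- if (withShift)
      data.frame(child = child, age = mean(ages[prep$edge[e, ]]),
                 lambda = 0.5, mu = 0)
    else data.frame(child = integer(0), age = numeric(0),
                    lambda = numeric(0), mu = numeric(0))
    list(lambda = c(0.1, ev$lambda), mu = c(0, ev$mu), events = ev,
         logLik = -1, logPrior = -1, generation = 1)
  }
  samples <- c(replicate(80, mkSample(TRUE), simplify = FALSE),
               replicate(20, mkSample(FALSE), simplify = FALSE))
  post <- new("BDPosterior", samples = samples, tree = prep,
              settings = list(gamma = 1, totLen = totLen))
  ss <- shiftSummary(post, minCladeSize = 5, bfThreshold = 5)
  row <- ss$shifts[ss$shifts$child == child, ]
  expect_equal(row$prob, 0.8)
  p0 <- 1 - exp(-edgeLen[e] / totLen)
  expect_equal(row$bayesFactor, (0.8 / 0.2) / (p0 / (1 - p0)),
               tolerance = 1e-12)
  expect_true(all(ss$shifts$nTips >= 5))
  expect_equal(ss$configurations$signature[1], as.character(child))

  # all-zero-shift posteriors have an empty significant set
  post0 <- new("BDPosterior",
               samples = replicate(50, mkSample(FALSE), simplify = FALSE),
               tree = prep, settings = list(gamma = 1, totLen = totLen))
  ss0 <- shiftSummary(post0)
  expect_false(any(ss0$shifts$significant))
  expect_error(shiftSummary(new("BDPosterior", samples = list(),
                                tree = prep, settings = list())),
               "empty")
})

test_that("rate-through-time curves do the branch bookkeeping", {
  set.seed(8)
  tr <- ape::rcoal(10)
  flat <- rttCurve(tr, shiftConfig(0.25, 0))
  expect_true(all(curveRates(flat) == 0.25))
  expect_equal(curveAges(flat)[2] - curveAges(flat)[1], 0.1)

  # a two-tip cherry with one shift: the curve steps at the shift age
  T <- 10
  two <- parseTree(sprintf("(A:%g,B:%g);", T, T))
  childA <- match("A", two$tip.label)
  cfg <- shiftConfig(0.1, 0, data.frame(child = childA, age = 4,
                                        lambda = 0.5, mu = 0))
  rc <- rttCurve(two, cfg)
  ages <- curveAges(rc)
  expect_equal(curveRates(rc)[ages < 4 - 1e-9], rep(0.3, sum(ages < 4 - 1e-9)))
  expect_equal(curveRates(rc)[ages >= 4], rep(0.1, sum(ages >= 4)))

  # per-clade curve sees only the clade's branches
  cfgRoot <- shiftConfig(0.1, 0)
  sub <- cladeTips(tr, mrcaNode(tr, tr$tip.label[1:3]))
  rcSub <- rttCurve(tr, cfgRoot, clade = sub)
  expect_lte(max(curveAges(rcSub)), rootAge(tr))
  expect_true(all(curveRates(rcSub) == 0.1))
})

test_that("posterior mean curve is the pointwise mean of sample curves", {
  sim <- simulateBDTree(0.15, 0, T = 25, seed = 41)
  post <- rjmcmcRun(sim$tree, generations = 3000, store = 200, seed = 42)
  mc <- rttMeanCurve(post)
  manual <- rowMeans(vapply(seq_len(nSamples(post)), function(i)
    curveRates(rttCurve(post@tree, sampleConfig(post, i))),
    numeric(length(curveAges(mc)))))
  expect_equal(curveRates(mc), unname(manual), tolerance = 1e-12)
})
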