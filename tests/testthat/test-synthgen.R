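test_that("pure-birth tip counts match the Yule expectation", {
  tips <- vapply(1:300, function(s) {
    r <- tryCatch(simulateBDTree(0.1, 0, T = 30, seed = s),
                  error = function(e) NULL)
    if (is.null(r)) NA_real_ else ape::Ntip(r$tree)
  }, 0)
  # failures only when < 2 lineages split; fold them in as count 1
  tips[is.na(tips)] <- 1
  expected <- exp(0.1 * 30)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 3 * se + 1)
})

test_that("simulated trees are ultrametric with extant tips at zero", {
  for (s in c(2, 5, 9)) {
    sim <- simulateBDTree(0.15, 0.05, T = 25, seed = s)
    expect_true(ape::is.ultrametric(sim$tree, tol = 1e-6))
    expect_true(all(nodeAges(sim$tree)[seq_len(ape::Ntip(sim$tree))] == 0))
  }
  simN <- simulateBDTree(0.2, 0, n = 40, seed = 3)
  expect_equal(ape::Ntip(simN$tree), 40L)
})

test_that("tip subsampling is binomial in the sampling fraction", {
  kept <- 0; total <- 0
  for (s in 1:80) {
    sim <- tryCatch(simulateBDTree(0.12, 0, T = 30, f = 0.5, seed = 600 + s),
                    error = function(e) NULL)
    if (is.null(sim)) next
    kept <- kept + ape::Ntip(sim$tree)
    total <- total + sim$nGenerated
  }
  bt <- stats::binom.test(kept, total, p = 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("planned shifts survive onto the pruned tree with their regimes", {
  sim <- simulateBDTree(0.05, 0, T = 40,
                        shifts = data.frame(age = 20, lambda = 0.3, mu = 0),
                        seed = 11)
  ev <- shiftEvents(sim$config)
  expect_equal(nrow(ev) + length(sim$lostShifts), 1L)
  if (nrow(ev)) {
    expect_equal(ev$lambda, 0.3)
    expect_equal(ev$age, 20)
    ages <- nodeAges(sim$tree)
    parent <- rep(NA_integer_, ape::Ntip(sim$tree) + sim$tree$Nnode)
    parent[sim$tree$edge[, 2]] <- sim$tree$edge[, 1]
    expect_lte(ages[ev$child], ev$age)
    expect_gt(ages[parent[ev$child]], ev$age)
  }
})

test_that("AR(1) proxies have the requested autocorrelation", {
  s0 <- simulateProxy(0, 1, span = c(0, 99.9), seed = 21)
  n <- length(seriesAges(s0))
  expect_equal(n, 1000L)
  ac0 <- stats::acf(seriesValues(s0), plot = FALSE)$acf[2]
  expect_lt(abs(ac0), 2 / sqrt(n))

  s9 <- simulateProxy(0.9, 1, span = c(0, 99.9), seed = 22)
  ac9 <- stats::acf(seriesValues(s9), plot = FALSE)$acf[2]
  expect_lt(abs(ac9 - 0.9), 2 / sqrt(n))

  sc <- simulateProxy(0.5, 0, span = c(0, 10), mean = 3, seed = 23)
  expect_true(all(seriesValues(sc) == 3))
  expect_identical(seriesValues(simulateProxy(0.5, 1, span = c(0, 5), seed = 4)),
                   seriesValues(simulateProxy(0.5, 1, span = c(0, 5), seed = 4)))
})

test_that("uncoupled histories match constant-rate simulations", {
  a <- log(0.12)
  nc <- vapply(1:150, function(s) {
    r <- tryCatch(simulateCoupledHistory(a, 0, T = 30,
                                         seriesSpec = list(phi = 0.8, sd = 0.3),
                                         seed = 700 + s),
                  error = function(e) NULL)
    if (is.null(r)) 1 else ape::Ntip(r$tree)
  }, 0)
  nb <- vapply(1:150, function(s) {
    r <- tryCatch(simulateBDTree(0.12, 0, T = 30, seed = 900 + s),
                  error = function(e) NULL)
    if (is.null(r)) 1 else ape::Ntip(r$tree)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(nc, nb))
  expect_gt(ks$p.value, 0.01)
})

test_that("negative coupling concentrates speciation in cool intervals", {
  # b < 0: lambda = exp(a + b*temp), temp = -value; with a cooling trend
  # (values rising toward the present) speciation events should fall where
  # the value is above (cooler than) the series mean
  diffs <- numeric(0)
  for (s in 1:25) {
    r <- tryCatch(
      simulateCoupledHistory(log(0.35), -2, T = 30,
                             seriesSpec = list(phi = 0.8, sd = 0.1,
                                               trend = -0.04),
                             seed = 50 + s),
      error = function(e) NULL)
    if (is.null(r) || ape::Ntip(r$tree) < 5) next
    evAges <- nodeAges(r$tree)[(ape::Ntip(r$tree) + 1):
                               (ape::Ntip(r$tree) + r$tree$Nnode)]
    evVal <- approx(seriesAges(r$series), seriesValues(r$series),
                    xout = evAges, rule = 2)$y
    diffs <- c(diffs, mean(evVal) - mean(seriesValues(r$series)))
  }
  tt <- t.test(diffs, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_error(simulateCoupledHistory(log(5), 0, T = 30, maxExpectedTips = 100),
               "runaway")
})

test_that("source-tree decomposition yields connected, faithful subtrees", {
  set.seed(31)
  model <- ape::rtree(40); model$edge.length <- NULL
  expect_error(decomposeToSourceTrees(model, k = 1, tipsPerTree = 10),
               "k >= 2")
  expect_error(decomposeToSourceTrees(model, k = 3, tipsPerTree = 3),
               "tipsPerTree >= 4")
  subs <- decomposeToSourceTrees(model, k = 8, tipsPerTree = 10, seed = 5)
  expect_true(isConnected(checkOverlap(subs)))
  for (sub in subs) {
    # restriction oracle: the induced subtree's clades are exactly the
    # model-tree clades intersected with the subset (nontrivial ones)
    S <- sub$tip.label
    induced <- lapply(cladeSets(model), function(cs) {
      inter <- intersect(strsplit(cs, "|", fixed = TRUE)[[1]], S)
      if (length(inter) >= 2) paste(sort(inter), collapse = "|") else NULL
    })
    induced <- sort(unique(unlist(induced)))
    expect_equal(cladeSets(sub), induced)
  }
})

test_that("fossil calibrations are valid minima with known truth", {
  sim <- simulateBDTree(0.12, 0, T = 35, seed = 77)
  tr <- sim$tree
  cal0 <- sampleFossilCalibrations(tr, 5, underestimateSd = 0, seed = 1)
  ages <- nodeAges(tr)
  expect_equal(cal0$age_ma, unname(ages[attr(cal0, "nodes")]))
  for (s in 1:10) {
    cals <- sampleFossilCalibrations(tr, 10, underestimateSd = 0.2, seed = s)
    expect_true(all(cals$age_ma <= ages[attr(cals, "nodes")] + 1e-12))
    expect_true(all(cals$age_ma > 0))
  }
  expect_equal(nrow(sampleFossilCalibrations(tr, 27, seed = 2)), 27L)
  expect_error(sampleFossilCalibrations(tr, 10000, seed = 1), "exceeds")
})

test_that("densely calibrated scaling tracks the true chronogram", {
  sim <- simulateBDTree(0.12, 0, T = 35, seed = 123)
  tr <- sim$tree
  nInt <- tr$Nnode
  n <- max(2L, floor(0.9 * nInt))
  cals <- sampleFossilCalibrations(tr, n, underestimateSd = 0.05, seed = 6)
  d <- equalScale(tr, resolveCalibrations(tr, cals))
  trueA <- nodeAges(tr); estA <- nodeAges(d)
  nodes <- attr(cals, "nodes")
  expect_true(all(estA[nodes] >= cals$age_ma - 1e-9))
  # high calibration density with small underestimation: ages close to truth
  relErr <- abs(estA[nodes] - trueA[nodes]) / pmax(trueA[nodes], 1)
  expect_lt(stats::median(relErr), 0.15)
})
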