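# Independent constant-rate birth-death log-likelihood by numerical ODE
# integration (deSolve), used as a verification oracle for the analytic
# implementation. Same node-join and survival-conditioning conventions,
# entirely numerical propagation.

odeBdLoglikOracle <- function(tree, lambda, mu, f = 1) {
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
  logDs <- numeric(nn)
  Eacc <- numeric(nn)
  propagate <- function(E0, logD0, t0, t1) {
    if (t1 - t0 < 1e-12) return(c(E0, logD0))
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
  logDs[root] + log(lambda) - 2 * log(1 - Eacc[root] / 2)
}
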