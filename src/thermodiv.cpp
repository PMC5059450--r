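#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Unordered (Fitch) parsimony length of a binary-state matrix on a rooted
// tree, computed by Sankoff dynamic programming so polytomies and missing
// data ('?', coded NA) are scored exactly. States per column: 0, 1, NA.
// When implicitOutgroup is true the score is min(c0, c1 + 1) at the root,
// i.e. the all-zero hypothetical outgroup is adjoined above the root.
// [[Rcpp::export]]
double sankoffScoreCpp(IntegerMatrix edge, int nTip, int nNodeTotal,
                       IntegerMatrix tipStates, bool implicitOutgroup) {
  const int nCol = tipStates.ncol();
  const double BIG = 1e9;
  std::vector<double> c0((size_t)nNodeTotal * nCol, 0.0);
  std::vector<double> c1((size_t)nNodeTotal * nCol, 0.0);
  for (int t = 0; t < nTip; ++t) {
    for (int j = 0; j < nCol; ++j) {
      int s = tipStates(t, j);
      if (s == NA_INTEGER) continue;           // '?': free, cost 0 either way
      if (s == 0) c1[(size_t)t * nCol + j] = BIG;
      else        c0[(size_t)t * nCol + j] = BIG;
    }
  }
  const int nEdge = edge.nrow();
  for (int e = 0; e < nEdge; ++e) {            // edges must be in postorder
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (int j = 0; j < nCol; ++j) {
      double a0 = c0[(size_t)c * nCol + j], a1 = c1[(size_t)c * nCol + j];
      c0[(size_t)p * nCol + j] += std::min(a0, a1 + 1.0);
      c1[(size_t)p * nCol + j] += std::min(a1, a0 + 1.0);
    }
  }
  int root = edge(nEdge - 1, 0) - 1;
  double total = 0.0;
  for (int j = 0; j < nCol; ++j) {
    double r0 = c0[(size_t)root * nCol + j], r1 = c1[(size_t)root * nCol + j];
    total += implicitOutgroup ? std::min(r0, r1 + 1.0) : std::min(r0, r1);
  }
  return total;
}

// One closed-form propagation step of the reconstructed birth-death process
// over duration dt under constant (lam, mu):
//   E' = mu - (lam+mu) E + lam E^2 ,  D' = -(lam+mu) D + 2 lam E D
// With x = 1 - E (survival probability) the E equation is logistic,
// x' = r x - lam x^2, r = lam - mu, giving
//   x(t)    = x0 e^{rt} / (1 + lam x0 (e^{rt}-1)/r)
//   log D(t)= log D0 + r t - 2 log(1 + lam x0 (e^{rt}-1)/r)
static inline void bdStep(double lam, double mu, double dt,
                          double &E, double &logD) {
  if (dt <= 0.0) return;
  double x0 = 1.0 - E;
  double r = lam - mu;
  double denom;
  if (std::fabs(r) * dt > 1e-8) {
    double ert = std::exp(r * dt);
    denom = 1.0 + lam * x0 * (ert - 1.0) / r;
    E = 1.0 - x0 * ert / denom;
  } else {                                     // lam ~ mu limit
    denom = 1.0 + lam * x0 * dt;
    E = 1.0 - x0 / denom;
  }
  logD += r * dt - 2.0 * std::log(denom);
}

// Log-likelihood of a dated, binary, extant-only tree under a
// compound-Poisson birth-death shift configuration with per-tip sampling
// fractions. Regimes: index 0 is the root regime; events (evChild[i] = the
// child-node id identifying the branch, evAge[i] strictly inside that
// branch's age interval) start regime i+1, inherited tipward until
// overridden by a younger event. Tip conditions E = 1 - f, D = f; at each
// internal node D <- D_L * D_R * lambda(regime at the node) and E is the
// mean of the two child-branch values; the root is conditioned on survival
// of both descendant lineages via (1 - E_root)^2.
// [[Rcpp::export]]
double bdLoglikCpp(IntegerMatrix edge, int nTip, NumericVector nodeAge,
                   NumericVector tipF,
                   NumericVector regLambda, NumericVector regMu,
                   IntegerVector evChild, NumericVector evAge) {
  const int nEdge = edge.nrow();
  const int nNode = nodeAge.size();
  const int nEv = evChild.size();
  const int root = edge(nEdge - 1, 0) - 1;

  // events attached to each branch (keyed by child node), youngest first
  std::vector<std::vector<int> > evOn(nNode);
  for (int i = 0; i < nEv; ++i) evOn[evChild[i] - 1].push_back(i);
  for (int v = 0; v < nNode; ++v)
    if (evOn[v].size() > 1)
      std::sort(evOn[v].begin(), evOn[v].end(),
                [&](int a, int b) { return evAge[a] < evAge[b]; });

  // regime governing each node position: preorder pass (reverse postorder)
  std::vector<int> nodeReg(nNode, 0);
  nodeReg[root] = 0;
  for (int e = nEdge - 1; e >= 0; --e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const std::vector<int> &ev = evOn[c];
    nodeReg[c] = ev.empty() ? nodeReg[p] : (ev.front() + 1);
  }

  std::vector<double> Esum(nNode, 0.0), logDsum(nNode, 0.0);
  std::vector<int> cnt(nNode, 0);
  std::vector<bool> done(nNode, false);

  for (int e = 0; e < nEdge; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double E, logD;
    if (c < nTip) {
      E = 1.0 - tipF[c];
      logD = std::log(tipF[c]);
    } else {
      if (cnt[c] != 2) return NA_REAL;         // tree must be binary
      E = Esum[c] / 2.0;
      logD = logDsum[c] + std::log(regLambda[nodeReg[c]]);
      done[c] = true;
    }
    // propagate from child age to parent age through the branch's segments
    double t = nodeAge[c];
    const std::vector<int> &ev = evOn[c];
    int reg = nodeReg[c];
    for (size_t k = 0; k < ev.size(); ++k) {
      double a = evAge[ev[k]];
      bdStep(regLambda[reg], regMu[reg], a - t, E, logD);
      t = a;
      reg = (k + 1 < ev.size()) ? (ev[k + 1] + 1) : nodeReg[p];
    }
    bdStep(regLambda[reg], regMu[reg], nodeAge[p] - t, E, logD);
    Esum[p] += E;
    logDsum[p] += logD;
    cnt[p] += 1;
    if (!R_finite(logD)) return R_NegInf;
  }
  if (cnt[root] != 2) return NA_REAL;
  double Eroot = Esum[root] / 2.0;
  if (Eroot >= 1.0) return R_NegInf;
  double logL = logDsum[root] + std::log(regLambda[0])
              - 2.0 * std::log(1.0 - Eroot);
  return R_finite(logL) ? logL : R_NegInf;
}

// lambda(age) on every branch of the tree at a vector of grid ages, under a
// shift configuration; used for rate-through-time curves. Returns a matrix
// (edges x grid ages) with NA where the branch does not cross the age
// (child-inclusive, parent-exclusive).
// [[Rcpp::export]]
NumericMatrix branchLambdaAtCpp(IntegerMatrix edge, NumericVector nodeAge,
                                NumericVector regLambda,
                                IntegerVector evChild, NumericVector evAge,
                                NumericVector grid) {
  const int nEdge = edge.nrow();
  const int nNode = nodeAge.size();
  const int nEv = evChild.size();
  const int nG = grid.size();
  const int root = edge(nEdge - 1, 0) - 1;

  std::vector<std::vector<int> > evOn(nNode);
  for (int i = 0; i < nEv; ++i) evOn[evChild[i] - 1].push_back(i);
  for (int v = 0; v < nNode; ++v)
    if (evOn[v].size() > 1)
      std::sort(evOn[v].begin(), evOn[v].end(),
                [&](int a, int b) { return evAge[a] < evAge[b]; });

  std::vector<int> nodeReg(nNode, 0);
  nodeReg[root] = 0;
  for (int e = nEdge - 1; e >= 0; --e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const std::vector<int> &ev = evOn[c];
    nodeReg[c] = ev.empty() ? nodeReg[p] : (ev.front() + 1);
  }

  NumericMatrix out(nEdge, nG);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int e = 0; e < nEdge; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double aC = nodeAge[c], aP = nodeAge[p];
    const std::vector<int> &ev = evOn[c];
    for (int g = 0; g < nG; ++g) {
      double a = grid[g];
      if (a < aC || a >= aP) continue;
      int reg = nodeReg[c];
      for (size_t k = 0; k < ev.size(); ++k) {
        if (a < evAge[ev[k]]) break;
        reg = (k + 1 < ev.size()) ? (ev[k + 1] + 1) : nodeReg[p];
      }
      out(e, g) = regLambda[reg];
    }
  }
  return out;
}
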