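// Single-flip Metropolis simulated annealing and multistart tabu search
// for quadratic binary / spin models.
//
// Models arrive as a linear vector plus strictly upper-triangular
// couplings in triplet form; an adjacency (CSR) structure is built once.
// For state s (entries {0,1} or {-1,+1}) with local field
//   phi_i = linear_i + sum_j w_ij s_j,
// flipping s_i -> s_i' changes the energy by (s_i' - s_i) * phi_i, after
// which neighbor fields are updated in O(degree). R's RNG is used
// throughout so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Adjacency {
  std::vector<int> ptr, idx;
  std::vector<double> w;
};

Adjacency buildAdjacency(int n, const IntegerVector &qi,
                         const IntegerVector &qj, const NumericVector &qx) {
  Adjacency adj;
  std::vector<int> deg(n, 0);
  const int nz = qi.size();
  for (int e = 0; e < nz; ++e) {
    ++deg[qi[e] - 1];
    ++deg[qj[e] - 1];
  }
  adj.ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) adj.ptr[i + 1] = adj.ptr[i] + deg[i];
  adj.idx.assign(adj.ptr[n], 0);
  adj.w.assign(adj.ptr[n], 0.0);
  std::vector<int> fill(adj.ptr.begin(), adj.ptr.end() - 1);
  for (int e = 0; e < nz; ++e) {
    const int a = qi[e] - 1, b = qj[e] - 1;
    adj.idx[fill[a]] = b; adj.w[fill[a]++] = qx[e];
    adj.idx[fill[b]] = a; adj.w[fill[b]++] = qx[e];
  }
  return adj;
}

// local fields for the current state
void computeFields(const NumericVector &linear, const Adjacency &adj,
                   const std::vector<double> &s, std::vector<double> &phi) {
  const int n = linear.size();
  for (int i = 0; i < n; ++i) {
    double f = linear[i];
    for (int e = adj.ptr[i]; e < adj.ptr[i + 1]; ++e)
      f += adj.w[e] * s[adj.idx[e]];
    phi[i] = f;
  }
}

double fullEnergy(const NumericVector &linear, const IntegerVector &qi,
                  const IntegerVector &qj, const NumericVector &qx,
                  const std::vector<double> &s) {
  double e = 0.0;
  for (int i = 0; i < (int)s.size(); ++i) e += linear[i] * s[i];
  for (int k = 0; k < qi.size(); ++k)
    e += qx[k] * s[qi[k] - 1] * s[qj[k] - 1];
  return e;
}

void randomState(std::vector<double> &s, double lo, double hi) {
  for (size_t i = 0; i < s.size(); ++i)
    s[i] = (unif_rand() < 0.5) ? lo : hi;
}

} // namespace

// [[Rcpp::export(name = ".saCpp")]]
List saCpp(int nvars, NumericVector linear, IntegerVector qi,
           IntegerVector qj, NumericVector qx, int numReads, int sweeps,
           double beta0, double beta1, bool spin) {
  const double lo = spin ? -1.0 : 0.0, hi = 1.0;
  Adjacency adj = buildAdjacency(nvars, qi, qj, qx);
  std::vector<double> s(nvars), phi(nvars), best(nvars);
  std::vector<double> readBest(numReads);
  double globalBest = R_PosInf;
  std::vector<double> globalBestState(nvars);

  // geometric inverse-temperature ladder
  std::vector<double> betas(sweeps);
  if (sweeps == 1) {
    betas[0] = beta1;
  } else {
    const double ratio = std::pow(beta1 / beta0, 1.0 / (sweeps - 1));
    double b = beta0;
    for (int t = 0; t < sweeps; ++t) { betas[t] = b; b *= ratio; }
  }

  for (int read = 0; read < numReads; ++read) {
    randomState(s, lo, hi);
    computeFields(linear, adj, s, phi);
    double cur = fullEnergy(linear, qi, qj, qx, s);
    double bestE = cur;
    best = s;
    for (int t = 0; t < sweeps; ++t) {
      const double beta = betas[t];
      for (int i = 0; i < nvars; ++i) {
        const double flip = (s[i] == hi) ? lo - hi : hi - lo;
        const double dE = flip * phi[i];
        if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
          s[i] += flip;
          cur += dE;
          for (int e = adj.ptr[i]; e < adj.ptr[i + 1]; ++e)
            phi[adj.idx[e]] += adj.w[e] * flip;
          if (cur < bestE - 1e-12) { bestE = cur; best = s; }
        }
      }
    }
    readBest[read] = bestE;
    if (bestE < globalBest) { globalBest = bestE; globalBestState = best; }
  }

  int occ = 0;
  for (int r = 0; r < numReads; ++r)
    if (readBest[r] <= globalBest + 1e-9) ++occ;
  return List::create(_["assignment"] = NumericVector(globalBestState.begin(),
                                                      globalBestState.end()),
                      _["energy"] = globalBest,
                      _["occurrencesBest"] = occ);
}

// [[Rcpp::export(name = ".tabuCpp")]]
List tabuCpp(int nvars, NumericVector linear, IntegerVector qi,
             IntegerVector qj, NumericVector qx, int numRestarts, int tenure,
             int maxIters, bool spin) {
  const double lo = spin ? -1.0 : 0.0, hi = 1.0;
  Adjacency adj = buildAdjacency(nvars, qi, qj, qx);
  std::vector<double> s(nvars), phi(nvars);
  std::vector<int> tabuUntil(nvars);
  std::vector<double> restartBest(numRestarts);
  double globalBest = R_PosInf;
  std::vector<double> globalBestState(nvars);

  for (int restart = 0; restart < numRestarts; ++restart) {
    randomState(s, lo, hi);
    computeFields(linear, adj, s, phi);
    std::fill(tabuUntil.begin(), tabuUntil.end(), -1);
    double cur = fullEnergy(linear, qi, qj, qx, s);
    double bestE = cur;
    std::vector<double> best = s;
    for (int it = 0; it < maxIters; ++it) {
      int moveVar = -1;
      double moveDE = R_PosInf;
      for (int i = 0; i < nvars; ++i) {
        const double flip = (s[i] == hi) ? lo - hi : hi - lo;
        const double dE = flip * phi[i];
        const bool isTabu = tabuUntil[i] > it;
        // aspiration: a tabu move is admitted if it beats the best so far
        if (isTabu && !(cur + dE < bestE - 1e-12)) continue;
        if (dE < moveDE) { moveDE = dE; moveVar = i; }
      }
      if (moveVar < 0) break;           // all moves tabu and none aspirates
      const double flip = (s[moveVar] == hi) ? lo - hi : hi - lo;
      s[moveVar] += flip;
      cur += moveDE;
      for (int e = adj.ptr[moveVar]; e < adj.ptr[moveVar + 1]; ++e)
        phi[adj.idx[e]] += adj.w[e] * flip;
      tabuUntil[moveVar] = it + tenure;
      if (cur < bestE - 1e-12) { bestE = cur; best = s; }
    }
    restartBest[restart] = bestE;
    if (bestE < globalBest) { globalBest = bestE; globalBestState = best; }
  }

  int occ = 0;
  for (int r = 0; r < numRestarts; ++r)
    if (restartBest[r] <= globalBest + 1e-9) ++occ;
  return List::create(_["assignment"] = NumericVector(globalBestState.begin(),
                                                      globalBestState.end()),
                      _["energy"] = globalBest,
                      _["occurrencesBest"] = occ);
}
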