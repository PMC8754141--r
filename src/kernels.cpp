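// Nearest-taxon distance kernels.
//
// MNTD and betaMNTD are recomputed hundreds of times per analysis under
// tip-shuffle null models, so the inner loops live here.  A shuffle is
// passed as a 0-based permutation `perm`: taxon column t of the community
// matrix is looked up at row/column perm[t] of the cophenetic matrix, so
// the (large) distance matrix itself is never copied.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct Presence {
  std::vector<std::vector<int> > idx;   // present taxon columns per sample
  std::vector<std::vector<double> > w;  // matching weights, summing to 1
};

Presence build_presence(const NumericMatrix &comm, bool weighted) {
  int n = comm.nrow(), S = comm.ncol();
  Presence p;
  p.idx.resize(n);
  p.w.resize(n);
  for (int k = 0; k < n; ++k) {
    double tot = 0.0;
    for (int t = 0; t < S; ++t) {
      if (comm(k, t) > 0) {
        p.idx[k].push_back(t);
        tot += comm(k, t);
      }
    }
    size_t m = p.idx[k].size();
    p.w[k].resize(m);
    for (size_t u = 0; u < m; ++u) {
      p.w[k][u] = weighted ? comm(k, p.idx[k][u]) / tot : 1.0 / m;
    }
  }
  return p;
}

// betaMNTD for all sample pairs under one permutation.
void beta_mntd_fill(const Presence &p, const NumericMatrix &D,
                    const int *perm, NumericMatrix &out) {
  int n = p.idx.size();
  const double inf = std::numeric_limits<double>::infinity();
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double s1 = 0.0, s2 = 0.0;
      const std::vector<int> &ia = p.idx[a], &ib = p.idx[b];
      const std::vector<double> &wa = p.w[a], &wb = p.w[b];
      for (size_t u = 0; u < ia.size(); ++u) {
        int pi = perm[ia[u]];
        double mn = inf;
        for (size_t v = 0; v < ib.size(); ++v) {
          double d = D(pi, perm[ib[v]]);
          if (d < mn) mn = d;
        }
        s1 += wa[u] * mn;
      }
      for (size_t v = 0; v < ib.size(); ++v) {
        int pj = perm[ib[v]];
        double mn = inf;
        for (size_t u = 0; u < ia.size(); ++u) {
          double d = D(perm[ia[u]], pj);
          if (d < mn) mn = d;
        }
        s2 += wb[v] * mn;
      }
      out(a, b) = out(b, a) = 0.5 * (s1 + s2);
    }
  }
}

// MNTD per sample under one permutation; samples with < 2 present taxa
// are NA.
void mntd_fill(const Presence &p, const NumericMatrix &D,
               const int *perm, NumericVector &out) {
  int n = p.idx.size();
  const double inf = std::numeric_limits<double>::infinity();
  for (int k = 0; k < n; ++k) {
    const std::vector<int> &ik = p.idx[k];
    const std::vector<double> &wk = p.w[k];
    if (ik.size() < 2) {
      out[k] = NA_REAL;
      continue;
    }
    double s = 0.0;
    for (size_t u = 0; u < ik.size(); ++u) {
      int pi = perm[ik[u]];
      double mn = inf;
      for (size_t v = 0; v < ik.size(); ++v) {
        if (v == u) continue;
        double d = D(pi, perm[ik[v]]);
        if (d < mn) mn = d;
      }
      s += wk[u] * mn;
    }
    out[k] = s;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix beta_mntd_pairs_cpp(NumericMatrix comm, NumericMatrix D,
                                  IntegerVector perm, bool weighted) {
  Presence p = build_presence(comm, weighted);
  NumericMatrix out(comm.nrow(), comm.nrow());
  beta_mntd_fill(p, D, INTEGER(perm), out);
  return out;
}

// Observed betaMNTD plus null mean/sd over the permutations in `perms`
// (n_rand x S, 0-based).  Returns matrices obs, null_mean, null_sd.
// [[Rcpp::export]]
List beta_mntd_null_cpp(NumericMatrix comm, NumericMatrix D,
                        IntegerMatrix perms, bool weighted) {
  int n = comm.nrow(), S = comm.ncol(), R = perms.nrow();
  Presence p = build_presence(comm, weighted);
  std::vector<int> ident(S);
  for (int t = 0; t < S; ++t) ident[t] = t;
  NumericMatrix obs(n, n), msum(n, n), msq(n, n), tmp(n, n);
  beta_mntd_fill(p, D, &ident[0], obs);
  std::vector<int> perm(S);
  for (int r = 0; r < R; ++r) {
    for (int t = 0; t < S; ++t) perm[t] = perms(r, t);
    beta_mntd_fill(p, D, &perm[0], tmp);
    for (int a = 0; a < n; ++a)
      for (int b = 0; b < n; ++b) {
        msum(a, b) += tmp(a, b);
        msq(a, b) += tmp(a, b) * tmp(a, b);
      }
    if (r % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix nmean(n, n), nsd(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) {
      double mu = msum(a, b) / R;
      nmean(a, b) = mu;
      double var = (msq(a, b) - R * mu * mu) / (R - 1);
      nsd(a, b) = var > 0 ? std::sqrt(var) : 0.0;
    }
  return List::create(_["obs"] = obs, _["null_mean"] = nmean,
                      _["null_sd"] = nsd);
}

// Observed MNTD plus null mean/sd per sample.
// [[Rcpp::export]]
List mntd_null_cpp(NumericMatrix comm, NumericMatrix D,
                   IntegerMatrix perms, bool weighted) {
  int n = comm.nrow(), S = comm.ncol(), R = perms.nrow();
  Presence p = build_presence(comm, weighted);
  std::vector<int> ident(S);
  for (int t = 0; t < S; ++t) ident[t] = t;
  NumericVector obs(n), tmp(n), msum(n), msq(n);
  mntd_fill(p, D, &ident[0], obs);
  std::vector<int> perm(S);
  for (int r = 0; r < R; ++r) {
    for (int t = 0; t < S; ++t) perm[t] = perms(r, t);
    mntd_fill(p, D, &perm[0], tmp);
    for (int k = 0; k < n; ++k) {
      msum[k] += tmp[k];
      msq[k] += tmp[k] * tmp[k];
    }
    if (r % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector nmean(n), nsd(n);
  for (int k = 0; k < n; ++k) {
    if (NumericVector::is_na(obs[k])) {
      nmean[k] = NA_REAL;
      nsd[k] = NA_REAL;
      continue;
    }
    double mu = msum[k] / R;
    nmean[k] = mu;
    double var = (msq[k] - R * mu * mu) / (R - 1);
    nsd[k] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["obs"] = obs, _["null_mean"] = nmean,
                      _["null_sd"] = nsd);
}

// [[Rcpp::export]]
NumericVector mntd_samples_cpp(NumericMatrix comm, NumericMatrix D,
                               IntegerVector perm, bool weighted) {
  Presence p = build_presence(comm, weighted);
  NumericVector out(comm.nrow());
  mntd_fill(p, D, INTEGER(perm), out);
  return out;
}
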