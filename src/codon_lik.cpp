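#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-site log-likelihood of a codon alignment on a rooted tree by
// Felsenstein pruning, with per-branch-class transition matrices built from
// the spectral decomposition of each class's (reversible) rate matrix.
//
// edge        postorder edge matrix (parent, child), 1-based ape node ids
//             (tips are 1..ntip); children always appear before their parent
// edge_class  1-based index into V/Vinv/lambda per edge
// V, Vinv     per-class 61x61 matrices with Q = V diag(lambda) Vinv
// tipstate    ntip x npat integer matrix, 1-based codon state, NA = missing
// pi          61 root (stationary) frequencies
//
// Missing tip states integrate over all 61 codons (a row of P sums to 1, so
// the tip contributes a factor of 1 and is skipped). Partial likelihoods are
// rescaled per site at every internal-node combination step to avoid
// underflow on deep trees.

static const int NS = 61;

// P (61x61, col-major [i + 61 j]) = M (col-major [i + 61 k]) * W (col-major
// [k + 61 j]); k-unrolled by 4 for register reuse.
static void gemm61x61(const double *__restrict M, const double *__restrict W,
                      double *__restrict P) {
  for (int j = 0; j < NS; ++j) {
    double *__restrict Pj = P + NS * j;
    for (int i = 0; i < NS; ++i) Pj[i] = 0.0;
    const double *Wj = W + NS * j;
    int k = 0;
    for (; k + 4 <= NS; k += 4) {
      const double w0 = Wj[k], w1 = Wj[k + 1], w2 = Wj[k + 2], w3 = Wj[k + 3];
      const double *M0 = M + NS * k, *M1 = M0 + NS, *M2 = M1 + NS, *M3 = M2 + NS;
      for (int i = 0; i < NS; ++i)
        Pj[i] += M0[i] * w0 + M1[i] * w1 + M2[i] * w2 + M3[i] * w3;
    }
    for (; k < NS; ++k) {
      const double w = Wj[k];
      const double *Mk = M + NS * k;
      for (int i = 0; i < NS; ++i) Pj[i] += Mk[i] * w;
    }
  }
}

// contrib (site-major [s + npat i]) = P (col-major [i + 61 j]) x cp
// (site-major [s + npat j]); j-unrolled by 4.
static void prop61(const double *__restrict P, const double *__restrict cp,
                   double *__restrict out, int npat) {
  for (int i = 0; i < NS; ++i) {
    double *__restrict ci = out + (size_t)npat * i;
    for (int s = 0; s < npat; ++s) ci[s] = 0.0;
    int j = 0;
    for (; j + 4 <= NS; j += 4) {
      const double p0 = P[i + NS * j], p1 = P[i + NS * (j + 1)];
      const double p2 = P[i + NS * (j + 2)], p3 = P[i + NS * (j + 3)];
      const double *c0 = cp + (size_t)npat * j, *c1 = c0 + npat,
                   *c2 = c1 + npat, *c3 = c2 + npat;
      for (int s = 0; s < npat; ++s)
        ci[s] += p0 * c0[s] + p1 * c1[s] + p2 * c2[s] + p3 * c3[s];
    }
    for (; j < NS; ++j) {
      const double pj = P[i + NS * j];
      const double *cj = cp + (size_t)npat * j;
      for (int s = 0; s < npat; ++s) ci[s] += pj * cj[s];
    }
  }
}

static void build_P(const NumericMatrix &Vc, const NumericMatrix &Wc,
                    const NumericVector &lam, double t,
                    std::vector<double> &M, std::vector<double> &Pe) {
  for (int k = 0; k < NS; ++k) {
    const double w = std::exp(lam[k] * t);
    for (int i = 0; i < NS; ++i) M[i + NS * k] = Vc(i, k) * w;
  }
  gemm61x61(&M[0], &Wc(0, 0), &Pe[0]);
  for (int q = 0; q < NS * NS; ++q) if (Pe[q] < 0.0) Pe[q] = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_codon_site_loglik(IntegerMatrix edge, int ntip, int nnode,
                                    IntegerVector edge_class,
                                    NumericVector edge_len,
                                    List V, List Vinv, List lambda,
                                    IntegerMatrix tipstate, NumericVector pi) {
  const int ns = NS;
  const int nedge = edge.nrow();
  const int npat = tipstate.ncol();

  // ---- transition matrices, column-major P[i + ns*j] = P(i -> j) ----------
  std::vector<std::vector<double> > P(nedge);
  std::vector<double> M(ns * ns);
  for (int e = 0; e < nedge; ++e) {
    const int cls = edge_class[e] - 1;
    NumericMatrix Vc = V[cls];
    NumericMatrix Wc = Vinv[cls];
    NumericVector lam = lambda[cls];
    P[e].assign(ns * ns, 0.0);
    build_P(Vc, Wc, lam, edge_len[e], M, P[e]);
  }

  // ---- pruning ------------------------------------------------------------
  // partials stored site-major: part[node][s + npat*i]
  std::vector<std::vector<double> > part(nnode);
  std::vector<std::vector<double> > lsc(nnode);
  std::vector<double> contrib(ns * npat);
  std::vector<int> sts(npat);

  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1;
    const int ch = edge(e, 1) - 1;
    if (part[p].empty()) {
      part[p].assign(ns * npat, 1.0);
      lsc[p].assign(npat, 0.0);
    }
    const std::vector<double> &Pe = P[e];
    std::vector<double> &pp = part[p];
    if (ch < ntip) {
      for (int s = 0; s < npat; ++s) {
        int st = tipstate(ch, s);
        sts[s] = (st == NA_INTEGER) ? -1 : st - 1;
      }
      for (int i = 0; i < ns; ++i) {
        double *row = &pp[(size_t)npat * i];
        for (int s = 0; s < npat; ++s) {
          if (sts[s] < 0) continue;  // missing: sum_j P(i,j) = 1
          row[s] *= Pe[i + ns * sts[s]];
        }
      }
    } else {
      const std::vector<double> &cp = part[ch];
      prop61(&Pe[0], &cp[0], &contrib[0], npat);
      // per-site rescale, fold child's log-scale into parent's
      for (int s = 0; s < npat; ++s) {
        double m = 0.0;
        for (int i = 0; i < ns; ++i) {
          const double v = contrib[s + (size_t)npat * i];
          if (v > m) m = v;
        }
        if (m <= 0.0) m = 1.0;  // impossible site; keep finite, yields -Inf later
        const double inv = 1.0 / m;
        for (int i = 0; i < ns; ++i) {
          pp[s + (size_t)npat * i] *= contrib[s + (size_t)npat * i] * inv;
        }
        lsc[p][s] += lsc[ch][s] + std::log(m);
      }
      part[ch].clear();
    }
  }

  const int root = edge(nedge - 1, 0) - 1;
  NumericVector out(npat);
  const std::vector<double> &rp = part[root];
  for (int s = 0; s < npat; ++s) {
    double tot = 0.0;
    for (int i = 0; i < ns; ++i) tot += pi[i] * rp[s + (size_t)npat * i];
    out[s] = std::log(tot) + lsc[root][s];
  }
  return out;
}

// Simulate codon states down a tree: given per-edge transition matrices
// (same spectral inputs as above), draw each child's states from its
// parent's. Returns nnode x nsite matrix of 1-based states; tips occupy
// rows 1..ntip. Uniform random numbers are supplied from R so that all
// randomness flows through R's RNG/seed.

// [[Rcpp::export]]
IntegerMatrix cpp_sim_codon_states(IntegerMatrix edge, int ntip, int nnode,
                                   IntegerVector edge_class,
                                   NumericVector edge_len,
                                   List V, List Vinv, List lambda,
                                   IntegerVector root_state,
                                   NumericVector unif) {
  const int ns = 61;
  const int nedge = edge.nrow();
  const int nsite = root_state.size();
  IntegerMatrix states(nnode, nsite);
  const int root = edge(nedge - 1, 0) - 1;
  for (int s = 0; s < nsite; ++s) states(root, s) = root_state[s];

  std::vector<double> Pe(ns * ns), M(ns * ns);
  size_t u = 0;
  // preorder = reverse postorder
  for (int e = nedge - 1; e >= 0; --e) {
    const int cls = edge_class[e] - 1;
    NumericMatrix Vc = V[cls];
    NumericMatrix Wc = Vinv[cls];
    NumericVector lam = lambda[cls];
    build_P(Vc, Wc, lam, edge_len[e], M, Pe);

    const int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    for (int s = 0; s < nsite; ++s) {
      const int ps = states(p, s) - 1;
      // row ps of P: entries Pe[ps + ns*j]
      double rowsum = 0.0;
      for (int j = 0; j < ns; ++j) rowsum += Pe[ps + ns * j];
      double target = unif[u++] * rowsum, acc = 0.0;
      int drawn = ns - 1;
      for (int j = 0; j < ns; ++j) {
        acc += Pe[ps + ns * j];
        if (acc >= target) { drawn = j; break; }
      }
      states(ch, s) = drawn + 1;
    }
  }
  return states;
}
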