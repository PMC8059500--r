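#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-deme structured coalescent, backward in time, in units of generations
// with diploid effective sizes: a pair of lineages in deme i coalesces at
// rate 1/(2*N_i) per generation; migration epochs give per-lineage backward
// rates m12 (deme 1 -> deme 2) and m21. At t = Tsplit all lineages merge
// into the ancestral deme of size Nanc. Exponential waiting times are
// re-drawn at every rate boundary (memoryless, so re-draw is exact).
//
// All randomness goes through R's RNG (unif_rand / exp_rand / R::rpois) so
// results are reproducible under set.seed().

struct Epoch {
  double t0, t1, m12, m21;
};

struct Genealogy {
  std::vector<double> time;   // node times, leaves first (time 0)
  std::vector<int> parent;    // parent node index, -1 for root
  std::vector<int> deme;      // deme of leaf / deme where coalescence happened
  int n1, n2;
};

static void sim_one(int n1, int n2, double N1, double N2, double Nanc,
                    double Tsplit, const std::vector<Epoch> &eps,
                    Genealogy &g) {
  const int n = n1 + n2;
  const int nnode = 2 * n - 1;
  g.n1 = n1; g.n2 = n2;
  g.time.assign(nnode, 0.0);
  g.parent.assign(nnode, -1);
  g.deme.assign(nnode, -1);

  std::vector<int> lid(n), ldeme(n);
  for (int i = 0; i < n; ++i) {
    lid[i] = i;
    ldeme[i] = (i < n1) ? 0 : 1;
    g.deme[i] = ldeme[i];
  }

  double t = 0.0;
  bool merged = false;
  if (Tsplit <= 0.0) {
    merged = true;
    for (int i = 0; i < n; ++i) ldeme[i] = 0;
  }
  int nextnode = n;
  int nlin = n;
  long guard = 0;
  const long guard_max = 100000000L;

  while (nlin > 1) {
    if (++guard > guard_max) stop("coalescent event loop exceeded guard");
    int k0 = 0;
    for (int i = 0; i < nlin; ++i) if (ldeme[i] == 0) ++k0;
    int k1 = nlin - k0;

    double m12 = 0.0, m21 = 0.0;
    double nb = merged ? R_PosInf : Tsplit;  // next rate boundary
    if (!merged) {
      for (size_t e = 0; e < eps.size(); ++e) {
        if (t >= eps[e].t0 && t < eps[e].t1) {
          m12 += eps[e].m12;
          m21 += eps[e].m21;
          if (eps[e].t1 < nb) nb = eps[e].t1;
        } else if (t < eps[e].t0 && eps[e].t0 < nb) {
          nb = eps[e].t0;
        }
      }
    }

    double rc0, rc1;
    if (merged) {
      rc0 = k0 * (k0 - 1.0) / 2.0 / (2.0 * Nanc);
      rc1 = 0.0;
    } else {
      rc0 = k0 * (k0 - 1.0) / 2.0 / (2.0 * N1);
      rc1 = k1 * (k1 - 1.0) / 2.0 / (2.0 * N2);
    }
    double rm0 = merged ? 0.0 : k0 * m12;
    double rm1 = merged ? 0.0 : k1 * m21;
    double rtot = rc0 + rc1 + rm0 + rm1;

    if (rtot <= 0.0) {
      // nothing can happen in this interval; jump to next boundary
      t = nb;
      if (!merged && t >= Tsplit) {
        merged = true;
        for (int i = 0; i < nlin; ++i) ldeme[i] = 0;
      }
      continue;
    }

    double dt = exp_rand() / rtot;
    if (!merged && t + dt >= nb) {
      t = nb;
      if (t >= Tsplit) {
        merged = true;
        for (int i = 0; i < nlin; ++i) ldeme[i] = 0;
      }
      continue;
    }
    t += dt;

    double u = unif_rand() * rtot;
    if (u < rc0 + rc1) {
      int d = (u < rc0) ? 0 : 1;
      int kd = (d == 0) ? k0 : k1;
      // choose an unordered pair uniformly within deme d
      int a = (int)std::floor(unif_rand() * kd);
      if (a >= kd) a = kd - 1;
      int b = (int)std::floor(unif_rand() * (kd - 1));
      if (b >= kd - 1) b = kd - 2;
      if (b >= a) ++b;
      // map within-deme indices to lineage slots
      int ia = -1, ib = -1, seen = 0;
      for (int i = 0; i < nlin; ++i) {
        if (ldeme[i] == d) {
          if (seen == a) ia = i;
          if (seen == b) ib = i;
          ++seen;
        }
      }
      int node = nextnode++;
      g.time[node] = t;
      g.deme[node] = merged ? 2 : d;
      g.parent[lid[ia]] = node;
      g.parent[lid[ib]] = node;
      // replace ia by the new node, drop ib
      lid[ia] = node;
      ldeme[ia] = d;
      lid[ib] = lid[nlin - 1];
      ldeme[ib] = ldeme[nlin - 1];
      --nlin;
    } else if (u < rc0 + rc1 + rm0) {
      int a = (int)std::floor(unif_rand() * k0);
      if (a >= k0) a = k0 - 1;
      int seen = 0;
      for (int i = 0; i < nlin; ++i) {
        if (ldeme[i] == 0) {
          if (seen == a) { ldeme[i] = 1; break; }
          ++seen;
        }
      }
    } else {
      int a = (int)std::floor(unif_rand() * k1);
      if (a >= k1) a = k1 - 1;
      int seen = 0;
      for (int i = 0; i < nlin; ++i) {
        if (ldeme[i] == 1) {
          if (seen == a) { ldeme[i] = 0; break; }
          ++seen;
        }
      }
    }
  }
}

static std::vector<Epoch> parse_epochs(const NumericMatrix &epochs) {
  std::vector<Epoch> eps;
  for (int i = 0; i < epochs.nrow(); ++i) {
    Epoch e;
    e.t0 = epochs(i, 0); e.t1 = epochs(i, 1);
    e.m12 = epochs(i, 2); e.m21 = epochs(i, 3);
    if (e.m12 > 0.0 || e.m21 > 0.0) eps.push_back(e);  // zero-rate epochs are no-ops
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_sim_genealogy(int n1, int n2, double N1, double N2, double Nanc,
                       double Tsplit, NumericMatrix epochs) {
  std::vector<Epoch> eps = parse_epochs(epochs);
  Genealogy g;
  sim_one(n1, n2, N1, N2, Nanc, Tsplit, eps, g);
  int nnode = 2 * (n1 + n2) - 1;
  IntegerVector parent(nnode);
  for (int i = 0; i < nnode; ++i)
    parent[i] = (g.parent[i] < 0) ? NA_INTEGER : g.parent[i] + 1;  // 1-based
  return List::create(_["time"] = NumericVector(g.time.begin(), g.time.end()),
                      _["parent"] = parent,
                      _["deme"] = IntegerVector(g.deme.begin(), g.deme.end()),
                      _["n1"] = n1, _["n2"] = n2);
}

// leaf counts (per deme) subtended by every node; children always have a
// smaller index than their parent, so one increasing pass suffices
static void leaf_counts(const Genealogy &g, std::vector<int> &d1,
                        std::vector<int> &d2) {
  int nnode = (int)g.time.size();
  int n = g.n1 + g.n2;
  d1.assign(nnode, 0);
  d2.assign(nnode, 0);
  for (int i = 0; i < n; ++i) {
    if (i < g.n1) d1[i] = 1; else d2[i] = 1;
  }
  for (int v = 0; v < nnode; ++v) {
    if (g.parent[v] >= 0) {
      d1[g.parent[v]] += d1[v];
      d2[g.parent[v]] += d2[v];
    }
  }
}

// drop infinite-sites mutations on one genealogy; accumulate joint SFS
static void drop_into_sfs(const Genealogy &g, double mu, double L,
                          NumericMatrix &sfs) {
  int nnode = (int)g.time.size();
  std::vector<int> d1, d2;
  leaf_counts(g, d1, d2);
  std::vector<double> blen(nnode, 0.0);
  double tot = 0.0;
  for (int v = 0; v < nnode; ++v) {
    if (g.parent[v] >= 0) {
      blen[v] = g.time[g.parent[v]] - g.time[v];
      tot += blen[v];
    }
  }
  if (tot <= 0.0 || mu <= 0.0 || L <= 0.0) return;
  int nm = (int)R::rpois(mu * L * tot);
  for (int m = 0; m < nm; ++m) {
    double x = unif_rand() * tot;
    double acc = 0.0;
    int v = 0;
    for (; v < nnode - 1; ++v) {
      acc += blen[v];
      if (x <= acc && blen[v] > 0.0) break;
    }
    if (v >= nnode - 1) v = nnode - 2;  // float-edge guard
    sfs(d1[v], d2[v]) += 1.0;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_drop_mutations(int n1, int n2, NumericVector time,
                                 IntegerVector parent, double mu, double L) {
  Genealogy g;
  g.n1 = n1; g.n2 = n2;
  int nnode = time.size();
  g.time.assign(time.begin(), time.end());
  g.parent.assign(nnode, -1);
  for (int i = 0; i < nnode; ++i)
    if (parent[i] != NA_INTEGER) g.parent[i] = parent[i] - 1;
  g.deme.assign(nnode, -1);
  for (int i = 0; i < n1 + n2; ++i) g.deme[i] = (i < n1) ? 0 : 1;

  std::vector<int> d1, d2;
  leaf_counts(g, d1, d2);
  std::vector<double> blen(nnode, 0.0);
  double tot = 0.0;
  for (int v = 0; v < nnode; ++v) {
    if (g.parent[v] >= 0) {
      blen[v] = g.time[g.parent[v]] - g.time[v];
      tot += blen[v];
    }
  }
  int nm = (tot > 0.0 && mu > 0.0 && L > 0.0) ? (int)R::rpois(mu * L * tot) : 0;
  IntegerMatrix out(nm, 3);  // deme-1 count, deme-2 count, branch (1-based)
  for (int m = 0; m < nm; ++m) {
    double x = unif_rand() * tot;
    double acc = 0.0;
    int v = 0;
    for (; v < nnode - 1; ++v) {
      acc += blen[v];
      if (x <= acc && blen[v] > 0.0) break;
    }
    if (v >= nnode - 1) v = nnode - 2;
    out(m, 0) = d1[v];
    out(m, 1) = d2[v];
    out(m, 2) = v + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sim_joint_sfs(int n1, int n2, double N1, double N2,
                                double Nanc, double Tsplit,
                                NumericMatrix epochs, double mu, double L,
                                int n_loci) {
  std::vector<Epoch> eps = parse_epochs(epochs);
  NumericMatrix sfs(n1 + 1, n2 + 1);
  Genealogy g;
  for (int l = 0; l < n_loci; ++l) {
    sim_one(n1, n2, N1, N2, Nanc, Tsplit, eps, g);
    drop_into_sfs(g, mu, L, sfs);
  }
  return sfs;
}
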