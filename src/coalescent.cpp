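#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Serial (heterochronous) coalescent for the two-deme cattle domestication
// model, haploid (mtDNA, female) scaling: a pair of lineages in a deme of
// size N(t) coalesces at instantaneous rate 1/N(t).
//
// Backward time t is measured in generations before present.  Demes:
//   0 = NE (Near East/Anatolia): N(t) = N_NE_mod * exp(-r_NE t) for t < T_dom,
//       N_anc for t >= T_dom, with r_NE = log(N_NE_mod/N_D)/T_dom.
//   1 = EU (Europe), exists only for t < T_split:
//       N(t) = N_E_mod * exp(-r_E t), r_E = log(N_E_mod/N_E0)/T_split,
//       N_E0 = P * N_NE(T_split).
// Symmetric per-lineage migration at rate M_L on [0,T_mig), M_E on
// [T_mig,T_split), 0 afterwards.  At T_split all EU lineages join NE.
//
// Exponential-size epochs are integrated by closed-form time rescaling:
// with N(s) = A exp(-r s) and k2 = k(k-1)/2 the waiting time w from t0
// solves (k2/(A r)) (exp(r(t0+w)) - exp(r t0)) = E, E ~ Exp(1).

static double coal_wait(double t0, double A, double r, double k2, double E) {
  if (k2 <= 0.0) return R_PosInf;
  if (std::fabs(r) < 1e-14) return A * E / k2;
  double x = std::exp(r * t0) + A * r * E / k2;
  if (x <= 0.0) return R_PosInf;
  return std::log(x) / r - t0;
}

struct SimState {
  std::vector<int> parent;
  std::vector<double> time;
  std::vector<int> lchild, rchild;
};

// [[Rcpp::export(name = ".sim_serial_cpp")]]
List sim_serial_cpp(NumericVector sample_time, IntegerVector sample_deme,
                    double N_anc, double N_NE_mod, double N_E_mod,
                    double N_D, double P, double mig_early, double mig_late,
                    double T_dom, double T_split, double T_mig,
                    int seed) {
  const int n = sample_time.size();
  if (n < 1) stop("need at least one sample");
  for (int i = 0; i < n; ++i) {
    if (sample_deme[i] == 1 && sample_time[i] >= T_split)
      stop("EU sample at or before the split time");
    if (sample_time[i] < 0) stop("negative sampling time");
  }
  if (P <= 0.0) {
    bool any_eu = false;
    for (int i = 0; i < n; ++i) if (sample_deme[i] == 1) any_eu = true;
    if (any_eu) stop("P = 0 with EU samples: empty founder population");
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 1442695040888963407ULL);
  std::exponential_distribution<double> rexp1(1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  const double r_NE = std::log(N_NE_mod / N_D) / T_dom;
  const double N_NE_split = N_NE_mod * std::exp(-r_NE * T_split);
  const double N_E0 = P * N_NE_split;
  const double r_E = std::log(N_E_mod / N_E0) / T_split;

  const int n_nodes = 2 * n - 1;
  SimState st;
  st.parent.assign(n_nodes, -1);
  st.time.assign(n_nodes, 0.0);
  st.lchild.assign(n_nodes, -1);
  st.rchild.assign(n_nodes, -1);

  // samples sorted by time (stable so output keeps caller order via ids)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) { ord[i] = i; st.time[i] = sample_time[i]; }
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return sample_time[a] < sample_time[b];
  });

  std::vector<int> act_ne, act_eu;
  size_t next_samp = 0;
  int next_node = n;
  double t = sample_time[ord[0]];

  auto activate = [&](double upto) {
    while (next_samp < ord.size() && sample_time[ord[next_samp]] <= upto + 1e-12) {
      int id = ord[next_samp++];
      if (sample_deme[id] == 0) act_ne.push_back(id); else act_eu.push_back(id);
    }
  };
  activate(t);

  while (next_samp < ord.size() || (int)(act_ne.size() + act_eu.size()) > 1) {
    // segment end: next sampling time or next model breakpoint
    double seg_end = R_PosInf;
    if (next_samp < ord.size()) seg_end = sample_time[ord[next_samp]];
    for (double b : {T_mig, T_split, T_dom})
      if (b > t + 1e-12 && b < seg_end) seg_end = b;

    double kne = (double)act_ne.size(), keu = (double)act_eu.size();
    double k2_ne = kne * (kne - 1.0) / 2.0, k2_eu = keu * (keu - 1.0) / 2.0;

    // epoch-constant parameters at current t
    double A_ne = (t >= T_dom) ? N_anc : N_NE_mod;
    double rr_ne = (t >= T_dom) ? 0.0 : r_NE;
    double mig = 0.0;
    if (t < T_mig) mig = mig_late;
    else if (t < T_split) mig = mig_early;

    double w_ne = (k2_ne > 0) ? coal_wait(t, A_ne, rr_ne, k2_ne, rexp1(rng)) : R_PosInf;
    double w_eu = (k2_eu > 0 && t < T_split)
      ? coal_wait(t, N_E_mod, r_E, k2_eu, rexp1(rng)) : R_PosInf;
    double mig_tot = mig * (kne + keu);
    double w_mig = (mig_tot > 0 && t < T_split) ? rexp1(rng) / mig_tot : R_PosInf;

    double w = std::min({w_ne, w_eu, w_mig});
    if (t + w >= seg_end) {
      t = seg_end;
      if (std::fabs(t - T_split) < 1e-9) {        // merge demes backward
        for (int id : act_eu) act_ne.push_back(id);
        act_eu.clear();
      }
      activate(t);
      continue;
    }
    t += w;
    if (w == w_mig) {
      int k = (int)(runif01(rng) * (kne + keu));
      if (k >= (int)(kne + keu)) k = (int)(kne + keu) - 1;
      if (k < (int)kne) {
        act_eu.push_back(act_ne[k]);
        act_ne.erase(act_ne.begin() + k);
      } else {
        int j = k - (int)kne;
        act_ne.push_back(act_eu[j]);
        act_eu.erase(act_eu.begin() + j);
      }
    } else {
      std::vector<int>& deme = (w == w_ne) ? act_ne : act_eu;
      int i = (int)(runif01(rng) * deme.size());
      int j = (int)(runif01(rng) * (deme.size() - 1));
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      int a = deme[i], b = deme[j];
      int node = next_node++;
      st.time[node] = t;
      st.lchild[node] = a; st.rchild[node] = b;
      st.parent[a] = node; st.parent[b] = node;
      deme.erase(deme.begin() + j);
      deme[i] = node;
    }
  }

  double tbl = 0.0;
  for (int i = 0; i < n_nodes - 1; ++i)
    if (st.parent[i] >= 0) tbl += st.time[st.parent[i]] - st.time[i];

  return List::create(
    _["parent"] = IntegerVector(st.parent.begin(), st.parent.end()),
    _["time"] = NumericVector(st.time.begin(), st.time.end()),
    _["lchild"] = IntegerVector(st.lchild.begin(), st.lchild.end()),
    _["rchild"] = IntegerVector(st.rchild.begin(), st.rchild.end()),
    _["n_tips"] = n,
    _["total_branch_length"] = tbl,
    _["tmrca"] = (n_nodes > 0) ? st.time[n_nodes - 1] - *std::min_element(st.time.begin(), st.time.begin() + n) : 0.0,
    _["root_time"] = st.time[n_nodes - 1]);
}

// Finite-sites mutation on a genealogy: Poisson number of hits per branch at
// rate mu_site * L per generation; each hit picks a uniform site and changes
// the base to a uniform different base; root sequence uniform random.
// [[Rcpp::export(name = ".mutate_tree_cpp")]]
IntegerMatrix mutate_tree_cpp(IntegerVector parent, NumericVector node_time,
                              int n_tips, int L, double mu_site, int seed) {
  const int n_nodes = parent.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 12345u);
  std::uniform_int_distribution<int> rbase(0, 3);
  std::uniform_int_distribution<int> rsite(0, L - 1);
  std::uniform_int_distribution<int> rshift(1, 3);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  // process parents before children: sort node ids by decreasing time
  std::vector<int> ord(n_nodes);
  for (int i = 0; i < n_nodes; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return node_time[a] > node_time[b];
  });

  std::vector<std::vector<int> > seq(n_nodes);
  int root = n_nodes - 1;
  seq[root].resize(L);
  for (int s = 0; s < L; ++s) seq[root][s] = rbase(rng);

  for (int id : ord) {
    if (id == root) continue;
    int pa = parent[id];
    double blen = node_time[pa] - node_time[id];
    seq[id] = seq[pa];
    double lam = blen * mu_site * (double)L;
    std::poisson_distribution<int> rpois(lam);
    int nmut = (lam > 0) ? rpois(rng) : 0;
    for (int m = 0; m < nmut; ++m) {
      int s = rsite(rng);
      seq[id][s] = (seq[id][s] + rshift(rng)) % 4;
    }
    if (pa != root && seq[pa].empty())
      stop("internal: parent sequence not yet assigned");
  }

  IntegerMatrix out(n_tips, L);
  for (int i = 0; i < n_tips; ++i)
    for (int s = 0; s < L; ++s) out(i, s) = seq[i][s];
  return out;
}

// Constant-size neutral coalescent null (infinite sites), coalescent time
// units (pair coalescence rate 1), mutation rate theta/2 per lineage:
// returns per replicate S (segregating sites), pi (mean pairwise
// differences) and K (number of distinct haplotypes).
// [[Rcpp::export(name = ".sim_null_cpp")]]
NumericMatrix sim_null_cpp(int n, double theta, int reps, int seed) {
  if (n < 2) stop("n >= 2 required");
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1u);
  std::exponential_distribution<double> rexp1(1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  NumericMatrix out(reps, 3);
  const double npairs = n * (n - 1) / 2.0;
  std::vector<int> active(n), ndesc(2 * n - 1);
  std::vector<double> tnode(2 * n - 1), sig(2 * n - 1);
  std::vector<int> par(2 * n - 1), nmut(2 * n - 1);

  for (int rep = 0; rep < reps; ++rep) {
    active.resize(n);
    for (int i = 0; i < n; ++i) active[i] = i;
    std::fill(ndesc.begin(), ndesc.end(), 0);
    std::fill(par.begin(), par.end(), -1);
    for (int i = 0; i < n; ++i) ndesc[i] = 1;
    std::fill(tnode.begin(), tnode.end(), 0.0);
    double t = 0.0;
    int next_node = n;
    for (int k = n; k >= 2; --k) {
      t += rexp1(rng) / (k * (k - 1) / 2.0);
      int i = (int)(runif01(rng) * k);
      int j = (int)(runif01(rng) * (k - 1));
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      int a = active[i], b = active[j];
      int node = next_node++;
      tnode[node] = t;
      par[a] = node; par[b] = node;
      ndesc[node] = ndesc[a] + ndesc[b];
      active.erase(active.begin() + j);
      active[i] = node;
    }
    // mutations per branch
    int S = 0;
    double pisum = 0.0;
    for (int v = 0; v < 2 * n - 1; ++v) { nmut[v] = 0; sig[v] = 0.0; }
    for (int v = 0; v < 2 * n - 2; ++v) {
      double blen = tnode[par[v]] - tnode[v];
      double lam = blen * theta / 2.0;
      std::poisson_distribution<int> rpois(lam);
      int m = (lam > 0) ? rpois(rng) : 0;
      if (m > 0) {
        nmut[v] = m;
        S += m;
        pisum += (double)m * ndesc[v] * (n - ndesc[v]);
        sig[v] = runif01(rng) * m;  // random branch tag scaled by hit count
      }
    }
    // tip signatures: sum of tags on root path; distinct values = haplotypes
    // (parents have larger ids than children under this construction)
    std::vector<double> acc(2 * n - 1, 0.0);
    for (int v = 2 * n - 3; v >= 0; --v) acc[v] = acc[par[v]] + (nmut[v] > 0 ? sig[v] : 0.0);
    std::vector<double> tips(acc.begin(), acc.begin() + n);
    std::sort(tips.begin(), tips.end());
    int K = 1;
    for (int i = 1; i < n; ++i) if (tips[i] != tips[i - 1]) ++K;
    out(rep, 0) = S;
    out(rep, 1) = pisum / npairs;
    out(rep, 2) = K;
  }
  colnames(out) = CharacterVector::create("S", "pi", "K");
  return out;
}

// Pairwise difference counts with pairwise deletion (codes: 0..3 bases,
// negative = missing/gap).
// [[Rcpp::export(name = ".pair_diff_cpp")]]
IntegerMatrix pair_diff_cpp(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int nd = 0;
      for (int s = 0; s < L; ++s) {
        int a = seqs(i, s), b = seqs(j, s);
        if (a >= 0 && b >= 0 && a != b) ++nd;
      }
      d(i, j) = nd; d(j, i) = nd;
    }
  }
  return d;
}

// log |Stirling numbers of the first kind| for row n: log|s(n,k)|, k=1..n.
// [[Rcpp::export(name = ".log_stirling1_row_cpp")]]
NumericVector log_stirling1_row_cpp(int n) {
  if (n < 1) stop("n >= 1 required");
  std::vector<double> prev(n + 2, R_NegInf), cur(n + 2, R_NegInf);
  prev[1] = 0.0;  // |s(1,1)| = 1
  for (int m = 1; m < n; ++m) {
    double lm = std::log((double)m);
    for (int k = 1; k <= m + 1; ++k) {
      double a = (k <= m) ? lm + prev[k] : R_NegInf;   // m * |s(m,k)|
      double b = prev[k - 1];                          // |s(m,k-1)|
      double hi = std::max(a, b);
      cur[k] = (hi == R_NegInf) ? R_NegInf
        : hi + std::log(std::exp(a - hi) + std::exp(b - hi));
    }
    std::copy(cur.begin(), cur.end(), prev.begin());
    std::fill(cur.begin(), cur.end(), R_NegInf);
  }
  NumericVector out(n);
  for (int k = 1; k <= n; ++k) out[k - 1] = prev[k];
  return out;
}
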