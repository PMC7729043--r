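// Simulation core: signed coevolving network with Metropolis dynamics on the
// social-stress Hamiltonian
//   H = - sum_(i,j) J_ij s_i s_j - g * sum_(i,j,k) J_ij J_jk J_ki
//       + (h/2) * sum_(i,j) (1 - J_ij)
// Pair sums run over each linked pair once, the triangle sum over each closed
// triangle once. All stochastic routines draw from R's RNG so that results
// are reproducible via set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <functional>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct SimState {
  int n;
  double g, h;
  // adjacency: parallel vectors of neighbour ids (0-based) and link signs
  std::vector<std::vector<int>> nbr;
  std::vector<std::vector<int>> sg;
  // edge registry with O(1) swap-delete; one row per undirected link
  std::vector<int> eu, ev, es;
  std::vector<int> s;      // opinions, +1/-1
  double H;                // maintained incrementally
  long stot;               // sum of opinions
  long tri_total;          // number of closed triangles
  long tri_unbal;          // number of unbalanced triangles (sign product -1)
  long neg_links;

  void init(int n_, const IntegerMatrix& edges, const IntegerVector& signs,
            const IntegerVector& opinions, double g_, double h_) {
    n = n_; g = g_; h = h_;
    nbr.assign(n, {});
    sg.assign(n, {});
    int m = edges.nrow();
    eu.resize(m); ev.resize(m); es.resize(m);
    for (int e = 0; e < m; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1, J = signs[e];
      if (a < 0 || b < 0 || a >= n || b >= n || a == b)
        stop("invalid edge endpoints");
      if (J != 1 && J != -1) stop("link signs must be -1 or +1");
      eu[e] = a; ev[e] = b; es[e] = J;
      nbr[a].push_back(b); sg[a].push_back(J);
      nbr[b].push_back(a); sg[b].push_back(J);
    }
    s.assign(opinions.begin(), opinions.end());
    for (int i = 0; i < n; ++i)
      if (s[i] != 1 && s[i] != -1) stop("opinions must be -1 or +1");
    recompute();
  }

  int sign_of(int a, int b) const {
    const std::vector<int>& na = nbr[a];
    for (size_t q = 0; q < na.size(); ++q)
      if (na[q] == b) return sg[a][q];
    return 0;  // unlinked
  }

  bool adjacent(int a, int b) const {
    const std::vector<int>& na = (nbr[a].size() <= nbr[b].size()) ? nbr[a] : nbr[b];
    int other = (nbr[a].size() <= nbr[b].size()) ? b : a;
    for (size_t q = 0; q < na.size(); ++q)
      if (na[q] == other) return true;
    return false;
  }

  // sum over common neighbours c of J_ac * J_bc, plus their count
  void common(int a, int b, long& csum, long& ncom) const {
    csum = 0; ncom = 0;
    const std::vector<int>& na = nbr[a];
    const std::vector<int>& sa = sg[a];
    for (size_t q = 0; q < na.size(); ++q) {
      int c = na[q];
      if (c == b) continue;
      int Jbc = sign_of(b, c);
      if (Jbc != 0) { csum += (long)sa[q] * Jbc; ++ncom; }
    }
  }

  // full recomputation of H, opinion sum, triangle census, negative links
  void recompute() {
    double Hed = 0.0, Htri = 0.0, Hh = 0.0;
    stot = 0; tri_total = 0; tri_unbal = 0; neg_links = 0;
    for (int i = 0; i < n; ++i) stot += s[i];
    for (size_t e = 0; e < eu.size(); ++e) {
      int a = eu[e], b = ev[e], J = es[e];
      Hed -= (double)J * s[a] * s[b];
      Hh  += 0.5 * h * (1.0 - J);
      if (J < 0) ++neg_links;
      // triangles counted once via the edge between their two smallest nodes
      int hi = std::max(a, b);
      const std::vector<int>& na = nbr[a];
      const std::vector<int>& sa = sg[a];
      for (size_t q = 0; q < na.size(); ++q) {
        int c = na[q];
        if (c <= hi) continue;
        int Jbc = sign_of(b, c);
        if (Jbc == 0) continue;
        int prod = J * sa[q] * Jbc;
        Htri -= g * prod;
        ++tri_total;
        if (prod < 0) ++tri_unbal;
      }
    }
    H = Hed + Htri + Hh;
  }

  double delta_opinion(int i) const {
    double acc = 0.0;
    const std::vector<int>& ni = nbr[i];
    const std::vector<int>& si = sg[i];
    for (size_t q = 0; q < ni.size(); ++q) acc += (double)si[q] * s[ni[q]];
    return 2.0 * s[i] * acc;
  }

  void flip_opinion(int i, double d) {
    H += d;
    stot -= 2L * s[i];
    s[i] = -s[i];
  }

  double delta_link(int e, long& csum) const {
    long ncom;
    int a = eu[e], b = ev[e], J = es[e];
    common(a, b, csum, ncom);
    return 2.0 * J * s[a] * s[b] + 2.0 * g * J * csum + h * J;
  }

  void set_adj_sign(int a, int b, int J) {
    std::vector<int>& na = nbr[a];
    for (size_t q = 0; q < na.size(); ++q)
      if (na[q] == b) { sg[a][q] = J; return; }
  }

  void flip_link(int e, double d, long csum) {
    int a = eu[e], b = ev[e], J = es[e];
    H += d;
    // triangles through (a,b): each sign product negates
    tri_unbal += (long)J * csum;  // (#balanced - #unbalanced) through the edge
    neg_links += (J > 0) ? 1 : -1;
    es[e] = -J;
    set_adj_sign(a, b, -J);
    set_adj_sign(b, a, -J);
  }

  void drop_adj(int a, int b) {
    std::vector<int>& na = nbr[a];
    std::vector<int>& za = sg[a];
    for (size_t q = 0; q < na.size(); ++q)
      if (na[q] == b) {
        na[q] = na.back(); na.pop_back();
        za[q] = za.back(); za.pop_back();
        return;
      }
  }

  // structural removal (registry + adjacency + census); H handled by caller
  void detach_edge(int e) {
    int a = eu[e], b = ev[e], J = es[e];
    long csum, ncom;
    common(a, b, csum, ncom);
    tri_total -= ncom;
    tri_unbal -= (ncom - (long)J * csum) / 2;
    if (J < 0) --neg_links;
    drop_adj(a, b);
    drop_adj(b, a);
    eu[e] = eu.back(); eu.pop_back();
    ev[e] = ev.back(); ev.pop_back();
    es[e] = es.back(); es.pop_back();
  }

  void attach_edge(int a, int b, int J) {
    long csum, ncom;
    common(a, b, csum, ncom);
    tri_total += ncom;
    tri_unbal += (ncom - (long)J * csum) / 2;
    if (J < 0) ++neg_links;
    eu.push_back(a); ev.push_back(b); es.push_back(J);
    nbr[a].push_back(b); sg[a].push_back(J);
    nbr[b].push_back(a); sg[b].push_back(J);
  }

  double f_balance() const {
    if (tri_total == 0) return NA_REAL;
    return (double)(tri_total - 2 * tri_unbal) / (double)tri_total;
  }

  double ground_abs() const {
    return (double)eu.size() + g * (double)tri_total;
  }
};

// Metropolis acceptance with a cached exp table for integer stress increments
struct Acceptor {
  double invT;
  std::vector<double> tab;  // tab[d] = exp(-d/T) for integer d in [0, 512]
  void init(double T) {
    invT = 1.0 / T;
    tab.resize(513);
    for (int d = 0; d <= 512; ++d) tab[d] = std::exp(-d * invT);
  }
  bool accept(double d) const {
    if (d <= 0.0) return true;
    double p;
    int di = (int)d;
    if ((double)di == d && di <= 512) p = tab[di];
    else p = std::exp(-d * invT);
    return unif_rand() < p;
  }
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

bool opinion_move(SimState& st, const Acceptor& acc) {
  int i = rand_int(st.n);
  double d = st.delta_opinion(i);
  if (acc.accept(d)) { st.flip_opinion(i, d); return true; }
  return false;
}

// returns 0 = rejected flip, 1 = accepted flip, 2 = rejected rewire,
// 3 = accepted rewire
int link_move(SimState& st, const Acceptor& acc, double p_rewire,
              bool homophilious) {
  int m = (int)st.eu.size();
  if (m == 0) stop("network has no links");
  int e = rand_int(m);
  bool rewire = (p_rewire > 0.0) && (unif_rand() < p_rewire);
  if (!rewire) {
    long csum;
    double d = st.delta_link(e, csum);
    if (acc.accept(d)) { st.flip_link(e, d, csum); return 1; }
    return 0;
  }
  // compound move: delete link e, add a link on a currently-unlinked pair
  int a = st.eu[e], b = st.ev[e], Jab = st.es[e];
  long csum_ab, ncom_ab;
  st.common(a, b, csum_ab, ncom_ab);
  double d_rm = (double)Jab * st.s[a] * st.s[b] + st.g * Jab * csum_ab
                - 0.5 * st.h * (1.0 - Jab);
  // draw the new pair among pairs unlinked in the current state
  int c = -1, dd = -1;
  for (int tries = 0; tries < 10000; ++tries) {
    c = rand_int(st.n); dd = rand_int(st.n);
    if (c == dd) continue;
    if ((c == a && dd == b) || (c == b && dd == a)) continue;
    if (!st.adjacent(c, dd)) break;
    c = -1;
  }
  if (c < 0) return 2;  // dense graph, no free pair found
  int Jn;
  if (homophilious) Jn = (st.s[c] == st.s[dd]) ? 1 : -1;
  else Jn = (unif_rand() < 0.5) ? 1 : -1;
  st.detach_edge(e);
  long csum_cd, ncom_cd;
  st.common(c, dd, csum_cd, ncom_cd);
  double d_ad = -(double)Jn * st.s[c] * st.s[dd] - st.g * Jn * csum_cd
                + 0.5 * st.h * (1.0 - Jn);
  if (acc.accept(d_rm + d_ad)) {
    st.attach_edge(c, dd, Jn);
    st.H += d_rm + d_ad;
    return 3;
  }
  st.attach_edge(a, b, Jab);  // revert
  return 2;
}

IntegerMatrix edges_out(const SimState& st) {
  int m = (int)st.eu.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = st.eu[e] + 1;
    out(e, 1) = st.ev[e] + 1;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_total_stress(int n, IntegerMatrix edges, IntegerVector signs,
                        IntegerVector opinions, double g, double h) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  return st.H;
}

// [[Rcpp::export]]
NumericVector cpp_triangle_census(int n, IntegerMatrix edges,
                                  IntegerVector signs) {
  SimState st;
  IntegerVector ones(n, 1);
  st.init(n, edges, signs, ones, 0.0, 0.0);
  return NumericVector::create(
      _["n_plus"] = (double)(st.tri_total - st.tri_unbal),
      _["n_minus"] = (double)st.tri_unbal);
}

// [[Rcpp::export]]
double cpp_delta_opinion(int n, IntegerMatrix edges, IntegerVector signs,
                         IntegerVector opinions, double g, double h, int i) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  if (i < 1 || i > n) stop("agent index out of range");
  return st.delta_opinion(i - 1);
}

// [[Rcpp::export]]
double cpp_delta_link(int n, IntegerMatrix edges, IntegerVector signs,
                      IntegerVector opinions, double g, double h,
                      int i, int j) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  if (i < 1 || i > n || j < 1 || j > n) stop("agent index out of range");
  int e = -1;
  for (size_t q = 0; q < st.eu.size(); ++q)
    if ((st.eu[q] == i - 1 && st.ev[q] == j - 1) ||
        (st.eu[q] == j - 1 && st.ev[q] == i - 1)) { e = (int)q; break; }
  if (e < 0) stop("pair (i, j) is not linked");
  long csum;
  return st.delta_link(e, csum);
}

// [[Rcpp::export]]
List cpp_opinion_sweep(int n, IntegerMatrix edges, IntegerVector signs,
                       IntegerVector opinions, double g, double temperature,
                       double h, double rate) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  Acceptor acc; acc.init(temperature);
  long nn = (long)std::lround(rate * n);
  long accepted = 0;
  for (long r = 0; r < nn; ++r)
    if (opinion_move(st, acc)) ++accepted;
  return List::create(_["opinions"] = IntegerVector(st.s.begin(), st.s.end()),
                      _["attempts"] = (double)nn,
                      _["accepted"] = (double)accepted,
                      _["stress"] = st.H);
}

// [[Rcpp::export]]
List cpp_link_update(int n, IntegerMatrix edges, IntegerVector signs,
                     IntegerVector opinions, double g, double temperature,
                     double h, double p_rewire, bool homophilious) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  Acceptor acc; acc.init(temperature);
  int code = link_move(st, acc, p_rewire, homophilious);
  return List::create(
      _["edges"] = edges_out(st),
      _["signs"] = IntegerVector(st.es.begin(), st.es.end()),
      _["move"] = (code <= 1) ? "flip" : "rewire",
      _["accepted"] = (code == 1 || code == 3),
      _["stress"] = st.H);
}

// [[Rcpp::export]]
List cpp_step(int n, IntegerMatrix edges, IntegerVector signs,
              IntegerVector opinions, double g, double temperature, double h,
              double rate, double p_rewire, bool homophilious,
              bool fast_links) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  Acceptor acc; acc.init(temperature);
  double nn = rate * n;
  long acc_op = 0;
  int link_code = 0;
  if (fast_links) link_code = link_move(st, acc, p_rewire, homophilious);
  if (nn >= 1.0) {
    long natt = (long)std::lround(nn);
    for (long r = 0; r < natt; ++r)
      if (opinion_move(st, acc)) ++acc_op;
  } else if (unif_rand() < nn) {
    if (opinion_move(st, acc)) ++acc_op;
  }
  if (!fast_links) link_code = link_move(st, acc, p_rewire, homophilious);
  return List::create(
      _["edges"] = edges_out(st),
      _["signs"] = IntegerVector(st.es.begin(), st.es.end()),
      _["opinions"] = IntegerVector(st.s.begin(), st.s.end()),
      _["stress"] = st.H,
      _["accepted_opinions"] = (double)acc_op,
      _["link_accepted"] = (link_code == 1 || link_code == 3));
}

// [[Rcpp::export]]
List cpp_run(int n, IntegerMatrix edges, IntegerVector signs,
             IntegerVector opinions, double g, double temperature, double h,
             double rate, double p_rewire, bool homophilious, int max_steps,
             int record_every, int window, double tol, bool fast_links,
             bool check_convergence, bool record_states) {
  SimState st;
  st.init(n, edges, signs, opinions, g, h);
  Acceptor acc; acc.init(temperature);
  double nn = rate * n;
  long natt = (nn >= 1.0) ? (long)std::lround(nn) : 0;
  int m0 = (int)st.eu.size();
  double kN = 2.0 * m0;  // mean degree times N equals twice the link count

  bool code_states = record_states && (n + m0 <= 30);
  std::vector<int> codes;

  // trajectory records
  std::vector<double> rec_t, rec_H, rec_f, rec_ef, rec_m, rec_neg;
  auto push_record = [&](int t) {
    rec_t.push_back(t);
    rec_H.push_back(st.H);
    rec_f.push_back(st.f_balance());
    rec_ef.push_back(st.H / st.ground_abs());
    rec_m.push_back(std::fabs((double)st.stot) / n);
    rec_neg.push_back((double)st.neg_links / (double)st.eu.size());
  };
  push_record(0);

  // rolling window of per-step observables for stationary averages
  int W = std::max(1, window);
  std::vector<double> rb_H(W), rb_f(W), rb_ef(W), rb_m(W), rb_neg(W);
  double rs_H = 0, rs_f = 0, rs_ef = 0, rs_m = 0, rs_neg = 0;
  long rb_count = 0, rb_fcount = 0;

  // sliding stationarity windows: rolling sums of H over the trailing
  // [t-W+1, t], [t-2W+1, t-W] and [t-3W+1, t-2W] step ranges
  std::vector<double> hbuf(3 * W + 1);
  double s_a = 0.0, s_b = 0.0, s_c = 0.0;
  bool converged = false;
  int t_conv = -1;
  long t_stop = -1;
  long acc_op = 0, acc_link = 0;
  int t = 0;

  for (t = 1; t <= max_steps; ++t) {
    if (fast_links) {
      if (link_move(st, acc, p_rewire, homophilious) % 2 == 1) ++acc_link;
    }
    if (natt > 0) {
      for (long r = 0; r < natt; ++r)
        if (opinion_move(st, acc)) ++acc_op;
    } else if (unif_rand() < nn) {
      if (opinion_move(st, acc)) ++acc_op;
    }
    if (!fast_links) {
      int code = link_move(st, acc, p_rewire, homophilious);
      if (code == 1 || code == 3) ++acc_link;
    }

    // rolling stationary-window accumulators
    int slot = (int)(rb_count % W);
    if (rb_count >= W) {
      rs_H -= rb_H[slot]; rs_ef -= rb_ef[slot]; rs_m -= rb_m[slot];
      rs_neg -= rb_neg[slot];
      if (!ISNA(rb_f[slot])) { rs_f -= rb_f[slot]; --rb_fcount; }
    }
    double fb = st.f_balance();
    rb_H[slot] = st.H; rb_ef[slot] = st.H / st.ground_abs();
    rb_m[slot] = std::fabs((double)st.stot) / n;
    rb_neg[slot] = (double)st.neg_links / (double)st.eu.size();
    rb_f[slot] = fb;
    rs_H += rb_H[slot]; rs_ef += rb_ef[slot]; rs_m += rb_m[slot];
    rs_neg += rb_neg[slot];
    if (!ISNA(fb)) { rs_f += fb; ++rb_fcount; }
    ++rb_count;

    if (t % record_every == 0) push_record(t);
    if (code_states) {
      uint32_t code = 0;
      for (int i = 0; i < n; ++i) if (st.s[i] > 0) code |= (1u << i);
      for (int e = 0; e < m0; ++e) if (st.es[e] > 0) code |= (1u << (n + e));
      codes.push_back((int)code);
    }

    // sliding stationarity criterion on H: converged at the first step
    // where the trailing two window means differ by less than tol, with a
    // third-window guard against slow monotone drift
    {
      int bidx = t % (3 * W + 1);
      s_a += st.H;
      if (t > W) {
        double hW = hbuf[(t - W) % (3 * W + 1)];
        s_a -= hW; s_b += hW;
      }
      if (t > 2 * W) {
        double h2W = hbuf[(t - 2 * W) % (3 * W + 1)];
        s_b -= h2W; s_c += h2W;
      }
      if (t > 3 * W) s_c -= hbuf[(t - 3 * W) % (3 * W + 1)];
      hbuf[bidx] = st.H;
      if (check_convergence && !converged && t >= 2 * W &&
          std::fabs(s_a - s_b) / W < tol &&
          (t < 3 * W || std::fabs(s_a - s_c) / W < 2.0 * tol)) {
        converged = true;
        t_conv = t;
        t_stop = (long)t + W;  // one further measurement window
      }
    }
    if (converged && t >= t_stop) break;
    if (t % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  int t_final = std::min(t, max_steps);
  if (rec_t.back() != (double)t_final) push_record(t_final);

  long denom = std::min((long)W, rb_count);
  double H_inc = st.H;
  st.recompute();  // exact final recomputation guards the incremental path

  NumericMatrix records((int)rec_t.size(), 6);
  colnames(records) = CharacterVector::create("t", "H", "f", "e_f", "m",
                                              "neg_frac");
  for (int r = 0; r < (int)rec_t.size(); ++r) {
    records(r, 0) = rec_t[r]; records(r, 1) = rec_H[r];
    records(r, 2) = rec_f[r]; records(r, 3) = rec_ef[r];
    records(r, 4) = rec_m[r]; records(r, 5) = rec_neg[r];
  }

  List out = List::create(
      _["edges"] = edges_out(st),
      _["signs"] = IntegerVector(st.es.begin(), st.es.end()),
      _["opinions"] = IntegerVector(st.s.begin(), st.s.end()),
      _["records"] = records,
      _["stress"] = st.H,
      _["stress_incremental"] = H_inc,
      _["converged"] = converged,
      _["t_conv"] = converged ? (double)t_conv : NA_REAL,
      _["tau"] = converged ? (double)t_conv / kN : NA_REAL,
      _["t_final"] = (double)t_final,
      _["stationary_H"] = denom > 0 ? rs_H / denom : NA_REAL,
      _["stationary_f"] = rb_fcount > 0 ? rs_f / rb_fcount : NA_REAL,
      _["stationary_e_f"] = denom > 0 ? rs_ef / denom : NA_REAL,
      _["stationary_m"] = denom > 0 ? rs_m / denom : NA_REAL,
      _["stationary_neg_frac"] = denom > 0 ? rs_neg / denom : NA_REAL,
      _["accepted_opinions"] = (double)acc_op,
      _["accepted_links"] = (double)acc_link);
  if (code_states) out["state_codes"] = IntegerVector(codes.begin(),
                                                      codes.end());
  return out;
}

// [[Rcpp::export]]
List cpp_signed_partition(int n, IntegerMatrix edges, IntegerVector signs,
                          int restarts) {
  SimState st;
  IntegerVector ones(n, 1);
  st.init(n, edges, signs, ones, 0.0, 0.0);
  int m = (int)st.eu.size();

  std::vector<int> best_lab(n), lab(n);
  long best_cost = -1;

  auto global_cost = [&](const std::vector<int>& L) {
    long c = 0;
    for (int e = 0; e < m; ++e) {
      bool same = (L[st.eu[e]] == L[st.ev[e]]);
      if (st.es[e] > 0 && !same) ++c;
      if (st.es[e] < 0 && same) ++c;
    }
    return c;
  };

  // union-find over positive links: the positive-component partition is a
  // natural starting point (most negative links already lie between groups)
  std::vector<int> pos_comp(n);
  {
    std::vector<int> parent(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    for (int e = 0; e < m; ++e)
      if (st.es[e] > 0) {
        int ra = find(st.eu[e]), rb = find(st.ev[e]);
        if (ra != rb) parent[ra] = rb;
      }
    for (int i = 0; i < n; ++i) pos_comp[i] = find(i);
  }

  // agglomerative phase: merge cluster pairs while any merge lowers the
  // objective (a positive surplus on the links between the two clusters)
  // rounds: rebuild inter-cluster surpluses, then greedily merge disjoint
  // pairs in descending gain order until no merge lowers the objective
  auto merge_pass = [&](std::vector<int>& L) {
    bool any = false;
    for (;;) {
      std::map<std::pair<int, int>, long> surplus;
      for (int e = 0; e < m; ++e) {
        int la = L[st.eu[e]], lb = L[st.ev[e]];
        if (la == lb) continue;
        std::pair<int, int> key = (la < lb) ? std::make_pair(la, lb)
                                            : std::make_pair(lb, la);
        surplus[key] += (st.es[e] > 0) ? 1 : -1;
      }
      std::vector<std::pair<long, std::pair<int, int>>> gains;
      for (std::map<std::pair<int, int>, long>::iterator it = surplus.begin();
           it != surplus.end(); ++it)
        if (it->second > 0) gains.push_back(std::make_pair(it->second,
                                                           it->first));
      if (gains.empty()) break;
      std::sort(gains.rbegin(), gains.rend());
      std::map<int, int> target;  // cluster -> merged-into label this round
      bool merged = false;
      for (size_t q = 0; q < gains.size(); ++q) {
        int la = gains[q].second.first, lb = gains[q].second.second;
        if (target.count(la) || target.count(lb)) continue;  // stale gain
        target[la] = la;
        target[lb] = la;
        merged = true;
      }
      if (!merged) break;
      for (int i = 0; i < n; ++i) {
        std::map<int, int>::iterator it = target.find(L[i]);
        if (it != target.end()) L[i] = it->second;
      }
      any = true;
    }
    return any;
  };

  for (int r = 0; r < std::max(1, restarts); ++r) {
    if (r == 0) {
      lab = pos_comp;  // positive-component start
    } else if (r == 1) {
      for (int i = 0; i < n; ++i) lab[i] = i;  // singleton start
    } else {
      for (int i = 0; i < n; ++i) lab[i] = rand_int(n);
    }
    int next_free = n;  // labels never reused, so n + pass count is free
    bool improved = true;
    int passes = 0;
    while (improved && passes < 200) {
      improved = false;
      ++passes;
      if (merge_pass(lab)) improved = true;
      // random scan order
      std::vector<int> order(n);
      for (int i = 0; i < n; ++i) order[i] = i;
      for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rand_int(i + 1)]);
      for (int oi = 0; oi < n; ++oi) {
        int v = order[oi];
        const std::vector<int>& nv = st.nbr[v];
        const std::vector<int>& zv = st.sg[v];
        if (nv.empty()) continue;
        // local cost of assigning label L to v:
        //   positive links to other labels + negative links to the same label
        long npos = 0;
        for (size_t q = 0; q < nv.size(); ++q) if (zv[q] > 0) ++npos;
        long cur = 0;
        for (size_t q = 0; q < nv.size(); ++q) {
          bool same = (lab[nv[q]] == lab[v]);
          if (zv[q] > 0 && !same) ++cur;
          if (zv[q] < 0 && same) ++cur;
        }
        int best_L = lab[v];
        long best_c = cur;
        // candidates: neighbour labels and a fresh singleton label
        for (size_t q = 0; q < nv.size(); ++q) {
          int L = lab[nv[q]];
          if (L == lab[v]) continue;
          long c = 0;
          for (size_t q2 = 0; q2 < nv.size(); ++q2) {
            bool same = (lab[nv[q2]] == L);
            if (zv[q2] > 0 && !same) ++c;
            if (zv[q2] < 0 && same) ++c;
          }
          if (c < best_c) { best_c = c; best_L = L; }
        }
        if (npos < best_c) { best_c = npos; best_L = next_free++; }
        if (best_L != lab[v]) { lab[v] = best_L; improved = true; }
      }
    }
    long cost = global_cost(lab);
    if (best_cost < 0 || cost < best_cost) {
      best_cost = cost;
      best_lab = lab;
    }
  }

  // relabel to consecutive ids 1..K
  std::map<int, int> seen;
  IntegerVector labels(n);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    auto it = seen.find(best_lab[i]);
    int id;
    if (it == seen.end()) { id = ++next_id; seen[best_lab[i]] = id; }
    else id = it->second;
    labels[i] = id;
  }
  return List::create(_["labels"] = labels,
                      _["frustration"] = (double)best_cost);
}
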