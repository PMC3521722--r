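#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Serial (heterochronous) coalescent under a piecewise-constant Ne trajectory,
// plus a generalized stepwise mutation model for microsatellite repeat counts.
// Time runs backward in generations before the most recent sample; all draws
// come from R's RNG stream so set.seed() governs reproducibility.

// Ne(t) lookup: epoch_breaks ascending; N = epoch_N[j] for t in
// [break_{j-1}, break_j) with break_{-1} = 0; last epoch extends to infinity,
// so epoch_N has length(epoch_breaks) + 1.
static inline double ne_at(double t, const std::vector<double>& breaks,
                           const std::vector<double>& N) {
  size_t j = 0;
  while (j < breaks.size() && t >= breaks[j]) ++j;
  return N[j];
}

static inline double next_break_after(double t, const std::vector<double>& breaks) {
  for (size_t j = 0; j < breaks.size(); ++j)
    if (breaks[j] > t) return breaks[j];
  return R_PosInf;
}

struct Tree {
  // nodes 0..n-1 are tips (input order), n..2n-2 internal; parent of root = -1
  std::vector<int> parent;
  std::vector<double> time;
  int n_tips;
};

// tip_times: generation offset (>= 0) of every gene copy, input order preserved
static Tree sim_tree(const std::vector<double>& tip_times,
                     const std::vector<double>& breaks,
                     const std::vector<double>& N) {
  const int n = (int)tip_times.size();
  Tree tr;
  tr.n_tips = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);
  for (int i = 0; i < n; ++i) tr.time[i] = tip_times[i];

  // tips sorted by entry time
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return tip_times[a] < tip_times[b]; });

  std::vector<int> active;
  active.reserve(n);
  int next_tip = 0;
  double t = tip_times[ord[0]];
  while (next_tip < n && tip_times[ord[next_tip]] <= t) {
    active.push_back(ord[next_tip]);
    ++next_tip;
  }
  int next_node = n;

  while ((int)active.size() > 1 || next_tip < n) {
    double entry = (next_tip < n) ? tip_times[ord[next_tip]] : R_PosInf;
    double brk = next_break_after(t, breaks);
    double boundary = std::min(entry, brk);
    int k = (int)active.size();
    double t_coal = R_PosInf;
    if (k >= 2) {
      double Ne = ne_at(t, breaks, N);
      double rate = (double)k * (k - 1) / (4.0 * Ne);
      t_coal = t + exp_rand() / rate;
    }
    if (t_coal <= boundary) {
      // coalesce two random active lineages
      int i = (int)std::floor(unif_rand() * k);
      if (i >= k) i = k - 1;
      int j = (int)std::floor(unif_rand() * (k - 1));
      if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = active[i], b = active[j];
      int node = next_node++;
      tr.parent[a] = node;
      tr.parent[b] = node;
      tr.time[node] = t_coal;
      // remove higher index first
      if (i < j) std::swap(i, j);
      active.erase(active.begin() + i);
      active.erase(active.begin() + j);
      active.push_back(node);
      t = t_coal;
    } else {
      t = boundary;
      while (next_tip < n && tip_times[ord[next_tip]] <= t) {
        active.push_back(ord[next_tip]);
        ++next_tip;
      }
    }
  }
  return tr;
}

// [[Rcpp::export(name = ".sim_tree_cpp")]]
List sim_tree_cpp(NumericVector tip_times, NumericVector epoch_breaks,
                  NumericVector epoch_N) {
  if (epoch_N.size() != epoch_breaks.size() + 1)
    stop("epoch_N must have one more element than epoch_breaks");
  for (double v : epoch_N)
    if (!(v > 0)) stop("nonpositive Ne in trajectory");
  std::vector<double> tt(tip_times.begin(), tip_times.end());
  std::vector<double> br(epoch_breaks.begin(), epoch_breaks.end());
  std::vector<double> N(epoch_N.begin(), epoch_N.end());
  RNGScope scope;
  Tree tr = sim_tree(tt, br, N);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
                      _["n_tips"] = tr.n_tips);
}

// geometric multi-step: step size s >= 1, P(S=s) = (1-p) p^(s-1); p = 0 is SMM
static inline int gsm_step(double p) {
  if (p <= 0.0) return 1;
  return 1 + (int)R::rgeom(1.0 - p);
}

static inline int reflect(int x, int lo, int hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2 * lo - x;
    else x = 2 * hi - x;
  }
  return x;
}

// mutate tip states down a tree from founder; children listed per node
static void drop_mut(const Tree& tr, double mu, double p, int founder,
                     int lo, int hi, std::vector<int>& state) {
  int m = 2 * tr.n_tips - 1;
  state.assign(m, founder);
  // process nodes in decreasing time order (root first): internal nodes were
  // created in increasing-time order, so iterate indices m-1 .. 0, tips last.
  // parent index is always > child index for internal nodes; tips (0..n-1)
  // can have any internal parent. Sort nodes by time descending.
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return tr.time[a] > tr.time[b]; });
  for (int idx : ord) {
    int par = tr.parent[idx];
    if (par < 0) continue; // root keeps founder state
    double len = tr.time[par] - tr.time[idx];
    int x = state[par];
    int nm = (int)R::rpois(mu * len);
    for (int k = 0; k < nm; ++k) {
      int s = gsm_step(p);
      x += (unif_rand() < 0.5) ? -s : s;
      x = reflect(x, lo, hi);
    }
    state[idx] = x;
  }
}

// [[Rcpp::export(name = ".drop_mutations_cpp")]]
IntegerVector drop_mutations_cpp(IntegerVector parent, NumericVector time,
                                 int n_tips, double mu, double gsm_p,
                                 int founder, int state_min, int state_max) {
  Tree tr;
  tr.n_tips = n_tips;
  tr.parent.assign(parent.begin(), parent.end());
  tr.time.assign(time.begin(), time.end());
  RNGScope scope;
  std::vector<int> state;
  drop_mut(tr, mu, gsm_p, founder, state_min, state_max, state);
  return IntegerVector(state.begin(), state.begin() + n_tips);
}

// Simulate a whole multi-locus dataset: one independent genealogy + mutation
// layer per locus. Returns gene-copy x locus matrix of allele states.
// [[Rcpp::export(name = ".sim_dataset_cpp")]]
IntegerMatrix sim_dataset_cpp(NumericVector tip_times, int n_loci,
                              NumericVector epoch_breaks, NumericVector epoch_N,
                              NumericVector mu_locus, double gsm_p, int founder,
                              int state_min, int state_max) {
  if (epoch_N.size() != epoch_breaks.size() + 1)
    stop("epoch_N must have one more element than epoch_breaks");
  for (double v : epoch_N)
    if (!(v > 0)) stop("nonpositive Ne in trajectory");
  if (mu_locus.size() != n_loci) stop("need one mutation rate per locus");
  const int n = tip_times.size();
  std::vector<double> tt(tip_times.begin(), tip_times.end());
  std::vector<double> br(epoch_breaks.begin(), epoch_breaks.end());
  std::vector<double> N(epoch_N.begin(), epoch_N.end());
  IntegerMatrix out(n, n_loci);
  RNGScope scope;
  std::vector<int> state;
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(tt, br, N);
    drop_mut(tr, mu_locus[l], gsm_p, founder, state_min, state_max, state);
    for (int i = 0; i < n; ++i) out(i, l) = state[i];
  }
  return out;
}

// ---- summary statistics fast path -------------------------------------------
// alleles: gene-copy x locus matrix, copies 2i, 2i+1 form individual i; sample
// membership per copy in sample_id (0-based, contiguous blocks). Computes, per
// temporal sample: locus means of unbiased H_E, allele count, unbiased
// allele-size variance, M ratio; plus multi-locus Weir-Cockerham theta between
// the first and last samples. Must agree exactly with the R summary_vector().

struct LocusSample {
  std::vector<int> counts; // per allele value (offset by lo)
  int n_copies;
};

// [[Rcpp::export(name = ".summaries_cpp")]]
NumericVector summaries_cpp(IntegerMatrix alleles, IntegerVector sample_id,
                            int n_samples, IntegerMatrix fst_pairs) {
  const int ncopy = alleles.nrow(), nloc = alleles.ncol();
  if (sample_id.size() != ncopy) stop("sample_id length mismatch");
  const int npair = fst_pairs.ncol();
  NumericVector out(4 * n_samples + npair);
  // per-sample per-locus stats
  for (int s = 0; s < n_samples; ++s) {
    double sum_he = 0, sum_na = 0, sum_v = 0, sum_m = 0;
    for (int l = 0; l < nloc; ++l) {
      int lo = INT_MAX, hi = INT_MIN, n = 0;
      for (int i = 0; i < ncopy; ++i) {
        if (sample_id[i] != s) continue;
        int a = alleles(i, l);
        lo = std::min(lo, a);
        hi = std::max(hi, a);
        ++n;
      }
      std::vector<int> cnt(hi - lo + 1, 0);
      double sum = 0, sumsq = 0;
      for (int i = 0; i < ncopy; ++i) {
        if (sample_id[i] != s) continue;
        int a = alleles(i, l);
        cnt[a - lo]++;
        sum += a;
        sumsq += (double)a * a;
      }
      int k = 0;
      double sump2 = 0;
      for (int c : cnt)
        if (c > 0) {
          ++k;
          double p = (double)c / n;
          sump2 += p * p;
        }
      double he = (n > 1) ? ((double)n / (n - 1)) * (1.0 - sump2) : 0.0;
      double v = (n > 1) ? (sumsq - sum * sum / n) / (n - 1) : 0.0;
      sum_he += he;
      sum_na += k;
      sum_v += v;
      sum_m += (double)k / (hi - lo + 1);
    }
    out[4 * s + 0] = sum_he / nloc;
    out[4 * s + 1] = sum_na / nloc;
    out[4 * s + 2] = sum_v / nloc;
    out[4 * s + 3] = sum_m / nloc;
  }
  for (int pp = 0; pp < npair; ++pp) {
    // Weir-Cockerham theta between one sample pair, r = 2 populations
    int sa = fst_pairs(0, pp), sb = fst_pairs(1, pp);
    double num = 0, den = 0;
    for (int l = 0; l < nloc; ++l) {
      // individuals per sample at this locus (no missing in simulated data)
      int lo = INT_MAX, hi = INT_MIN;
      int n1 = 0, n2 = 0;
      for (int i = 0; i < ncopy; ++i) {
        if (sample_id[i] == sa) ++n1;
        else if (sample_id[i] == sb) ++n2;
        if (sample_id[i] == sa || sample_id[i] == sb) {
          lo = std::min(lo, (int)alleles(i, l));
          hi = std::max(hi, (int)alleles(i, l));
        }
      }
      n1 /= 2; n2 /= 2; // diploids
      int width = hi - lo + 1;
      std::vector<double> p1(width, 0), p2(width, 0), h1(width, 0), h2(width, 0);
      for (int i = 0; i < ncopy; i += 2) {
        int s = sample_id[i];
        if (s != sa && s != sb) continue;
        int a = alleles(i, l) - lo, b = alleles(i + 1, l) - lo;
        std::vector<double>& p = (s == sa) ? p1 : p2;
        std::vector<double>& h = (s == sa) ? h1 : h2;
        p[a] += 1; p[b] += 1;
        if (a != b) { h[a] += 1; h[b] += 1; }
      }
      for (int u = 0; u < width; ++u) {
        p1[u] /= 2.0 * n1; p2[u] /= 2.0 * n2;
        h1[u] /= n1; h2[u] /= n2;
      }
      double nbar = (n1 + n2) / 2.0;
      double r = 2.0;
      double nc = (r * nbar - ((double)n1 * n1 + (double)n2 * n2) / (r * nbar)) / (r - 1.0);
      for (int u = 0; u < width; ++u) {
        if (p1[u] == 0 && p2[u] == 0) continue;
        double pbar = (n1 * p1[u] + n2 * p2[u]) / (r * nbar);
        double s2 = (n1 * (p1[u] - pbar) * (p1[u] - pbar) +
                     n2 * (p2[u] - pbar) * (p2[u] - pbar)) / ((r - 1.0) * nbar);
        double hbar = (n1 * h1[u] + n2 * h2[u]) / (r * nbar);
        double a = (nbar / nc) *
                   (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4.0) / (nbar - 1));
        double b = (nbar / (nbar - 1)) *
                   (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                    (2 * nbar - 1) / (4.0 * nbar) * hbar);
        double c = hbar / 2.0;
        num += a;
        den += a + b + c;
      }
    }
    out[4 * n_samples + pp] = (den != 0) ? num / den : 0.0;
  }
  return out;
}
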