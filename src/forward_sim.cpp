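// Forward Wright-Fisher simulation of a single genomic window with
// infinite-sites mutation, uniform crossover, multiplicative selection
// (fitness exp(-s * k) over selected mutations) and a staged demography of
// one or two demes with symmetric migration. All randomness comes from R's
// RNG so set.seed() governs the whole simulation.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct MutTable {
  std::vector<double> pos;   // position in [0, L)
  std::vector<int> type;     // 0 neutral, 1 deleterious, 2 beneficial
};

struct Config {
  double L, mu, rr;          // window length, per-site rates (already rescaled)
  double s_del, s_ben;
  double sel_lo, sel_hi;     // deleterious block [lo, hi)
  bool scattered;
  double sel_frac;           // scattered-mode probability that a new mutation is selected
};

struct Deme {
  std::vector<std::vector<int>> hap;  // each: mutation ids sorted by position
  std::vector<double> logw;           // per-haplotype log fitness
};

int draw_new_mutation(MutTable& mt, const Config& cf) {
  double p = unif_rand() * cf.L;
  int t = 0;
  if (cf.scattered) {
    if (cf.sel_frac > 0 && unif_rand() < cf.sel_frac) t = 1;
  } else if (p >= cf.sel_lo && p < cf.sel_hi) {
    t = 1;
  }
  mt.pos.push_back(p);
  mt.type.push_back(t);
  return (int)mt.pos.size() - 1;
}

// keep mutations of h lying in crossover segments of the given parity;
// parity 0 keeps [0, xo[0]), [xo[1], xo[2]), ...
void take_segments(const std::vector<int>& h, const std::vector<double>& xo,
                   int parity, const MutTable& mt, std::vector<int>& out) {
  size_t k = 0;
  for (int id : h) {
    double p = mt.pos[id];
    while (k < xo.size() && xo[k] <= p) ++k;
    if ((int)(k % 2) == parity) out.push_back(id);
  }
}

void merge_by_pos(const std::vector<int>& a, const std::vector<int>& b,
                  const MutTable& mt, std::vector<int>& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (mt.pos[a[i]] < mt.pos[b[j]]) out.push_back(a[i++]);
    else out.push_back(b[j++]);
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
}

void make_gamete(const std::vector<int>& a, const std::vector<int>& b,
                 MutTable& mt, const Config& cf, std::vector<int>& out) {
  int nco = (int)R::rpois(cf.rr * cf.L);
  bool start_a = unif_rand() < 0.5;
  if (nco == 0) {
    out = start_a ? a : b;
  } else {
    std::vector<double> xo(nco);
    for (int i = 0; i < nco; ++i) xo[i] = unif_rand() * cf.L;
    std::sort(xo.begin(), xo.end());
    std::vector<int> fa, fb;
    take_segments(start_a ? a : b, xo, 0, mt, fa);
    take_segments(start_a ? b : a, xo, 1, mt, fb);
    merge_by_pos(fa, fb, mt, out);
  }
  int nmut = (int)R::rpois(cf.mu * cf.L);
  for (int m = 0; m < nmut; ++m) {
    int id = draw_new_mutation(mt, cf);
    double p = mt.pos[id];
    auto it = std::lower_bound(out.begin(), out.end(), p,
      [&mt](int lhs, double val) { return mt.pos[lhs] < val; });
    out.insert(it, id);
  }
}

double hap_logw(const std::vector<int>& h, const MutTable& mt, const Config& cf) {
  int kd = 0, kb = 0;
  for (int id : h) {
    if (mt.type[id] == 1) ++kd;
    else if (mt.type[id] == 2) ++kb;
  }
  return -cf.s_del * kd + cf.s_ben * kb;
}

void build_cumw(const Deme& d, std::vector<double>& cumw) {
  size_t n = d.hap.size() / 2;
  cumw.resize(n);
  double tot = 0;
  for (size_t j = 0; j < n; ++j) {
    tot += std::exp(d.logw[2 * j] + d.logw[2 * j + 1]);
    cumw[j] = tot;
  }
}

int pick_parent(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  int j = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
  if (j >= (int)cumw.size()) j = (int)cumw.size() - 1;
  return j;
}

void step_generation(std::vector<Deme>& cur, std::vector<Deme>& nxt,
                     int n1, int n2, double mig, MutTable& mt, const Config& cf,
                     bool neutral) {
  int ndeme = (n2 > 0) ? 2 : 1;
  std::vector<std::vector<double>> cumw(2);
  if (!neutral)
    for (int d = 0; d < 2; ++d)
      if (!cur[d].hap.empty()) build_cumw(cur[d], cumw[d]);
  int sizes[2] = {n1, n2};
  for (int d = 0; d < ndeme; ++d) {
    Deme& out = nxt[d];
    out.hap.assign(2 * sizes[d], std::vector<int>());
    out.logw.assign(2 * sizes[d], 0.0);
    for (int i = 0; i < sizes[d]; ++i) {
      for (int g = 0; g < 2; ++g) {
        int src = d;
        if (ndeme == 2 && mig > 0 && unif_rand() < mig) src = 1 - d;
        if (cur[src].hap.empty()) src = 0;  // deme-founding generation
        int par;
        if (neutral) {
          int np = (int)(cur[src].hap.size() / 2);
          par = (int)(unif_rand() * np);
          if (par >= np) par = np - 1;
        } else {
          par = pick_parent(cumw[src]);
        }
        std::vector<int>& h = out.hap[2 * i + g];
        make_gamete(cur[src].hap[2 * par], cur[src].hap[2 * par + 1], mt, cf, h);
        if (!neutral) out.logw[2 * i + g] = hap_logw(h, mt, cf);
      }
    }
  }
  if (ndeme == 1) { nxt[1].hap.clear(); nxt[1].logw.clear(); }
}

long count_id(const std::vector<Deme>& pop, int id, const MutTable& mt) {
  double p = mt.pos[id];
  long c = 0;
  for (const Deme& d : pop)
    for (const auto& h : d.hap) {
      auto it = std::lower_bound(h.begin(), h.end(), p,
        [&mt](int lhs, double val) { return mt.pos[lhs] < val; });
      for (; it != h.end() && mt.pos[*it] == p; ++it)
        if (*it == id) { ++c; break; }
    }
  return c;
}

long pop_haplotypes(const std::vector<Deme>& pop) {
  long tot = 0;
  for (const Deme& d : pop) tot += (long)d.hap.size();
  return tot;
}

int interp_size(double ns, double ne, int t, int dur) {
  double v = (ns == ne) ? ns : ns * std::pow(ne / ns, (double)t / (double)dur);
  int n = (int)std::lround(v);
  return n < 2 ? 2 : n;
}

struct EpochRunner {
  NumericMatrix epochs;
  // run generations with absolute index in (g_from, g_to]; a negative stop_id
  // disables the loss check. Returns false if stop_id was lost.
  bool run(std::vector<Deme>& cur, std::vector<Deme>& nxt, MutTable& mt,
           const Config& cf, long g_from, long g_to, int watch_id,
           bool neutral_base) {
    long gen = 0;
    for (int e = 0; e < epochs.nrow(); ++e) {
      int dur = (int)epochs(e, 0);
      for (int t = 1; t <= dur; ++t) {
        ++gen;
        if (gen <= g_from) continue;
        if (gen > g_to) return true;
        int n1 = interp_size(epochs(e, 1), epochs(e, 2), t, dur);
        int n2 = (epochs(e, 3) > 0)
                   ? interp_size(epochs(e, 3), epochs(e, 4), t, dur) : 0;
        bool neutral = neutral_base && watch_id < 0;
        step_generation(cur, nxt, n1, n2, epochs(e, 5), mt, cf, neutral);
        std::swap(cur, nxt);
        if (watch_id >= 0 && count_id(cur, watch_id, mt) == 0) return false;
        if (gen % 64 == 0) Rcpp::checkUserInterrupt();
      }
    }
    return true;
  }
  long total() {
    long g = 0;
    for (int e = 0; e < epochs.nrow(); ++e) g += (long)epochs(e, 0);
    return g;
  }
};

int introduce_beneficial(std::vector<Deme>& cur, MutTable& mt, const Config& cf,
                         double sweep_pos) {
  mt.pos.push_back(sweep_pos);
  mt.type.push_back(2);
  int id = (int)mt.pos.size() - 1;
  size_t H = cur[0].hap.size();
  size_t hi = (size_t)(unif_rand() * H);
  if (hi >= H) hi = H - 1;
  std::vector<int>& h = cur[0].hap[hi];
  auto it = std::lower_bound(h.begin(), h.end(), sweep_pos,
    [&mt](int lhs, double val) { return mt.pos[lhs] < val; });
  h.insert(it, id);
  cur[0].logw[hi] = hap_logw(h, mt, cf);
  return id;
}

}  // namespace

// epochs: matrix with columns duration, n1_start, n1_end, n2_start, n2_end,
// mig (sizes in diploids, already Q-rescaled; n2 of 0 means deme absent).
// sweep_gen: absolute post-burn-in generation (1-based) at which a single
// beneficial mutation is introduced; 0 disables the sweep. Sweeps are
// conditioned on fixation before sampling, retrying from the introduction
// generation on loss or non-fixation.
// [[Rcpp::export(name = ".simWindowCpp")]]
List sim_window_cpp(NumericMatrix epochs, double L, double mu, double rr,
                    double s_del, double sel_lo, double sel_hi,
                    bool scattered, double sel_frac,
                    int burn_in, int sample_n1, int sample_n2,
                    double s_ben, double sweep_pos, int sweep_gen,
                    int max_retries, bool return_haplotypes) {
  Config cf{L, mu, rr, s_del, s_ben, sel_lo, sel_hi, scattered, sel_frac};
  MutTable mt;
  std::vector<Deme> cur(2), nxt(2);
  EpochRunner er{epochs};

  int n1_0 = (int)epochs(0, 1);
  cur[0].hap.assign(2 * n1_0, std::vector<int>());
  cur[0].logw.assign(2 * n1_0, 0.0);

  bool neutral_base = (s_del == 0.0);
  for (int t = 0; t < burn_in; ++t) {
    step_generation(cur, nxt, n1_0, 0, 0.0, mt, cf, neutral_base);
    std::swap(cur, nxt);
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  long g_total = er.total();
  int attempts = 0;
  if (sweep_gen <= 0) {
    er.run(cur, nxt, mt, cf, 0, g_total, -1, neutral_base);
  } else {
    if ((long)sweep_gen > g_total)
      stop("sweep introduction generation exceeds total epoch length");
    er.run(cur, nxt, mt, cf, 0, sweep_gen - 1, -1, neutral_base);
    std::vector<Deme> snapshot = cur;
    MutTable mt_snap = mt;
    bool done = false;
    while (!done) {
      ++attempts;
      if (attempts > max_retries)
        stop("beneficial mutation failed to fix within max_retries attempts");
      int ben_id = introduce_beneficial(cur, mt, cf, sweep_pos);
      bool survived = er.run(cur, nxt, mt, cf, sweep_gen - 1, g_total,
                             ben_id, neutral_base);
      if (survived && count_id(cur, ben_id, mt) == pop_haplotypes(cur)) {
        done = true;
      } else {
        cur = snapshot;
        mt = mt_snap;
      }
    }
  }

  // sample haplotypes without replacement, deme 1 then deme 2
  std::vector<const std::vector<int>*> sampled;
  for (int d = 0; d < 2; ++d) {
    int want = d == 0 ? sample_n1 : sample_n2;
    if (want == 0) continue;
    int have = (int)cur[d].hap.size();
    if (want > have) stop("sample size exceeds deme size");
    std::vector<int> idx(have);
    for (int i = 0; i < have; ++i) idx[i] = i;
    for (int i = 0; i < want; ++i) {
      int j = i + (int)(unif_rand() * (have - i));
      if (j >= have) j = have - 1;
      std::swap(idx[i], idx[j]);
      sampled.push_back(&cur[d].hap[idx[i]]);
    }
  }
  int n = (int)sampled.size();

  std::vector<long> cnt(mt.pos.size(), 0);
  for (auto* h : sampled)
    for (int id : *h) ++cnt[id];
  std::vector<int> keep;
  for (size_t id = 0; id < cnt.size(); ++id)
    if (cnt[id] > 0) keep.push_back((int)id);
  std::sort(keep.begin(), keep.end(),
            [&](int a, int b) { return mt.pos[a] < mt.pos[b]; });

  int S = (int)keep.size();
  NumericVector pos(S);
  IntegerVector dcount(S), typ(S);
  for (int k = 0; k < S; ++k) {
    pos[k] = mt.pos[keep[k]];
    dcount[k] = (int)cnt[keep[k]];
    typ[k] = mt.type[keep[k]];
  }
  List out = List::create(
    _["positions"] = pos, _["derived_count"] = dcount, _["type"] = typ,
    _["n"] = n, _["sweep_attempts"] = attempts);
  if (return_haplotypes) {
    IntegerMatrix G(n, S);
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& h = *sampled[i];
      size_t ptr = 0;
      for (int k = 0; k < S; ++k) {
        double p = pos[k];
        while (ptr < h.size() && mt.pos[h[ptr]] < p) ++ptr;
        G(i, k) = (ptr < h.size() && mt.pos[h[ptr]] == p) ? 1 : 0;
      }
    }
    out["haplotypes"] = G;
  }
  return out;
}
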