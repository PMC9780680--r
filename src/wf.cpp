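// Forward-time haploid Wright-Fisher engine with recombination, infinite-sites
// mutation and genic selection, plus the EHH integration core of the iHS scan.
// All randomness flows from R's global RNG (set.seed() gives bit-identical
// output).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef std::vector<uint32_t> Hap;   // sorted positions of derived alleles
typedef std::vector<Hap> Pop;

static inline int runif_int(int n) {
  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline bool carries(const Hap &h, uint32_t pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// copy from parent alternating at breakpoints
static Hap recombine(const Hap &a, const Hap &b,
                     const std::vector<uint32_t> &brk, uint32_t L) {
  Hap child;
  child.reserve(std::max(a.size(), b.size()) + 4);
  const Hap *cur = &a;
  uint32_t lo = 1;
  size_t bi = 0;
  while (lo <= L) {
    uint32_t hi = (bi < brk.size()) ? brk[bi] : (L + 1);  // segment [lo, hi)
    auto it0 = std::lower_bound(cur->begin(), cur->end(), lo);
    auto it1 = std::lower_bound(cur->begin(), cur->end(), hi);
    child.insert(child.end(), it0, it1);
    cur = (cur == &a) ? &b : &a;
    lo = hi;
    ++bi;
    if (bi > brk.size()) break;
  }
  return child;
}

struct Engine {
  uint32_t L;
  double mu, rho;
  uint32_t sweep_pos;  // 0 = none
  std::unordered_set<uint32_t> active;  // positions currently in any haplotype

  uint32_t draw_position() {
    for (int tries = 0; tries < 100000; ++tries) {
      uint32_t p = 1 + (uint32_t)(unif_rand() * L);
      if (p > L) p = L;
      if (p != sweep_pos && !active.count(p)) return p;
    }
    stop("mutation position supply exhausted (region too small for mu)");
  }

  void mutate(Hap &child) {
    int m = (int)R::rpois(mu * L);
    for (int i = 0; i < m; ++i) {
      uint32_t p = draw_position();
      child.insert(std::lower_bound(child.begin(), child.end(), p), p);
      active.insert(p);
    }
  }

  // One WF generation; selection at sweep_pos with coefficient s if sel.
  void step(Pop &pop, int n_next, bool sel, double s) {
    int N = (int)pop.size();
    std::vector<int> car, non;
    double p_car = 0.0;
    if (sel && sweep_pos) {
      for (int i = 0; i < N; ++i)
        (carries(pop[i], sweep_pos) ? car : non).push_back(i);
      if (car.empty() || non.empty()) sel = false;
      else {
        double wc = car.size() * (1.0 + s);
        p_car = wc / (wc + non.size());
      }
    }
    auto pick = [&]() -> int {
      if (!sel) return runif_int(N);
      if (unif_rand() < p_car) return car[runif_int((int)car.size())];
      return non[runif_int((int)non.size())];
    };
    Pop next;
    next.reserve(n_next);
    double xlam = rho * (double)L;
    for (int i = 0; i < n_next; ++i) {
      int p1 = pick();
      int k = (int)R::rpois(xlam);
      Hap child;
      if (k == 0) {
        child = pop[p1];
      } else {
        int p2 = pick();
        std::vector<uint32_t> brk(k);
        for (int j = 0; j < k; ++j) {
          uint32_t b = 2 + (uint32_t)(unif_rand() * (L - 1));
          brk[j] = std::min(b, L);
        }
        std::sort(brk.begin(), brk.end());
        child = recombine(pop[p1], pop[p2], brk, L);
      }
      mutate(child);
      next.push_back(std::move(child));
    }
    pop.swap(next);
  }

  // remove mutations fixed in every population; rebuild active set
  void purge(std::vector<Pop *> &pops) {
    std::unordered_map<uint32_t, size_t> fixed_in;
    std::unordered_set<uint32_t> present;
    for (Pop *pp : pops) {
      std::unordered_map<uint32_t, size_t> cnt;
      for (const Hap &h : *pp)
        for (uint32_t p : h) cnt[p]++;
      for (auto &kv : cnt) {
        present.insert(kv.first);
        if (kv.second == pp->size()) fixed_in[kv.first]++;
      }
    }
    std::unordered_set<uint32_t> drop;
    for (auto &kv : fixed_in)
      if (kv.second == pops.size() && kv.first != sweep_pos)
        drop.insert(kv.first);
    if (!drop.empty()) {
      for (Pop *pp : pops)
        for (Hap &h : *pp) {
          Hap keep;
          keep.reserve(h.size());
          for (uint32_t p : h)
            if (!drop.count(p)) keep.push_back(p);
          h.swap(keep);
        }
    }
    active.clear();
    for (uint32_t p : present)
      if (!drop.count(p)) active.insert(p);
  }
};

static int count_carriers(const Pop &pop, uint32_t pos) {
  int c = 0;
  for (const Hap &h : pop) c += carries(h, pos);
  return c;
}

static std::vector<int> sample_wo_repl(int N, int k) {
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(N - i);
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(double L_, int N_anc, int N_out, int N_hi, int N_lo,
                int t_out, int t_hilo, int burnin, double mu, double rho,
                double sweep_pos_, double s, int t_sweep,
                bool condition_est, int retry_cap,
                int nsamp_hi, int nsamp_lo, int nsamp_out) {
  uint32_t L = (uint32_t)L_;
  Engine eng{L, mu, rho, (uint32_t)sweep_pos_, {}};
  bool has_out = t_out > 0, has_split = t_hilo > 0, has_sweep = eng.sweep_pos > 0;
  if (has_sweep && (eng.sweep_pos < 1 || eng.sweep_pos > L))
    stop("sweep position outside the simulated region");
  if (has_out && has_split && t_out <= t_hilo)
    stop("t_out_split must exceed t_hilo_split");

  Pop anc(N_anc), hi, lo, out;
  // burn-in of the ancestral population
  for (int g = 0; g < burnin; ++g) {
    std::vector<Pop *> ps{&anc};
    eng.step(anc, N_anc, false, 0.0);
    if (g % 64 == 63) eng.purge(ps);
  }

  int T = has_out ? t_out : (has_split ? t_hilo : 0);
  bool sweep_on = false, sweep_lost_final = false;
  int retries = 0, fixation_gen = -1;
  // checkpoint state for restart-on-loss
  Pop cp_anc, cp_hi, cp_lo, cp_out;
  std::unordered_set<uint32_t> cp_active;
  bool cp_valid = false;
  int t = T;
  while (t > 0) {
    if (has_out && t == t_out) { out = anc; }
    if (has_split && t == t_hilo) { hi = anc; lo = anc; anc.clear(); }
    bool anc_alive = !(has_split && t <= t_hilo);
    if (has_sweep && t == t_sweep) {
      Pop &target = has_split ? hi : anc;
      if (!cp_valid) {
        cp_anc = anc; cp_hi = hi; cp_lo = lo; cp_out = out;
        cp_active = eng.active;
        cp_valid = true;
      }
      Hap &th = target[runif_int((int)target.size())];
      th.insert(std::lower_bound(th.begin(), th.end(), eng.sweep_pos),
                eng.sweep_pos);
      sweep_on = true;
    }
    std::vector<Pop *> ps;
    if (anc_alive) { eng.step(anc, N_anc, sweep_on && !has_split, s); ps.push_back(&anc); }
    if (has_out && t <= t_out) { eng.step(out, N_out, false, 0.0); ps.push_back(&out); }
    if (has_split && t <= t_hilo) {
      eng.step(hi, N_hi, sweep_on, s);
      eng.step(lo, N_lo, false, 0.0);
      ps.push_back(&hi); ps.push_back(&lo);
    }
    if (sweep_on) {
      Pop &target = has_split ? hi : anc;
      int c = count_carriers(target, eng.sweep_pos);
      if (c == 0) {
        if (condition_est) {
          if (++retries > retry_cap)
            stop("sweep failed to establish within the retry cap (%d)", retry_cap);
          anc = cp_anc; hi = cp_hi; lo = cp_lo; out = cp_out;
          eng.active = cp_active;
          sweep_on = false;
          fixation_gen = -1;
          t = t_sweep;  // re-enter injection at t_sweep
          continue;
        } else {
          sweep_on = false;
          sweep_lost_final = true;
        }
      } else if (c == (int)target.size() && fixation_gen < 0) {
        fixation_gen = t - 1;
      }
    }
    if (t % 64 == 0 && !ps.empty()) eng.purge(ps);
    --t;
  }

  // final populations at generation 0
  std::vector<Pop *> finals;
  std::vector<std::string> labels;
  std::vector<int> nsamp;
  if (has_split) {
    finals.push_back(&hi); labels.push_back("hi"); nsamp.push_back(nsamp_hi);
    finals.push_back(&lo); labels.push_back("lo"); nsamp.push_back(nsamp_lo);
  } else {
    finals.push_back(&anc); labels.push_back("hi"); nsamp.push_back(nsamp_hi);
  }
  if (has_out) {
    finals.push_back(&out); labels.push_back("out"); nsamp.push_back(nsamp_out);
  }
  eng.purge(finals);
  // population-level beneficial-allele frequencies
  NumericVector ben_freq(finals.size());
  for (size_t i = 0; i < finals.size(); ++i)
    ben_freq[i] = has_sweep
        ? count_carriers(*finals[i], eng.sweep_pos) / (double)finals[i]->size()
        : 0.0;

  // draw samples without replacement
  std::vector<Hap *> sampled;
  std::vector<int> sampled_pop;
  for (size_t i = 0; i < finals.size(); ++i) {
    int k = nsamp[i];
    if (k > (int)finals[i]->size())
      stop("sample size exceeds population size for population %d", (int)i + 1);
    std::vector<int> pick = sample_wo_repl((int)finals[i]->size(), k);
    std::sort(pick.begin(), pick.end());
    for (int j : pick) {
      sampled.push_back(&(*finals[i])[j]);
      sampled_pop.push_back((int)i);
    }
  }
  int H = (int)sampled.size();
  // pooled-sample segregating sites
  std::unordered_map<uint32_t, int> cnt;
  for (Hap *h : sampled)
    for (uint32_t p : *h) cnt[p]++;
  std::vector<uint32_t> sites;
  for (auto &kv : cnt)
    if (kv.second > 0 && kv.second < H) sites.push_back(kv.first);
  std::sort(sites.begin(), sites.end());
  std::unordered_map<uint32_t, int> site_col;
  for (size_t j = 0; j < sites.size(); ++j) site_col[sites[j]] = (int)j;
  IntegerMatrix M(H, (int)sites.size());
  for (int i = 0; i < H; ++i)
    for (uint32_t p : *sampled[i]) {
      auto it = site_col.find(p);
      if (it != site_col.end()) M(i, it->second) = 1;
    }
  IntegerVector pos((int)sites.size());
  for (size_t j = 0; j < sites.size(); ++j) pos[(int)j] = (int)sites[j];

  return List::create(
      _["positions"] = pos, _["matrix"] = M,
      _["pop_index"] = IntegerVector(sampled_pop.begin(), sampled_pop.end()),
      _["pop_labels"] = CharacterVector(labels.begin(), labels.end()),
      _["beneficial_freq"] = ben_freq,
      _["fixation_generation"] = fixation_gen,
      _["retries"] = retries,
      _["sweep_lost"] = sweep_lost_final);
}

// ---------------------------------------------------------------------------
// EHH integration core: per-site integrated EHH for the ancestral and derived
// allele classes, trapezoid over physical distance, stopping at the first
// marker where EHH < cutoff; flags border truncation and oversized gaps.

// flag bits
static const int FLAG_BORDER = 1, FLAG_GAP = 2, FLAG_FEWCARR = 4,
                 FLAG_UNPOL = 8;

// EHH among `rows` carriers after refining haplotype groups marker by marker.
// Returns integral contribution of one side and sets flag bits.
static double side_ihh(const IntegerMatrix &hap, const IntegerVector &pos,
                       const std::vector<int> &rows, int core, int dir,
                       double cutoff, double maxgap, int *flag) {
  int n = (int)rows.size();
  int S = hap.ncol();
  double denom = n * (n - 1.0) / 2.0;
  std::vector<int> grp(n, 0);
  int ngrp = 1;
  double ehh_prev = 1.0;
  double integral = 0.0;
  int k = core + dir;
  int prev = core;
  std::vector<int> remap;
  while (k >= 0 && k < S) {
    double d = std::abs((double)pos[k] - (double)pos[prev]);
    if (d > maxgap) { *flag |= FLAG_GAP; return integral; }
    // refine groups by allele at marker k
    remap.assign(2 * ngrp, -1);
    int nn = 0;
    for (int i = 0; i < n; ++i) {
      int key = grp[i] * 2 + hap(rows[i], k);
      if (remap[key] < 0) remap[key] = nn++;
      grp[i] = remap[key];
    }
    ngrp = nn;
    std::vector<int> sz(ngrp, 0);
    for (int i = 0; i < n; ++i) sz[grp[i]]++;
    double hom = 0.0;
    for (int g = 0; g < ngrp; ++g) hom += sz[g] * (sz[g] - 1.0) / 2.0;
    double ehh = hom / denom;
    integral += 0.5 * (ehh_prev + ehh) * d;
    if (ehh < cutoff) return integral;  // stopped normally
    ehh_prev = ehh;
    prev = k;
    k += dir;
  }
  *flag |= FLAG_BORDER;
  return integral;
}

// [[Rcpp::export(name = ".ihh_scan_cpp")]]
List ihh_scan_cpp(IntegerMatrix hap, IntegerVector pos, IntegerVector anc,
                  double cutoff, double maxgap) {
  int S = hap.ncol(), H = hap.nrow();
  NumericVector ihh_a(S, NA_REAL), ihh_d(S, NA_REAL);
  IntegerVector flags(S, 0);
  for (int j = 0; j < S; ++j) {
    if (anc[j] == NA_INTEGER) { flags[j] |= FLAG_UNPOL; continue; }
    int anc_allele = anc[j], der_allele = 1 - anc[j];
    std::vector<int> rows_a, rows_d;
    for (int i = 0; i < H; ++i)
      (hap(i, j) == anc_allele ? rows_a : rows_d).push_back(i);
    if ((int)rows_a.size() < 2 || (int)rows_d.size() < 2) {
      flags[j] |= FLAG_FEWCARR;
      continue;
    }
    int fl = 0;
    double ia = side_ihh(hap, pos, rows_a, j, -1, cutoff, maxgap, &fl) +
                side_ihh(hap, pos, rows_a, j, +1, cutoff, maxgap, &fl);
    double id = side_ihh(hap, pos, rows_d, j, -1, cutoff, maxgap, &fl) +
                side_ihh(hap, pos, rows_d, j, +1, cutoff, maxgap, &fl);
    ihh_a[j] = ia;
    ihh_d[j] = id;
    flags[j] = fl;
  }
  return List::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["flags"] = flags);
}
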