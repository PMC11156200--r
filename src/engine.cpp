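#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic hashing for seeded random GP maps.
//
// A random GP map assigns every genotype an independent phenotype draw from a
// fixed spectrum.  To make the map lazily evaluable over K^L genotypes the
// draw is a pure function of (genotype, map seed): the symbol sequence is
// mixed through splitmix64 and the resulting uniform deviate is inverted
// through the cumulative spectrum.  The identical code path is used when the
// map is queried from R and when the simulation engine mutates genotypes, so
// both views of the map agree bit-for-bit.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double geno_hash_unit(const std::vector<int>& sym, uint64_t seed_mix) {
  uint64_t h = 0xcbf29ce484222325ULL ^ seed_mix;
  for (size_t j = 0; j < sym.size(); ++j) {
    h = splitmix64(h ^ (uint64_t)(sym[j] + 1) ^ ((uint64_t)(j + 1) << 32));
  }
  return (double)(splitmix64(h) >> 11) * (1.0 / 9007199254740992.0); /* 2^-53 */
}

static inline int draw_from_cum(double u, const std::vector<double>& cum) {
  // first index k (0-based) with u < cum[k]; cum is nondecreasing, last ~= 1
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u < cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export(name = ".rmap_phenotype_idx")]]
IntegerVector rmap_phenotype_idx(IntegerMatrix symbols0, double map_seed,
                                 NumericVector cum_phi) {
  uint64_t seed_mix = splitmix64((uint64_t)map_seed);
  std::vector<double> cum(cum_phi.begin(), cum_phi.end());
  int n = symbols0.nrow(), L = symbols0.ncol();
  IntegerVector out(n);
  std::vector<int> sym(L);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < L; ++j) sym[j] = symbols0(i, j);
    out[i] = draw_from_cum(geno_hash_unit(sym, seed_mix), cum) + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Unified Wright-Fisher engine.
//
// Haploid population of fixed size N; every generation N offspring are drawn
// multinomially with probabilities proportional to parent count x parent
// fitness; each offspring then mutates at every site independently with
// probability u (the number of mutated offspring is Binomial(N, 1-(1-u)^L)
// and the per-offspring site count is a zero-truncated Binomial(L, u)).
//
// Genotype resolution modes:
//   mode 0 ("view")   : genotypes are rows of an explicit node table with a
//                       phenotype id each; interior nodes carry a full
//                       adjacency row (L*(K-1) neighbour node ids,
//                       position-major).  Mutating a node without adjacency
//                       turns the offspring into a phenotype-only individual
//                       whose later mutations draw from a mean-spectrum row.
//   mode 1 ("full")   : the whole K^L space is materialised as a phenotype
//                       vector indexed by the base-K genotype code; neighbour
//                       codes are computed arithmetically.
//   mode 2 ("random") : phenotypes are hash draws from cum_phi (seeded random
//                       map); neighbour codes arithmetic, phenotypes cached.
//
// Keys: node index (mode 0) or base-K code (modes 1-2), stored in uint64.
// Phenotype-only individuals (mode 0 fallback) are stored separately.
// ---------------------------------------------------------------------------

struct EventLogC {
  std::vector<double> gen;
  std::vector<double> parent_key;   // NA for phenotype-only parents
  std::vector<double> child_key;    // NA for phenotype-only children
  std::vector<int> parent_phen;
  std::vector<int> child_phen;
};

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(int mode,
                IntegerVector phen,          // per node (mode 0) / per code (mode 1)
                IntegerMatrix adj,           // mode 0: nodes x D, 1-based ids, 0 = unknown
                LogicalVector has_adj,       // mode 0
                NumericVector cum_phi,       // mode 2
                double map_seed,             // mode 2
                int L, int K,
                NumericVector fitness_phen,  // fitness by phenotype id (1-based)
                NumericVector fitness_node,  // mode 0: per-node fitness (len 0 => by phenotype)
                NumericMatrix spectrum,      // P x P fallback rows; 0x0 => fallback is an error
                NumericVector init_key, IntegerVector init_n,
                int N, double u,
                double generations,
                IntegerVector tracked,       // phenotype ids to log
                int initial_phen,
                bool stop_at_fixation, double fix_threshold,
                bool stop_when_monomorphic,
                bool track_substitutions,
                int max_events) {
  const int P = fitness_phen.size();
  const int D = L * (K - 1);
  uint64_t seed_mix = splitmix64((uint64_t)map_seed);
  std::vector<double> cum(cum_phi.begin(), cum_phi.end());
  std::unordered_map<uint64_t, int> phen_cache; // mode 2

  std::vector<bool> is_tracked(P + 1, false);
  for (int i = 0; i < tracked.size(); ++i)
    if (tracked[i] >= 1 && tracked[i] <= P) is_tracked[tracked[i]] = true;

  const bool have_spectrum = spectrum.nrow() == P && P > 0;
  std::vector<std::vector<double>> spec_cum;
  if (have_spectrum) {
    spec_cum.assign(P, std::vector<double>(P));
    for (int p = 0; p < P; ++p) {
      double c = 0;
      for (int q = 0; q < P; ++q) { c += spectrum(p, q); spec_cum[p][q] = c; }
    }
  }

  // zero-truncated Binomial(L, u) cumulative table for the per-offspring
  // number of mutated sites, conditioned on >= 1
  double pmut = 1.0 - std::pow(1.0 - u, (double)L);
  std::vector<double> cum_sites(L);
  if (pmut > 0) {
    double c = 0;
    for (int k = 1; k <= L; ++k) {
      c += R::dbinom((double)k, (double)L, u, 0) / pmut;
      cum_sites[k - 1] = c;
    }
    cum_sites[L - 1] = 1.0;
  }

  // population state
  std::map<uint64_t, int> pop;                 // genotype-keyed individuals
  std::vector<int> pop_phen_only(P + 1, 0);    // phenotype-only individuals
  for (int i = 0; i < init_key.size(); ++i)
    pop[(uint64_t)init_key[i]] += init_n[i];

  std::vector<double> powK(L);
  powK[0] = 1.0;
  for (int j = 1; j < L; ++j) powK[j] = powK[j - 1] * K;

  auto phen_of_key = [&](uint64_t key) -> int {
    if (mode == 0 || mode == 1) return phen[(R_xlen_t)key];
    auto it = phen_cache.find(key);
    if (it != phen_cache.end()) return it->second;
    std::vector<int> sym(L);
    uint64_t c = key;
    for (int j = 0; j < L; ++j) { sym[j] = (int)(c % (uint64_t)K); c /= (uint64_t)K; }
    int p = draw_from_cum(geno_hash_unit(sym, seed_mix), cum) + 1;
    phen_cache.emplace(key, p);
    return p;
  };
  auto fitness_of_key = [&](uint64_t key) -> double {
    if (mode == 0 && fitness_node.size() > 0) return fitness_node[(R_xlen_t)key];
    return fitness_phen[phen_of_key(key) - 1];
  };

  EventLogC ev;
  std::vector<double> fix_gen; std::vector<int> fix_phen;
  std::vector<double> sub_gen; std::vector<double> sub_key;
  bool fixation_recorded = false;
  uint64_t last_sub_key = 0; bool have_sub = false;
  std::string error_msg = "";
  double error_gen = -1;
  bool overflow = false;

  // scratch buffers reused across generations
  std::vector<uint64_t> cls_key; std::vector<int> cls_phen_only;
  std::vector<int> cls_count; std::vector<double> cls_w;
  std::vector<double> probs; std::vector<int> off;

  double gen = 0;
  for (gen = 0; gen < generations; gen += 1.0) {
    // ---- collect parent classes -------------------------------------------
    cls_key.clear(); cls_phen_only.clear(); cls_count.clear(); cls_w.clear();
    double W = 0;
    for (auto& kv : pop) {
      if (kv.second <= 0) continue;
      cls_key.push_back(kv.first); cls_phen_only.push_back(0);
      cls_count.push_back(kv.second);
      double w = kv.second * fitness_of_key(kv.first);
      cls_w.push_back(w); W += w;
    }
    for (int p = 1; p <= P; ++p) {
      if (pop_phen_only[p] <= 0) continue;
      cls_key.push_back(0); cls_phen_only.push_back(p);
      cls_count.push_back(pop_phen_only[p]);
      double w = pop_phen_only[p] * fitness_phen[p - 1];
      cls_w.push_back(w); W += w;
    }
    int nc = (int)cls_key.size();
    if (W <= 0) { error_msg = "no viable individuals left"; error_gen = gen; break; }

    // ---- selection: multinomial offspring counts --------------------------
    off.assign(nc, 0);
    if (nc == 1) {
      off[0] = N;
    } else {
      probs.assign(nc, 0.0);
      for (int i = 0; i < nc; ++i) probs[i] = cls_w[i] / W;
      rmultinom(N, probs.data(), nc, off.data());
    }

    // ---- mutation ---------------------------------------------------------
    int m = (pmut > 0) ? (int)R::rbinom((double)N, pmut) : 0;
    // children produced by mutation, added after the draw
    std::vector<std::pair<uint64_t, int>> child_geno;   // key, phen
    std::vector<int> child_phen_only;
    int remaining = N;
    for (int t = 0; t < m; ++t) {
      // pick one not-yet-mutated offspring uniformly
      double r = unif_rand() * remaining;
      int ci = 0; double acc = 0;
      for (; ci < nc; ++ci) { acc += off[ci]; if (r < acc) break; }
      if (ci >= nc) ci = nc - 1;
      off[ci] -= 1; remaining -= 1;

      int k_sites = draw_from_cum(unif_rand(), cum_sites) + 1;
      int parent_phen_id, child_phen_id;
      bool child_is_geno; uint64_t child_key_v = 0;
      double parent_key_out = NA_REAL;

      if (cls_phen_only[ci] > 0) {
        // phenotype-only parent: chain of spectrum draws
        parent_phen_id = cls_phen_only[ci];
        if (!have_spectrum) { error_msg = "mutation on phenotype-only individual without a spectrum"; error_gen = gen; goto done; }
        int p = parent_phen_id;
        for (int s = 0; s < k_sites; ++s) p = draw_from_cum(unif_rand(), spec_cum[p - 1]) + 1;
        child_phen_id = p; child_is_geno = false;
      } else {
        uint64_t g = cls_key[ci];
        parent_phen_id = phen_of_key(g);
        parent_key_out = (double)g;
        child_is_geno = true;
        if (mode == 0) {
          int p_cur = parent_phen_id; bool fell_back = false;
          for (int s = 0; s < k_sites; ++s) {
            if (!fell_back && has_adj[(R_xlen_t)g]) {
              int d = (int)(unif_rand() * D); if (d >= D) d = D - 1;
              int g2 = adj((R_xlen_t)g, d);
              if (g2 > 0) { g = (uint64_t)(g2 - 1); p_cur = phen[(R_xlen_t)g]; continue; }
            }
            // node without adjacency (or unknown neighbour): phenotype fallback
            if (!have_spectrum) { error_msg = "mutation outside the materialised view without a spectrum"; error_gen = gen; goto done; }
            fell_back = true;
            p_cur = draw_from_cum(unif_rand(), spec_cum[p_cur - 1]) + 1;
          }
          if (fell_back) { child_is_geno = false; child_phen_id = p_cur; }
          else { child_key_v = g; child_phen_id = p_cur; }
        } else {
          for (int s = 0; s < k_sites; ++s) {
            int site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
            int cur = (int)((uint64_t)(g / (uint64_t)powK[site]) % (uint64_t)K);
            int r2 = (int)(unif_rand() * (K - 1)); if (r2 >= K - 1) r2 = K - 2;
            int nsym = r2 + (r2 >= cur ? 1 : 0);
            g = g + (uint64_t)((int64_t)(nsym - cur) * (int64_t)powK[site]);
          }
          child_key_v = g; child_phen_id = phen_of_key(g);
        }
      }

      if (is_tracked[child_phen_id] && child_phen_id != parent_phen_id) {
        if ((int)ev.gen.size() < max_events) {
          ev.gen.push_back(gen);
          ev.parent_key.push_back(parent_key_out);
          ev.child_key.push_back(child_is_geno ? (double)child_key_v : NA_REAL);
          ev.parent_phen.push_back(parent_phen_id);
          ev.child_phen.push_back(child_phen_id);
        } else overflow = true;
      }
      if (child_is_geno) child_geno.push_back(std::make_pair(child_key_v, child_phen_id));
      else child_phen_only.push_back(child_phen_id);
    }

    // ---- commit the new generation ----------------------------------------
    pop.clear();
    std::fill(pop_phen_only.begin(), pop_phen_only.end(), 0);
    for (int i = 0; i < nc; ++i) {
      if (off[i] <= 0) continue;
      if (cls_phen_only[i] > 0) pop_phen_only[cls_phen_only[i]] += off[i];
      else pop[cls_key[i]] += off[i];
    }
    for (auto& cg : child_geno) pop[cg.first] += 1;
    for (int p : child_phen_only) pop_phen_only[p] += 1;

    // ---- fixation / substitution bookkeeping ------------------------------
    if (stop_at_fixation || stop_when_monomorphic || initial_phen > 0) {
      std::vector<int> phen_counts(P + 1, 0);
      for (auto& kv : pop) phen_counts[phen_of_key(kv.first)] += kv.second;
      for (int p = 1; p <= P; ++p) phen_counts[p] += pop_phen_only[p];
      if (initial_phen > 0 && !fixation_recorded &&
          phen_counts[initial_phen] < fix_threshold * N) {
        int winner = 0, best = -1;
        for (int p = 1; p <= P; ++p)
          if (p != initial_phen && phen_counts[p] > best) { best = phen_counts[p]; winner = p; }
        fix_gen.push_back(gen); fix_phen.push_back(winner);
        fixation_recorded = true;
        if (stop_at_fixation) { gen += 1.0; break; }
      }
      if (stop_when_monomorphic) {
        int nz = 0;
        for (int p = 1; p <= P; ++p) if (phen_counts[p] > 0) nz++;
        if (nz <= 1) { gen += 1.0; break; }
      }
    }
    if (track_substitutions) {
      // a substitution is recorded when the population becomes fully
      // monomorphic on a new genotype; in the weak-mutation regime this
      // matches the neutral molecular clock (threshold crossings below
      // full monomorphy would double-count drift flip-flops around the
      // threshold)
      for (auto& kv : pop) {
        if (kv.second == N) {
          if (!have_sub || kv.first != last_sub_key) {
            if ((int)sub_gen.size() < max_events) {
              sub_gen.push_back(gen); sub_key.push_back((double)kv.first);
            }
            last_sub_key = kv.first; have_sub = true;
          }
          break;
        }
      }
    }
  }

done:
  // final state
  std::vector<double> fin_key; std::vector<int> fin_n; std::vector<int> fin_phen;
  for (auto& kv : pop) {
    if (kv.second <= 0) continue;
    fin_key.push_back((double)kv.first); fin_n.push_back(kv.second);
    fin_phen.push_back(phen_of_key(kv.first));
  }
  IntegerVector fin_po(P);
  for (int p = 1; p <= P; ++p) fin_po[p - 1] = pop_phen_only[p];

  return List::create(
    _["event_gen"] = wrap(ev.gen),
    _["event_parent_key"] = wrap(ev.parent_key),
    _["event_child_key"] = wrap(ev.child_key),
    _["event_parent_phen"] = wrap(ev.parent_phen),
    _["event_child_phen"] = wrap(ev.child_phen),
    _["fix_gen"] = wrap(fix_gen),
    _["fix_phen"] = wrap(fix_phen),
    _["sub_gen"] = wrap(sub_gen),
    _["sub_key"] = wrap(sub_key),
    _["final_key"] = wrap(fin_key),
    _["final_n"] = wrap(fin_n),
    _["final_phen"] = wrap(fin_phen),
    _["final_phen_only"] = fin_po,
    _["generations_run"] = gen,
    _["event_overflow"] = overflow,
    _["error"] = error_msg,
    _["error_gen"] = error_gen);
}

// ---------------------------------------------------------------------------
// Average-rate engine: no genotype state at all.  Each mutation turns the
// offspring's phenotype into a draw from the spectrum row of its current
// phenotype (for the initial phenotype p0 that row is phi, whose diagonal
// entry is the robustness rho).  Identical Wright-Fisher resampling.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".avgrate_engine")]]
List avgrate_engine(NumericMatrix spectrum,     // P x P rows sum to 1
                    NumericVector fitness_phen, // length P
                    IntegerVector init_counts,  // length P
                    int N, double u, int L,
                    double generations,
                    IntegerVector tracked,
                    int initial_phen,
                    bool stop_at_fixation, double fix_threshold,
                    bool stop_when_monomorphic,
                    int max_events) {
  const int P = fitness_phen.size();
  std::vector<bool> is_tracked(P + 1, false);
  for (int i = 0; i < tracked.size(); ++i)
    if (tracked[i] >= 1 && tracked[i] <= P) is_tracked[tracked[i]] = true;

  std::vector<std::vector<double>> spec_cum(P, std::vector<double>(P));
  for (int p = 0; p < P; ++p) {
    double c = 0;
    for (int q = 0; q < P; ++q) { c += spectrum(p, q); spec_cum[p][q] = c; }
  }

  double pmut = 1.0 - std::pow(1.0 - u, (double)L);
  std::vector<double> cum_sites(L > 0 ? L : 1);
  if (pmut > 0) {
    double c = 0;
    for (int k = 1; k <= L; ++k) {
      c += R::dbinom((double)k, (double)L, u, 0) / pmut;
      cum_sites[k - 1] = c;
    }
    cum_sites[L - 1] = 1.0;
  }

  std::vector<int> counts(init_counts.begin(), init_counts.end());
  std::vector<double> ev_gen; std::vector<int> ev_parent; std::vector<int> ev_child;
  std::vector<double> fix_gen; std::vector<int> fix_phen;
  bool fixation_recorded = false, overflow = false;
  std::string error_msg = ""; double error_gen = -1;

  std::vector<double> probs(P); std::vector<int> off(P);

  double gen = 0;
  for (gen = 0; gen < generations; gen += 1.0) {
    double W = 0; int nviable = 0; int only = -1;
    for (int p = 0; p < P; ++p) {
      double w = counts[p] * fitness_phen[p];
      probs[p] = w; W += w;
      if (w > 0) { nviable++; only = p; }
    }
    if (W <= 0) { error_msg = "no viable individuals left"; error_gen = gen; break; }
    if (nviable == 1) {
      std::fill(off.begin(), off.end(), 0); off[only] = N;
    } else {
      for (int p = 0; p < P; ++p) probs[p] /= W;
      rmultinom(N, probs.data(), P, off.data());
    }

    int m = (pmut > 0) ? (int)R::rbinom((double)N, pmut) : 0;
    int remaining = N;
    std::vector<int> child_add(P, 0);
    for (int t = 0; t < m; ++t) {
      double r = unif_rand() * remaining;
      int ci = 0; double acc = 0;
      for (; ci < P; ++ci) { acc += off[ci]; if (r < acc) break; }
      if (ci >= P) ci = P - 1;
      off[ci] -= 1; remaining -= 1;
      int k_sites = draw_from_cum(unif_rand(), cum_sites) + 1;
      int p = ci + 1;
      for (int s = 0; s < k_sites; ++s) p = draw_from_cum(unif_rand(), spec_cum[p - 1]) + 1;
      if (is_tracked[p] && p != ci + 1) {
        if ((int)ev_gen.size() < max_events) {
          ev_gen.push_back(gen); ev_parent.push_back(ci + 1); ev_child.push_back(p);
        } else overflow = true;
      }
      child_add[p - 1] += 1;
    }
    for (int p = 0; p < P; ++p) counts[p] = off[p] + child_add[p];

    if (initial_phen > 0 && !fixation_recorded &&
        counts[initial_phen - 1] < fix_threshold * N) {
      int winner = 0, best = -1;
      for (int p = 1; p <= P; ++p)
        if (p != initial_phen && counts[p - 1] > best) { best = counts[p - 1]; winner = p; }
      fix_gen.push_back(gen); fix_phen.push_back(winner);
      fixation_recorded = true;
      if (stop_at_fixation) { gen += 1.0; break; }
    }
    if (stop_when_monomorphic) {
      int nz = 0;
      for (int p = 0; p < P; ++p) if (counts[p] > 0) nz++;
      if (nz <= 1) { gen += 1.0; break; }
    }
  }

  return List::create(
    _["event_gen"] = wrap(ev_gen),
    _["event_parent_phen"] = wrap(ev_parent),
    _["event_child_phen"] = wrap(ev_child),
    _["fix_gen"] = wrap(fix_gen),
    _["fix_phen"] = wrap(fix_phen),
    _["final_counts"] = wrap(counts),
    _["generations_run"] = gen,
    _["event_overflow"] = overflow,
    _["error"] = error_msg,
    _["error_gen"] = error_gen);
}
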