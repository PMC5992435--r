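// Compiled tick engine. Replays exactly the schedule implemented by the
// pure-R reference path in R/schedule.R, consuming R's random stream through
// the same draw contract (see R/rng.R), so that both paths are bit-identical
// under a shared seed for either list semantics. Trait sets are mirrored as
// 64-bit masks (values lie in 0..50) for O(1) membership tests and popcount
// overlaps.
//
// Two list semantics are supported (config list_semantics):
//   multiset (default): adoption copies any partner slot (duplicates can
//     accumulate within an agent's list), rebirth draws without exclusion,
//     and breed switching counts trait occurrences that appear in a culture
//     (> 7 occurrences qualifies).
//   set: lists stay duplicate-free — adoption copies a partner trait the
//     adopter lacks (no-op if none), rebirth excludes held values, and
//     switching requires a culture's full 8 distinct values.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int draw_int(int n) {
  // one uniform deviate mapped to 0..n-1; matches floor(runif(1) * n) in R
  double u = unif_rand();
  int j = (int)(u * (double)n);
  if (j >= n) j = n - 1;
  return j;
}

static inline uint64_t row_mask(const std::vector<int>& t, int i, int L) {
  uint64_t m = 0;
  for (int s = 0; s < L; ++s) m |= (1ull << t[(size_t)i * L + s]);
  return m;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// culture recompilation for one breed; consumes draws only on a tie at the
// 8th rank. `counts` are pooled value frequencies (occurrences); `prev` the
// previous culture (used when the breed is empty or the pool is under-full).
static void recompute_culture_cpp(const int* counts, int n_members,
                                  const int* prev, int* out) {
  if (n_members == 0) {
    for (int s = 0; s < 8; ++s) out[s] = prev[s];
    std::sort(out, out + 8);
    return;
  }
  std::vector<int> present;
  for (int v = 0; v <= 50; ++v) if (counts[v] > 0) present.push_back(v);
  std::vector<int> chosen;
  if ((int)present.size() <= 8) {
    chosen = present;
    // pad from the previous culture, highest pooled frequency first,
    // stable in the previous culture's stored order
    std::vector<int> pad;
    for (int s = 0; s < 8; ++s) {
      int v = prev[s];
      if (std::find(chosen.begin(), chosen.end(), v) == chosen.end())
        pad.push_back(v);
    }
    std::stable_sort(pad.begin(), pad.end(),
                     [&](int a, int b) { return counts[a] > counts[b]; });
    for (size_t p = 0; p < pad.size() && chosen.size() < 8; ++p)
      chosen.push_back(pad[p]);
  } else {
    std::vector<int> cnt;
    for (int v : present) cnt.push_back(counts[v]);
    std::vector<int> sorted = cnt;
    std::sort(sorted.begin(), sorted.end(), std::greater<int>());
    int thr = sorted[7];
    std::vector<int> tied;
    for (int v : present) {
      if (counts[v] > thr) chosen.push_back(v);
      else if (counts[v] == thr) tied.push_back(v);  // ascending already
    }
    int need = 8 - (int)chosen.size();
    int m = (int)tied.size();
    if (m > need) {
      for (int i = 0; i < need; ++i) {             // partial Fisher-Yates
        int j = i + draw_int(m - i);
        std::swap(tied[i], tied[j]);
      }
      tied.resize(need);
    }
    for (int v : tied) chosen.push_back(v);
  }
  std::sort(chosen.begin(), chosen.end());
  for (int s = 0; s < 8; ++s) out[s] = chosen[s];
}

// [[Rcpp::export]]
List run_ticks_cpp(IntegerMatrix traits_, IntegerVector breed_,
                   IntegerVector interactions_, IntegerVector generation_,
                   IntegerVector id_, int next_id,
                   IntegerMatrix cultures_, IntegerMatrix initial_cultures_,
                   NumericMatrix rtc, int lifespan, int n_ticks, int tick0,
                   int p_lo, int p_hi, int s_lo, int s_hi, bool multiset) {
  const int n = traits_.nrow();
  const int L = traits_.ncol();
  if (L > 51) stop("trait lists longer than the value alphabet");

  // flat row-major working copies (R matrices are column-major)
  std::vector<int> t((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) t[(size_t)i * L + s] = traits_(i, s);
  std::vector<int> breed(n), inter(n), gen(n), id(n);
  for (int i = 0; i < n; ++i) {
    breed[i] = breed_[i] - 1;                    // 0-based internally
    inter[i] = interactions_[i];
    gen[i] = generation_[i];
    id[i] = id_[i];
  }
  std::vector<uint64_t> mask(n);
  for (int i = 0; i < n; ++i) mask[i] = row_mask(t, i, L);

  int cult[4][8];
  uint64_t cmask[4], imask[4];
  for (int b = 0; b < 4; ++b) {
    cmask[b] = 0; imask[b] = 0;
    for (int s = 0; s < 8; ++s) {
      cult[b][s] = cultures_(b, s);
      cmask[b] |= (1ull << cult[b][s]);
      imask[b] |= (1ull << initial_cultures_(b, s));
    }
  }

  const int np = p_hi - p_lo + 1, ns = s_hi - s_lo + 1;
  NumericMatrix records(n_ticks, 14);
  IntegerVector adoptions(n_ticks);
  std::vector<int> ord(n), cand(n), dvals(64), poolv(L), child(L);

  for (int tick = 0; tick < n_ticks; ++tick) {
    // (a) interactions, agents in a fresh random order
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i >= 1; --i) {
      int j = draw_int(i + 1);
      std::swap(ord[i], ord[j]);
    }
    int n_adopt = 0;
    for (int pos = 0; pos < n; ++pos) {
      int i = ord[pos];
      int v = t[(size_t)i * L + draw_int(L)];
      uint64_t bit = 1ull << v;
      int nc = 0;
      for (int j = 0; j < n; ++j)
        if (j != i && (mask[j] & bit)) cand[nc++] = j;
      if (nc > 0) {
        int partner = cand[draw_int(nc)];
        double r = unif_rand();
        if (r < rtc(breed[partner], breed[i])) {
          if (multiset) {
            int slot = draw_int(L);
            int gained = t[(size_t)partner * L + draw_int(L)];
            t[(size_t)i * L + slot] = gained;
            mask[i] = row_mask(t, i, L);
            ++n_adopt;
          } else {
            uint64_t novel = mask[partner] & ~mask[i];
            int nd = 0;
            for (int v2 = 0; v2 <= 50; ++v2)
              if (novel & (1ull << v2)) dvals[nd++] = v2;
            if (nd > 0) {
              int slot = draw_int(L);
              int gained = dvals[draw_int(nd)];
              int old = t[(size_t)i * L + slot];
              t[(size_t)i * L + slot] = gained;
              mask[i] = (mask[i] & ~(1ull << old)) | (1ull << gained);
              ++n_adopt;
            }
          }
        }
      }
      ++inter[i];
    }

    // (b) culture recompilation, breeds in canonical order
    for (int b = 0; b < 4; ++b) {
      int counts[51] = {0};
      int nm = 0;
      for (int i = 0; i < n; ++i) {
        if (breed[i] != b) continue;
        ++nm;
        for (int s = 0; s < L; ++s) ++counts[t[(size_t)i * L + s]];
      }
      recompute_culture_cpp(counts, nm, cult[b], cult[b]);
      cmask[b] = 0;
      for (int s = 0; s < 8; ++s) cmask[b] |= (1ull << cult[b][s]);
    }

    // (c) breed switching, agents in index order
    for (int i = 0; i < n; ++i) {
      int matches[4], nm = 0;
      for (int b = 0; b < 4; ++b) {
        bool hit;
        if (multiset) {
          int hits = 0;
          for (int s2 = 0; s2 < L; ++s2)
            if (cmask[b] & (1ull << t[(size_t)i * L + s2])) ++hits;
          hit = hits > 7;
        } else {
          hit = (cmask[b] & ~mask[i]) == 0;
        }
        if (hit) matches[nm++] = b;
      }
      if (nm == 1) breed[i] = matches[0];
      else if (nm > 1) breed[i] = matches[draw_int(nm)];
    }

    // (d) death and rebirth, agents in index order
    for (int i = 0; i < n; ++i) {
      if (inter[i] < lifespan) continue;
      for (int s = 0; s < L; ++s) poolv[s] = t[(size_t)i * L + s];
      int n_inh = draw_int(9);
      for (int k = 0; k < n_inh; ++k) {
        int j = k + draw_int(L - k);
        std::swap(poolv[k], poolv[j]);
      }
      uint64_t chm = 0;
      for (int s = 0; s < n_inh; ++s) {
        child[s] = poolv[s];
        chm |= (1ull << child[s]);
      }
      for (int s = n_inh; s < 8; ++s) {
        int v;
        if (multiset) v = p_lo + draw_int(np);
        else do { v = p_lo + draw_int(np); } while (chm & (1ull << v));
        child[s] = v;
        chm |= (1ull << v);
      }
      for (int s = 8; s < L; ++s) {
        int v;
        if (multiset) v = s_lo + draw_int(ns);
        else do { v = s_lo + draw_int(ns); } while (chm & (1ull << v));
        child[s] = v;
        chm |= (1ull << v);
      }
      for (int s = 0; s < L; ++s) t[(size_t)i * L + s] = child[s];
      mask[i] = chm;
      ++gen[i];
      inter[i] = 0;
      id[i] = next_id++;
    }

    // record: proportions, change from t = 0 cultures, pairwise similarity
    int bc[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) ++bc[breed[i]];
    for (int b = 0; b < 4; ++b) records(tick, b) = (double)bc[b] / n;
    for (int b = 0; b < 4; ++b)
      records(tick, 4 + b) = 1.0 - popcount64(cmask[b] & imask[b]) / 8.0;
    int pc = 8;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b)
        records(tick, pc++) = popcount64(cmask[a] & cmask[b]) / 8.0;
    adoptions[tick] = n_adopt;
  }

  IntegerMatrix traits_out(n, L);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) traits_out(i, s) = t[(size_t)i * L + s];
  IntegerVector breed_out(n), inter_out(n), gen_out(n), id_out(n);
  for (int i = 0; i < n; ++i) {
    breed_out[i] = breed[i] + 1;
    inter_out[i] = inter[i];
    gen_out[i] = gen[i];
    id_out[i] = id[i];
  }
  IntegerMatrix cult_out(4, 8);
  for (int b = 0; b < 4; ++b)
    for (int s = 0; s < 8; ++s) cult_out(b, s) = cult[b][s];

  return List::create(
    _["traits"] = traits_out, _["breed"] = breed_out,
    _["interactions"] = inter_out, _["generation"] = gen_out,
    _["id"] = id_out, _["next_id"] = next_id,
    _["cultures"] = cult_out, _["records"] = records,
    _["adoptions"] = adoptions, _["tick"] = tick0 + n_ticks);
}
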