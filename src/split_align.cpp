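#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Two-segment ungapped split alignment of reads against exon-pair chimeric
// references. A read is placed end-to-end as segment A (read[0, s)) ending
// at or before the junction of a reference and segment B (read[s, L))
// starting at or after it; score = matches - mismatches = 2*matches - L.
//
// Candidate diagonals come from exact k-mer seeds shared by read and
// reference; with exhaustive = true every valid diagonal of every reference
// is enumerated instead (exact, used for small reference sets).
//
// Per reference the optimum over (dA, dB, s) is found in O(|D| * L): first
// maxA[s], the best segment-A prefix score over all diagonals compatible
// with split s, then a scan over segment-B diagonals. Ties on score are
// broken by smaller reference index (the R wrapper passes references sorted
// by ref_id), then forward orientation, then first placement in scan order.
// Reads whose best score is attained on references of two different gene
// pairs are flagged ambiguous.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;  // N and anything else: mismatches every base
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? 3 - c : 4;
  }
  return r;
}

// prefix matches along one diagonal: pref[i] = matches of read[0,i) vs
// ref[d, d+i), out-of-bounds reference positions scoring 0 (callers
// restrict segment ranges so such positions are never part of a segment).
static void diag_prefix(const std::vector<int>& read,
                        const std::vector<int>& ref,
                        int d, std::vector<int>& pref) {
  const int L = (int)read.size();
  const int Lr = (int)ref.size();
  pref.assign(L + 1, 0);
  for (int i = 0; i < L; ++i) {
    int p = d + i;
    int m = 0;
    if (p >= 0 && p < Lr) {
      m = (read[i] < 4 && read[i] == ref[p]) ? 1 : 0;
    }
    pref[i + 1] = pref[i] + m;
  }
}

struct Best {
  bool valid = false;
  int matches = -1;
  int ref = 0;
  int split = 0;
  int dA = 0;
  int dB = 0;
  bool fwd = true;
};

// [[Rcpp::export(name = ".split_align_batch")]]
DataFrame split_align_batch(CharacterVector reads,
                            CharacterVector ref_seqs,
                            IntegerVector junction_pos,
                            IntegerVector pair_group,
                            int seed_len,
                            bool exhaustive) {
  const int n_refs = ref_seqs.size();
  std::vector<std::vector<int>> refs(n_refs);
  for (int r = 0; r < n_refs; ++r) {
    refs[r] = encode(std::string(ref_seqs[r]));
  }

  // k-mer index over references (skipped in exhaustive mode)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (seed_len >= 32) ? ~0ULL
    : ((1ULL << (2 * seed_len)) - 1ULL);
  if (!exhaustive) {
    for (int r = 0; r < n_refs; ++r) {
      const std::vector<int>& ref = refs[r];
      uint64_t h = 0;
      int run = 0;  // length of current N-free suffix
      for (int p = 0; p < (int)ref.size(); ++p) {
        if (ref[p] >= 4) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)ref[p]) & mask;
        if (++run >= seed_len) {
          index[h].push_back(std::make_pair(r, p - seed_len + 1));
        }
      }
    }
  }

  std::vector<int> out_read, out_ref, out_split, out_mA, out_mB;
  std::vector<int> out_aend, out_bstart;
  std::vector<bool> out_fwd, out_amb;

  std::vector<int> prefB, maxA, argA;
  std::vector<std::vector<int>> prefA_store;

  for (int q = 0; q < reads.size(); ++q) {
    std::string rs = std::string(reads[q]);
    std::vector<int> fwd = encode(rs);
    const int L = (int)fwd.size();
    if (L < 2) continue;
    std::vector<int> rev = revcomp_codes(fwd);

    Best best;
    std::set<int> best_groups;

    for (int orient = 0; orient < 2; ++orient) {
      const std::vector<int>& read = (orient == 0) ? fwd : rev;

      // candidate diagonals per reference, sorted by (ref, diagonal)
      std::vector<std::pair<int, int>> cand;
      if (exhaustive) {
        for (int r = 0; r < n_refs; ++r) {
          const int Lr = (int)refs[r].size();
          const int J = junction_pos[r];
          int lo = std::min(0, J - L + 1);
          int hi = std::max(J - 1, Lr - L);
          for (int d = lo; d <= hi; ++d) cand.push_back({r, d});
        }
      } else {
        uint64_t h = 0;
        int run = 0;
        std::set<std::pair<int, int>> seen;
        for (int i = 0; i < L; ++i) {
          if (read[i] >= 4) { run = 0; h = 0; continue; }
          h = ((h << 2) | (uint64_t)read[i]) & mask;
          if (++run >= seed_len) {
            auto it = index.find(h);
            if (it == index.end()) continue;
            int rpos = i - seed_len + 1;
            for (const auto& pr : it->second) {
              seen.insert({pr.first, pr.second - rpos});
            }
          }
        }
        cand.assign(seen.begin(), seen.end());
      }

      size_t a = 0;
      while (a < cand.size()) {
        size_t b = a;
        const int r = cand[a].first;
        while (b < cand.size() && cand[b].first == r) ++b;
        const std::vector<int>& ref = refs[r];
        const int Lr = (int)ref.size();
        const int J = junction_pos[r];
        const size_t nd = b - a;

        // prefix-match arrays for every candidate diagonal
        prefA_store.resize(nd);
        for (size_t k = 0; k < nd; ++k) {
          diag_prefix(read, ref, cand[a + k].second, prefA_store[k]);
        }

        // maxA[s]: best segment-A score over diagonals dA with
        // 0 <= dA <= J - s; argA[s] records the smallest such dA's index
        maxA.assign(L, -1);
        argA.assign(L, -1);
        for (size_t k = 0; k < nd; ++k) {
          const int dA = cand[a + k].second;
          if (dA < 0 || dA > J - 1) continue;
          const std::vector<int>& pa = prefA_store[k];
          const int smax = std::min(L - 1, J - dA);
          for (int s = 1; s <= smax; ++s) {
            if (pa[s] > maxA[s]) { maxA[s] = pa[s]; argA[s] = (int)k; }
          }
        }

        // scan segment-B diagonals
        Best ref_best;
        for (size_t k = 0; k < nd; ++k) {
          const int dB = cand[a + k].second;
          if (dB + L > Lr || dB + L <= J) continue;
          const std::vector<int>& pb = prefA_store[k];
          const int slo = std::max(1, J - dB);
          for (int s = slo; s <= L - 1; ++s) {
            if (maxA[s] < 0) continue;
            const int m = maxA[s] + (pb[L] - pb[s]);
            if (!ref_best.valid || m > ref_best.matches) {
              ref_best.valid = true;
              ref_best.matches = m;
              ref_best.split = s;
              ref_best.dA = cand[a + argA[s]].second;
              ref_best.dB = dB;
            }
          }
        }

        if (ref_best.valid) {
          ref_best.ref = r;
          ref_best.fwd = (orient == 0);
          if (!best.valid || ref_best.matches > best.matches) {
            best = ref_best;
            best_groups.clear();
            best_groups.insert(pair_group[r]);
          } else if (ref_best.matches == best.matches) {
            best_groups.insert(pair_group[r]);
            const bool tie_better = (r < best.ref) ||
              (r == best.ref && orient == 0 && !best.fwd);
            if (tie_better) best = ref_best;
          }
        }
        a = b;
      }
    }

    if (best.valid) {
      out_read.push_back(q + 1);
      out_ref.push_back(best.ref + 1);
      out_split.push_back(best.split);
      const std::vector<int>& read = best.fwd ? fwd : rev;
      std::vector<int> pa, pb2;
      diag_prefix(read, refs[best.ref], best.dA, pa);
      diag_prefix(read, refs[best.ref], best.dB, pb2);
      out_mA.push_back(pa[best.split]);
      out_mB.push_back(pb2[L] - pb2[best.split]);
      out_aend.push_back(best.dA + best.split);
      out_bstart.push_back(best.dB + best.split);
      out_fwd.push_back(best.fwd);
      out_amb.push_back(best_groups.size() >= 2);
    }
  }

  return DataFrame::create(
    _["read"] = out_read,
    _["ref"] = out_ref,
    _["split"] = out_split,
    _["a_ref_end"] = out_aend,
    _["b_ref_start"] = out_bstart,
    _["matches_a"] = out_mA,
    _["matches_b"] = out_mB,
    _["forward"] = out_fwd,
    _["ambiguous"] = out_amb
  );
}
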