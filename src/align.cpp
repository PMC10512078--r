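#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Alignment cost model: match 0, mismatch / insertion (extra read base) /
// deletion (extra reference base) carry positive integer costs. Alignments are
// semi-global: the read (or read segment) is consumed in full, the reference
// start and end are free. Reads running off a reference end are absorbed as
// terminal insertions, which the coverage filter then penalizes.

struct SgResult {
  int cost;
  int ref_start;   // 0-based
  int ref_end;     // half-open
  int matches;
  int mismatches;
  int insertions;  // read bases not aligned to reference
  int deletions;   // reference bases skipped inside the alignment
  bool ok;
};

static SgResult semiglobal_tb(const std::string& read, const std::string& ref,
                              int mm, int ins, int del) {
  const int L = (int)read.size(), n = (int)ref.size();
  SgResult res; res.ok = false;
  if (L == 0) return res;
  // D[i][j]: min cost aligning read[0..i) ending exactly at ref position j.
  std::vector<int> prev(n + 1), cur(n + 1);
  // moves: 0 = diag, 1 = up (insertion), 2 = left (deletion)
  std::vector<unsigned char> tb((size_t)(L + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) prev[j] = 0;  // free start anywhere
  for (int i = 1; i <= L; ++i) {
    cur[0] = prev[0] + ins;
    tb[(size_t)i * (n + 1)] = 1;
    for (int j = 1; j <= n; ++j) {
      int cd = prev[j - 1] + (read[i - 1] == ref[j - 1] ? 0 : mm);
      int cu = prev[j] + ins;
      int cl = cur[j - 1] + del;
      int best = cd; unsigned char mv = 0;
      if (cu < best) { best = cu; mv = 1; }
      if (cl < best) { best = cl; mv = 2; }
      cur[j] = best;
      tb[(size_t)i * (n + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  // best end column (prev holds row L after final swap)
  int bj = 0, bc = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] < bc) { bc = prev[j]; bj = j; }
  // traceback
  int i = L, j = bj;
  int matches = 0, mismatches = 0, insertions = 0, deletions = 0;
  while (i > 0) {
    unsigned char mv = tb[(size_t)i * (n + 1) + j];
    if (mv == 0) {
      if (read[i - 1] == ref[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (mv == 1) {
      ++insertions; --i;
    } else {
      ++deletions; --j;
    }
  }
  res.cost = bc; res.ref_start = j; res.ref_end = bj;
  res.matches = matches; res.mismatches = mismatches;
  res.insertions = insertions; res.deletions = deletions;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_semiglobal(std::string read, std::string ref,
                    int mismatch_cost, int insertion_cost, int deletion_cost) {
  SgResult r = semiglobal_tb(read, ref, mismatch_cost, insertion_cost, deletion_cost);
  return List::create(_["cost"] = r.cost,
                      _["ref_start"] = r.ref_start,
                      _["ref_end"] = r.ref_end,
                      _["matches"] = r.matches,
                      _["mismatches"] = r.mismatches,
                      _["insertions"] = r.insertions,
                      _["deletions"] = r.deletions);
}

// Exact-seed candidate diagonals of `read` against `ref`.
static std::vector<int> seed_diagonals(const std::string& read, const std::string& ref,
                                       int k) {
  std::vector<int> diags;
  const int L = (int)read.size(), n = (int)ref.size();
  if (n < k || L < k) return diags;
  std::vector<int> offs;
  for (int o = 0; o + k <= L; o += k) offs.push_back(o);
  if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
  for (int o : offs) {
    size_t pos = ref.find(read.substr(o, k), 0);
    while (pos != std::string::npos) {
      diags.push_back((int)pos - o);
      pos = ref.find(read.substr(o, k), pos + 1);
    }
  }
  std::sort(diags.begin(), diags.end());
  // merge diagonals closer than 8 (same candidate locus under small indels)
  std::vector<int> merged;
  for (int d : diags) {
    if (merged.empty() || d - merged.back() > 8) merged.push_back(d);
  }
  return merged;
}

// Seed-and-extend alignment of one (oriented) read against a set of reference
// sequences. Returns every candidate locus alignment; filtering on coverage /
// identity and hit capping happen in R.
// [[Rcpp::export]]
DataFrame cpp_align_read(std::string read, CharacterVector refs,
                         int mismatch_cost, int insertion_cost, int deletion_cost,
                         int seed_k, int pad) {
  const int L = (int)read.size();
  std::vector<int> target, rstart, rend, cost, matches, mismatches, insertions, deletions;
  for (int t = 0; t < refs.size(); ++t) {
    std::string ref = as<std::string>(refs[t]);
    std::vector<int> diags = seed_diagonals(read, ref, seed_k);
    std::vector<std::pair<int,int>> seen;  // (ref_start) dedupe
    for (int d : diags) {
      int w0 = std::max(0, d - pad);
      int w1 = std::min((int)ref.size(), d + L + pad);
      if (w1 <= w0) continue;
      SgResult r = semiglobal_tb(read, ref.substr(w0, w1 - w0),
                                 mismatch_cost, insertion_cost, deletion_cost);
      if (!r.ok) continue;
      int gs = w0 + r.ref_start, ge = w0 + r.ref_end;
      bool dup = false;
      for (auto& p : seen) {
        if (p.first == t && std::abs(p.second - gs) <= 4) { dup = true; break; }
      }
      if (dup) continue;
      seen.push_back(std::make_pair(t, gs));
      target.push_back(t + 1);
      rstart.push_back(gs); rend.push_back(ge);
      cost.push_back(r.cost);
      matches.push_back(r.matches); mismatches.push_back(r.mismatches);
      insertions.push_back(r.insertions); deletions.push_back(r.deletions);
    }
  }
  return DataFrame::create(_["target"] = target,
                           _["ref_start"] = rstart, _["ref_end"] = rend,
                           _["cost"] = cost, _["matches"] = matches,
                           _["mismatches"] = mismatches,
                           _["insertions"] = insertions,
                           _["deletions"] = deletions);
}

// Prefix/suffix best alignment cost profiles for split mapping. For each
// reference t and each split point s: pref_cost[s+1, t] is the best cost of a
// semi-global alignment of read[0..s) into t (pref_end the reference position
// where it ends), suf_cost[s+1, t] the best cost of read[s..L) into t
// (suf_start where it begins).
// [[Rcpp::export]]
List cpp_split_costs(std::string read, CharacterVector refs,
                     int mismatch_cost, int insertion_cost, int deletion_cost) {
  const int L = (int)read.size();
  const int nt = refs.size();
  IntegerMatrix pref_cost(L + 1, nt), pref_end(L + 1, nt);
  IntegerMatrix suf_cost(L + 1, nt), suf_start(L + 1, nt);
  for (int t = 0; t < nt; ++t) {
    std::string ref = as<std::string>(refs[t]);
    const int n = (int)ref.size();
    std::vector<int> prev(n + 1), cur(n + 1);
    // forward pass: row minima give prefix costs
    for (int j = 0; j <= n; ++j) prev[j] = 0;
    pref_cost(0, t) = 0; pref_end(0, t) = 0;
    for (int i = 1; i <= L; ++i) {
      cur[0] = prev[0] + insertion_cost;
      int rm = cur[0], rj = 0;
      for (int j = 1; j <= n; ++j) {
        int cd = prev[j - 1] + (read[i - 1] == ref[j - 1] ? 0 : mismatch_cost);
        int cu = prev[j] + insertion_cost;
        int cl = cur[j - 1] + deletion_cost;
        int best = cd;
        if (cu < best) best = cu;
        if (cl < best) best = cl;
        cur[j] = best;
        if (best < rm) { rm = best; rj = j; }
      }
      pref_cost(i, t) = rm; pref_end(i, t) = rj;
      std::swap(prev, cur);
    }
    // backward pass on reversed strings: suffix costs
    std::string rread(read.rbegin(), read.rend());
    std::string rref(ref.rbegin(), ref.rend());
    for (int j = 0; j <= n; ++j) prev[j] = 0;
    suf_cost(L, t) = 0; suf_start(L, t) = n;
    for (int i = 1; i <= L; ++i) {
      cur[0] = prev[0] + insertion_cost;
      int rm = cur[0], rj = 0;
      for (int j = 1; j <= n; ++j) {
        int cd = prev[j - 1] + (rread[i - 1] == rref[j - 1] ? 0 : mismatch_cost);
        int cu = prev[j] + insertion_cost;
        int cl = cur[j - 1] + deletion_cost;
        int best = cd;
        if (cu < best) best = cu;
        if (cl < best) best = cl;
        cur[j] = best;
        if (best < rm) { rm = best; rj = j; }
      }
      // reversed prefix of length i == forward suffix starting at L - i
      suf_cost(L - i, t) = rm; suf_start(L - i, t) = n - rj;
      std::swap(prev, cur);
    }
  }
  return List::create(_["pref_cost"] = pref_cost, _["pref_end"] = pref_end,
                      _["suf_cost"] = suf_cost, _["suf_start"] = suf_start);
}

static std::string revcomp_cpp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default: break;
    }
  }
  return r;
}

// Batched seed-and-extend over many reads, both strands.
// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector reads, CharacterVector refs,
                          int mismatch_cost, int insertion_cost, int deletion_cost,
                          int seed_k, int pad) {
  std::vector<int> ridx, target, rstart, rend, cost, matches, mismatches,
      insertions, deletions;
  std::vector<std::string> strands;
  std::vector<std::string> refstr(refs.size());
  for (int t = 0; t < refs.size(); ++t) refstr[t] = as<std::string>(refs[t]);
  for (int k = 0; k < reads.size(); ++k) {
    std::string fwd = as<std::string>(reads[k]);
    for (int s = 0; s < 2; ++s) {
      std::string read = (s == 0) ? fwd : revcomp_cpp(fwd);
      const int L = (int)read.size();
      for (int t = 0; t < (int)refstr.size(); ++t) {
        const std::string& ref = refstr[t];
        std::vector<int> diags = seed_diagonals(read, ref, seed_k);
        std::vector<int> seen;
        for (int d : diags) {
          int w0 = std::max(0, d - pad);
          int w1 = std::min((int)ref.size(), d + L + pad);
          if (w1 <= w0) continue;
          SgResult r = semiglobal_tb(read, ref.substr(w0, w1 - w0),
                                     mismatch_cost, insertion_cost, deletion_cost);
          if (!r.ok) continue;
          int gs = w0 + r.ref_start, ge = w0 + r.ref_end;
          bool dup = false;
          for (int p : seen) if (std::abs(p - gs) <= 4) { dup = true; break; }
          if (dup) continue;
          seen.push_back(gs);
          ridx.push_back(k + 1);
          strands.push_back(s == 0 ? "+" : "-");
          target.push_back(t + 1);
          rstart.push_back(gs); rend.push_back(ge);
          cost.push_back(r.cost);
          matches.push_back(r.matches); mismatches.push_back(r.mismatches);
          insertions.push_back(r.insertions); deletions.push_back(r.deletions);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = ridx, _["strand"] = strands,
                           _["target"] = target,
                           _["ref_start"] = rstart, _["ref_end"] = rend,
                           _["cost"] = cost, _["matches"] = matches,
                           _["mismatches"] = mismatches,
                           _["insertions"] = insertions,
                           _["deletions"] = deletions,
                           _["stringsAsFactors"] = false);
}
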