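#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Exhaustive k-mismatch placement of short reads on a set of targets,
// both strands, with optional all-best-strata filtering (only placements
// tied at the per-read minimal mismatch count are reported).  'N' on
// either side never matches, including N vs N.  Coordinates are 0-based;
// for a minus-strand hit 'start' is the leftmost target coordinate of the
// placement (the read's 5' end sits at start + len - 1).
//
// Completeness comes from a pigeonhole seed index: a placement with at
// most m mismatches within the first (m+1)*w read bases has at least one
// exact (hence N-free) w-mer chunk, so enumerating exact w-mer seed hits
// enumerates every valid placement.  Verification counts mismatches with
// early exit at the current reporting threshold.  When reads are too
// short to carry informative seeds the mapper falls back to a plain scan
// over every offset; both paths implement identical semantics.

static inline bool mismatch(char a, char b) {
  return a != b || a == 'N' || b == 'N';
}

static inline int count_mm(const char *q, const char *p, int len, int thr) {
  int mm = 0;
  for (int i = 0; i < len; ++i)
    if (mismatch(q[i], p[i]) && ++mm > thr) return thr + 1;
  return mm;
}

struct Hit { int t, s, strand, mm; };

// plain scan of one read (both strands given) over all targets
static void scan_brute(const std::string &fwd, const std::string &rev,
                       const std::vector<std::string> &tg, int max_mm,
                       bool best_strata, int &best, std::vector<Hit> &hits) {
  const int ql = (int)fwd.size();
  for (int t = 0; t < (int)tg.size(); ++t) {
    const std::string &T = tg[t];
    const int tl = (int)T.size();
    if (ql > tl) continue;
    for (int strand = 1; strand >= 0; --strand) {
      const char *q = (strand ? fwd.c_str() : rev.c_str());
      for (int s = 0; s + ql <= tl; ++s) {
        int thr = best_strata ? best : max_mm;
        int mm = count_mm(q, T.c_str() + s, ql, thr);
        if (mm <= thr) {
          hits.push_back({t, s, strand, mm});
          if (best_strata && mm < best) best = mm;
        }
      }
    }
  }
}

struct Loc { int t, pos; };

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// encode w-mer starting at p; returns false if it contains a non-ACGT base
static inline bool encode(const char *p, int w, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < w; ++i) {
    int c = base_code(p[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector rc_reads,
                        CharacterVector targets, int max_mm,
                        bool best_strata) {
  const int nr = reads.size(), nt = targets.size();
  std::vector<std::string> tg(nt);
  for (int t = 0; t < nt; ++t) tg[t] = as<std::string>(targets[t]);

  int min_len = INT32_MAX;
  for (int r = 0; r < nr; ++r)
    min_len = std::min(min_len, (int)LENGTH(STRING_ELT(reads, r)));
  const int k = max_mm + 1;
  const int w = (nr > 0 && min_len >= 2 * k) ?
    std::min(min_len / k, 31) : 0;
  const bool use_index = w >= 4;

  std::unordered_map<uint64_t, std::vector<Loc>> idx;
  if (use_index) {
    for (int t = 0; t < nt; ++t) {
      const std::string &T = tg[t];
      for (int p = 0; p + w <= (int)T.size(); ++p) {
        uint64_t code;
        if (encode(T.c_str() + p, w, code))
          idx[code].push_back({t, p});
      }
    }
  }

  std::vector<int> out_read, out_target, out_start, out_strand, out_mm;
  std::vector<std::pair<int64_t, int>> cand; // (t,start) packed, strand

  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const std::string rev = as<std::string>(rc_reads[r]);
    const int ql = (int)fwd.size();
    int best = max_mm;
    std::vector<Hit> hits;

    if (!use_index) {
      scan_brute(fwd, rev, tg, max_mm, best_strata, best, hits);
    } else {
      cand.clear();
      for (int strand = 1; strand >= 0; --strand) {
        const char *q = (strand ? fwd.c_str() : rev.c_str());
        for (int i = 0; i < k; ++i) {
          const int off = i * w;
          uint64_t code;
          if (!encode(q + off, w, code)) continue;
          auto it = idx.find(code);
          if (it == idx.end()) continue;
          for (const Loc &loc : it->second) {
            const int s = loc.pos - off;
            if (s >= 0 && s + ql <= (int)tg[loc.t].size())
              cand.emplace_back(((int64_t)loc.t << 32) |
                                (uint32_t)s, strand);
          }
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (const auto &c : cand) {
        const int t = (int)(c.first >> 32);
        const int s = (int)(uint32_t)(c.first & 0xffffffff);
        const char *q = (c.second ? fwd.c_str() : rev.c_str());
        int thr = best_strata ? best : max_mm;
        int mm = count_mm(q, tg[t].c_str() + s, ql, thr);
        if (mm <= thr) {
          hits.push_back({t, s, c.second, mm});
          if (best_strata && mm < best) best = mm;
        }
      }
    }

    for (const Hit &h : hits) {
      if (best_strata && h.mm != best) continue;
      out_read.push_back(r + 1);
      out_target.push_back(h.t + 1);
      out_start.push_back(h.s);
      out_strand.push_back(h.strand);
      out_mm.push_back(h.mm);
    }
  }
  return DataFrame::create(
    _["read"] = out_read, _["target"] = out_target, _["start"] = out_start,
    _["strand"] = out_strand, _["mismatches"] = out_mm);
}
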