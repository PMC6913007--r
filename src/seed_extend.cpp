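// k-mer seeded greedy extension engine behind the homology module.
// Finds local similarities between each subject and each query sequence:
// exact shared k-mers seed an ungapped-with-rescue extension (X-drop
// controlled, single-base gaps allowed via a short lookahead). Coordinates
// returned are 1-based closed. Strand handling (reverse complement of the
// queries) is done by the R callers.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;  // N and anything else never matches
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) baseCode(s[i]);
  return v;
}

struct Snap { int cs, cq, m, x, g; };

// count matches over the next w diagonal steps starting at (si, qi)
static inline int lookahead(const std::vector<int8_t>& S,
                            const std::vector<int8_t>& Q,
                            int si, int qi, int dir, int w) {
  int m = 0;
  int ns = (int) S.size(), nq = (int) Q.size();
  for (int t = 0; t < w; ++t) {
    int a = si + dir * t, b = qi + dir * t;
    if (a < 0 || b < 0 || a >= ns || b >= nq) break;
    if (S[a] >= 0 && S[a] == Q[b]) ++m;
  }
  return m;
}

// greedy extension from (s0, q0) inclusive, in direction dir (+1/-1);
// returns the best-scoring prefix (number of consumed subject/query bases
// plus match/mismatch/gap counts at the score maximum)
static Snap extend(const std::vector<int8_t>& S, const std::vector<int8_t>& Q,
                   int s0, int q0, int dir,
                   double mp, double gp, double xdrop) {
  Snap best = {0, 0, 0, 0, 0};
  double score = 0.0, bestScore = 0.0;
  int cs = 0, cq = 0, m = 0, x = 0, g = 0;
  int ns = (int) S.size(), nq = (int) Q.size();
  const int w = 4;
  for (;;) {
    int si = s0 + dir * cs, qi = q0 + dir * cq;
    if (si < 0 || qi < 0 || si >= ns || qi >= nq) break;
    if (S[si] >= 0 && S[si] == Q[qi]) {
      score += 1.0; ++m; ++cs; ++cq;
    } else {
      int la_d = lookahead(S, Q, si + dir, qi + dir, dir, w);
      int la_s = lookahead(S, Q, si + dir, qi, dir, w);  // gap in query
      int la_q = lookahead(S, Q, si, qi + dir, dir, w);  // gap in subject
      if (la_d >= la_s && la_d >= la_q) {
        score -= mp; ++x; ++cs; ++cq;
      } else if (la_s >= la_q) {
        score -= gp; ++g; ++cs;
      } else {
        score -= gp; ++g; ++cq;
      }
    }
    if (score > bestScore) {
      bestScore = score;
      best.cs = cs; best.cq = cq; best.m = m; best.x = x; best.g = g;
    }
    if (bestScore - score > xdrop) break;
  }
  return best;
}

struct HitRec {
  int si, qi;                  // subject / query index (0-based)
  int s_lo, s_hi, q_lo, q_hi;  // 0-based inclusive
  int matches, mismatches, gaps;
};

// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(CharacterVector subjects, CharacterVector queries,
                          int k, double mismatch_pen, double gap_pen,
                          double xdrop) {
  if (k < 4 || k > 15) stop("k must be between 4 and 15");
  const uint32_t mask = (k == 16) ? 0xffffffffu : ((1u << (2 * k)) - 1u);

  int nq = queries.size();
  std::vector<std::vector<int8_t> > Q(nq);
  std::unordered_multimap<uint32_t, std::pair<int, int> > index;
  size_t total = 0;
  for (int qi = 0; qi < nq; ++qi) {
    Q[qi] = encode(as<std::string>(queries[qi]));
    if ((int) Q[qi].size() >= k) total += Q[qi].size() - k + 1;
  }
  index.reserve(total * 2);
  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<int8_t>& q = Q[qi];
    uint32_t kmer = 0; int valid = 0;
    for (int i = 0; i < (int) q.size(); ++i) {
      if (q[i] < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint32_t) q[i]) & mask;
      if (++valid >= k)
        index.insert(std::make_pair(kmer, std::make_pair(qi, i - k + 1)));
    }
  }

  std::vector<HitRec> hits;
  std::vector<std::vector<int> > byQuery(nq);  // hit ids per query, for seed skip

  for (int si = 0; si < subjects.size(); ++si) {
    std::vector<int8_t> S = encode(as<std::string>(subjects[si]));
    for (int qi = 0; qi < nq; ++qi) byQuery[qi].clear();
    uint32_t kmer = 0; int valid = 0;
    for (int i = 0; i < (int) S.size(); ++i) {
      if (S[i] < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint32_t) S[i]) & mask;
      if (++valid < k) continue;
      int pos = i - k + 1;
      auto range = index.equal_range(kmer);
      for (auto it = range.first; it != range.second; ++it) {
        int qi2 = it->second.first, qpos = it->second.second;
        int diag = pos - qpos;
        // skip seeds inside an already-extended hit on a nearby diagonal
        bool covered = false;
        for (int hid : byQuery[qi2]) {
          const HitRec& h = hits[hid];
          if (pos >= h.s_lo && pos + k - 1 <= h.s_hi &&
              std::abs(diag - (h.s_lo - h.q_lo)) <= 20) { covered = true; break; }
        }
        if (covered) continue;
        Snap L = extend(S, Q[qi2], pos - 1, qpos - 1, -1,
                        mismatch_pen, gap_pen, xdrop);
        Snap R = extend(S, Q[qi2], pos + k, qpos + k, +1,
                        mismatch_pen, gap_pen, xdrop);
        HitRec h;
        h.si = si; h.qi = qi2;
        h.s_lo = pos - L.cs; h.s_hi = pos + k - 1 + R.cs;
        h.q_lo = qpos - L.cq; h.q_hi = qpos + k - 1 + R.cq;
        h.matches = k + L.m + R.m;
        h.mismatches = L.x + R.x;
        h.gaps = L.g + R.g;
        byQuery[qi2].push_back((int) hits.size());
        hits.push_back(h);
      }
    }
  }

  int n = (int) hits.size();
  IntegerVector subj(n), qry(n), s_start(n), s_end(n), q_start(n), q_end(n),
      matches(n), mismatches(n), gaps(n);
  for (int i = 0; i < n; ++i) {
    const HitRec& h = hits[i];
    subj[i] = h.si + 1; qry[i] = h.qi + 1;
    s_start[i] = h.s_lo + 1; s_end[i] = h.s_hi + 1;
    q_start[i] = h.q_lo + 1; q_end[i] = h.q_hi + 1;
    matches[i] = h.matches; mismatches[i] = h.mismatches; gaps[i] = h.gaps;
  }
  return DataFrame::create(
      _["subject"] = subj, _["query"] = qry,
      _["sStart"] = s_start, _["sEnd"] = s_end,
      _["qStart"] = q_start, _["qEnd"] = q_end,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gaps"] = gaps);
}
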