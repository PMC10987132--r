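// Seed-and-extend ungapped local alignment (HSP) engine.
//
// k-mer exact seeds on both strands, ungapped X-drop extension, merging of
// overlapping segments on the same diagonal. Identity counts only A/C/G/T
// matches: N never matches anything, including another N.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

struct Seg {
  int qs, qe, ss, se;   // 0-based half-open, query / subject
  int matches;
  int score;
};

// Count matching non-N bases over a diagonal-aligned interval.
static inline int count_matches(const std::string& q, const std::string& s,
                                int qs, int qe, int ss) {
  int m = 0;
  for (int i = 0; i < qe - qs; ++i) {
    char a = q[qs + i], b = s[ss + i];
    if (a == b && base_code(a) >= 0) ++m;
  }
  return m;
}

// Seed-and-extend on one strand; q vs s as given. Returns raw segments.
static std::vector<Seg> scan_strand(const std::string& q, const std::string& s,
                                    int k, int xdrop, int match, int mismatch,
                                    int max_seed_hits) {
  std::vector<Seg> out;
  const int nq = (int)q.size(), ns = (int)s.size();
  if (nq < k || ns < k) return out;

  // index subject k-mers (2 bits/base; k <= 31)
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(ns);
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < ns; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }
  }

  // furthest query end already extended, per diagonal (diag = q - s)
  std::unordered_map<long long, int> covered;

  uint64_t h = 0; int run = 0;
  for (int i = 0; i < nq; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    auto it = idx.find(h);
    if (it == idx.end()) continue;
    const std::vector<int>& hits = it->second;
    if ((int)hits.size() > max_seed_hits) continue;
    int qpos = i - k + 1;
    for (int spos : hits) {
      long long diag = (long long)qpos - spos;
      auto cv = covered.find(diag);
      if (cv != covered.end() && qpos < cv->second) continue;

      // right extension from end of seed
      int score = k * match, best = score;
      int qe = qpos + k, se = spos + k;
      int bqe = qe;
      {
        int qq = qe, sr = se;
        while (qq < nq && sr < ns) {
          char a = q[qq], b = s[sr];
          bool is_match = (a == b && base_code(a) >= 0);
          score += is_match ? match : mismatch;
          ++qq; ++sr;
          if (score >= best) {            // prefer the longer endpoint on ties
            if (score > best || qq > bqe) bqe = qq;
            best = std::max(best, score);
          } else if (best - score > xdrop) break;
        }
      }
      // left extension from start of seed
      int bqs = qpos;
      {
        int score2 = best, best2 = best;
        int qq = qpos, sr = spos;
        while (qq > 0 && sr > 0) {
          char a = q[qq - 1], b = s[sr - 1];
          bool is_match = (a == b && base_code(a) >= 0);
          score2 += is_match ? match : mismatch;
          --qq; --sr;
          if (score2 >= best2) {          // prefer the longer endpoint on ties
            if (score2 > best2 || qq < bqs) bqs = qq;
            best2 = std::max(best2, score2);
          } else if (best2 - score2 > xdrop) break;
        }
        best = best2;
      }
      Seg g;
      g.qs = bqs; g.qe = bqe;
      g.ss = bqs - (int)diag; g.se = bqe - (int)diag;
      g.matches = count_matches(q, s, g.qs, g.qe, g.ss);
      g.score = g.matches * match + ((g.qe - g.qs) - g.matches) * mismatch;
      out.push_back(g);
      int prev = (cv == covered.end()) ? -1 : cv->second;
      covered[diag] = std::max(prev, g.qe);
    }
  }

  // merge overlapping/adjacent segments sharing a diagonal
  std::sort(out.begin(), out.end(), [](const Seg& a, const Seg& b) {
    long long da = (long long)a.qs - a.ss, db = (long long)b.qs - b.ss;
    if (da != db) return da < db;
    return a.qs < b.qs;
  });
  std::vector<Seg> merged;
  for (const Seg& g : out) {
    if (!merged.empty()) {
      Seg& m = merged.back();
      long long dm = (long long)m.qs - m.ss, dg = (long long)g.qs - g.ss;
      if (dm == dg && g.qs <= m.qe) {
        if (g.qe > m.qe) { m.qe = g.qe; m.se = m.qe - (int)dm; }
        continue;
      }
    }
    merged.push_back(g);
  }
  for (Seg& m : merged) {
    m.matches = count_matches(q, s, m.qs, m.qe, m.ss);
    m.score = m.matches * match + ((m.qe - m.qs) - m.matches) * mismatch;
  }
  return merged;
}

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string query, std::string subject,
                        double min_identity, int min_len,
                        int k, int xdrop, int match, int mismatch,
                        int max_seed_hits) {
  std::vector<Seg> fwd = scan_strand(query, subject, k, xdrop, match,
                                     mismatch, max_seed_hits);
  std::string subrc = revcomp(subject);
  std::vector<Seg> rev = scan_strand(query, subrc, k, xdrop, match,
                                     mismatch, max_seed_hits);
  const int ns = (int)subject.size();

  std::vector<int> qs, qe, ss, se, alen, scv;
  std::vector<double> ident;
  std::vector<std::string> strand;
  auto keep = [&](const Seg& g, bool minus) {
    int len = g.qe - g.qs;
    if (len < min_len) return;
    double id = len > 0 ? 100.0 * g.matches / len : 0.0;
    if (id < min_identity) return;
    qs.push_back(g.qs); qe.push_back(g.qe);
    if (minus) {              // map back to original subject orientation
      ss.push_back(ns - g.se); se.push_back(ns - g.ss);
    } else {
      ss.push_back(g.ss); se.push_back(g.se);
    }
    alen.push_back(len); ident.push_back(id); scv.push_back(g.score);
    strand.push_back(minus ? "-" : "+");
  };
  for (const Seg& g : fwd) keep(g, false);
  for (const Seg& g : rev) keep(g, true);

  // sort by query start (ties: higher score first)
  std::vector<int> ord(qs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qs[a] != qs[b]) return qs[a] < qs[b];
    return scv[a] > scv[b];
  });
  auto pick_i = [&](const std::vector<int>& v) {
    IntegerVector r(ord.size());
    for (size_t i = 0; i < ord.size(); ++i) r[i] = v[ord[i]];
    return r;
  };
  NumericVector id_out(ord.size());
  CharacterVector st_out(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    id_out[i] = ident[ord[i]];
    st_out[i] = strand[ord[i]];
  }
  return DataFrame::create(
    _["q_start"] = pick_i(qs), _["q_end"] = pick_i(qe),
    _["s_start"] = pick_i(ss), _["s_end"] = pick_i(se),
    _["identity"] = id_out, _["aligned_len"] = pick_i(alen),
    _["strand"] = st_out, _["score"] = pick_i(scv),
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) { return revcomp(seq); }
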