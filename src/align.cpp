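#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3 N=4 X=5 (X = masked, never realignable).
static inline int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    case 'N': return 4; default: return 5;
  }
}

static inline int pair_score(int a, int b, int ma, int mi) {
  if (a == 5 || b == 5) return -1000000;   // masked: impassable
  if (a == 4 || b == 4) return mi;         // N never counts as a match
  return (a == b) ? ma : mi;
}

struct Hsp {
  int q_start, q_end, s_start, s_end;      // 0-based half-open
  std::string q_row, s_row;
  int score, n_matches, n_columns;
};

// One full affine-gap Smith-Waterman pass with traceback.
// E: gap in subject row (consumes query), F: gap in query row (consumes subject).
static bool sw_once(const std::vector<int>& q, const std::vector<int>& s,
                    int ma, int mi, int go, int ge, Hsp& out) {
  const int n = (int)q.size(), m = (int)s.size();
  const int W = m + 1;
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  // traceback codes for H: 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<uint8_t> tbH((size_t)(n + 1) * W, 0), tbE((size_t)(n + 1) * W, 0),
      tbF((size_t)(n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * W, p = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      int e_open = H[p + j] - go - ge, e_ext = E[p + j] - ge;
      int ev = e_open >= e_ext ? e_open : e_ext;
      E[r + j] = ev; tbE[r + j] = e_open >= e_ext ? 1 : 0;
      int f_open = H[r + j - 1] - go - ge, f_ext = F[r + j - 1] - ge;
      int fv = f_open >= f_ext ? f_open : f_ext;
      F[r + j] = fv; tbF[r + j] = f_open >= f_ext ? 1 : 0;
      int dv = H[p + j - 1] + pair_score(q[i - 1], s[j - 1], ma, mi);
      int h = 0; uint8_t tb = 0;
      if (dv > h) { h = dv; tb = 1; }
      if (ev > h) { h = ev; tb = 2; }
      if (fv > h) { h = fv; tb = 3; }
      H[r + j] = h; tbH[r + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  static const char LUT[] = "ACGTNX";
  std::string qr, sr;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    const size_t r = (size_t)i * W;
    if (state == 0) {
      uint8_t tb = tbH[r + j];
      if (tb == 0) break;
      if (tb == 1) { qr += LUT[q[i - 1]]; sr += LUT[s[j - 1]]; --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qr += LUT[q[i - 1]]; sr += '-';
      uint8_t tb = tbE[r + j]; --i;
      if (tb == 1) state = 0;
    } else {
      qr += '-'; sr += LUT[s[j - 1]];
      uint8_t tb = tbF[r + j]; --j;
      if (tb == 1) state = 0;
    }
  }
  std::reverse(qr.begin(), qr.end());
  std::reverse(sr.begin(), sr.end());
  out.q_start = i; out.s_start = j; out.q_end = bi; out.s_end = bj;
  out.q_row = qr; out.s_row = sr; out.score = best;
  int nm = 0;
  for (size_t k = 0; k < qr.size(); ++k)
    if (qr[k] == sr[k] && qr[k] != '-' && qr[k] != 'N') ++nm;
  out.n_matches = nm; out.n_columns = (int)qr.size();
  return true;
}

// Optimal local HSP plus non-overlapping (on the query) suboptimal HSPs via
// greedy query masking, down to min_score. Single orientation; the R wrapper
// handles the reverse-complement strand.
// [[Rcpp::export]]
List sw_hsps_cpp(std::string query, std::string subject,
                 int match, int mismatch, int gap_open, int gap_extend,
                 int min_score, int max_hsps) {
  std::vector<int> q(query.size()), s(subject.size());
  for (size_t k = 0; k < query.size(); ++k) q[k] = enc(query[k]);
  for (size_t k = 0; k < subject.size(); ++k) s[k] = enc(subject[k]);
  std::vector<int> qs, qe, ss, se, sc, nm, nc;
  std::vector<std::string> qr, sr;
  for (int it = 0; it < max_hsps; ++it) {
    Hsp h;
    if (!sw_once(q, s, match, mismatch, gap_open, gap_extend, h)) break;
    if (h.score < min_score) break;
    qs.push_back(h.q_start); qe.push_back(h.q_end);
    ss.push_back(h.s_start); se.push_back(h.s_end);
    sc.push_back(h.score); nm.push_back(h.n_matches); nc.push_back(h.n_columns);
    qr.push_back(h.q_row); sr.push_back(h.s_row);
    for (int k = h.q_start; k < h.q_end; ++k) q[k] = 5;  // mask
  }
  return List::create(_["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["score"] = sc, _["n_matches"] = nm, _["n_columns"] = nc,
                      _["q_row"] = qr, _["s_row"] = sr);
}

// Best ungapped dovetail/containment overlap between a and b over all relative
// offsets. offset = start of b relative to start of a (may be negative).
// Best = highest identity, ties broken by longer overlap, then smaller offset.
// [[Rcpp::export]]
List scan_overlap_cpp(std::string a, std::string b, int min_overlap,
                      double min_identity) {
  const int la = (int)a.size(), lb = (int)b.size();
  bool found = false;
  int best_len = 0, best_off = 0, best_matches = 0;
  double best_id = -1.0;
  for (int d = -(lb - min_overlap); d <= la - min_overlap; ++d) {
    int a0 = d > 0 ? d : 0;
    int a1 = (d + lb) < la ? (d + lb) : la;
    int L = a1 - a0;
    if (L < min_overlap) continue;
    int matches = 0;
    for (int i = a0; i < a1; ++i) {
      char ca = a[i], cb = b[i - d];
      if (ca == cb && ca != 'N') ++matches;
    }
    double id = (double)matches / (double)L;
    if (id < min_identity) continue;
    if (id > best_id || (id == best_id && (L > best_len ||
        (L == best_len && d < best_off)))) {
      best_id = id; best_len = L; best_off = d; best_matches = matches;
      found = true;
    }
  }
  return List::create(_["found"] = found, _["offset"] = best_off,
                      _["length"] = best_len, _["matches"] = best_matches,
                      _["identity"] = found ? best_id : NA_REAL);
}

static inline bool encode_kmer(const std::string& s, size_t pos, int k,
                               uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int e = enc(s[pos + i]);
    if (e > 3) return false;
    v = (v << 2) | (uint64_t)e;
  }
  out = v;
  return true;
}

// Candidate pairs sharing >= min_shared k-mers, forward and reverse-complement
// counted separately. If same_set, only i < j pairs are returned.
// [[Rcpp::export]]
DataFrame kmer_pairs_cpp(CharacterVector A, CharacterVector B, int k,
                         int min_shared, bool same_set) {
  const int nB = B.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(1 << 20);
  for (int j = 0; j < nB; ++j) {
    std::string s = as<std::string>(B[j]);
    if ((int)s.size() < k) continue;
    uint64_t last_v = 0; bool have_last = false;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t v;
      if (!encode_kmer(s, p, k, v)) { have_last = false; continue; }
      if (have_last && v == last_v) continue;  // collapse homopolymer repeats
      last_v = v; have_last = true;
      std::vector<int>& vec = index[v];
      if (vec.empty() || vec.back() != j) vec.push_back(j);
    }
  }
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::vector<int> out_i, out_j, out_fwd, out_rc;
  const int nA = A.size();
  for (int i = 0; i < nA; ++i) {
    std::string s = as<std::string>(A[i]);
    if ((int)s.size() < k) continue;
    std::unordered_map<int, int> fwd, rc;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t v;
      if (!encode_kmer(s, p, k, v)) continue;
      uint64_t r = 0, t = v;
      for (int x = 0; x < k; ++x) { r = (r << 2) | (3 - (t & 3)); t >>= 2; }
      r &= mask;
      auto itf = index.find(v);
      if (itf != index.end()) for (int j : itf->second) ++fwd[j];
      auto itr = index.find(r);
      if (itr != index.end()) for (int j : itr->second) ++rc[j];
    }
    std::unordered_map<int, std::pair<int,int>> merged;
    for (auto& kv : fwd) merged[kv.first].first = kv.second;
    for (auto& kv : rc) merged[kv.first].second = kv.second;
    for (auto& kv : merged) {
      int j = kv.first;
      if (same_set && j <= i) continue;
      int f = kv.second.first, r = kv.second.second;
      if (f >= min_shared || r >= min_shared) {
        out_i.push_back(i + 1); out_j.push_back(j + 1);
        out_fwd.push_back(f); out_rc.push_back(r);
      }
    }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j,
                           _["n_fwd"] = out_fwd, _["n_rc"] = out_rc);
}
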