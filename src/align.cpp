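// Local alignment kernels for fragment-based ANI.
//
// Two routes share one scoring scheme (match/mismatch, affine gaps where a
// gap of length L costs gap_open + L * gap_ext):
//   * sw_align_cpp      exact affine-gap Smith-Waterman with traceback,
//                       used for small targets and as the precision route.
//   * seeded_fragments_cpp  k-mer seeded, gapless (per-diagonal best segment
//                       via Kadane's scan) for genome-scale targets.
// Bases are encoded A=0 C=1 G=2 T=3, anything else 4; code 4 never matches.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> revcomp(const std::vector<int> &v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? 3 - b : 4;
  }
  return r;
}

struct AlnHit {
  double score;
  int matches, columns;       // columns include gap columns
  int q_start, q_end, t_start, t_end;  // 0-based half-open
  bool valid;
};

// Exact affine-gap local alignment with traceback.
static AlnHit sw_core(const std::vector<int> &q, const std::vector<int> &t,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int m = (int)q.size(), n = (int)t.size();
  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Fcol(n + 1, NEG);
  // traceback codes per cell: bits 0-1 H-case (0 stop, 1 diag, 2 E, 3 F),
  // bit 2: E extended, bit 3: F extended
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    double E = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      uint8_t code = 0;
      double e_ext = E - gap_ext;
      double e_open = Hcur[j - 1] - gap_open - gap_ext;
      if (e_ext >= e_open) { E = e_ext; code |= 4; } else E = e_open;
      double f_ext = Fcol[j] - gap_ext;
      double f_open = Hprev[j] - gap_open - gap_ext;
      double F;
      if (f_ext >= f_open) { F = f_ext; code |= 8; } else F = f_open;
      Fcol[j] = F;
      double s = (q[i - 1] < 4 && q[i - 1] == t[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; int hc = 0;
      if (diag > h) { h = diag; hc = 1; }
      if (E > h) { h = E; hc = 2; }
      if (F > h) { h = F; hc = 3; }
      Hcur[j] = h;
      tb[(size_t)i * (n + 1) + j] = code | (uint8_t)hc;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  AlnHit hit; hit.score = best; hit.valid = best > 0;
  hit.matches = 0; hit.columns = 0;
  hit.q_end = bi; hit.t_end = bj;
  if (!hit.valid) { hit.q_start = hit.q_end = hit.t_start = hit.t_end = 0; return hit; }
  // traceback
  int i = bi, j = bj; int state = 0; // 0=H, 2=E, 3=F
  while (i > 0 && j > 0) {
    uint8_t code = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int hc = code & 3;
      if (hc == 0) break;
      if (hc == 1) {
        hit.columns++;
        if (q[i - 1] < 4 && q[i - 1] == t[j - 1]) hit.matches++;
        --i; --j;
      } else state = hc; // 2 or 3
    } else if (state == 2) { // gap consuming target
      hit.columns++;
      bool ext = code & 4;
      --j;
      if (!ext) state = 0;
      else {
        // remain in E; the extend flag of the new cell governs next step
      }
      if (ext) state = 2; // explicit
    } else { // state == 3, gap consuming query
      hit.columns++;
      bool ext = code & 8;
      --i;
      state = ext ? 3 : 0;
    }
  }
  hit.q_start = i; hit.t_start = j;
  return hit;
}

// E-state traceback needs the flag of the cell we *leave*, handled above by
// reading code before moving; re-check of logic: when in E at (i,j) we consumed
// t[j-1]; flag bit 4 of (i,j) says whether E came from E(i,j-1) (extend) or
// from H(i,j-1) (open). Same for F with bit 8. That is what the loop does.

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  std::vector<int> q = encode(query), t = encode(target);
  AlnHit h = sw_core(q, t, match, mismatch, gap_open, gap_ext);
  return List::create(_["score"] = h.score, _["matches"] = h.matches,
                      _["columns"] = h.columns, _["q_start"] = h.q_start,
                      _["q_end"] = h.q_end, _["t_start"] = h.t_start,
                      _["t_end"] = h.t_end, _["valid"] = h.valid);
}

// ---- seeded gapless route ----

struct KmerIndex {
  std::unordered_map<uint32_t, std::vector<int> > map;
  int k;
};

static void build_index(const std::vector<int> &t, int k, KmerIndex &idx) {
  idx.k = k;
  idx.map.clear();
  if ((int)t.size() < k) return;
  uint32_t key = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0; // consecutive valid bases
  for (int i = 0; i < (int)t.size(); ++i) {
    if (t[i] < 4) { key = ((key << 2) | (uint32_t)t[i]) & mask; run++; }
    else { run = 0; key = 0; }
    if (run >= k) idx.map[key].push_back(i - k + 1);
  }
}

// Best gapless local segment of query vs one strand of target, over all
// seeded diagonals. Kadane scan per candidate diagonal.
static AlnHit seeded_one_strand(const std::vector<int> &q,
                                const std::vector<int> &t,
                                const KmerIndex &idx,
                                double match, double mismatch) {
  AlnHit best; best.score = 0; best.valid = false;
  best.matches = best.columns = 0;
  best.q_start = best.q_end = best.t_start = best.t_end = 0;
  const int k = idx.k;
  const int qlen = (int)q.size(), tlen = (int)t.size();
  if (qlen < k || tlen < k) return best;
  std::unordered_map<int, char> seen; // diagonals already scanned
  uint32_t key = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < qlen; ++i) {
    if (q[i] < 4) { key = ((key << 2) | (uint32_t)q[i]) & mask; run++; }
    else { run = 0; key = 0; }
    if (run < k) continue;
    int qpos = i - k + 1;
    auto it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    for (int tpos : it->second) {
      int d = tpos - qpos;  // diagonal offset: t index = q index + d
      if (seen.count(d)) continue;
      seen[d] = 1;
      int q0 = std::max(0, -d);
      int q1 = std::min(qlen, tlen - d);
      double cur = 0; int cur_start = q0;
      double loc_best = 0; int loc_s = q0, loc_e = q0;
      for (int x = q0; x < q1; ++x) {
        double s = (q[x] < 4 && q[x] == t[x + d]) ? match : mismatch;
        cur += s;
        if (cur <= 0) { cur = 0; cur_start = x + 1; }
        else if (cur > loc_best) { loc_best = cur; loc_s = cur_start; loc_e = x + 1; }
      }
      if (loc_best > best.score) {
        int mt = 0;
        for (int x = loc_s; x < loc_e; ++x)
          if (q[x] < 4 && q[x] == t[x + d]) mt++;
        best.score = loc_best; best.valid = true;
        best.matches = mt; best.columns = loc_e - loc_s;
        best.q_start = loc_s; best.q_end = loc_e;
        best.t_start = loc_s + d; best.t_end = loc_e + d;
      }
    }
  }
  return best;
}

// Batch: align each fragment against both strands of one target.
// exact = use the Smith-Waterman route per fragment instead of seeding.
// Returns one row per fragment: score, matches, columns, aligned fragment
// length (query bases consumed), strand (+1/-1), 0 rows are kept (valid flag).
// [[Rcpp::export]]
DataFrame align_fragments_cpp(CharacterVector fragments, std::string target,
                              int k, double match, double mismatch,
                              double gap_open, double gap_ext, bool exact) {
  std::vector<int> t = encode(target);
  std::vector<int> trc = revcomp(t);
  KmerIndex idx_f, idx_r;
  if (!exact) { build_index(t, k, idx_f); build_index(trc, k, idx_r); }
  int n = fragments.size();
  NumericVector score(n);
  IntegerVector matches(n), columns(n), qlen_aln(n), strand(n);
  LogicalVector valid(n);
  for (int i = 0; i < n; ++i) {
    std::string frag = as<std::string>(fragments[i]);
    std::vector<int> q = encode(frag);
    AlnHit hf, hr;
    if (exact) {
      hf = sw_core(q, t, match, mismatch, gap_open, gap_ext);
      hr = sw_core(q, trc, match, mismatch, gap_open, gap_ext);
    } else {
      hf = seeded_one_strand(q, t, idx_f, match, mismatch);
      hr = seeded_one_strand(q, trc, idx_r, match, mismatch);
    }
    AlnHit h = (hr.score > hf.score) ? hr : hf;
    int st = (hr.score > hf.score) ? -1 : 1;
    score[i] = h.score; matches[i] = h.matches; columns[i] = h.columns;
    qlen_aln[i] = h.q_end - h.q_start; strand[i] = st; valid[i] = h.valid;
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["columns"] = columns, _["q_aligned"] = qlen_aln,
                           _["strand"] = strand, _["valid"] = valid);
}
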