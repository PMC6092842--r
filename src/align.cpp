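// Seed-and-extend local alignment engine.
//
// Pipeline per (query, subject, strand) call:
//   1. hash every subject word (rolling 2-bit code, words containing N skipped)
//   2. exact word seeds query->subject, redundant seeds on an already-extended
//      diagonal skipped
//   3. ungapped X-drop extension of each seed into an HSP
//   4. greedy colinear chaining of HSPs (bridges mismatch deserts and indels)
//   5. banded affine-gap Smith-Waterman with traceback over each chain region
//
// Coordinates are 0-based half-open throughout. Strand handling (aligning
// against the reverse complement and remapping) is done by the R callers.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

namespace {

const int NEG_INF = -(1 << 28);

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
  return v;
}

struct Params {
  int word, match, mismatch, gap_open, gap_extend;
  int xdrop, hsp_min, min_report, band_pad, max_chain_gap, max_occ;
  int self_mod;  // >0: skip +strand seeds with (s - q) %% self_mod == 0
};

struct HSP {
  int qs, qe, ss, se, score;
  int diag() const { return qs - ss; }
};

struct Aln {
  int qs, qe, ss, se;
  int score, matches, mism, gapo, cols;
};

// ---- seeding -------------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int> > WordIndex;

void index_words(const std::vector<uint8_t>& s, int w, WordIndex& idx) {
  uint64_t key = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | s[i]) & mask;
    if (++run >= w) idx[key].push_back((int)(i + 1 - w));
  }
}

struct Seed { int q, s; };

void collect_seeds(const std::vector<uint8_t>& q, const WordIndex& idx,
                   const Params& p, std::vector<Seed>& seeds) {
  uint64_t key = 0, mask = (p.word >= 32) ? ~0ULL : ((1ULL << (2 * p.word)) - 1);
  int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (q[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | q[i]) & mask;
    if (++run < p.word) continue;
    WordIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<int>& pos = it->second;
    if ((int)pos.size() > p.max_occ) continue;
    int qp = (int)(i + 1 - p.word);
    for (size_t k = 0; k < pos.size(); ++k) {
      if (p.self_mod > 0) {
        long d = (long)pos[k] - (long)qp;
        long m = d % p.self_mod; if (m < 0) m += p.self_mod;
        if (m == 0) continue;
      }
      Seed sd; sd.q = qp; sd.s = pos[k];
      seeds.push_back(sd);
    }
  }
}

// ---- ungapped X-drop extension ------------------------------------------

HSP extend_seed(const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
                const Seed& sd, const Params& p) {
  int qlen = (int)q.size(), slen = (int)s.size();
  int sc = p.word * p.match;
  // right
  int i = sd.q + p.word, j = sd.s + p.word;
  int best = sc, be_i = i;
  while (i < qlen && j < slen) {
    sc += (q[i] <= 3 && q[i] == s[j]) ? p.match : -p.mismatch;
    ++i; ++j;
    if (sc > best) { best = sc; be_i = i; }
    if (best - sc > p.xdrop) break;
  }
  // left
  sc = best;
  i = sd.q - 1; j = sd.s - 1;
  int best2 = sc, bs_i = sd.q;
  while (i >= 0 && j >= 0) {
    sc += (q[i] <= 3 && q[i] == s[j]) ? p.match : -p.mismatch;
    if (sc > best2) { best2 = sc; bs_i = i; }
    if (best2 - sc > p.xdrop) break;
    --i; --j;
  }
  HSP h;
  h.qs = bs_i; h.qe = be_i;
  h.ss = sd.s - (sd.q - bs_i); h.se = sd.s + (be_i - sd.q);
  h.score = best2;
  return h;
}

// ---- chaining ------------------------------------------------------------

struct Chain {
  int qs, qe, ss, se, dmin, dmax, score;
  bool open;
};

void chain_hsps(std::vector<HSP>& hsps, const Params& p,
                std::vector<Chain>& chains) {
  std::sort(hsps.begin(), hsps.end(),
            [](const HSP& a, const HSP& b) {
              return a.qs != b.qs ? a.qs < b.qs : a.ss < b.ss;
            });
  const int ovl = 30, dtol = 60;
  std::vector<int> active;
  for (size_t h = 0; h < hsps.size(); ++h) {
    const HSP& x = hsps[h];
    int bestc = -1, bestgap = 1 << 30;
    size_t n_open = 0;
    for (size_t a = 0; a < active.size(); ++a) {
      Chain& ch = chains[active[a]];
      if (!ch.open) continue;
      if (ch.qe < x.qs - p.max_chain_gap) { ch.open = false; continue; }
      ++n_open;
      int qgap = x.qs - ch.qe, sgap = x.ss - ch.se;
      if (qgap < -ovl || sgap < -ovl || sgap > p.max_chain_gap) continue;
      int dshift = std::abs(x.diag() - (ch.qe - ch.se));
      if (dshift > dtol) continue;
      int gap = std::max(qgap, 0) + std::max(sgap, 0) + dshift;
      if (gap < bestgap) { bestgap = gap; bestc = active[a]; }
    }
    if (n_open * 2 < active.size() && active.size() > 64) {
      std::vector<int> keep;
      for (size_t a = 0; a < active.size(); ++a)
        if (chains[active[a]].open) keep.push_back(active[a]);
      active.swap(keep);
    }
    if (bestc >= 0) {
      Chain& ch = chains[bestc];
      ch.qe = std::max(ch.qe, x.qe); ch.se = std::max(ch.se, x.se);
      ch.dmin = std::min(ch.dmin, x.diag());
      ch.dmax = std::max(ch.dmax, x.diag());
      ch.score += x.score;
    } else {
      Chain ch;
      ch.qs = x.qs; ch.qe = x.qe; ch.ss = x.ss; ch.se = x.se;
      ch.dmin = ch.dmax = x.diag(); ch.score = x.score; ch.open = true;
      chains.push_back(ch);
      active.push_back((int)chains.size() - 1);
    }
  }
}

// ---- banded affine Smith-Waterman with traceback -------------------------

// traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E/left, 3 F/up),
// bit 2: E extends E, bit 3: F extends F
bool banded_sw(const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
               int q0, int q1, int dlo, int dhi, const Params& p, Aln& out) {
  int qlen = (int)q.size(), slen = (int)s.size();
  q0 = std::max(q0, 0); q1 = std::min(q1, qlen);
  if (q0 >= q1) return false;
  int W = dhi - dlo + 1;
  if (W <= 0) return false;
  int R = q1 - q0 + 1;
  std::vector<int> H(W, 0), E(W, NEG_INF), F(W, NEG_INF);
  std::vector<int> Hn(W), En(W), Fn(W);
  std::vector<uint8_t> tb((size_t)R * W, 0);
  const int gopen = p.gap_open + p.gap_extend;
  int best = 0, bi = -1, bk = -1;

  for (int r = 1; r < R; ++r) {
    int i = q0 + r;               // consumed i query chars, current char q[i-1]
    std::fill(Hn.begin(), Hn.end(), 0);
    std::fill(En.begin(), En.end(), NEG_INF);
    std::fill(Fn.begin(), Fn.end(), NEG_INF);
    int jmin = i - dhi, jmax = i - dlo;
    int lo = std::max(jmin, 1), hi = std::min(jmax, slen);
    for (int j = lo; j <= hi; ++j) {
      int k = j - jmin;           // band offset in row r
      uint8_t t = 0;
      // E: gap consuming s char, from (i, j-1) = (r, k-1)
      int e = NEG_INF;
      if (k - 1 >= 0) {
        int fromH = Hn[k - 1] - gopen;
        int fromE = En[k - 1] - p.gap_extend;
        if (fromE > fromH) { e = fromE; t |= 4; } else e = fromH;
      }
      // F: gap consuming q char, from (i-1, j) = (r-1, k+1)
      int f = NEG_INF;
      if (k + 1 < W) {
        int fromH = H[k + 1] - gopen;
        int fromF = F[k + 1] - p.gap_extend;
        if (fromF > fromH) { f = fromF; t |= 8; } else f = fromH;
      }
      // diagonal from (i-1, j-1) = (r-1, k)
      int sub = (q[i - 1] <= 3 && q[i - 1] == s[j - 1]) ? p.match : -p.mismatch;
      int d = H[k] + sub;
      int hbest = 0; uint8_t src = 0;
      if (d > hbest) { hbest = d; src = 1; }
      if (e > hbest) { hbest = e; src = 2; }
      if (f > hbest) { hbest = f; src = 3; }
      Hn[k] = hbest; En[k] = e; Fn[k] = f;
      tb[(size_t)r * W + k] = (uint8_t)(t | src);
      if (hbest > best) { best = hbest; bi = r; bk = k; }
    }
    H.swap(Hn); E.swap(En); F.swap(Fn);
  }
  if (best < p.min_report || bi < 0) return false;

  // traceback
  int r = bi, k = bk;
  int i = q0 + r, j = (i - dhi) + k;
  out.qe = i; out.se = j; out.score = best;
  out.matches = 0; out.mism = 0; out.gapo = 0; out.cols = 0;
  int state = 0;  // 0 = M, 1 = E, 2 = F
  while (r > 0) {
    uint8_t t = tb[(size_t)r * W + k];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ++out.cols;
        if (q[i - 1] <= 3 && q[i - 1] == s[j - 1]) ++out.matches; else ++out.mism;
        --r; --i; --j;            // k unchanged on diagonal moves
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {      // gap consuming s char at (i, j)
      ++out.cols;
      bool ext = (t & 4) != 0;
      --j; --k;
      if (!ext) { ++out.gapo; state = 0; }
    } else {                      // gap consuming q char at (i, j)
      ++out.cols;
      bool ext = (t & 8) != 0;
      --r; --i; ++k;
      if (!ext) { ++out.gapo; state = 0; }
    }
  }
  out.qs = i; out.ss = j;
  return out.qe > out.qs && out.se > out.ss;
}

// ---- full pipeline for one (query, subject) pair -------------------------

void align_pair(const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
                const WordIndex& idx, const Params& p, std::vector<Aln>& out) {
  std::vector<Seed> seeds;
  collect_seeds(q, idx, p, seeds);
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    int da = a.q - a.s, db = b.q - b.s;
    return da != db ? da < db : a.q < b.q;
  });
  std::vector<HSP> hsps;
  int cur_diag = INT32_MIN, next_free = 0;
  for (size_t i = 0; i < seeds.size(); ++i) {
    int d = seeds[i].q - seeds[i].s;
    if (d != cur_diag) { cur_diag = d; next_free = 0; }
    if (seeds[i].q < next_free) continue;
    HSP h = extend_seed(q, s, seeds[i], p);
    next_free = h.qe;
    if (h.score >= p.hsp_min) hsps.push_back(h);
  }
  if (hsps.empty()) return;
  std::vector<Chain> chains;
  chain_hsps(hsps, p, chains);
  int min_chain = std::max(p.hsp_min, (int)(0.5 * p.min_report));
  for (size_t c = 0; c < chains.size(); ++c) {
    const Chain& ch = chains[c];
    if (ch.score < min_chain) continue;
    Aln a;
    int slop = p.band_pad;
    if (banded_sw(q, s, ch.qs - slop, ch.qe + slop,
                  ch.dmin - p.band_pad, ch.dmax + p.band_pad, p, a))
      out.push_back(a);
  }
  // exact-coordinate de-duplication, keep best score
  std::sort(out.begin(), out.end(), [](const Aln& a, const Aln& b) {
    if (a.qs != b.qs) return a.qs < b.qs;
    if (a.qe != b.qe) return a.qe < b.qe;
    if (a.ss != b.ss) return a.ss < b.ss;
    if (a.se != b.se) return a.se < b.se;
    return a.score > b.score;
  });
  out.erase(std::unique(out.begin(), out.end(), [](const Aln& a, const Aln& b) {
    return a.qs == b.qs && a.qe == b.qe && a.ss == b.ss && a.se == b.se;
  }), out.end());
}

Params make_params(int word, int match, int mismatch, int gap_open,
                   int gap_extend, int xdrop, int hsp_min, int min_report,
                   int band_pad, int max_chain_gap, int max_occ, int self_mod) {
  Params p;
  p.word = word; p.match = match; p.mismatch = mismatch;
  p.gap_open = gap_open; p.gap_extend = gap_extend;
  p.xdrop = xdrop; p.hsp_min = hsp_min; p.min_report = min_report;
  p.band_pad = band_pad; p.max_chain_gap = max_chain_gap;
  p.max_occ = max_occ; p.self_mod = self_mod;
  return p;
}

DataFrame alns_to_df(const std::vector<Aln>& v) {
  int n = (int)v.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), sc(n), mt(n), mm(n), go(n), co(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = v[i].qs; qe[i] = v[i].qe; ss[i] = v[i].ss; se[i] = v[i].se;
    sc[i] = v[i].score; mt[i] = v[i].matches; mm[i] = v[i].mism;
    go[i] = v[i].gapo; co[i] = v[i].cols;
  }
  return DataFrame::create(
      _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
      _["score"] = sc, _["matches"] = mt, _["mismatches"] = mm,
      _["gap_opens"] = go, _["columns"] = co);
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string subject, int word,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int xdrop, int hsp_min, int min_report, int band_pad,
                          int max_chain_gap, int max_occ, int self_mod) {
  Params p = make_params(word, match, mismatch, gap_open, gap_extend, xdrop,
                         hsp_min, min_report, band_pad, max_chain_gap, max_occ,
                         self_mod);
  std::vector<uint8_t> q = encode(query), s = encode(subject);
  WordIndex idx;
  index_words(s, p.word, idx);
  std::vector<Aln> out;
  align_pair(q, s, idx, p, out);
  return alns_to_df(out);
}

namespace {
struct RefIndex {
  std::vector<uint8_t> seq;
  WordIndex idx;
  int word;
};
}  // namespace

// Build a reusable word index over a subject sequence.
// [[Rcpp::export]]
SEXP cpp_index_build(std::string subject, int word) {
  XPtr<RefIndex> p(new RefIndex(), true);
  p->seq = encode(subject);
  p->word = word;
  index_words(p->seq, word, p->idx);
  return p;
}

// Align one query against a prebuilt subject index.
// [[Rcpp::export]]
DataFrame cpp_align_to_index(std::string query, SEXP ptr, int match,
                             int mismatch, int gap_open, int gap_extend,
                             int xdrop, int hsp_min, int min_report,
                             int band_pad, int max_chain_gap, int max_occ,
                             int self_mod) {
  XPtr<RefIndex> rp(ptr);
  Params p = make_params(rp->word, match, mismatch, gap_open, gap_extend,
                         xdrop, hsp_min, min_report, band_pad, max_chain_gap,
                         max_occ, self_mod);
  std::vector<uint8_t> q = encode(query);
  std::vector<Aln> out;
  align_pair(q, rp->seq, rp->idx, p, out);
  return alns_to_df(out);
}

// Best alignment of each reference against one read (read hashed once; the
// reference plays the query so q-side coordinates land on the reference).
// Returns a matrix with one row per (reference, strand) best hit:
// ref_index(1-based), strand(1/-1), score, q_start, q_end, s_start, s_end,
// matches, mismatches, gap_opens, columns. Rows with score 0 mean no hit.
// [[Rcpp::export]]
NumericMatrix cpp_map_refs_to_read(CharacterVector refs, std::string read,
                                   std::string read_rc, int word, int match,
                                   int mismatch, int gap_open, int gap_extend,
                                   int xdrop, int hsp_min, int min_report,
                                   int band_pad, int max_chain_gap,
                                   int max_occ) {
  Params p = make_params(word, match, mismatch, gap_open, gap_extend, xdrop,
                         hsp_min, min_report, band_pad, max_chain_gap, max_occ,
                         0);
  std::vector<uint8_t> fwd = encode(read), rev = encode(read_rc);
  WordIndex idx_f, idx_r;
  index_words(fwd, p.word, idx_f);
  index_words(rev, p.word, idx_r);
  int n = refs.size();
  NumericMatrix m(2 * n, 11);
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> q = encode(std::string(refs[i]));
    for (int st = 0; st < 2; ++st) {
      std::vector<Aln> hits;
      align_pair(q, st == 0 ? fwd : rev, st == 0 ? idx_f : idx_r, p, hits);
      int row = 2 * i + st;
      m(row, 0) = i + 1;
      m(row, 1) = st == 0 ? 1 : -1;
      if (!hits.empty()) {
        const Aln* b = &hits[0];
        for (size_t h = 1; h < hits.size(); ++h)
          if (hits[h].score > b->score) b = &hits[h];
        m(row, 2) = b->score;
        m(row, 3) = b->qs; m(row, 4) = b->qe;
        m(row, 5) = b->ss; m(row, 6) = b->se;
        m(row, 7) = b->matches; m(row, 8) = b->mism;
        m(row, 9) = b->gapo; m(row, 10) = b->cols;
      }
    }
  }
  colnames(m) = CharacterVector::create(
      "ref", "strand", "score", "q_start", "q_end", "s_start", "s_end",
      "matches", "mismatches", "gap_opens", "columns");
  return m;
}

// Apply per-base substitution / insertion / deletion errors to a sequence.
// Uses the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string cpp_mutate_read(std::string seq, double sub_rate, double ins_rate,
                            double del_rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(seq.size() + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    double u = unif_rand();
    if (u < del_rate) continue;
    if (u < del_rate + ins_rate) {
      out.push_back(seq[i]);
      out.push_back(BASES[(int)(unif_rand() * 4) & 3]);
      continue;
    }
    if (u < del_rate + ins_rate + sub_rate) {
      int c = base_code(seq[i]);
      if (c <= 3) {
        int alt = (c + 1 + (int)(unif_rand() * 3)) % 4;
        out.push_back(BASES[alt]);
      } else out.push_back(seq[i]);
      continue;
    }
    out.push_back(seq[i]);
  }
  return out;
}
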