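// Alignment and seeding core: IUPAC-aware semi-global primer scanning,
// banded affine-gap global and local (anchored) alignment, and the
// discontiguous-seed index + seed-and-extend batch classifier.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// 4-bit nucleotide mask: A=1, C=2, G=4, T=8; IUPAC codes are unions.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4;
    case 'W': return 1|8; case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8;
    case 'V': return 1|2|4; case 'N': return 1|2|4|8;
    default: return 0;
  }
}

static inline char iupac_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'U': return 'A';
    case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S';
    case 'W': return 'W'; case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B'; case 'D': return 'H';
    case 'H': return 'D'; case 'N': return 'N';
    default: return 'N';
  }
}

static std::string revcomp_iupac(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = iupac_comp(r[i]);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_iupac(s); }

// ---------------------------------------------------------------------------
// Semi-global (free read ends) edit-distance scan of one primer against one
// read strand; primer may contain IUPAC codes.  Emits every end position with
// edit distance <= max_ed along with the traced start of the placement.
struct ScanHit { int start, end, ed; };

// given a candidate end position (edit distance `ed` at read position j,
// exclusive), recover the start of the placement by a reverse column DP on
// the window read[j-m-ed .. j); ties prefer the most diagonal placement
static int trace_start(const std::string& read, const std::vector<int>& pm,
                       int j, int ed) {
  const int m = (int)pm.size();
  int lo = std::max(0, j - m - ed);
  int wn = j - lo;
  std::vector<int> dp(m + 1), ndp(m + 1);
  for (int i = 0; i <= m; ++i) dp[i] = i;
  int best_ed = INT_MAX, best_c = m;
  if (dp[m] <= ed) { best_ed = dp[m]; best_c = 0; }
  for (int c = 1; c <= wn; ++c) {
    int rmask = iupac_mask(read[j - c]);
    ndp[0] = 0;
    for (int i = 1; i <= m; ++i) {
      int sub = dp[i - 1] + ((pm[m - i] & rmask) ? 0 : 1);
      int del = dp[i] + 1;
      int ins = ndp[i - 1] + 1;
      ndp[i] = std::min(sub, std::min(del, ins));
    }
    if (ndp[m] < best_ed ||
        (ndp[m] == best_ed && std::abs(c - m) < std::abs(best_c - m))) {
      best_ed = ndp[m]; best_c = c;
    }
    dp.swap(ndp);
  }
  return j - best_c;
}

// Myers bit-parallel semi-global search (pattern <= 64); emits every end
// position with edit distance <= max_ed.  Falls back to plain column DP for
// longer patterns.
static void scan_one(const std::string& read, const std::string& primer,
                     int max_ed, std::vector<ScanHit>& out) {
  const int n = (int)read.size(), m = (int)primer.size();
  if (m == 0 || n == 0) return;
  std::vector<int> pm(m);
  for (int i = 0; i < m; ++i) pm[i] = iupac_mask(primer[i]);
  std::vector<std::pair<int, int> > ends; // (end, ed)
  if (m <= 64) {
    uint64_t peq[256];
    bool built[256] = {false};
    const uint64_t msb = 1ULL << (m - 1);
    uint64_t Pv = ~0ULL, Mv = 0ULL;
    int score = m;
    for (int j = 0; j < n; ++j) {
      unsigned char c = (unsigned char)read[j];
      if (!built[c]) {
        uint64_t eq = 0; int rm = iupac_mask(read[j]);
        for (int i = 0; i < m; ++i) if (pm[i] & rm) eq |= (1ULL << i);
        peq[c] = eq; built[c] = true;
      }
      uint64_t Eq = peq[c];
      uint64_t Xv = Eq | Mv;
      uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      if (Ph & msb) ++score; else if (Mh & msb) --score;
      // search variant: D[0][j] = 0, so a zero is shifted into both deltas
      Ph <<= 1;
      Mh <<= 1;
      Pv = Mh | ~(Xv | Ph);
      Mv = Ph & Xv;
      if (score <= max_ed) ends.push_back(std::make_pair(j + 1, score));
    }
  } else {
    std::vector<int> dp(m + 1), ndp(m + 1);
    for (int i = 0; i <= m; ++i) dp[i] = i;
    for (int j = 1; j <= n; ++j) {
      int rmask = iupac_mask(read[j - 1]);
      ndp[0] = 0;
      for (int i = 1; i <= m; ++i) {
        int sub = dp[i - 1] + ((pm[i - 1] & rmask) ? 0 : 1);
        ndp[i] = std::min(sub, std::min(dp[i] + 1, ndp[i - 1] + 1));
      }
      if (ndp[m] <= max_ed) ends.push_back(std::make_pair(j, ndp[m]));
      dp.swap(ndp);
    }
  }
  for (size_t e = 0; e < ends.size(); ++e) {
    int st = trace_start(read, pm, ends[e].first, ends[e].second);
    out.push_back({st, ends[e].first, ends[e].second});
  }
}

// Scan a panel of primers against a set of reads, both strands.  Overlapping
// placements of one primer on one strand are merged keeping minimal edit
// distance (leftmost on ties).  Coordinates are 0-based half-open on the read
// as given.  Strand '-' means the reverse complement of the primer matched.
// [[Rcpp::export]]
DataFrame cpp_scan_panel(CharacterVector reads, CharacterVector primers,
                         IntegerVector max_eds) {
  std::vector<int> o_read, o_primer, o_start, o_end, o_ed;
  std::vector<char> o_strand;
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    for (int p = 0; p < primers.size(); ++p) {
      std::string pr = as<std::string>(primers[p]);
      int k = max_eds[p];
      for (int sdir = 0; sdir < 2; ++sdir) {
        std::vector<ScanHit> hits;
        scan_one(rd, sdir == 0 ? pr : revcomp_iupac(pr), k, hits);
        if (hits.empty()) continue;
        std::sort(hits.begin(), hits.end(), [](const ScanHit& a, const ScanHit& b) {
          if (a.start != b.start) return a.start < b.start;
          return a.end < b.end;
        });
        // merge overlapping placements, keep the minimal-edit representative
        std::vector<ScanHit> merged;
        ScanHit cur = hits[0];
        int cur_hi = hits[0].end;
        for (size_t h = 1; h < hits.size(); ++h) {
          if (hits[h].start < cur_hi) { // overlaps current cluster
            cur_hi = std::max(cur_hi, hits[h].end);
            if (hits[h].ed < cur.ed) cur = hits[h];
          } else {
            merged.push_back(cur);
            cur = hits[h]; cur_hi = hits[h].end;
          }
        }
        merged.push_back(cur);
        for (const ScanHit& h : merged) {
          o_read.push_back(r + 1); o_primer.push_back(p + 1);
          o_strand.push_back(sdir == 0 ? '+' : '-');
          o_start.push_back(h.start); o_end.push_back(h.end);
          o_ed.push_back(h.ed);
        }
      }
    }
  }
  CharacterVector strand(o_strand.size());
  for (size_t i = 0; i < o_strand.size(); ++i)
    strand[i] = std::string(1, o_strand[i]);
  return DataFrame::create(_["read_idx"] = o_read, _["primer_idx"] = o_primer,
                           _["strand"] = strand, _["start"] = o_start,
                           _["end"] = o_end, _["edits"] = o_ed,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Banded affine-gap global alignment (Gotoh).  Band of half-width `band`
// around the length-proportional diagonal; a gap of length L costs
// gap_open + L * gap_ext.  Returns aligned strings plus column statistics.
struct TB { std::vector<uint8_t> v; int rows, width;
  uint8_t& at(int i, int t) { return v[(size_t)i * width + t]; } };

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_ext, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (band < 0) band = std::abs(la - lb) + 150;
  band = std::max(band, std::abs(la - lb) + 8);
  const int W = 2 * band + 1;
  auto center = [&](int i) -> int {
    return la == 0 ? 0 : (int)std::llround((double)i * lb / la);
  };
  std::vector<int> M(W), X(W), Y(W), nM(W), nX(W), nY(W);
  TB tb; tb.rows = la + 1; tb.width = W; tb.v.assign((size_t)(la + 1) * W, 0);
  // row 0
  {
    int c0 = 0;
    for (int t = 0; t < W; ++t) { M[t] = X[t] = Y[t] = NEG; }
    for (int j = 0; j <= lb; ++j) {
      int t = j - c0 + band; if (t < 0 || t >= W) continue;
      if (j == 0) M[t] = 0;
      else {
        Y[t] = -(gap_open + j * gap_ext);
        tb.at(0, t) |= ((j == 1 ? 0 : 1) << 4); // open from M at (0,0), then extend
      }
    }
  }
  for (int i = 1; i <= la; ++i) {
    int ci = center(i), cp = center(i - 1);
    for (int t = 0; t < W; ++t) { nM[t] = nX[t] = nY[t] = NEG; }
    int jlo = std::max(0, ci - band), jhi = std::min(lb, ci + band);
    for (int j = jlo; j <= jhi; ++j) {
      int t = j - ci + band;
      // X: gap in b (consume a[i])
      {
        int tp = j - cp + band;
        int fm = NEG, fx = NEG, fy = NEG;
        if (tp >= 0 && tp < W) { fm = M[tp]; fx = X[tp]; fy = Y[tp]; }
        int open = std::max(fm, fy) - gap_open - gap_ext;
        int ext = fx - gap_ext;
        if (j == 0 && i >= 1) { /* left edge handled via recurrence from (i-1,0) */ }
        if (open >= ext) { nX[t] = open; tb.at(i, t) |= ((fm >= fy ? 0 : 2) << 2); }
        else { nX[t] = ext; tb.at(i, t) |= (1 << 2); }
      }
      if (j > 0) {
        // M: a[i] vs b[j]
        int tp = j - 1 - cp + band;
        int fm = NEG, fx = NEG, fy = NEG;
        if (tp >= 0 && tp < W) { fm = M[tp]; fx = X[tp]; fy = Y[tp]; }
        int best = fm; uint8_t src = 0;
        if (fx > best) { best = fx; src = 1; }
        if (fy > best) { best = fy; src = 2; }
        if (best > NEG) {
          int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          nM[t] = best + s; tb.at(i, t) |= src;
        }
        // Y: gap in a (consume b[j]) within this row
        int tl = t - 1;
        int fm2 = NEG, fx2 = NEG, fy2 = NEG;
        if (tl >= 0) { fm2 = nM[tl]; fx2 = nX[tl]; fy2 = nY[tl]; }
        int open = std::max(fm2, fx2) - gap_open - gap_ext;
        int ext = fy2 - gap_ext;
        if (open >= ext) { nY[t] = open; tb.at(i, t) |= ((fm2 >= fx2 ? 0 : 2) << 4); }
        else { nY[t] = ext; tb.at(i, t) |= (1 << 4); }
      }
    }
    M.swap(nM); X.swap(nX); Y.swap(nY);
  }
  int tend = lb - center(la) + band;
  if (tend < 0 || tend >= W)
    stop("band too narrow for global alignment");
  int score = M[tend]; int state = 0;
  if (X[tend] > score) { score = X[tend]; state = 1; }
  if (Y[tend] > score) { score = Y[tend]; state = 2; }
  if (score <= NEG) stop("band too narrow for global alignment");
  // traceback
  std::string aa, bb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int t = j - center(i) + band;
    uint8_t code = tb.at(i, t);
    if (state == 0) {
      uint8_t src = code & 3;
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      --i; --j; state = src;
    } else if (state == 1) {
      uint8_t src = (code >> 2) & 3;
      aa.push_back(a[i - 1]); bb.push_back('-');
      --i; state = (src == 1) ? 1 : (src == 0 ? 0 : 2);
    } else {
      uint8_t src = (code >> 4) & 3;
      aa.push_back('-'); bb.push_back(b[j - 1]);
      --j; state = (src == 1) ? 2 : (src == 0 ? 0 : 1);
    }
    if (i == 0 && j == 0) break;
    if (i < 0 || j < 0) stop("traceback escaped matrix");
  }
  std::reverse(aa.begin(), aa.end()); std::reverse(bb.begin(), bb.end());
  int matches = 0, cols = (int)aa.size();
  for (int c = 0; c < cols; ++c)
    if (aa[c] != '-' && aa[c] == bb[c]) ++matches;
  return List::create(_["score"] = score, _["aln_a"] = aa, _["aln_b"] = bb,
                      _["matches"] = matches, _["columns"] = cols,
                      _["identity"] = cols ? 100.0 * matches / cols : 0.0);
}

// ---------------------------------------------------------------------------
// Banded local (Smith-Waterman) alignment restricted to diagonals
// j - i in [diag - band, diag + band], with optional X-drop row termination.
// Returns 1-based inclusive spans and column statistics; aligned strings on
// request.
// [[Rcpp::export]]
List cpp_align_local(std::string q, std::string s, int diag, int band,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int xdrop, bool want_strings) {
  const int lq = (int)q.size(), ls = (int)s.size();
  const int W = 2 * band + 1;
  std::vector<int> M(W), X(W), Y(W), nM(W), nX(W), nY(W);
  TB tb; tb.rows = lq + 1; tb.width = W; tb.v.assign((size_t)(lq + 1) * W, 0);
  for (int t = 0; t < W; ++t) { M[t] = X[t] = Y[t] = NEG; }
  // row 0: empty prefix of q; local => zeros where in band
  {
    int ci = diag; // j - 0 = diag center for row 0
    for (int j = std::max(0, ci - band); j <= std::min(ls, ci + band); ++j)
      M[j - ci + band] = 0;
  }
  int best = 0, bi = 0, bj = 0, bstate = 0;
  for (int i = 1; i <= lq; ++i) {
    int ci = i + diag, cp = i - 1 + diag;
    for (int t = 0; t < W; ++t) { nM[t] = nX[t] = nY[t] = NEG; }
    int jlo = std::max(0, ci - band), jhi = std::min(ls, ci + band);
    if (jlo > jhi) break;
    int rowmax = NEG;
    for (int j = jlo; j <= jhi; ++j) {
      int t = j - ci + band;
      // X: consume q[i] (gap in s)
      {
        int tp = j - cp + band;
        int fm = NEG, fx = NEG, fy = NEG;
        if (tp >= 0 && tp < W) { fm = M[tp]; fx = X[tp]; fy = Y[tp]; }
        int open = std::max(fm, fy) - gap_open - gap_ext;
        int ext = fx - gap_ext;
        if (open >= ext) { nX[t] = open; tb.at(i, t) |= ((fm >= fy ? 0 : 2) << 2); }
        else { nX[t] = ext; tb.at(i, t) |= (1 << 2); }
      }
      if (j > 0) {
        int tp = j - 1 - cp + band;
        int fm = NEG, fx = NEG, fy = NEG;
        if (tp >= 0 && tp < W) { fm = M[tp]; fx = X[tp]; fy = Y[tp]; }
        int prev = 0; uint8_t src = 0; // 0 = fresh start
        if (fm > prev) { prev = fm; src = 1; }
        if (fx > prev) { prev = fx; src = 2; }
        if (fy > prev) { prev = fy; src = 3; }
        int sc = (q[i - 1] == s[j - 1]) ? match : mismatch;
        nM[t] = prev + sc; tb.at(i, t) |= src;
        // Y: consume s[j] (gap in q)
        int tl = t - 1;
        int fm2 = NEG, fx2 = NEG, fy2 = NEG;
        if (tl >= 0) { fm2 = nM[tl]; fx2 = nX[tl]; fy2 = nY[tl]; }
        int open = std::max(fm2, fx2) - gap_open - gap_ext;
        int ext = fy2 - gap_ext;
        if (open >= ext) { nY[t] = open; tb.at(i, t) |= ((fm2 >= fx2 ? 0 : 2) << 4); }
        else { nY[t] = ext; tb.at(i, t) |= (1 << 4); }
      }
      int cm = std::max(nM[t], std::max(nX[t], nY[t]));
      if (cm > rowmax) rowmax = cm;
      if (nM[t] > best) { best = nM[t]; bi = i; bj = j; bstate = 0; }
    }
    M.swap(nM); X.swap(nX); Y.swap(nY);
    if (xdrop >= 0 && best > 0 && rowmax < best - xdrop) break;
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0,
                        _["mismatches"] = 0, _["gap_opens"] = 0,
                        _["columns"] = 0, _["identity"] = 0.0,
                        _["aln_q"] = "", _["aln_s"] = "");
  }
  // traceback from (bi, bj, M)
  std::string aq, as_;
  int i = bi, j = bj, state = bstate;
  int matches = 0, mismatches = 0, gap_opens = 0, cols = 0;
  while (true) {
    int t = j - (i + diag) + band;
    uint8_t code = tb.at(i, t);
    if (state == 0) {
      uint8_t src = code & 3;
      if (want_strings) { aq.push_back(q[i - 1]); as_.push_back(s[j - 1]); }
      if (q[i - 1] == s[j - 1]) ++matches; else ++mismatches;
      ++cols; --i; --j;
      if (src == 0) break;
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
    } else if (state == 1) {
      uint8_t src = (code >> 2) & 3;
      if (want_strings) { aq.push_back(q[i - 1]); as_.push_back('-'); }
      ++cols; --i;
      if (src != 1) ++gap_opens;
      state = (src == 1) ? 1 : (src == 0 ? 0 : 2);
    } else {
      uint8_t src = (code >> 4) & 3;
      if (want_strings) { aq.push_back('-'); as_.push_back(s[j - 1]); }
      ++cols; --j;
      if (src != 1) ++gap_opens;
      state = (src == 1) ? 2 : (src == 0 ? 0 : 1);
    }
  }
  std::reverse(aq.begin(), aq.end()); std::reverse(as_.begin(), as_.end());
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1, _["s_end"] = bj,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_opens"] = gap_opens, _["columns"] = cols,
                      _["identity"] = cols ? 100.0 * matches / cols : 0.0,
                      _["aln_q"] = aq, _["aln_s"] = as_);
}

// Score-only variant of the banded local alignment (no traceback matrix, no
// List construction); used to rank candidate subjects before the full
// alignment is recomputed for the winner only.
static int local_score(const std::string& q, const std::string& s, int diag,
                       int band, int match, int mismatch, int gap_open,
                       int gap_ext, int xdrop) {
  const int lq = (int)q.size(), ls = (int)s.size();
  const int W = 2 * band + 1;
  std::vector<int> M(W), X(W), Y(W), nM(W), nX(W), nY(W);
  for (int t = 0; t < W; ++t) { M[t] = X[t] = Y[t] = NEG; }
  {
    int ci = diag;
    for (int j = std::max(0, ci - band); j <= std::min(ls, ci + band); ++j)
      M[j - ci + band] = 0;
  }
  int best = 0;
  for (int i = 1; i <= lq; ++i) {
    int ci = i + diag, cp = i - 1 + diag;
    for (int t = 0; t < W; ++t) { nM[t] = nX[t] = nY[t] = NEG; }
    int jlo = std::max(0, ci - band), jhi = std::min(ls, ci + band);
    if (jlo > jhi) break;
    int rowmax = NEG;
    for (int j = jlo; j <= jhi; ++j) {
      int t = j - ci + band;
      {
        int tp = j - cp + band;
        int fm = NEG, fx = NEG, fy = NEG;
        if (tp >= 0 && tp < W) { fm = M[tp]; fx = X[tp]; fy = Y[tp]; }
        nX[t] = std::max(std::max(fm, fy) - gap_open - gap_ext, fx - gap_ext);
      }
      if (j > 0) {
        int tp = j - 1 - cp + band;
        int fm = NEG, fx = NEG, fy = NEG;
        if (tp >= 0 && tp < W) { fm = M[tp]; fx = X[tp]; fy = Y[tp]; }
        int prev = std::max(0, std::max(fm, std::max(fx, fy)));
        nM[t] = prev + ((q[i - 1] == s[j - 1]) ? match : mismatch);
        int tl = t - 1;
        int fm2 = NEG, fx2 = NEG, fy2 = NEG;
        if (tl >= 0) { fm2 = nM[tl]; fx2 = nX[tl]; fy2 = nY[tl]; }
        nY[t] = std::max(std::max(fm2, fx2) - gap_open - gap_ext,
                         fy2 - gap_ext);
      }
      int cm = std::max(nM[t], std::max(nX[t], nY[t]));
      if (cm > rowmax) rowmax = cm;
      if (nM[t] > best) best = nM[t];
    }
    M.swap(nM); X.swap(nX); Y.swap(nY);
    if (xdrop >= 0 && best > 0 && rowmax < best - xdrop) break;
  }
  return best;
}

// ---------------------------------------------------------------------------
// Discontiguous-seed inverted index over a reference set.
struct SeedIndexC {
  int span;
  std::vector<int> care;                 // offsets of care positions
  std::vector<std::string> ids, seqs;
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t> > > h;
};

static inline int base2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

static inline bool template_key(const std::string& s, int pos,
                                const std::vector<int>& care, uint32_t& key) {
  uint32_t k = 0;
  for (size_t c = 0; c < care.size(); ++c) {
    int b = base2(s[pos + care[c]]);
    if (b < 0) return false;
    k = (k << 2) | (uint32_t)b;
  }
  key = k;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector ids,
                     std::string mask) {
  SeedIndexC* idx = new SeedIndexC();
  idx->span = (int)mask.size();
  for (int i = 0; i < (int)mask.size(); ++i)
    if (mask[i] == '1') idx->care.push_back(i);
  for (int s = 0; s < seqs.size(); ++s) {
    idx->ids.push_back(as<std::string>(ids[s]));
    idx->seqs.push_back(as<std::string>(seqs[s]));
  }
  for (int s = 0; s < (int)idx->seqs.size(); ++s) {
    const std::string& sq = idx->seqs[s];
    int n = (int)sq.size() - idx->span;
    for (int p = 0; p <= n; ++p) {
      uint32_t key;
      if (template_key(sq, p, idx->care, key))
        idx->h[key].push_back(std::make_pair((int32_t)s, (int32_t)p));
    }
  }
  XPtr<SeedIndexC> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<SeedIndexC> idx(xp);
  return (int)idx->h.size();
}

// [[Rcpp::export]]
List cpp_index_keys(SEXP xp) {
  XPtr<SeedIndexC> idx(xp);
  size_t tot = 0;
  for (auto& kv : idx->h) tot += kv.second.size();
  return List::create(_["n_keys"] = (int)idx->h.size(),
                      _["n_positions"] = (double)tot,
                      _["n_refs"] = (int)idx->seqs.size());
}

// Best-hit classification of a batch of queries against the index.
// Anchors are chained per subject in diagonal bins of width chain_band;
// the max_subjects highest-weight subjects are extended with banded local
// alignment around the chain diagonal.
// [[Rcpp::export]]
DataFrame cpp_classify_batch(CharacterVector queries, SEXP xp,
                             int match, int mismatch, int gap_open,
                             int gap_ext, int chain_band, int max_subjects,
                             int ext_band, int xdrop) {
  XPtr<SeedIndexC> idx(xp);
  const int nq = queries.size();
  const int nref = (int)idx->seqs.size();
  std::vector<std::string> o_subj(nq);
  IntegerVector o_score(nq), o_len(nq), o_match(nq), o_mm(nq), o_go(nq),
      o_qs(nq), o_qe(nq), o_ss(nq), o_se(nq), o_nanch(nq), o_nsubj(nq);
  NumericVector o_ident(nq);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    // gather anchors per (subject, diagonal bin)
    std::unordered_map<int64_t, std::pair<int32_t, int64_t> > bins; // count, diag sum
    int qn = (int)q.size() - idx->span;
    int total_anchors = 0;
    for (int p = 0; p <= qn; ++p) {
      uint32_t key;
      if (!template_key(q, p, idx->care, key)) continue;
      auto it = idx->h.find(key);
      if (it == idx->h.end()) continue;
      for (size_t a = 0; a < it->second.size(); ++a) {
        int s = it->second[a].first;
        int diag = it->second[a].second - p;
        int bin = (int)std::floor((double)diag / chain_band);
        int64_t bk = (int64_t)s * 2000003LL + (bin + 1000000);
        auto& e = bins[bk];
        e.first += 1; e.second += diag;
        ++total_anchors;
      }
    }
    o_nanch[qi] = total_anchors;
    if (bins.empty()) {
      o_subj[qi] = ""; o_score[qi] = 0; o_ident[qi] = 0; o_len[qi] = 0;
      o_match[qi] = 0; o_mm[qi] = 0; o_go[qi] = 0;
      o_qs[qi] = NA_INTEGER; o_qe[qi] = NA_INTEGER;
      o_ss[qi] = NA_INTEGER; o_se[qi] = NA_INTEGER; o_nsubj[qi] = 0;
      continue;
    }
    // per subject: best pair of adjacent bins (chains straddling a bin edge)
    std::vector<int> w(nref, 0); std::vector<double> rep(nref, 0.0);
    for (auto& kv : bins) {
      int s = (int)(kv.first / 2000003LL);
      int bin = (int)(kv.first % 2000003LL) - 1000000;
      int cnt = kv.second.first;
      double dsum = kv.second.second;
      // combine with right neighbour if present
      int64_t bk2 = (int64_t)s * 2000003LL + (bin + 1 + 1000000);
      auto it2 = bins.find(bk2);
      if (it2 != bins.end()) {
        cnt += it2->second.first; dsum += it2->second.second;
      }
      if (cnt > w[s]) { w[s] = cnt; rep[s] = dsum / cnt; }
    }
    std::vector<int> order;
    for (int s = 0; s < nref; ++s) if (w[s] > 0) order.push_back(s);
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      if (w[a] != w[b]) return w[a] > w[b];
      return idx->ids[a] < idx->ids[b];
    });
    o_nsubj[qi] = (int)order.size();
    // candidate filter: chain weight >= 25% of the best chain (and >= 3
    // anchors), capped at max_subjects
    int floorw = std::max(3, (w[order[0]] + 3) / 4);
    std::vector<int> cand;
    for (size_t k = 0; k < order.size() &&
                       (int)cand.size() < max_subjects; ++k)
      if (w[order[k]] >= floorw) cand.push_back(order[k]);
    if (cand.empty()) cand.push_back(order[0]);
    // score-only pass, full traceback only for the top score (ties broken
    // by gap-inclusive identity, then subject id)
    int bscore = -1;
    std::vector<int> winners;
    for (size_t k = 0; k < cand.size(); ++k) {
      int s = cand[k];
      int sc = local_score(q, idx->seqs[s], (int)std::llround(rep[s]),
                           ext_band, match, mismatch, gap_open, gap_ext,
                           xdrop);
      if (sc > bscore) { bscore = sc; winners.assign(1, s); }
      else if (sc == bscore) winners.push_back(s);
    }
    double bident = -1; int bidx = -1;
    List bhit;
    for (size_t k = 0; k < winners.size(); ++k) {
      int s = winners[k];
      List hit = cpp_align_local(q, idx->seqs[s], (int)std::llround(rep[s]),
                                 ext_band, match, mismatch, gap_open, gap_ext,
                                 xdrop, false);
      double id = as<double>(hit["identity"]);
      bool better = (bidx < 0) || id > bident ||
                    (id == bident && idx->ids[s] < idx->ids[bidx]);
      if (better) { bident = id; bidx = s; bhit = hit; }
    }
    if (bidx < 0 || bscore <= 0) {
      o_subj[qi] = ""; o_score[qi] = 0; o_ident[qi] = 0; o_len[qi] = 0;
      o_match[qi] = 0; o_mm[qi] = 0; o_go[qi] = 0;
      o_qs[qi] = NA_INTEGER; o_qe[qi] = NA_INTEGER;
      o_ss[qi] = NA_INTEGER; o_se[qi] = NA_INTEGER;
      continue;
    }
    o_subj[qi] = idx->ids[bidx];
    o_score[qi] = bscore; o_ident[qi] = bident;
    o_len[qi] = as<int>(bhit["columns"]); o_match[qi] = as<int>(bhit["matches"]);
    o_mm[qi] = as<int>(bhit["mismatches"]); o_go[qi] = as<int>(bhit["gap_opens"]);
    o_qs[qi] = as<int>(bhit["q_start"]); o_qe[qi] = as<int>(bhit["q_end"]);
    o_ss[qi] = as<int>(bhit["s_start"]); o_se[qi] = as<int>(bhit["s_end"]);
  }
  return DataFrame::create(
      _["subject_id"] = wrap(o_subj), _["score"] = o_score,
      _["percent_identity"] = o_ident, _["alignment_length"] = o_len,
      _["matches"] = o_match, _["mismatches"] = o_mm, _["gap_opens"] = o_go,
      _["q_start"] = o_qs, _["q_end"] = o_qe, _["s_start"] = o_ss,
      _["s_end"] = o_se, _["n_anchors"] = o_nanch,
      _["n_subjects"] = o_nsubj, _["stringsAsFactors"] = false);
}
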