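// Alignment engines: affine-gap global (Gotoh) aligner and a seed-and-extend
// local aligner (exact-word seeding, ungapped X-drop extension, banded affine
// local realignment, identity trimming of hit termini).
//
// Conventions shared with the R layer:
//   * coordinates are 0-based half-open on the plus strand of each input;
//   * a gap of length L costs gap_open + L * gap_extend (blast-style);
//   * 'N' never matches anything (counts as mismatch);
//   * deterministic tie-breaking: match/mismatch state preferred over a gap
//     in s2 (s1 base over '-'), preferred over a gap in s1.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const long long NEG_INF = -(1LL << 60);

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else: never matches
  }
}

static inline bool is_match(char a, char b) {
  int ca = base_code(a), cb = base_code(b);
  return ca >= 0 && ca == cb;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t k = 0; k < r.size(); ++k) {
    switch (r[k]) {
    case 'A': r[k] = 'T'; break;
    case 'C': r[k] = 'G'; break;
    case 'G': r[k] = 'C'; break;
    case 'T': r[k] = 'A'; break;
    default:  r[k] = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(std::string s) { return revcomp_str(s); }

// ---------------------------------------------------------------------------
// Global affine alignment (Needleman-Wunsch-Gotoh), full traceback.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string s1, std::string s2,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) s1.size(), m = (int) s2.size();
  if (n == 0 || m == 0) stop("global alignment requires non-empty sequences");
  const long long open_cost = (long long) gap_open + gap_extend;
  const long long ext_cost  = gap_extend;

  // rolling score rows; packed traceback bytes (2 bits per state)
  std::vector<long long> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<long long> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  Mprev[0] = 0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF; Xprev[j] = NEG_INF;
    Yprev[j] = -(long long) gap_open - (long long) gap_extend * j;
    tb[j] = (uint8_t)(2u << 4); // Y from Y
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    Xcur[0] = -(long long) gap_open - (long long) gap_extend * i;
    tb[(size_t) i * (m + 1)] = (uint8_t)(1u << 2); // X from X
    for (int j = 1; j <= m; ++j) {
      uint8_t code = 0;
      // M: diagonal, source order M > X > Y on ties
      long long best = Mprev[j - 1]; int src = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; src = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; src = 2; }
      long long sub = is_match(s1[i - 1], s2[j - 1]) ? match : mismatch;
      Mcur[j] = (best <= NEG_INF / 2) ? NEG_INF : best + sub;
      code |= (uint8_t) src;
      // X: gap in s2, consumes s1 (vertical), from row i-1 same j
      best = Mprev[j] - open_cost; src = 0;
      if (Xprev[j] - ext_cost > best) { best = Xprev[j] - ext_cost; src = 1; }
      if (Yprev[j] - open_cost > best) { best = Yprev[j] - open_cost; src = 2; }
      Xcur[j] = (best <= NEG_INF / 2) ? NEG_INF : best;
      code |= (uint8_t)(src << 2);
      // Y: gap in s1, consumes s2 (horizontal), same row j-1
      best = Mcur[j - 1] - open_cost; src = 0;
      if (Xcur[j - 1] - open_cost > best) { best = Xcur[j - 1] - open_cost; src = 1; }
      if (Ycur[j - 1] - ext_cost > best) { best = Ycur[j - 1] - ext_cost; src = 2; }
      Ycur[j] = (best <= NEG_INF / 2) ? NEG_INF : best;
      code |= (uint8_t)(src << 4);
      tb[(size_t) i * (m + 1) + j] = code;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  long long score = Mprev[m]; int state = 0; // 0=M, 1=X, 2=Y
  if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
  if (Yprev[m] > score) { score = Yprev[m]; state = 2; }
  // tie preference M > X > Y
  if (Mprev[m] == score) state = 0;
  else if (Xprev[m] == score) state = 1;

  std::string a1, a2;
  a1.reserve(n + m); a2.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t) i * (m + 1) + j];
    if (state == 0) {
      a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]);
      state = code & 3u; --i; --j;
    } else if (state == 1) {
      a1.push_back(s1[i - 1]); a2.push_back('-');
      state = (code >> 2) & 3u; --i;
    } else {
      a1.push_back('-'); a2.push_back(s2[j - 1]);
      state = (code >> 4) & 3u; --j;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(_["a1"] = a1, _["a2"] = a2, _["score"] = (double) score);
}

// ---------------------------------------------------------------------------
// Banded affine local alignment (Smith-Waterman-Gotoh restricted to a
// diagonal band), used to realign candidate hit regions.
// ---------------------------------------------------------------------------

struct LocalAln {
  int i0, i1, j0, j1;      // half-open on the two input windows
  long long score;
  std::string a1, a2;
  bool ok;
};

static LocalAln banded_local(const std::string& s1, const std::string& s2,
                             int dlo, int dhi,
                             int match, int mismatch, int gap_open, int gap_extend) {
  LocalAln out; out.ok = false;
  const int n = (int) s1.size(), m = (int) s2.size();
  dlo = std::max(dlo, -n); dhi = std::min(dhi, m);
  if (dlo > dhi) return out;
  const int W = dhi - dlo + 1;
  const long long open_cost = (long long) gap_open + gap_extend;
  const long long ext_cost  = gap_extend;

  std::vector<long long> Mprev(W, NEG_INF), Xprev(W, NEG_INF), Yprev(W, NEG_INF);
  std::vector<long long> Mcur(W, NEG_INF), Xcur(W, NEG_INF), Ycur(W, NEG_INF);
  // traceback codes: M: 0=start,1=M,2=X,3=Y (2 bits), X: 0..2, Y: 0..2
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);

  long long best_score = 0; int best_i = -1, best_c = -1;

  for (int i = 0; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    int jmin = std::max(0, i + dlo), jmax = std::min(m, i + dhi);
    for (int j = jmin; j <= jmax; ++j) {
      int c = j - i - dlo; // column in band
      uint8_t code = 0;
      if (i >= 1 && j >= 1) {
        // diagonal predecessor lives at (i-1, j-1) -> same band column c
        long long prev = 0; int src = 0; // 0 = fresh start
        if (Mprev[c] > prev) { prev = Mprev[c]; src = 1; }
        if (c < W && Xprev[c] > prev) { prev = Xprev[c]; src = 2; }
        if (Yprev[c] > prev) { prev = Yprev[c]; src = 3; }
        long long sub = is_match(s1[i - 1], s2[j - 1]) ? match : mismatch;
        Mcur[c] = prev + sub;
        code |= (uint8_t) src;
      }
      if (i >= 1 && c + 1 < W) {
        // X from (i-1, j): band column c+1 in previous row
        long long best = Mprev[c + 1] - open_cost; int src = 0;
        if (Xprev[c + 1] - ext_cost > best) { best = Xprev[c + 1] - ext_cost; src = 1; }
        if (Yprev[c + 1] - open_cost > best) { best = Yprev[c + 1] - open_cost; src = 2; }
        if (best > NEG_INF / 2) { Xcur[c] = best; code |= (uint8_t)(src << 2); }
      }
      if (j >= 1 && c - 1 >= 0) {
        // Y from (i, j-1): band column c-1 in same row
        long long best = Mcur[c - 1] - open_cost; int src = 0;
        if (Xcur[c - 1] - open_cost > best) { best = Xcur[c - 1] - open_cost; src = 1; }
        if (Ycur[c - 1] - ext_cost > best) { best = Ycur[c - 1] - ext_cost; src = 2; }
        if (best > NEG_INF / 2) { Ycur[c] = best; code |= (uint8_t)(src << 4); }
      }
      tb[(size_t) i * W + c] = code;
      if (Mcur[c] > best_score) { best_score = Mcur[c]; best_i = i; best_c = c; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (best_i < 0 || best_score <= 0) return out;

  // traceback from best M cell
  std::string a1, a2;
  int i = best_i, c = best_c, state = 0; // 0=M,1=X,2=Y
  int j = i + dlo + c;
  out.i1 = i; out.j1 = j; out.score = best_score;
  while (true) {
    uint8_t code = tb[(size_t) i * W + c];
    if (state == 0) {
      a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]);
      int src = code & 3u;
      --i; --j; // band column unchanged
      if (src == 0) break;
      state = src - 1;
    } else if (state == 1) {
      a1.push_back(s1[i - 1]); a2.push_back('-');
      int src = (code >> 2) & 3u;
      --i; ++c; // same j, previous row
      state = src;
    } else {
      a1.push_back('-'); a2.push_back(s2[j - 1]);
      int src = (code >> 4) & 3u;
      --j; --c;
      state = src;
    }
  }
  out.i0 = i; out.j0 = j;
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  out.a1 = a1; out.a2 = a2; out.ok = true;
  return out;
}

// ---------------------------------------------------------------------------
// Seed-and-extend machinery.
// ---------------------------------------------------------------------------

struct Hsp {
  int i0, i1, j0, j1;  // half-open
  long long score;
  int diag() const { return i0 - j0; }
  int ilen() const { return i1 - i0; }
  int jlen() const { return j1 - j0; }
};

struct Hit {
  int g1_start, g1_end, g2_start, g2_end;
  char strand;
  long long score;
  int n_match, n_mismatch, n_gapcols;
  std::string a1, a2;
};

static void ungapped_extend(const std::string& s1, const std::string& s2,
                            int i, int j, int word,
                            int match, int mismatch, long long xdrop,
                            Hsp& out) {
  const int n = (int) s1.size(), m = (int) s2.size();
  long long seed_score = (long long) word * match;
  // right
  long long cur = 0, best = 0; int besti = i + word, bestj = j + word;
  for (int ii = i + word, jj = j + word; ii < n && jj < m; ++ii, ++jj) {
    cur += is_match(s1[ii], s2[jj]) ? match : mismatch;
    if (cur > best) { best = cur; besti = ii + 1; bestj = jj + 1; }
    if (cur < best - xdrop) break;
  }
  long long right = best; int i1 = besti, j1 = bestj;
  // left
  cur = 0; best = 0; besti = i; bestj = j;
  for (int ii = i - 1, jj = j - 1; ii >= 0 && jj >= 0; --ii, --jj) {
    cur += is_match(s1[ii], s2[jj]) ? match : mismatch;
    if (cur > best) { best = cur; besti = ii; bestj = jj; }
    if (cur < best - xdrop) break;
  }
  out.i0 = besti; out.j0 = bestj; out.i1 = i1; out.j1 = j1;
  out.score = seed_score + right + best;
}

static double overlap_frac(int a0, int a1, int b0, int b1) {
  int ov = std::min(a1, b1) - std::max(a0, b0);
  if (ov <= 0) return 0.0;
  int denom = std::min(a1 - a0, b1 - b0);
  return denom > 0 ? (double) ov / denom : 0.0;
}

// trim alignment columns to the maximal-scoring contiguous block under a
// scoring with break-even identity trim_id (match +1, other -t/(1-t));
// returns [c0, c1) column range, empty when nothing positive remains
static std::pair<int,int> kadane_trim(const std::string& a1, const std::string& a2,
                                      double trim_id) {
  const int L = (int) a1.size();
  const double pen = trim_id / (1.0 - trim_id);
  // ties resolved toward the longer block so zero-sum terminal stretches
  // (isolated mismatch clusters at the true boundary) are retained
  double cur = 0.0, best = 0.0;
  int cur0 = 0, b0 = 0, b1 = 0;
  for (int c = 0; c < L; ++c) {
    double w = (a1[c] != '-' && a2[c] != '-' && is_match(a1[c], a2[c])) ? 1.0 : -pen;
    cur += w;
    if (cur < 0) { cur = 0.0; cur0 = c + 1; }
    else if (cur >= best && cur > 0) { best = cur; b0 = cur0; b1 = c + 1; }
  }
  return std::make_pair(b0, b1);
}

static long long score_alignment(const std::string& a1, const std::string& a2,
                                 int match, int mismatch, int gap_open, int gap_extend,
                                 int& n_match, int& n_mismatch, int& n_gapcols) {
  long long s = 0;
  n_match = n_mismatch = n_gapcols = 0;
  int L = (int) a1.size();
  for (int c = 0; c < L; ++c) {
    bool g1 = a1[c] == '-', g2 = a2[c] == '-';
    if (g1 || g2) {
      ++n_gapcols;
      s -= gap_extend;
      bool prev_same_gap = c > 0 &&
        ((g1 && a1[c - 1] == '-') || (g2 && a2[c - 1] == '-'));
      if (!prev_same_gap) s -= gap_open;
    } else if (is_match(a1[c], a2[c])) {
      ++n_match; s += match;
    } else {
      ++n_mismatch; s += mismatch;
    }
  }
  return s;
}

static int count_nongap(const std::string& a, int c0, int c1) {
  int k = 0;
  for (int c = c0; c < c1; ++c) if (a[c] != '-') ++k;
  return k;
}

// one strand of the search; s2s is s2 (plus) or revcomp(s2) (minus)
static void strand_hits(const std::string& s1, const std::string& s2s, char strand,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int word, long long xdrop, int band, int diag_window,
                        int min_len, double min_identity, double trim_identity,
                        std::vector<Hit>& hits) {
  const int n = (int) s1.size(), m = (int) s2s.size();
  if (n < word || m < word) return;

  // index words of s1
  std::unordered_map<uint32_t, std::vector<int> > index;
  index.reserve((size_t) n * 2);
  {
    uint32_t code = 0; int run = 0;
    const uint32_t mask = (word < 16) ? ((1u << (2 * word)) - 1u) : 0xFFFFFFFFu;
    for (int i = 0; i < n; ++i) {
      int b = base_code(s1[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++run >= word) index[code].push_back(i - word + 1);
    }
  }

  std::unordered_map<int, int> covered; // diag -> i end (exclusive) of last HSP
  std::vector<Hsp> hsps;
  {
    uint32_t code = 0; int run = 0;
    const uint32_t mask = (word < 16) ? ((1u << (2 * word)) - 1u) : 0xFFFFFFFFu;
    for (int j = 0; j < m; ++j) {
      int b = base_code(s2s[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++run < word) continue;
      int jpos = j - word + 1;
      std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = index.find(code);
      if (it == index.end()) continue;
      for (size_t k = 0; k < it->second.size(); ++k) {
        int i = it->second[k];
        int d = i - jpos;
        std::unordered_map<int, int>::iterator cit = covered.find(d);
        if (cit != covered.end() && i < cit->second) continue;
        Hsp h;
        ungapped_extend(s1, s2s, i, jpos, word, match, mismatch, xdrop, h);
        covered[d] = h.i1;
        hsps.push_back(h);
      }
    }
  }
  if (hsps.empty()) return;

  // greedy dedupe, highest score first (deterministic tie keys)
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.i0 != b.i0) return a.i0 < b.i0;
    return a.j0 < b.j0;
  });
  if (hsps.size() > 20000) hsps.resize(20000);
  std::vector<Hsp> kept;
  for (size_t k = 0; k < hsps.size(); ++k) {
    bool dup = false;
    for (size_t q = 0; q < kept.size(); ++q) {
      if (std::abs(hsps[k].diag() - kept[q].diag()) <= diag_window &&
          overlap_frac(hsps[k].i0, hsps[k].i1, kept[q].i0, kept[q].i1) >= 0.5 &&
          overlap_frac(hsps[k].j0, hsps[k].j1, kept[q].j0, kept[q].j1) >= 0.5) {
        dup = true; break;
      }
    }
    if (!dup) kept.push_back(hsps[k]);
  }

  // chain near-diagonal neighbours so indel-split fragments realign together
  std::sort(kept.begin(), kept.end(), [](const Hsp& a, const Hsp& b) {
    if (a.i0 != b.i0) return a.i0 < b.i0;
    return a.j0 < b.j0;
  });
  struct Chain { int i0, i1, j0, j1, dmin, dmax; long long score; };
  std::vector<Chain> chains;
  for (size_t k = 0; k < kept.size(); ++k) {
    const Hsp& h = kept[k];
    bool merged = false;
    if (!chains.empty()) {
      Chain& c = chains.back();
      if (std::abs(h.diag() - c.dmin) <= diag_window + band &&
          std::abs(h.diag() - c.dmax) <= diag_window + band &&
          h.i0 - c.i1 <= 300 && h.j0 - c.j1 <= 300 && h.j0 >= c.j0) {
        c.i1 = std::max(c.i1, h.i1); c.j1 = std::max(c.j1, h.j1);
        c.dmin = std::min(c.dmin, h.diag()); c.dmax = std::max(c.dmax, h.diag());
        c.score += h.score;
        merged = true;
      }
    }
    if (!merged) {
      Chain c; c.i0 = h.i0; c.i1 = h.i1; c.j0 = h.j0; c.j1 = h.j1;
      c.dmin = c.dmax = h.diag(); c.score = h.score;
      chains.push_back(c);
    }
  }

  const int pad = 100;
  for (size_t k = 0; k < chains.size(); ++k) {
    const Chain& c = chains[k];
    if (c.i1 - c.i0 < std::max(word, min_len / 3)) continue; // noise
    int ilo = std::max(0, c.i0 - pad), ihi = std::min(n, c.i1 + pad);
    int jlo = std::max(0, c.j0 - pad), jhi = std::min(m, c.j1 + pad);
    std::string w1 = s1.substr(ilo, ihi - ilo);
    std::string w2 = s2s.substr(jlo, jhi - jlo);
    // global diag d = j - i; in window coords d' = d - (jlo - ilo);
    // band around the chain's observed diagonal range
    int doff = jlo - ilo;
    int dlo = -c.dmax - band - doff;   // chain diag stored as i - j
    int dhi = -c.dmin + band - doff;
    dlo = std::max(dlo, -(int) w1.size());
    dhi = std::min(dhi, (int) w2.size());
    LocalAln la = banded_local(w1, w2, dlo, dhi, match, mismatch, gap_open, gap_extend);
    if (!la.ok) continue;
    int c0 = 0, c1 = (int) la.a1.size();
    if (trim_identity > 0.0 && trim_identity < 1.0) {
      std::pair<int,int> tr = kadane_trim(la.a1, la.a2, trim_identity);
      c0 = tr.first; c1 = tr.second;
      if (c1 - c0 <= 0) continue;
      // a short, reasonably identical trimmed block is a boundary mismatch
      // cluster belonging to the hit, not flanking homology: restore it
      const int L = (int) la.a1.size();
      const double restore_id = 0.8 * trim_identity;
      auto block_identity = [&](int lo, int hi) {
        int nm = 0;
        for (int c = lo; c < hi; ++c)
          if (la.a1[c] != '-' && la.a2[c] != '-' && is_match(la.a1[c], la.a2[c]))
            ++nm;
        return (hi > lo) ? (double) nm / (hi - lo) : 0.0;
      };
      if (c0 > 0 && c0 <= 25 && block_identity(0, c0) >= restore_id) c0 = 0;
      if (c1 < L && L - c1 <= 25 && block_identity(c1, L) >= restore_id) c1 = L;
    }
    int skip1 = count_nongap(la.a1, 0, c0);
    int skip2 = count_nongap(la.a2, 0, c0);
    int take1 = count_nongap(la.a1, c0, c1);
    int take2 = count_nongap(la.a2, c0, c1);
    Hit hit;
    hit.a1 = la.a1.substr(c0, c1 - c0);
    hit.a2 = la.a2.substr(c0, c1 - c0);
    hit.g1_start = ilo + la.i0 + skip1;
    hit.g1_end   = hit.g1_start + take1;
    int j0s = jlo + la.j0 + skip2;
    int j1s = j0s + take2;
    hit.strand = strand;
    if (strand == '+') { hit.g2_start = j0s; hit.g2_end = j1s; }
    else { hit.g2_start = m - j1s; hit.g2_end = m - j0s; }
    hit.score = score_alignment(hit.a1, hit.a2, match, mismatch, gap_open, gap_extend,
                                hit.n_match, hit.n_mismatch, hit.n_gapcols);
    int L = (int) hit.a1.size();
    double identity = L > 0 ? (double) hit.n_match / L : 0.0;
    if (L < min_len || identity < min_identity) continue;
    hits.push_back(hit);
  }
}

// [[Rcpp::export(name = ".local_hits_cpp")]]
DataFrame local_hits_cpp(std::string s1, std::string s2,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int word, double xdrop_mult, int band, int diag_window,
                         int min_len, double min_identity, double trim_identity,
                         bool both_strands) {
  long long xdrop = (long long) std::max(1.0, xdrop_mult * match);
  std::vector<Hit> hits;
  strand_hits(s1, s2, '+', match, mismatch, gap_open, gap_extend,
              word, xdrop, band, diag_window, min_len, min_identity,
              trim_identity, hits);
  if (both_strands) {
    std::string s2rc = revcomp_str(s2);
    strand_hits(s1, s2rc, '-', match, mismatch, gap_open, gap_extend,
                word, xdrop, band, diag_window, min_len, min_identity,
                trim_identity, hits);
  }

  // final dedupe across realigned hits (same strand only)
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.g1_start != b.g1_start) return a.g1_start < b.g1_start;
    if (a.g2_start != b.g2_start) return a.g2_start < b.g2_start;
    return a.strand < b.strand;
  });
  std::vector<Hit> kept;
  for (size_t k = 0; k < hits.size(); ++k) {
    bool dup = false;
    for (size_t q = 0; q < kept.size(); ++q) {
      if (hits[k].strand != kept[q].strand) continue;
      if (overlap_frac(hits[k].g1_start, hits[k].g1_end,
                       kept[q].g1_start, kept[q].g1_end) >= 0.5 &&
          overlap_frac(hits[k].g2_start, hits[k].g2_end,
                       kept[q].g2_start, kept[q].g2_end) >= 0.5) {
        dup = true; break;
      }
    }
    if (!dup) kept.push_back(hits[k]);
  }
  std::sort(kept.begin(), kept.end(), [](const Hit& a, const Hit& b) {
    if (a.g1_start != b.g1_start) return a.g1_start < b.g1_start;
    if (a.g2_start != b.g2_start) return a.g2_start < b.g2_start;
    return a.strand < b.strand;
  });

  const int H = (int) kept.size();
  IntegerVector g1s(H), g1e(H), g2s(H), g2e(H), nm(H), nmm(H), ng(H), len(H);
  NumericVector sc(H), ident(H);
  CharacterVector strand(H), a1(H), a2(H);
  for (int k = 0; k < H; ++k) {
    const Hit& h = kept[k];
    g1s[k] = h.g1_start; g1e[k] = h.g1_end;
    g2s[k] = h.g2_start; g2e[k] = h.g2_end;
    strand[k] = std::string(1, h.strand);
    sc[k] = (double) h.score;
    nm[k] = h.n_match; nmm[k] = h.n_mismatch; ng[k] = h.n_gapcols;
    len[k] = (int) h.a1.size();
    ident[k] = len[k] > 0 ? (double) h.n_match / len[k] : 0.0;
    a1[k] = h.a1; a2[k] = h.a2;
  }
  return DataFrame::create(
    _["g1_start"] = g1s, _["g1_end"] = g1e,
    _["g2_start"] = g2s, _["g2_end"] = g2e,
    _["strand"] = strand, _["length"] = len,
    _["n_match"] = nm, _["n_mismatch"] = nmm, _["n_gapcols"] = ng,
    _["identity"] = ident, _["score"] = sc,
    _["a1"] = a1, _["a2"] = a2,
    _["stringsAsFactors"] = false);
}

// column classification of an alignment: 0 = match, 1 = mismatch, 2 = gap
// [[Rcpp::export(name = ".aln_columns_cpp")]]
IntegerVector aln_columns_cpp(std::string a1, std::string a2) {
  if (a1.size() != a2.size()) stop("aligned strings differ in length");
  IntegerVector out((int) a1.size());
  for (size_t c = 0; c < a1.size(); ++c) {
    if (a1[c] == '-' || a2[c] == '-') out[(int) c] = 2;
    else out[(int) c] = is_match(a1[c], a2[c]) ? 0 : 1;
  }
  return out;
}
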