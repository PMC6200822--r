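// Seed-and-extend local alignment and primer complementarity scoring.
//
// The aligner is BLASTN-like: exact k-mer seeds on the forward strand of
// both inputs, seeds grouped into diagonal bands, then a banded local
// affine-gap DP (with row-level X-drop termination) around each band.
// Scores therefore never exceed full Smith-Waterman with the same
// parameters: the search space is a subset.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Seed { int q, t, d; };

struct AlnHit {
  int qs, qe, ts, te, score, alen, matches;
  std::string qa, ta;
};

static const int NEG = -1000000000;

// Banded local affine alignment of q vs t over diagonals [dlo, dhi]
// (diag = j - i in 0-based consumed-character coordinates).
static bool bandedLocal(const std::string &q, const std::string &t,
                        int match, int mismatch, int gapOpen, int gapExt,
                        int dlo, int dhi, int xdrop, AlnHit &out) {
  const int m = (int)q.size(), n = (int)t.size();
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  if (dlo > dhi) return false;
  const int B = dhi - dlo + 1;
  const size_t sz = (size_t)(m + 1) * B;
  std::vector<int> H(sz, NEG), E(sz, NEG), F(sz, NEG);
  std::vector<unsigned char> tbH(sz, 0), tbE(sz, 0), tbF(sz, 0);
  auto idx = [B](int i, int b) { return (size_t)i * B + b; };

  int best = 0, bi = -1, bj = -1;
  for (int i = 0; i <= m; ++i) {
    int rowmax = NEG;
    for (int b = 0; b < B; ++b) {
      int j = i + dlo + b;
      if (j < 0 || j > n) continue;
      size_t c = idx(i, b);
      if (i == 0 || j == 0) { H[c] = 0; continue; }
      // E: gap in query (consume target), from (i, j-1) = band b-1.
      int e = NEG;
      unsigned char te_ = 0;
      if (b - 1 >= 0) {
        size_t cl = idx(i, b - 1);
        if (H[cl] > NEG || E[cl] > NEG) {
          int open = (H[cl] > NEG) ? H[cl] + gapOpen + gapExt : NEG;
          int ext  = (E[cl] > NEG) ? E[cl] + gapExt : NEG;
          if (ext >= open) { e = ext; te_ = 1; } else { e = open; te_ = 0; }
        }
      }
      E[c] = e; tbE[c] = te_;
      // F: gap in target (consume query), from (i-1, j) = band b+1, row i-1.
      int f = NEG;
      unsigned char tf_ = 0;
      if (b + 1 < B) {
        size_t cu = idx(i - 1, b + 1);
        if (H[cu] > NEG || F[cu] > NEG) {
          int open = (H[cu] > NEG) ? H[cu] + gapOpen + gapExt : NEG;
          int ext  = (F[cu] > NEG) ? F[cu] + gapExt : NEG;
          if (ext >= open) { f = ext; tf_ = 1; } else { f = open; tf_ = 0; }
        }
      }
      F[c] = f; tbF[c] = tf_;
      // Diagonal.
      int diag = NEG;
      size_t cd = idx(i - 1, b);
      if (H[cd] > NEG) {
        int qc = bcode(q[i - 1]), tc = bcode(t[j - 1]);
        int sub = (qc >= 0 && qc == tc) ? match : mismatch;
        diag = H[cd] + sub;
      }
      int h = 0;
      unsigned char th_ = 0;
      if (diag > h) { h = diag; th_ = 1; }
      if (e > h) { h = e; th_ = 2; }
      if (f > h) { h = f; th_ = 3; }
      H[c] = h; tbH[c] = th_;
      if (h > rowmax) rowmax = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    if (best > 0 && rowmax < best - xdrop) break;  // X-drop row termination
  }
  if (best <= 0) return false;

  // Traceback from (bi, bj).
  std::string qa, ta;
  int i = bi, j = bj, matches = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    int b = j - i - dlo;
    if (b < 0 || b >= B) break;
    size_t c = idx(i, b);
    if (state == 0) {
      unsigned char tb = tbH[c];
      if (tb == 0) break;
      if (tb == 1) {
        char qc = q[i - 1], tc = t[j - 1];
        qa.push_back(qc); ta.push_back(tc);
        int a = bcode(qc), bb = bcode(tc);
        if (a >= 0 && a == bb) ++matches;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back('-'); ta.push_back(t[j - 1]);
      unsigned char tb = tbE[c];
      --j;
      if (tb == 0) state = 0;
    } else {
      qa.push_back(q[i - 1]); ta.push_back('-');
      unsigned char tb = tbF[c];
      --i;
      if (tb == 0) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  out.qs = i + 1; out.qe = bi; out.ts = j + 1; out.te = bj;
  out.score = best; out.alen = (int)qa.size(); out.matches = matches;
  out.qa = qa; out.ta = ta;
  return true;
}

// Collect exact k-mer seed matches between q and t.
static void collectSeeds(const std::string &q, const std::string &t, int k,
                         std::vector<Seed> &seeds) {
  const int m = (int)q.size(), n = (int)t.size();
  if (m < k || n < k || k > 15) return;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  std::unordered_map<uint32_t, std::vector<int>> index;
  index.reserve(n);
  uint32_t h = 0; int run = 0;
  for (int j = 0; j < n; ++j) {
    int c = bcode(t[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      auto &v = index[h];
      if ((int)v.size() < 256) v.push_back(j - k + 1);
    }
  }
  h = 0; run = 0;
  for (int i = 0; i < m; ++i) {
    int c = bcode(q[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(h);
      if (it != index.end()) {
        int qp = i - k + 1;
        for (int tp : it->second) seeds.push_back({qp, tp, tp - qp});
      }
    }
  }
}

// [[Rcpp::export(name = ".cppLocalAlign")]]
DataFrame cppLocalAlign(std::string query, std::string target,
                        int match, int mismatch, int gapOpen, int gapExtend,
                        int k, int xdrop, int bandPad, int minScore,
                        int maxHits) {
  std::vector<Seed> seeds;
  collectSeeds(query, target, k, seeds);
  std::vector<AlnHit> hits;
  if (!seeds.empty()) {
    std::sort(seeds.begin(), seeds.end(),
              [](const Seed &a, const Seed &b) { return a.d < b.d; });
    size_t s0 = 0;
    for (size_t s = 1; s <= seeds.size(); ++s) {
      if (s == seeds.size() || seeds[s].d - seeds[s - 1].d > 2 * bandPad) {
        int dlo = seeds[s0].d - bandPad;
        int dhi = seeds[s - 1].d + bandPad;
        if (dhi - dlo + 1 > 1024) {  // clamp runaway bands
          int mid = (dlo + dhi) / 2;
          dlo = mid - 512; dhi = mid + 511;
        }
        AlnHit h;
        if (bandedLocal(query, target, match, mismatch, gapOpen, gapExtend,
                        dlo, dhi, xdrop, h) && h.score >= minScore)
          hits.push_back(h);
        s0 = s;
      }
    }
  }
  std::sort(hits.begin(), hits.end(),
            [](const AlnHit &a, const AlnHit &b) { return a.score > b.score; });
  // Suppress hits covering the same region as a better hit.
  std::vector<AlnHit> keep;
  for (const AlnHit &h : hits) {
    bool dup = false;
    for (const AlnHit &g : keep) {
      int qov = std::min(h.qe, g.qe) - std::max(h.qs, g.qs) + 1;
      int tov = std::min(h.te, g.te) - std::max(h.ts, g.ts) + 1;
      int qlen = std::min(h.qe - h.qs, g.qe - g.qs) + 1;
      int tlen = std::min(h.te - h.ts, g.te - g.ts) + 1;
      if (qov > qlen / 2 && tov > tlen / 2) { dup = true; break; }
    }
    if (!dup) keep.push_back(h);
    if ((int)keep.size() >= maxHits) break;
  }
  const int N = (int)keep.size();
  IntegerVector qs(N), qe(N), ts(N), te(N), sc(N), al(N), ma(N);
  CharacterVector qa(N), ta(N);
  for (int i = 0; i < N; ++i) {
    qs[i] = keep[i].qs; qe[i] = keep[i].qe;
    ts[i] = keep[i].ts; te[i] = keep[i].te;
    sc[i] = keep[i].score; al[i] = keep[i].alen; ma[i] = keep[i].matches;
    qa[i] = keep[i].qa; ta[i] = keep[i].ta;
  }
  return DataFrame::create(
      Named("qstart") = qs, Named("qend") = qe,
      Named("sstart") = ts, Named("send") = te,
      Named("score") = sc, Named("alnLength") = al, Named("matches") = ma,
      Named("qaln") = qa, Named("saln") = ta,
      Named("stringsAsFactors") = false);
}

static inline bool wcPair(char a, char b) {
  int x = bcode(a), y = bcode(b);
  if (x < 0 || y < 0) return false;
  return x + y == 3;  // A<->T (0,3), C<->G (1,2)
}

// Antiparallel ungapped complementarity score: max over offsets of
// sum(+1 complementary, -1 not), floored at 0. With anchor3 only offsets
// whose overlap includes a's 3'-terminal base count.
static int compScore(const std::string &a, const std::string &b,
                     bool anchor3) {
  const int la = (int)a.size(), lb = (int)b.size();
  int best = 0;
  // shift s: a[i] pairs with b[lb-1-(i-s)] for i in overlap
  for (int s = -(lb - 1); s <= la - 1; ++s) {
    int lo = std::max(0, s), hi = std::min(la - 1, s + lb - 1);
    if (lo > hi) continue;
    if (anchor3 && hi != la - 1) continue;
    int sc = 0;
    for (int i = lo; i <= hi; ++i) {
      sc += wcPair(a[i], b[lb - 1 - (i - s)]) ? 1 : -1;
    }
    if (sc > best) best = sc;
  }
  return best;
}

// [[Rcpp::export(name = ".cppCompScore")]]
int cppCompScore(std::string a, std::string b, bool anchor3) {
  for (char c : a) if (bcode(c) < 0) stop("non-DNA character in sequence");
  for (char c : b) if (bcode(c) < 0) stop("non-DNA character in sequence");
  return compScore(a, b, anchor3);
}

// Vectorised self-complementarity: returns cbind(selfAny, self3prime).
// [[Rcpp::export(name = ".cppSelfScores")]]
IntegerMatrix cppSelfScores(CharacterVector seqs) {
  const int n = seqs.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out(i, 0) = compScore(s, s, false);
    out(i, 1) = compScore(s, s, true);
  }
  return out;
}

// Vectorised pair 3' complementarity: max of either primer anchored.
// [[Rcpp::export(name = ".cppPair3Scores")]]
IntegerVector cppPair3Scores(CharacterVector fwd, CharacterVector rev) {
  const int n = fwd.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(fwd[i]);
    std::string r = as<std::string>(rev[i]);
    out[i] = std::max(compScore(f, r, true), compScore(r, f, true));
  }
  return out;
}
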