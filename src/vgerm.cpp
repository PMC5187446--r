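#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Local affine-gap alignment (Smith-Waterman) with traceback.
//
// Both sequence ends are free: the optimal alignment may skip a prefix and a
// suffix of the query and of the reference, which is what a V(D)J amplicon
// needs (UTR/leader upstream of V, junction + J downstream, terminal
// truncations of the reference). A gap of length L costs gap_open + L *
// gap_extend. An optional band restricts cells to |(i - j) - diag| <= half
// (i = query pos, j = ref pos, both 1-based).
// ---------------------------------------------------------------------------

struct AlnResult {
  int score;
  int qs, qe, rs, re;   // 1-based inclusive spans; 0 if empty alignment
  int mism, gapbases;
};

static const int NEG_INF = INT_MIN / 4;

// traceback byte layout: bits 0-1 = M predecessor (0 start, 1 M, 2 X, 3 Y),
// bit 2 = X from X (else from M), bit 3 = Y from Y (else from M)
static AlnResult sw_affine2(const char* q, int n, const char* r, int m,
                            int mt, int ms, int go, int ge,
                            int diag, int half,
                            std::vector<uint8_t>& tb) {
  AlnResult res{0, 0, 0, 0, 0, 0, 0};
  if (n == 0 || m == 0) return res;
  bool banded = half >= 0;
  size_t need = static_cast<size_t>(n) * m;
  if (tb.size() < need) tb.resize(need);

  // scratch rows reused across calls (single-threaded R)
  static std::vector<int> Mprev, Xprev, Yprev, Mcur, Xcur, Ycur;
  if (static_cast<int>(Mprev.size()) < m + 2) {
    Mprev.resize(m + 2); Xprev.resize(m + 2); Yprev.resize(m + 2);
    Mcur.resize(m + 2); Xcur.resize(m + 2); Ycur.resize(m + 2);
  }
  std::fill(Mprev.begin(), Mprev.begin() + m + 1, NEG_INF);
  std::fill(Xprev.begin(), Xprev.begin() + m + 1, NEG_INF);
  std::fill(Yprev.begin(), Yprev.begin() + m + 1, NEG_INF);
  std::fill(Mcur.begin(), Mcur.begin() + m + 1, NEG_INF);
  std::fill(Xcur.begin(), Xcur.begin() + m + 1, NEG_INF);
  std::fill(Ycur.begin(), Ycur.begin() + m + 1, NEG_INF);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (banded) {
      jlo = std::max(1, i - diag - half);
      jhi = std::min(m, i - diag + half);
      if (jlo > jhi) {
        Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
        continue;
      }
    }
    // clear only the band neighbourhood (the band shifts by at most one
    // column per row, so [jlo-1, jhi+1] covers every cell read later)
    int clo = std::max(0, jlo - 1), chi = std::min(m, jhi + 1);
    std::fill(Mcur.begin() + clo, Mcur.begin() + chi + 1, NEG_INF);
    std::fill(Xcur.begin() + clo, Xcur.begin() + chi + 1, NEG_INF);
    std::fill(Ycur.begin() + clo, Ycur.begin() + chi + 1, NEG_INF);
    uint8_t* tbrow = &tb[static_cast<size_t>(i - 1) * m];
    const char qc = q[i - 1];
    const int goe = go + ge;
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t t = 0;
      // M: align q[i] to r[j]; fresh start allowed anywhere (free ends)
      int pb = 0, pred = 0;
      int d1 = Mprev[j - 1], d2 = Xprev[j - 1], d3 = Yprev[j - 1];
      if (d1 > pb) { pb = d1; pred = 1; }
      if (d2 > pb) { pb = d2; pred = 2; }
      if (d3 > pb) { pb = d3; pred = 3; }
      int Mval = pb + ((qc == r[j - 1] && qc != 'N') ? mt : ms);
      t = static_cast<uint8_t>(pred);
      // X: gap in reference (consume query base i)
      int xm = Mprev[j] + goe, xx = Xprev[j] + ge;
      int Xval;
      if (xx > xm) { Xval = xx; t |= 4; } else Xval = xm;
      // Y: gap in query (consume ref base j)
      int ym = Mcur[j - 1] + goe, yy = Ycur[j - 1] + ge;
      int Yval;
      if (yy > ym) { Yval = yy; t |= 8; } else Yval = ym;

      Mcur[j] = Mval; Xcur[j] = Xval; Ycur[j] = Yval;
      tbrow[j - 1] = t;
      if (Mval > best) { best = Mval; bi = i; bj = j; }
    }
    Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
  }

  if (best <= 0) return res;
  res.score = best; res.qe = bi; res.re = bj;
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = X, 2 = Y
  while (true) {
    uint8_t t = tb[static_cast<size_t>(i - 1) * m + (j - 1)];
    if (state == 0) {
      if (!(q[i - 1] == r[j - 1] && q[i - 1] != 'N')) res.mism++;
      int pred = t & 3;
      if (pred == 0) { res.qs = i; res.rs = j; break; }
      --i; --j;
      state = (pred == 1) ? 0 : (pred == 2 ? 1 : 2);
    } else if (state == 1) {  // X: query base aligned to gap
      res.gapbases++;
      bool fromX = (t & 4) != 0;
      --i;
      state = fromX ? 1 : 0;
    } else {  // Y: ref base aligned to gap
      res.gapbases++;
      bool fromY = (t & 8) != 0;
      --j;
      state = fromY ? 2 : 0;
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_align(std::string query, std::string ref,
               int match, int mismatch, int gap_open, int gap_extend,
               int diag = 0, int band_half = -1) {
  if (static_cast<double>(query.size()) * ref.size() > 6.4e7)
    stop("sequences too long for full alignment");
  std::vector<uint8_t> tb;
  AlnResult a = sw_affine2(query.c_str(), query.size(), ref.c_str(), ref.size(),
                           match, mismatch, gap_open, gap_extend,
                           diag, band_half, tb);
  return List::create(
      _["score"] = a.score, _["query_start"] = a.qs, _["query_end"] = a.qe,
      _["ref_start"] = a.rs, _["ref_end"] = a.re,
      _["mismatches"] = a.mism, _["gap_bases"] = a.gapbases);
}

// ---------------------------------------------------------------------------
// Batch V/J assignment: k-mer diagonal prescreen, then banded local alignment
// against the top-voted reference alleles.
// ---------------------------------------------------------------------------

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
DataFrame cpp_assign_batch(CharacterVector queries, CharacterVector vseqs,
                           CharacterVector jseqs,
                           int match, int mismatch, int gap_open,
                           int gap_extend, int k, int band_half,
                           int max_candidates) {
  int nq = queries.size(), nv = vseqs.size(), nj = jseqs.size();
  std::vector<std::string> vs(nv), js(nj);
  for (int i = 0; i < nv; ++i) vs[i] = as<std::string>(vseqs[i]);
  for (int i = 0; i < nj; ++i) js[i] = as<std::string>(jseqs[i]);

  // k-mer index over all V references: kmer -> (ref, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  index.reserve(1 << 14);
  const uint64_t kmask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ri = 0; ri < nv; ++ri) {
    const std::string& s = vs[ri];
    uint64_t cur = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | b) & kmask;
      if (++run >= k) index[cur].push_back({ri, static_cast<int>(p) - k + 1});
    }
  }

  IntegerVector v_idx(nq, NA_INTEGER), v_score(nq, NA_INTEGER),
      v_qs(nq, NA_INTEGER), v_qe(nq, NA_INTEGER), v_rs(nq, NA_INTEGER),
      v_re(nq, NA_INTEGER), v_mism(nq, NA_INTEGER), v_gap(nq, NA_INTEGER),
      j_idx(nq, NA_INTEGER), j_score(nq, NA_INTEGER), j_qs(nq, NA_INTEGER),
      j_qe(nq, NA_INTEGER), j_rs(nq, NA_INTEGER), j_re(nq, NA_INTEGER),
      j_mism(nq, NA_INTEGER), j_gap(nq, NA_INTEGER);

  std::vector<uint8_t> tb;
  // per-(ref, diagonal) vote counters with epoch stamps (no per-read clear)
  int maxref = 0;
  for (int ri = 0; ri < nv; ++ri)
    maxref = std::max(maxref, static_cast<int>(vs[ri].size()));
  int maxq = 0;
  for (int qi = 0; qi < nq; ++qi)
    maxq = std::max(maxq, static_cast<int>(LENGTH(STRING_ELT(queries, qi))));
  int ndiag = maxref + maxq + 2;
  std::vector<int> votes(static_cast<size_t>(nv) * ndiag, 0);
  std::vector<int> stamp(static_cast<size_t>(nv) * ndiag, -1);
  std::vector<int> bestvote(nv), bestdiag(nv);

  // J reference k-mer index (shared across reads)
  const int jk_len = 8;
  const uint64_t jk_mask = (1ULL << (2 * jk_len)) - 1;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> jindex;
  int jmaxlen = 0;
  for (int ji = 0; ji < nj; ++ji) {
    jmaxlen = std::max(jmaxlen, static_cast<int>(js[ji].size()));
    uint64_t jcur = 0; int jrun = 0;
    for (size_t p = 0; p < js[ji].size(); ++p) {
      int b = base2bits(js[ji][p]);
      if (b < 0) { jrun = 0; jcur = 0; continue; }
      jcur = ((jcur << 2) | b) & jk_mask;
      if (++jrun >= jk_len)
        jindex[jcur].push_back({ji, static_cast<int>(p) - jk_len + 1});
    }
  }
  const int jdiag_n = 122 + jmaxlen;
  std::vector<int> jdiagv(static_cast<size_t>(std::max(nj, 1)) * jdiag_n);

  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int qn = q.size();
    // --- prescreen ---
    std::fill(bestvote.begin(), bestvote.end(), 0);
    uint64_t cur = 0; int run = 0;
    for (int p = 0; p < qn; ++p) {
      int b = base2bits(q[p]);
      if (b < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | b) & kmask;
      if (++run >= k) {
        auto it = index.find(cur);
        if (it == index.end()) continue;
        int qpos = p - k + 1;
        for (auto& rp : it->second) {
          int d = qpos - rp.second;
          size_t key = static_cast<size_t>(rp.first) * ndiag +
                       (d + maxref + 1);
          if (stamp[key] != qi) { stamp[key] = qi; votes[key] = 0; }
          int v = ++votes[key];
          if (v > bestvote[rp.first]) {
            bestvote[rp.first] = v; bestdiag[rp.first] = d;
          }
        }
      }
    }
    int topvote = 0;
    for (int ri = 0; ri < nv; ++ri) topvote = std::max(topvote, bestvote[ri]);
    std::vector<int> cand;
    if (topvote >= 2) {
      std::vector<std::pair<int,int>> ranked;  // (-votes, ref)
      for (int ri = 0; ri < nv; ++ri)
        if (bestvote[ri] >= std::max(2, topvote / 3))
          ranked.push_back({-bestvote[ri], ri});
      std::sort(ranked.begin(), ranked.end());
      // a clear vote leader (>= ~4 substitutions ahead of the runner-up)
      // cannot be outscored by alignment; skip the also-rans
      size_t nkeep = ranked.size();
      if (nkeep > 1 && ranked[0].first + 45 <= ranked[1].first) nkeep = 1;
      for (size_t t = 0; t < nkeep && static_cast<int>(t) < max_candidates; ++t)
        cand.push_back(ranked[t].second);
    } else {
      for (int ri = 0; ri < nv; ++ri) cand.push_back(ri);  // fallback: all refs
    }

    AlnResult bestA{0,0,0,0,0,0,0}; int bestRef = -1;
    for (int ci : cand) {
      AlnResult a;
      if (topvote >= 2) {
        // diag convention: qpos - rpos (0-based) == (i - j) for 1-based i,j
        a = sw_affine2(q.c_str(), qn, vs[ci].c_str(), vs[ci].size(),
                       match, mismatch, gap_open, gap_extend,
                       bestdiag[ci], band_half, tb);
      } else {
        a = sw_affine2(q.c_str(), qn, vs[ci].c_str(), vs[ci].size(),
                       match, mismatch, gap_open, gap_extend, 0, -1, tb);
      }
      int aerr = a.mism + a.gapbases;
      int berr = bestA.mism + bestA.gapbases;
      if (bestRef < 0 || a.score > bestA.score ||
          (a.score == bestA.score && aerr < berr)) {
        bestA = a; bestRef = ci;
      }
    }
    if (bestRef < 0 || bestA.score <= 0) continue;
    v_idx[qi] = bestRef + 1; v_score[qi] = bestA.score;
    v_qs[qi] = bestA.qs; v_qe[qi] = bestA.qe;
    v_rs[qi] = bestA.rs; v_re[qi] = bestA.re;
    v_mism[qi] = bestA.mism; v_gap[qi] = bestA.gapbases;

    // --- J: only 3' of the V alignment end (junction + J fit in 120 nt) ---
    if (nj > 0 && bestA.qe < qn) {
      std::string tail = q.substr(bestA.qe, 120);
      int tn = tail.size();
      // k-mer diagonal prescreen against the (short) J references
      std::vector<int> jbestvote(nj, 0), jbestdiag(nj, 0);
      if (tn >= jk_len) {
        std::fill(jdiagv.begin(), jdiagv.end(), 0);
        uint64_t jcur = 0; int jrun = 0;
        for (int p = 0; p < tn; ++p) {
          int b = base2bits(tail[p]);
          if (b < 0) { jrun = 0; jcur = 0; continue; }
          jcur = ((jcur << 2) | b) & jk_mask;
          if (++jrun >= jk_len) {
            auto it = jindex.find(jcur);
            if (it == jindex.end()) continue;
            int qpos = p - jk_len + 1;
            for (auto& rp : it->second) {
              int v = ++jdiagv[static_cast<size_t>(rp.first) * jdiag_n +
                               (qpos - rp.second + jmaxlen)];
              if (v > jbestvote[rp.first]) {
                jbestvote[rp.first] = v;
                jbestdiag[rp.first] = qpos - rp.second;
              }
            }
          }
        }
      }
      int jtop = 0;
      for (int ji = 0; ji < nj; ++ji) jtop = std::max(jtop, jbestvote[ji]);
      AlnResult bestJ{0,0,0,0,0,0,0}; int bestJref = -1;
      for (int ji = 0; ji < nj; ++ji) {
        AlnResult a;
        if (jtop >= 2 && jbestvote[ji] >= 2) {
          a = sw_affine2(tail.c_str(), tn, js[ji].c_str(), js[ji].size(),
                         match, mismatch, gap_open, gap_extend,
                         jbestdiag[ji], 10, tb);
        } else if (jtop >= 2) {
          continue;  // some ref had seeds, this one none: cannot win
        } else {
          a = sw_affine2(tail.c_str(), tn, js[ji].c_str(), js[ji].size(),
                         match, mismatch, gap_open, gap_extend, 0, -1, tb);
        }
        int aerr = a.mism + a.gapbases, berr = bestJ.mism + bestJ.gapbases;
        if (bestJref < 0 || a.score > bestJ.score ||
            (a.score == bestJ.score && aerr < berr)) {
          bestJ = a; bestJref = ji;
        }
      }
      if (bestJref >= 0 && bestJ.score > 0) {
        j_idx[qi] = bestJref + 1; j_score[qi] = bestJ.score;
        j_qs[qi] = bestJ.qs + bestA.qe; j_qe[qi] = bestJ.qe + bestA.qe;
        j_rs[qi] = bestJ.rs; j_re[qi] = bestJ.re;
        j_mism[qi] = bestJ.mism; j_gap[qi] = bestJ.gapbases;
      }
    }
  }

  return DataFrame::create(
      _["v_idx"] = v_idx, _["v_score"] = v_score, _["v_qstart"] = v_qs,
      _["v_qend"] = v_qe, _["v_rstart"] = v_rs, _["v_rend"] = v_re,
      _["v_mismatches"] = v_mism, _["v_gap_bases"] = v_gap,
      _["j_idx"] = j_idx, _["j_score"] = j_score, _["j_qstart"] = j_qs,
      _["j_qend"] = j_qe, _["j_rstart"] = j_rs, _["j_rend"] = j_re,
      _["j_mismatches"] = j_mism, _["j_gap_bases"] = j_gap,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Levenshtein distance: Myers/Hyyro bit-parallel algorithm, blocked for
// patterns longer than 64 characters. Exact for arbitrary strings.
// ---------------------------------------------------------------------------

static int myers_distance(const std::string& pat, const std::string& txt,
                          std::vector<uint64_t>* peq_cache = nullptr) {
  int m = pat.size(), n = txt.size();
  if (m == 0) return n;
  if (n == 0) return m;
  int W = (m + 63) / 64;
  // Peq[block * 256 + char]
  std::vector<uint64_t> peq_local;
  std::vector<uint64_t>* peq = peq_cache;
  if (!peq || peq->empty()) {
    peq_local.assign(static_cast<size_t>(W) * 256, 0);
    for (int i = 0; i < m; ++i)
      peq_local[static_cast<size_t>(i / 64) * 256 +
                static_cast<unsigned char>(pat[i])] |= 1ULL << (i % 64);
    if (peq) { *peq = peq_local; peq = &*peq; }
    else peq = &peq_local;
  }
  std::vector<uint64_t> Pv(W, ~0ULL), Mv(W, 0);
  int score = m;
  uint64_t lastmask = 1ULL << ((m - 1) % 64);
  for (int j = 0; j < n; ++j) {
    unsigned char c = txt[j];
    int hin = 1;  // global distance: top row D[0][j] = j
    for (int b = 0; b < W; ++b) {
      uint64_t Eq = (*peq)[static_cast<size_t>(b) * 256 + c];
      uint64_t Pvb = Pv[b], Mvb = Mv[b];
      uint64_t Xv = Eq | Mvb;
      if (hin < 0) Eq |= 1ULL;
      uint64_t Xh = (((Eq & Pvb) + Pvb) ^ Pvb) | Eq;
      uint64_t Ph = Mvb | ~(Xh | Pvb);
      uint64_t Mh = Pvb & Xh;
      uint64_t mask = (b == W - 1) ? lastmask : (1ULL << 63);
      int hout = 0;
      if (Ph & mask) hout = 1;
      else if (Mh & mask) hout = -1;
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1ULL;
      else if (hin > 0) Ph |= 1ULL;
      Pv[b] = Mh | ~(Xv | Ph);
      Mv[b] = Ph & Xv;
      hin = hout;
    }
    score += hin;  // hin now holds hout of the last block
  }
  return score;
}

// Banded Myers: exact when the true distance is at most k (guaranteed here
// because k is always a proven upper bound). Only the pattern blocks the
// diagonal band |i - j| <= k touches are processed; cells outside the band
// are replaced by upper bounds (virtual +1 deltas), which cannot change
// in-band values when an optimal path stays inside the band.
static int myers_banded(const std::string& pat, const std::string& txt,
                        int k, std::vector<uint64_t>* peq_cache) {
  int m = pat.size(), n = txt.size();
  if (m == 0) return n;
  if (n == 0) return m;
  int W = (m + 63) / 64;
  std::vector<uint64_t>* peq = peq_cache;
  std::vector<uint64_t> peq_local;
  if (!peq) peq = &peq_local;
  if (peq->empty()) {
    peq->assign(static_cast<size_t>(W) * 256, 0);
    for (int i = 0; i < m; ++i)
      (*peq)[static_cast<size_t>(i / 64) * 256 +
             static_cast<unsigned char>(pat[i])] |= 1ULL << (i % 64);
  }
  static std::vector<uint64_t> Pv, Mv;
  static std::vector<int> S;
  if (static_cast<int>(Pv.size()) < W) { Pv.resize(W); Mv.resize(W); S.resize(W); }
  int mb = (m - 1) / 64;  // block holding row m
  uint64_t lastmask = 1ULL << ((m - 1) % 64);
  int fb = 0, lb = std::min(mb, k / 64);
  for (int b = fb; b <= lb; ++b) {
    Pv[b] = ~0ULL; Mv[b] = 0;
    S[b] = (b == mb) ? m : 64 * (b + 1);
  }
  for (int j = 0; j < n; ++j) {
    unsigned char c = txt[j];
    int nfb = std::max(0, (j - k) / 64);
    int nlb = std::min(mb, (j + k) / 64);
    if (nlb > lb) {  // activate block below: virtual +1 column
      Pv[nlb] = ~0ULL; Mv[nlb] = 0;
      S[nlb] = S[lb] + ((nlb == mb) ? (m - 64 * nlb) : 64);
    }
    fb = std::max(fb, nfb); lb = nlb;
    int hin = 1;
    for (int b = fb; b <= lb; ++b) {
      uint64_t Eq = (*peq)[static_cast<size_t>(b) * 256 + c];
      uint64_t Pvb = Pv[b], Mvb = Mv[b];
      uint64_t Xv = Eq | Mvb;
      if (hin < 0) Eq |= 1ULL;
      uint64_t Xh = (((Eq & Pvb) + Pvb) ^ Pvb) | Eq;
      uint64_t Ph = Mvb | ~(Xh | Pvb);
      uint64_t Mh = Pvb & Xh;
      uint64_t mask = (b == mb) ? lastmask : (1ULL << 63);
      int hout = 0;
      if (Ph & mask) hout = 1;
      else if (Mh & mask) hout = -1;
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1ULL;
      else if (hin > 0) Ph |= 1ULL;
      Pv[b] = Mh | ~(Xv | Ph);
      Mv[b] = Ph & Xv;
      S[b] += hout;
      hin = hout;
    }
  }
  return S[mb];
}

// exact edit distance choosing the cheapest exact route; peq (blocked
// Peq table of `a`, shared by both Myers variants) may be reused across
// calls with the same pattern
static int edit_distance_fast(const std::string& a, const std::string& b,
                              std::vector<uint64_t>* peq = nullptr) {
  int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return m + n;
  // upper bound: length difference plus left-aligned mismatches
  int k0 = std::abs(m - n);
  int mn = std::min(m, n);
  for (int i = 0; i < mn; ++i) if (a[i] != b[i]) ++k0;
  // same length with <= 2 mismatches: a shift needs an ins+del pair and
  // must explain >= 3 mismatches to win, so the distance equals k0
  if (m == n && k0 <= 2) return k0;
  if (k0 <= 63 && m > 64) return myers_banded(a, b, k0, peq);
  return myers_distance(a, b, peq);
}

// ---------------------------------------------------------------------------
// Frame-1 translation with the standard genetic code; incomplete trailing
// codons are dropped and codons containing non-ACGT characters become X.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_translate(CharacterVector seqs) {
  static const char aa_tab[65] =
      "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVVYYYYSSSSWCWCLFLF";
  // index = a*16 + c*4 + g with A=0,C=1,G=2,T=3 (codon base order AAA..TTT)
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int nc = s.size() / 3;
    buf.assign(nc, 'X');
    for (int c = 0; c < nc; ++c) {
      int v = 0; bool okc = true;
      for (int p = 0; p < 3; ++p) {
        int b = base2bits(s[3 * c + p]);
        if (b < 0) { okc = false; break; }
        v = v * 4 + b;
      }
      if (okc) {
        // stop codons TAA (48), TAG (50), TGA (56)
        if (v == 48 || v == 50 || v == 56) buf[c] = '*';
        else buf[c] = aa_tab[v];
      }
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_edit_distance(CharacterVector a, CharacterVector b) {
  int n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("lengths of 'a' and 'b' must match (or be 1)");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    out[i] = edit_distance_fast(sa, sb);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_edit_matrix(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    std::vector<uint64_t> peq;  // pattern Peq reused across the row
    for (int j = i + 1; j < n; ++j) {
      int d = edit_distance_fast(s[i], s[j], &peq);
      out(i, j) = d; out(j, i) = d;
    }
    if ((i & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Weighted consensus over near-identical sequences (center-star projection).
// Members of the same length as the center are projected column-by-column;
// members of different length are aligned to the center with the banded
// local aligner and projected onto center coordinates (insertions relative
// to the center are ignored). Columns with a gap majority (> 50% of total
// weight) are deleted; a base is emitted if it reaches >= `majority` of the
// covering (non-gap) weight, otherwise 'N'.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
String cpp_consensus(CharacterVector members, NumericVector weights,
                     double majority, int match, int mismatch, int gap_open,
                     int gap_extend, int band_half) {
  int n = members.size();
  if (n == 0) return NA_STRING;
  int center = 0;
  for (int i = 1; i < n; ++i) {
    if (weights[i] > weights[center] ||
        (weights[i] == weights[center] &&
         LENGTH(STRING_ELT(members, i)) > LENGTH(STRING_ELT(members, center))))
      center = i;
  }
  std::string cs = as<std::string>(members[center]);
  int L = cs.size();
  std::vector<double> wA(L, 0), wC(L, 0), wG(L, 0), wT(L, 0), wGap(L, 0);
  double wTot = 0;
  std::vector<uint8_t> tb;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(members[i]);
    double w = weights[i];
    wTot += w;
    if (static_cast<int>(s.size()) == L) {
      for (int p = 0; p < L; ++p) {
        switch (s[p]) {
          case 'A': wA[p] += w; break; case 'C': wC[p] += w; break;
          case 'G': wG[p] += w; break; case 'T': wT[p] += w; break;
          default: break;  // N: covering weight, no base vote
        }
      }
    } else {
      AlnResult a = sw_affine2(s.c_str(), s.size(), cs.c_str(), L, match,
                               mismatch, gap_open, gap_extend, 0, band_half,
                               tb);
      if (a.score <= 0) { for (int p = 0; p < L; ++p) wGap[p] += w; continue; }
      // re-walk the traceback, recording query base per covered ref column
      std::vector<char> col(L, '-');
      int ii = a.qe, jj = a.re, state = 0;
      while (true) {
        uint8_t t = tb[static_cast<size_t>(ii - 1) * L + (jj - 1)];
        if (state == 0) {
          col[jj - 1] = s[ii - 1];
          int pred = t & 3;
          if (pred == 0) break;
          --ii; --jj; state = (pred == 1) ? 0 : (pred == 2 ? 1 : 2);
        } else if (state == 1) { --ii; state = (t & 4) ? 1 : 0; }
        else { col[jj - 1] = '-'; --jj; state = (t & 8) ? 2 : 0; }
      }
      for (int p = 0; p < L; ++p) {
        switch (col[p]) {
          case 'A': wA[p] += w; break; case 'C': wC[p] += w; break;
          case 'G': wG[p] += w; break; case 'T': wT[p] += w; break;
          case '-': wGap[p] += w; break;
          default: break;
        }
      }
    }
  }

  std::string out;
  out.reserve(L);
  for (int p = 0; p < L; ++p) {
    if (wGap[p] > wTot / 2) continue;  // gap-majority column deleted
    double cov = wTot - wGap[p];
    double bw = wA[p]; char bb = 'A';
    if (wC[p] > bw) { bw = wC[p]; bb = 'C'; }
    if (wG[p] > bw) { bw = wG[p]; bb = 'G'; }
    if (wT[p] > bw) { bw = wT[p]; bb = 'T'; }
    out.push_back((cov > 0 && bw >= majority * cov) ? bb : 'N');
  }
  return String(out);
}

// ---------------------------------------------------------------------------
// Paired-end read merging by overlap scan.
// ---------------------------------------------------------------------------

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector rev,
                     CharacterVector fq, CharacterVector rq,
                     int min_overlap, double max_mismatch_frac) {
  int n = fwd.size();
  CharacterVector merged(n), mqual(n);
  IntegerVector overlap(n, NA_INTEGER), mism(n, NA_INTEGER);
  LogicalVector ok(n, false);
  bool haveq = fq.size() == n && rq.size() == n;
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(fwd[i]);
    std::string rc = revcomp(as<std::string>(rev[i]));
    std::string fquals = haveq && fq[i] != NA_STRING ? as<std::string>(fq[i]) : "";
    std::string rquals = haveq && rq[i] != NA_STRING ? as<std::string>(rq[i]) : "";
    if (!rquals.empty()) rquals = std::string(rquals.rbegin(), rquals.rend());
    int lf = f.size(), lr = rc.size();
    int bestO = -1, bestMatches = -1, bestMm = 0;
    int omax = std::min(lf, lr);
    for (int o = omax; o >= min_overlap; --o) {
      int mm = 0;
      const char* fa = f.c_str() + (lf - o);
      for (int p = 0; p < o; ++p) if (fa[p] != rc[p]) ++mm;
      int matches = o - mm;
      if (static_cast<double>(mm) / o <= max_mismatch_frac &&
          matches > bestMatches) {
        bestMatches = matches; bestO = o; bestMm = mm;
      }
    }
    if (bestO < 0) { merged[i] = NA_STRING; mqual[i] = NA_STRING; continue; }
    int o = bestO;
    std::string out = f.substr(0, lf - o);
    std::string oq;
    bool usequal = !fquals.empty() && !rquals.empty() &&
                   static_cast<int>(fquals.size()) == lf &&
                   static_cast<int>(rquals.size()) == lr;
    for (int p = 0; p < o; ++p) {
      char fb = f[lf - o + p], rb = rc[p];
      if (fb == rb) { out.push_back(fb); if (usequal) oq.push_back(std::max(fquals[lf - o + p], rquals[p])); }
      else if (usequal && rquals[p] > fquals[lf - o + p]) {
        out.push_back(rb); oq.push_back(rquals[p]);
      } else {
        out.push_back(fb);  // forward wins on tie / no qualities
        if (usequal) oq.push_back(fquals[lf - o + p]);
      }
    }
    out += rc.substr(o);
    merged[i] = out;
    if (usequal) mqual[i] = fquals.substr(0, lf - o) + oq + rquals.substr(o);
    else mqual[i] = NA_STRING;
    overlap[i] = o; mism[i] = bestMm; ok[i] = true;
  }
  return List::create(_["merged"] = merged, _["quality"] = mqual,
                      _["overlap"] = overlap, _["mismatches"] = mism,
                      _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// Terminal-tolerant comparison: the shorter sequence must fit fully inside
// the longer one with <= tol overhang of the longer sequence at each end;
// returns the minimal number of internal mismatches, or -1 if the length
// difference alone exceeds what the tolerance allows.
// ---------------------------------------------------------------------------

static int terminal_diffs_one(const std::string& a, const std::string& b,
                              int tol) {
  const std::string& s = a.size() <= b.size() ? a : b;
  const std::string& l = a.size() <= b.size() ? b : a;
  int ds = l.size() - s.size();
  if (ds > 2 * tol) return -1;
  int best = -1;
  for (int off = 0; off <= ds; ++off) {
    if (off > tol || (ds - off) > tol) continue;
    int mm = 0;
    for (size_t p = 0; p < s.size(); ++p) if (s[p] != l[off + p]) ++mm;
    if (best < 0 || mm < best) best = mm;
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_terminal_diffs(CharacterVector a, CharacterVector b,
                                 int tol) {
  int n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("lengths of 'a' and 'b' must match (or be 1)");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    int d = terminal_diffs_one(sa, sb, tol);
    out[i] = d < 0 ? NA_INTEGER : d;
  }
  return out;
}
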