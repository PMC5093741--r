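// Alignment kernels: seed-and-extend local alignment with gapped x-drop
// extension (blastn-like), a batch best-hit read mapper sharing the same
// core, and an affine-gap semi-global (free reference end gaps) aligner.
//
// Conventions: sequences arrive as uppercase strings over {A,C,G,T,N};
// N is scored as a mismatch against everything, including N. All
// coordinates are 0-based half-open on the forward strand. A gap of
// length L costs gap_open + (L - 1) * gap_extend (both negative), so a
// single-base gap costs gap_open.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> revcomp_enc(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  size_t n = v.size();
  for (size_t i = 0; i < n; ++i) {
    int c = v[n - 1 - i];
    r[i] = (c < 4) ? 3 - c : 4;
  }
  return r;
}

static inline int subst(int a, int b, int match, int mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

// ---------------------------------------------------------------------------
// k-mer index over the subject (direct-address for word_size <= 12)

struct KmerIndex {
  int w;
  std::vector<int> starts;     // 4^w + 1 offsets
  std::vector<int> positions;  // subject positions, bucketed by kmer
};

static void build_index(const std::vector<int>& s, int w, KmerIndex& idx) {
  idx.w = w;
  const size_t nkey = (size_t)1 << (2 * w);
  std::vector<int> counts(nkey, 0);
  const int n = (int)s.size();
  const uint32_t mask = (w == 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1u);
  uint32_t key = 0;
  int run = 0;  // consecutive non-N
  for (int i = 0; i < n; ++i) {
    if (s[i] >= 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)s[i]) & mask;
    if (++run >= w) counts[key]++;
  }
  idx.starts.assign(nkey + 1, 0);
  for (size_t k = 0; k < nkey; ++k) idx.starts[k + 1] = idx.starts[k] + counts[k];
  idx.positions.assign(idx.starts[nkey], 0);
  std::vector<int> fill(idx.starts.begin(), idx.starts.end() - 1);
  key = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    if (s[i] >= 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)s[i]) & mask;
    if (++run >= w) idx.positions[fill[key]++] = i - w + 1;
  }
}

// ---------------------------------------------------------------------------
// gapped x-drop extension, anchored at (0,0), banded by diagonal offset

struct ExtRes {
  int ai, bj;      // consumed lengths at the best cell
  int score;
  int matches, cols;
};

// a: extension sequence accessed as A[a0 + adir*i], i in [0, na)
// b: likewise. Band: |j - i| <= band. Match/column counts are propagated
// forward through the DP alongside the scores (same argmax choices), so no
// traceback is needed and memory stays O(band).
static ExtRes xdrop_extend(const std::vector<int>& A, int a0, int adir, int na,
                           const std::vector<int>& B, int b0, int bdir, int nb,
                           int match, int mismatch, int go, int ge,
                           int xdrop, int band,
                           int kmin = -1, int kmax = -1) {
  ExtRes res{0, 0, 0, 0, 0};
  if (na <= 0 || nb <= 0) return res;
  const int W = 2 * band + 1;
  if (kmin < 0) kmin = 0;
  if (kmax < 0) kmax = W - 1;
  // score / match-count / column-count per state, previous and current row
  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  std::vector<int> Mpm(W, 0), Xpm(W, 0), Ypm(W, 0);
  std::vector<int> Mcm(W, 0), Xcm(W, 0), Ycm(W, 0);
  std::vector<int> Mpc(W, 0), Xpc(W, 0), Ypc(W, 0);
  std::vector<int> Mcc(W, 0), Xcc(W, 0), Ycc(W, 0);

  // row 0
  Mp[band] = 0;  // start cell (0,0)
  for (int k = band + 1; k <= kmax; ++k) {
    int j = k - band;
    if (j > nb) break;
    Yp[k] = go + ge * (j - 1);
    Ypm[k] = 0; Ypc[k] = j;
  }
  int best = 0, besti = 0, bestj = 0, bestm = 0, bestc = 0;

  for (int i = 1; i <= na; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int rowmax = NEG;
    int ca = A[a0 + adir * (i - 1)];
    for (int k = kmin; k <= kmax; ++k) {
      int j = i + k - band;
      if (j < 0) continue;
      if (j > nb) break;
      // M: from (i-1, j-1) -> previous row, same k
      if (j >= 1) {
        int pd = Mp[k], pm = Mpm[k], pc = Mpc[k];
        if (Xp[k] > pd) { pd = Xp[k]; pm = Xpm[k]; pc = Xpc[k]; }
        if (Yp[k] > pd) { pd = Yp[k]; pm = Ypm[k]; pc = Ypc[k]; }
        if (pd > NEG) {
          int cb = B[b0 + bdir * (j - 1)];
          int hit = (ca == cb && ca < 4) ? 1 : 0;
          Mc[k] = pd + (hit ? match : mismatch);
          Mcm[k] = pm + hit; Mcc[k] = pc + 1;
        }
      }
      // X: consume a only, from (i-1, j) -> previous row, k+1
      if (k + 1 <= kmax) {
        int opn = Mp[k + 1], om = Mpm[k + 1], oc = Mpc[k + 1];
        if (Yp[k + 1] > opn) { opn = Yp[k + 1]; om = Ypm[k + 1]; oc = Ypc[k + 1]; }
        int vo = (opn > NEG) ? opn + go : NEG;
        int ve = (Xp[k + 1] > NEG) ? Xp[k + 1] + ge : NEG;
        if (vo >= ve) {
          if (vo > NEG) { Xc[k] = vo; Xcm[k] = om; Xcc[k] = oc + 1; }
        } else { Xc[k] = ve; Xcm[k] = Xpm[k + 1]; Xcc[k] = Xpc[k + 1] + 1; }
      }
      // Y: consume b only, from (i, j-1) -> same row, k-1
      if (k - 1 >= kmin) {
        int opn = Mc[k - 1], om = Mcm[k - 1], oc = Mcc[k - 1];
        if (Xc[k - 1] > opn) { opn = Xc[k - 1]; om = Xcm[k - 1]; oc = Xcc[k - 1]; }
        int vo = (opn > NEG) ? opn + go : NEG;
        int ve = (Yc[k - 1] > NEG) ? Yc[k - 1] + ge : NEG;
        if (vo >= ve) {
          if (vo > NEG) { Yc[k] = vo; Ycm[k] = om; Ycc[k] = oc + 1; }
        } else { Yc[k] = ve; Ycm[k] = Ycm[k - 1]; Ycc[k] = Ycc[k - 1] + 1; }
      }
      int c = Mc[k], cm = Mcm[k], cc = Mcc[k];
      if (Xc[k] > c) { c = Xc[k]; cm = Xcm[k]; cc = Xcc[k]; }
      if (Yc[k] > c) { c = Yc[k]; cm = Ycm[k]; cc = Ycc[k]; }
      if (c > rowmax) rowmax = c;
      if (c > best) { best = c; besti = i; bestj = j; bestm = cm; bestc = cc; }
    }
    if (rowmax < best - xdrop) break;
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::swap(Mpm, Mcm); std::swap(Xpm, Xcm); std::swap(Ypm, Ycm);
    std::swap(Mpc, Mcc); std::swap(Xpc, Xcc); std::swap(Ypc, Ycc);
  }

  res.ai = besti; res.bj = bestj; res.score = best;
  res.matches = bestm; res.cols = bestc;
  return res;
}

// ---------------------------------------------------------------------------

struct Hit {
  int qs, qe, ss, se;
  int strand;  // 0 = '+', 1 = '-'
  int score, matches, cols;
};

static void seed_pass(const std::vector<int>& q, const std::vector<int>& s,
                      const KmerIndex& idx, int strand, bool self_mode,
                      bool suppress, int w, int match, int mismatch,
                      int go, int ge, int xdrop, int band, int min_score,
                      int nq_fwd, std::vector<Hit>& hits) {
  const int nq = (int)q.size(), ns = (int)s.size();
  if (nq < w) return;
  const uint32_t mask = (1u << (2 * w)) - 1u;
  std::unordered_map<int, int> cover;  // diagonal -> covered query end
  uint32_t key = 0; int run = 0;
  for (int i = 0; i < nq; ++i) {
    if (q[i] >= 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)q[i]) & mask;
    if (++run < w) continue;
    int qpos = i - w + 1;
    int b0 = idx.starts[key], b1 = idx.starts[key + 1];
    for (int t = b0; t < b1; ++t) {
      int spos = idx.positions[t];
      if (self_mode && strand == 0 && spos <= qpos) continue;
      int d = spos - qpos;
      if (suppress) {
        auto it = cover.find(d);
        if (it != cover.end() && qpos < it->second) continue;
      }
      int kmin_r = -1, kmax_l = -1;
      if (self_mode && strand == 0) {
        // keep every alignment column strictly above the main diagonal
        kmin_r = std::max(0, band - d + 1);
        kmax_l = std::min(2 * band, band + d - 1);
      }
      ExtRes L = xdrop_extend(q, qpos - 1, -1, qpos, s, spos - 1, -1, spos,
                              match, mismatch, go, ge, xdrop, band,
                              -1, kmax_l);
      ExtRes R = xdrop_extend(q, qpos + w, +1, nq - qpos - w,
                              s, spos + w, +1, ns - spos - w,
                              match, mismatch, go, ge, xdrop, band,
                              kmin_r, -1);
      Hit h;
      h.score = w * match + L.score + R.score;
      h.matches = w + L.matches + R.matches;
      h.cols = w + L.cols + R.cols;
      int qs = qpos - L.ai, qe = qpos + w + R.ai;
      h.ss = spos - L.bj; h.se = spos + w + R.bj;
      h.strand = strand;
      if (strand == 0) { h.qs = qs; h.qe = qe; }
      else { h.qs = nq_fwd - qe; h.qe = nq_fwd - qs; }
      if (suppress) {
        int& ce = cover[d];
        if (qe > ce) ce = qe;
      }
      if (h.score >= min_score) hits.push_back(h);
    }
  }
}

static inline int ov_len(int a0, int a1, int b0, int b1) {
  int lo = std::max(a0, b0), hi = std::min(a1, b1);
  return hi > lo ? hi - lo : 0;
}

static void dedup_hits(std::vector<Hit>& hits) {
  // suppress a hit when a higher-scoring hit on the same strand covers most
  // of it on both the query and the subject side (redundant re-discoveries
  // of one locus from different seeds)
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.ss < b.ss;
  });
  std::vector<Hit> out;
  out.reserve(hits.size());
  for (const Hit& h : hits) {
    bool drop = false;
    int hq = h.qe - h.qs, hs = h.se - h.ss;
    for (const Hit& g : out) {
      if (g.strand != h.strand) continue;
      int qo = ov_len(g.qs, g.qe, h.qs, h.qe);
      int so = ov_len(g.ss, g.se, h.ss, h.se);
      if (2 * qo >= hq && 2 * so >= hs) { drop = true; break; }
    }
    if (!drop) out.push_back(h);
  }
  hits.swap(out);
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string subject,
                          int word_size, int match, int mismatch,
                          int gap_open, int gap_extend, int xdrop,
                          int band, bool self_mode, int min_score,
                          int exact_limit) {
  if (word_size < 4 || word_size > 12)
    stop("word_size must be between 4 and 12");
  std::vector<int> q = encode_seq(query), s = encode_seq(subject);
  const int nq = (int)q.size(), ns = (int)s.size();
  std::vector<Hit> hits;
  if (nq >= word_size && ns >= word_size) {
    KmerIndex idx;
    build_index(s, word_size, idx);
    bool suppress = (std::max(nq, ns) > exact_limit);
    seed_pass(q, s, idx, 0, self_mode, suppress, word_size, match, mismatch,
              gap_open, gap_extend, xdrop, band, min_score, nq, hits);
    std::vector<int> qrc = revcomp_enc(q);
    seed_pass(qrc, s, idx, 1, self_mode, suppress, word_size, match, mismatch,
              gap_open, gap_extend, xdrop, band, min_score, nq, hits);
    dedup_hits(hits);
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });
  int n = (int)hits.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), score(n), matches(n), cols(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    score[i] = hits[i].score; matches[i] = hits[i].matches;
    cols[i] = hits[i].cols;
    strand[i] = hits[i].strand == 0 ? "+" : "-";
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = strand, _["score"] = score, _["matches"] = matches,
    _["cols"] = cols, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_map_batch(CharacterVector queries, std::string subject,
                        int word_size, int match, int mismatch,
                        int gap_open, int gap_extend, int xdrop,
                        int band, int min_score) {
  if (word_size < 4 || word_size > 12)
    stop("word_size must be between 4 and 12");
  std::vector<int> s = encode_seq(subject);
  KmerIndex idx;
  const int ns = (int)s.size();
  if (ns >= word_size) build_index(s, word_size, idx);
  std::vector<int> o_idx, o_qs, o_qe, o_ss, o_se, o_score, o_matches, o_cols;
  std::vector<int> o_strand;
  const uint32_t mask = (1u << (2 * word_size)) - 1u;

  for (int qi = 0; qi < queries.size(); ++qi) {
    if (ns < word_size) break;
    std::string qstr = as<std::string>(queries[qi]);
    std::vector<int> qf = encode_seq(qstr);
    const int nq = (int)qf.size();
    if (nq < word_size) continue;
    Hit best; best.score = NEG;
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<int> q = (strand == 0) ? qf : revcomp_enc(qf);
      std::unordered_map<int, int> cover;
      uint32_t key = 0; int run = 0;
      for (int i = 0; i < nq; ++i) {
        if (q[i] >= 4) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t)q[i]) & mask;
        if (++run < word_size) continue;
        int qpos = i - word_size + 1;
        int b0 = idx.starts[key], b1 = idx.starts[key + 1];
        for (int t = b0; t < b1; ++t) {
          int spos = idx.positions[t];
          int d = spos - qpos;
          auto it = cover.find(d);
          if (it != cover.end() && qpos < it->second) continue;
          ExtRes L = xdrop_extend(q, qpos - 1, -1, qpos, s, spos - 1, -1, spos,
                                  match, mismatch, gap_open, gap_extend, xdrop, band);
          ExtRes R = xdrop_extend(q, qpos + word_size, +1, nq - qpos - word_size,
                                  s, spos + word_size, +1, ns - spos - word_size,
                                  match, mismatch, gap_open, gap_extend, xdrop, band);
          Hit h;
          h.score = word_size * match + L.score + R.score;
          h.matches = word_size + L.matches + R.matches;
          h.cols = word_size + L.cols + R.cols;
          int hqs = qpos - L.ai, hqe = qpos + word_size + R.ai;
          h.ss = spos - L.bj; h.se = spos + word_size + R.bj;
          h.strand = strand;
          if (strand == 0) { h.qs = hqs; h.qe = hqe; }
          else { h.qs = nq - hqe; h.qe = nq - hqs; }
          int& ce = cover[d];
          if (hqe > ce) ce = hqe;
          if (h.score > best.score ||
              (h.score == best.score && h.ss < best.ss))
            best = h;
        }
      }
    }
    if (best.score >= min_score && best.score > NEG) {
      o_idx.push_back(qi + 1);
      o_qs.push_back(best.qs); o_qe.push_back(best.qe);
      o_ss.push_back(best.ss); o_se.push_back(best.se);
      o_strand.push_back(best.strand);
      o_score.push_back(best.score);
      o_matches.push_back(best.matches);
      o_cols.push_back(best.cols);
    }
  }
  int n = (int)o_idx.size();
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) strand[i] = o_strand[i] == 0 ? "+" : "-";
  return DataFrame::create(
    _["query"] = wrap(o_idx), _["q_start"] = wrap(o_qs), _["q_end"] = wrap(o_qe),
    _["s_start"] = wrap(o_ss), _["s_end"] = wrap(o_se), _["strand"] = strand,
    _["score"] = wrap(o_score), _["matches"] = wrap(o_matches),
    _["cols"] = wrap(o_cols), _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// semi-global Needleman-Wunsch: full query aligned, reference end gaps free

// [[Rcpp::export]]
List cpp_nw_semiglobal(std::string ref, std::string qry,
                       int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int> a = encode_seq(ref), b = encode_seq(qry);
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("sequences too long for full dynamic programming");
  const size_t Wm = (size_t)m + 1;
  std::vector<int> M((size_t)(n + 1) * Wm, NEG);
  std::vector<int> X((size_t)(n + 1) * Wm, NEG);
  std::vector<int> Y((size_t)(n + 1) * Wm, NEG);
  std::vector<uint8_t> D((size_t)(n + 1) * Wm, 0);
  // column 0: free skip of reference prefix (score 0, "start" state)
  for (int i = 0; i <= n; ++i) M[(size_t)i * Wm] = 0;
  // row 0: leading insertions in query are penalized
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + gap_extend * (j - 1);
    D[j] |= (uint8_t)((j == 1 ? 0 : 2) << 4);
  }
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * Wm, p = (size_t)(i - 1) * Wm;
    for (int j = 1; j <= m; ++j) {
      uint8_t d = 0;
      int pm = M[p + j - 1], px = X[p + j - 1], py = Y[p + j - 1];
      int pd = pm, pc = 0;
      if (px >= pd) { pd = px; pc = 1; }
      if (py > pd) { pd = py; pc = 2; }
      if (pd > NEG) {
        M[r + j] = pd + subst(a[i - 1], b[j - 1], match, mismatch);
        d |= (uint8_t)pc;
      }
      // X: gap in query (consume ref)
      {
        int opn = std::max(M[p + j], Y[p + j]);
        int vo = (opn > NEG) ? opn + gap_open : NEG;
        int ve = (X[p + j] > NEG) ? X[p + j] + gap_extend : NEG;
        if (vo >= ve) { if (vo > NEG) { X[r + j] = vo; d |= (uint8_t)((M[p + j] >= Y[p + j] ? 0 : 2) << 2); } }
        else { X[r + j] = ve; d |= (uint8_t)(1 << 2); }
      }
      // Y: gap in reference (consume qry)
      {
        int opn = std::max(M[r + j - 1], X[r + j - 1]);
        int vo = (opn > NEG) ? opn + gap_open : NEG;
        int ve = (Y[r + j - 1] > NEG) ? Y[r + j - 1] + gap_extend : NEG;
        if (vo >= ve) { if (vo > NEG) { Y[r + j] = vo; d |= (uint8_t)((M[r + j - 1] >= X[r + j - 1] ? 0 : 1) << 4); } }
        else { Y[r + j] = ve; d |= (uint8_t)(2 << 4); }
      }
      D[r + j] = d;
    }
  }
  // best over last column (free trailing reference skip)
  int best = NEG, iend = 0, stbest = 0;
  for (int i = 0; i <= n; ++i) {
    const size_t r = (size_t)i * Wm;
    int vm = M[r + m], vx = X[r + m], vy = Y[r + m];
    int v = vm, st = 0;
    if (vx > v) { v = vx; st = 1; }
    if (vy > v) { v = vy; st = 2; }
    if (v >= best) { best = v; iend = i; stbest = st; }
  }
  // traceback to column 0
  std::string ra, qa;
  int i = iend, j = m, state = stbest;
  while (j > 0) {
    const size_t r = (size_t)i * Wm;
    uint8_t d = D[r + j];
    if (state == 0) {
      ra.push_back(ref[i - 1]); qa.push_back(qry[j - 1]);
      state = d & 3; --i; --j;
      if (j == 0) break;
      if (i == 0 && j > 0) { state = 2; }
    } else if (state == 1) {
      ra.push_back(ref[i - 1]); qa.push_back('-');
      state = (d >> 2) & 3; --i;
    } else {
      ra.push_back('-'); qa.push_back(qry[j - 1]);
      state = (d >> 4) & 3; --j;
    }
  }
  int istart = i;
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(
    _["score"] = best, _["ref_start"] = istart, _["ref_end"] = iend,
    _["ref_aln"] = ra, _["qry_aln"] = qa);
}
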