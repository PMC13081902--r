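#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Affine-gap pairwise alignment over protein alphabets, plus the translated
// read search used for metagenomic quantification. Gap model: a gap of length
// L costs gap_open + L * gap_ext (EMBOSS convention). Co-optimal tracebacks
// are resolved deterministically: diagonal > up (gap in b) > left (gap in a).

static const double NEG_INF = -1e18;

struct ScoreTable {
  int idx[256];
  std::vector<double> s; // n x n
  int n;
  void init(const NumericMatrix& m, const CharacterVector& letters) {
    n = m.nrow();
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    for (int i = 0; i < n; ++i) {
      std::string l = as<std::string>(letters[i]);
      idx[(unsigned char)l[0]] = i;
    }
    s.resize((size_t)n * n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) s[(size_t)i * n + j] = m(i, j);
  }
  inline double score(unsigned char a, unsigned char b) const {
    int ia = idx[a], ib = idx[b];
    if (ia < 0 || ib < 0) stop("residue not covered by the substitution matrix");
    return s[(size_t)ia * n + ib];
  }
  inline bool known(unsigned char a) const { return idx[a] >= 0; }
};

enum State { DIAG = 0, UP = 1, LEFT = 2, STOP = 3 };

// scratch buffers reused across calls (R is single-threaded); avoids a
// fresh multi-megabyte allocation per alignment in the read search
struct AlignScratch {
  std::vector<double> M, X, Y;
  std::vector<signed char> tbM, tbX, tbY;
};
static AlignScratch g_scratch;

// Full DP with traceback. local = Smith-Waterman (score floored at 0 in the
// match state, best cell anywhere); global = Needleman-Wunsch end-to-end.
static List align_pair(const std::string& a, const std::string& b,
                       const ScoreTable& st, double go, double ge,
                       bool local) {
  int na = (int)a.size(), nb = (int)b.size();
  size_t w = (size_t)nb + 1;
  size_t need = (size_t)(na + 1) * w;
  AlignScratch& ws = g_scratch;
  if (ws.M.size() < need) {
    ws.M.resize(need); ws.X.resize(need); ws.Y.resize(need);
    ws.tbM.resize(need); ws.tbX.resize(need); ws.tbY.resize(need);
  }
  std::vector<double>& M = ws.M; std::vector<double>& X = ws.X;
  std::vector<double>& Y = ws.Y;
  std::vector<signed char>& tbM = ws.tbM;
  std::vector<signed char>& tbX = ws.tbX;
  std::vector<signed char>& tbY = ws.tbY;
  // borders; interior cells are all written in the main loop
  M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF; tbM[0] = STOP;
  for (int i = 1; i <= na; ++i) {
    size_t c = (size_t)i * w;
    M[c] = NEG_INF; Y[c] = NEG_INF; tbM[c] = STOP;
    if (local) { X[c] = NEG_INF; tbX[c] = 0; }
    else { X[c] = -(go + ge * i); tbX[c] = (i == 1) ? 0 : 1; }
  }
  for (int j = 1; j <= nb; ++j) {
    M[j] = NEG_INF; X[j] = NEG_INF; tbM[j] = STOP;
    if (local) { Y[j] = NEG_INF; tbY[j] = 0; }
    else { Y[j] = -(go + ge * j); tbY[j] = (j == 1) ? 0 : 1; }
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      size_t c = i * w + j, d = (i - 1) * w + (j - 1), u = (i - 1) * w + j,
             l = i * w + (j - 1);
      // match state
      double sm = st.score(a[i - 1], b[j - 1]);
      double vm = M[d], vx = X[d], vy = Y[d];
      double pv = vm; signed char pt = DIAG;
      if (vx > pv) { pv = vx; pt = UP; }
      if (vy > pv) { pv = vy; pt = LEFT; }
      if (i == 1 && j == 1 && !local) { pv = 0.0; pt = STOP; } // from origin
      double mval;
      if (local) {
        if (pv < 0.0 || pv == NEG_INF) { pv = 0.0; pt = STOP; }
        mval = sm + pv;
        if (mval < 0.0) { mval = sm + 0.0; pt = STOP; }
        if (mval < 0.0) mval = NEG_INF; // never start on a negative pair
      } else {
        mval = (pv == NEG_INF) ? NEG_INF : sm + pv;
        if (i == 1 && j == 1) { mval = sm; pt = STOP; }
      }
      M[c] = mval; tbM[c] = pt;
      // gap in b (consume a_i): up
      double xo = (M[u] == NEG_INF) ? NEG_INF : M[u] - (go + ge);
      double xe = (X[u] == NEG_INF) ? NEG_INF : X[u] - ge;
      if (xo >= xe) { X[c] = xo; tbX[c] = 0; } else { X[c] = xe; tbX[c] = 1; }
      // gap in a (consume b_j): left
      double yo = (M[l] == NEG_INF) ? NEG_INF : M[l] - (go + ge);
      double yev = (Y[l] == NEG_INF) ? NEG_INF : Y[l] - ge;
      if (yo >= yev) { Y[c] = yo; tbY[c] = 0; } else { Y[c] = yev; tbY[c] = 1; }
      if (local && M[c] != NEG_INF && M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  std::string ga, gb;
  int qs = 0, qe = 0, ss = 0, se = 0;
  double score;
  if (local) {
    score = best;
    if (best > 0.0) {
      int i = bi, j = bj;
      qe = i; se = j;
      State stt = DIAG;
      bool done = false;
      while (!done && (i > 0 || j > 0)) {
        size_t c = (size_t)i * w + j;
        switch (stt) {
          case DIAG: {
            ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
            signed char pt = tbM[c];
            --i; --j;
            if (pt == STOP) done = true; else stt = (State)pt;
            break;
          }
          case UP: {
            ga.push_back(a[i - 1]); gb.push_back('-');
            signed char ext = tbX[c];
            --i;
            stt = ext ? UP : DIAG;
            break;
          }
          default: {
            ga.push_back('-'); gb.push_back(b[j - 1]);
            signed char ext = tbY[c];
            --j;
            stt = ext ? LEFT : DIAG;
            break;
          }
        }
      }
      qs = i + 1; ss = j + 1;
    }
  } else {
    // global: end state = best of M,X,Y at (na, nb)
    size_t c = (size_t)na * w + nb;
    double vm = (na > 0 && nb > 0) ? M[c] : (na == 0 && nb == 0 ? 0.0 : NEG_INF);
    double vx = X[c], vy = Y[c];
    State stt = DIAG; score = vm;
    if (vx > score) { score = vx; stt = UP; }
    if (vy > score) { score = vy; stt = LEFT; }
    int i = na, j = nb;
    bool done = false;
    while (!done && (i > 0 || j > 0)) {
      size_t cc = (size_t)i * w + j;
      switch (stt) {
        case DIAG: {
          ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
          signed char pt = tbM[cc];
          --i; --j;
          if (pt == STOP) done = true; else stt = (State)pt;
          break;
        }
        case UP: {
          ga.push_back(a[i - 1]); gb.push_back('-');
          signed char ext = tbX[cc];
          --i;
          stt = ext ? UP : DIAG;
          break;
        }
        default: {
          ga.push_back('-'); gb.push_back(b[j - 1]);
          signed char ext = tbY[cc];
          --j;
          stt = ext ? LEFT : DIAG;
          break;
        }
      }
    }
    qs = 1; qe = na; ss = 1; se = nb;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  // identity: identical iff same letter, not a gap, and not X or '*'
  int nid = 0, mism = 0, gapopens = 0;
  bool inGap = false;
  for (size_t t = 0; t < ga.size(); ++t) {
    char ca = ga[t], cb = gb[t];
    if (ca == '-' || cb == '-') {
      if (!inGap) ++gapopens;
      inGap = true;
    } else {
      inGap = false;
      if (ca == cb && ca != 'X' && ca != '*') ++nid; else ++mism;
    }
  }
  return List::create(
      _["score"] = score, _["aligned_a"] = ga, _["aligned_b"] = gb,
      _["n_identical"] = nid, _["aln_len"] = (int)ga.size(),
      _["mismatch"] = mism, _["gapopen"] = gapopens,
      _["start_a"] = qs, _["end_a"] = qe, _["start_b"] = ss, _["end_b"] = se);
}

// [[Rcpp::export]]
List cpp_pair_align(std::string a, std::string b, NumericMatrix submat,
                    CharacterVector letters, double gap_open, double gap_ext,
                    bool local) {
  ScoreTable st; st.init(submat, letters);
  for (char c : a) if (!st.known(c)) stop("invalid residue '%s' in sequence", std::string(1, c).c_str());
  for (char c : b) if (!st.known(c)) stop("invalid residue '%s' in sequence", std::string(1, c).c_str());
  return align_pair(a, b, st, gap_open, gap_ext, local);
}

// ---- brute-force oracles: plain recursion over every alignment path, no DP -

static double brute_global_rec(const std::string& a, const std::string& b,
                               size_t i, size_t j, int prev,
                               const ScoreTable& st, double go, double ge) {
  if (i == a.size() && j == b.size()) return 0.0;
  double best = NEG_INF;
  if (i < a.size() && j < b.size()) {
    double v = st.score(a[i], b[j]) +
               brute_global_rec(a, b, i + 1, j + 1, DIAG, st, go, ge);
    if (v > best) best = v;
  }
  if (i < a.size()) {
    double cost = (prev == UP) ? ge : go + ge;
    double v = -cost + brute_global_rec(a, b, i + 1, j, UP, st, go, ge);
    if (v > best) best = v;
  }
  if (j < b.size()) {
    double cost = (prev == LEFT) ? ge : go + ge;
    double v = -cost + brute_global_rec(a, b, i, j + 1, LEFT, st, go, ge);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
double cpp_brute_global(std::string a, std::string b, NumericMatrix submat,
                        CharacterVector letters, double gap_open,
                        double gap_ext) {
  ScoreTable st; st.init(submat, letters);
  return brute_global_rec(a, b, 0, 0, STOP, st, gap_open, gap_ext);
}

static double brute_local_rec(const std::string& a, const std::string& b,
                              size_t i, size_t j, int prev,
                              const ScoreTable& st, double go, double ge) {
  double best = 0.0; // stopping here is always allowed
  if (i < a.size() && j < b.size()) {
    double v = st.score(a[i], b[j]) +
               brute_local_rec(a, b, i + 1, j + 1, DIAG, st, go, ge);
    if (v > best) best = v;
  }
  if (i < a.size()) {
    double cost = (prev == UP) ? ge : go + ge;
    double v = -cost + brute_local_rec(a, b, i + 1, j, UP, st, go, ge);
    if (v > best) best = v;
  }
  if (j < b.size()) {
    double cost = (prev == LEFT) ? ge : go + ge;
    double v = -cost + brute_local_rec(a, b, i, j + 1, LEFT, st, go, ge);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
double cpp_brute_local(std::string a, std::string b, NumericMatrix submat,
                       CharacterVector letters, double gap_open,
                       double gap_ext) {
  ScoreTable st; st.init(submat, letters);
  double best = 0.0;
  for (size_t i = 0; i <= a.size(); ++i)
    for (size_t j = 0; j <= b.size(); ++j) {
      double v = brute_local_rec(a, b, i, j, STOP, st, gap_open, gap_ext);
      if (v > best) best = v;
    }
  return best;
}

// ---- six-frame translation ------------------------------------------------

static const char* CODON_AA =
    // indexed by 16*b1 + 4*b2 + b3 with T=0, C=1, A=2, G=3
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline int base_idx(char c) {
  switch (c) {
    case 'T': case 't': case 'U': case 'u': return 0;
    case 'C': case 'c': return 1;
    case 'A': case 'a': return 2;
    case 'G': case 'g': return 3;
    default: return -1; // N or other ambiguity
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': case 'U': case 'u': return 'A';
    default: return 'N';
  }
}

static std::string translate_frame(const std::string& nt, int offset) {
  std::string pep;
  size_t n = nt.size();
  if (n < (size_t)offset + 3) return pep;
  pep.reserve((n - offset) / 3);
  for (size_t p = offset; p + 2 < n; p += 3) {
    int b1 = base_idx(nt[p]), b2 = base_idx(nt[p + 1]), b3 = base_idx(nt[p + 2]);
    if (b1 < 0 || b2 < 0 || b3 < 0) pep.push_back('X');
    else pep.push_back(CODON_AA[16 * b1 + 4 * b2 + b3]);
  }
  return pep;
}

static std::string revcomp(const std::string& nt) {
  std::string rc(nt.rbegin(), nt.rend());
  for (auto& c : rc) c = comp_base(c);
  return rc;
}

// [[Rcpp::export]]
CharacterVector cpp_six_frames(std::string read) {
  CharacterVector out(6);
  std::string rc = revcomp(read);
  for (int f = 0; f < 3; ++f) {
    out[f] = translate_frame(read, f);
    out[f + 3] = translate_frame(rc, f);
  }
  out.attr("names") = CharacterVector::create("+1", "+2", "+3", "-1", "-2", "-3");
  return out;
}

// ---- translated read search ------------------------------------------------

static inline bool kmer_encode(const std::string& s, size_t pos, int k,
                               uint32_t& code) {
  code = 0;
  for (int t = 0; t < k; ++t) {
    char c = s[pos + t];
    if (c < 'A' || c > 'Z' || c == 'X') return false; // skip X/'*' kmers
    if (c == '*') return false;
    code = code * 27u + (uint32_t)(c - 'A');
  }
  return true;
}

// Score-only local alignment (classic Gotoh with H floored at 0, rolling
// rows), used to screen candidates before the traceback DP runs on
// reported hits. The optimum never ends in a gap, so the floored-H
// formulation returns the same best score as the traceback DP. Sequences
// arrive pre-mapped to substitution-matrix row indices.
static double local_score_only(const std::vector<int>& aidx,
                               const std::vector<int>& bidx,
                               const ScoreTable& st, double go, double ge) {
  int na = (int)aidx.size(), nb = (int)bidx.size();
  const double BIG = -1e15, open = go + ge;
  static std::vector<double> H, E;
  if ((int)H.size() < nb + 1) { H.resize(nb + 1); E.resize(nb + 1); }
  for (int j = 0; j <= nb; ++j) { H[j] = 0.0; E[j] = BIG; }
  double best = 0.0;
  const int* bp = bidx.data();
  for (int i = 1; i <= na; ++i) {
    double hdiag = 0.0; // H[i-1][j-1]
    double hleft = 0.0; // H[i][j-1]
    double f = BIG;     // F[i][j-1] rolled along the row
    const double* srow = &st.s[(size_t)aidx[i - 1] * st.n];
    double* Hp = H.data();
    double* Ep = E.data();
    for (int j = 1; j <= nb; ++j) {
      double e = Ep[j] - ge, eo = Hp[j] - open;
      if (eo > e) e = eo;
      Ep[j] = e;
      double fc = f - ge, fo = hleft - open;
      f = (fo > fc) ? fo : fc;
      double h = hdiag + srow[bp[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      hdiag = Hp[j];
      Hp[j] = h;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_search_reads(CharacterVector reads, CharacterVector db,
                           NumericMatrix submat, CharacterVector letters,
                           double gap_open, double gap_ext, int k,
                           double min_score, bool prefilter) {
  ScoreTable st; st.init(submat, letters);
  int nd = db.size();
  std::vector<std::string> dbs(nd);
  std::vector<std::vector<int> > dbidx(nd); // residue indices per entry
  // k-mer -> list of db entries containing it
  std::unordered_map<uint32_t, std::vector<int> > index;
  for (int d = 0; d < nd; ++d) {
    dbs[d] = as<std::string>(db[d]);
    dbidx[d].resize(dbs[d].size());
    for (size_t p = 0; p < dbs[d].size(); ++p) {
      int ix = st.idx[(unsigned char)dbs[d][p]];
      if (ix < 0) stop("database residue not covered by the substitution matrix");
      dbidx[d][p] = ix;
    }
    if (!prefilter) continue;
    std::unordered_set<uint32_t> seen;
    if ((int)dbs[d].size() >= k)
      for (size_t p = 0; p + k <= dbs[d].size(); ++p) {
        uint32_t code;
        if (kmer_encode(dbs[d], p, k, code) && seen.insert(code).second)
          index[code].push_back(d);
      }
  }
  std::vector<int> r_read, r_frame, r_target, r_alnlen, r_nid, r_mism, r_gap;
  std::vector<int> r_qs, r_qe, r_ss, r_se;
  std::vector<double> r_score, r_ident;
  static const int FRAMES[6] = {1, 2, 3, -1, -2, -3};
  std::vector<int> stamp(nd, -1);
  int epoch = 0;
  std::vector<int> candList;
  std::vector<int> pidx;
  for (int r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    int L = (int)read.size();
    std::string rc = revcomp(read);
    for (int f = 0; f < 6; ++f) {
      const std::string& src = (f < 3) ? read : rc;
      std::string pep = translate_frame(src, f % 3);
      if ((int)pep.size() < 1) continue;
      candList.clear();
      ++epoch;
      if (prefilter) {
        if ((int)pep.size() < k) continue;
        for (size_t p = 0; p + k <= pep.size(); ++p) {
          uint32_t code;
          if (!kmer_encode(pep, p, k, code)) continue;
          auto it = index.find(code);
          if (it != index.end())
            for (int d : it->second)
              if (stamp[d] != epoch) { stamp[d] = epoch; candList.push_back(d); }
        }
      } else {
        for (int d = 0; d < nd; ++d) candList.push_back(d);
      }
      if (candList.empty()) continue;
      pidx.resize(pep.size());
      for (size_t p = 0; p < pep.size(); ++p) {
        int ix = st.idx[(unsigned char)pep[p]];
        if (ix < 0) stop("translated residue not covered by the substitution matrix");
        pidx[p] = ix;
      }
      for (int d : candList) {
        double sc = local_score_only(pidx, dbidx[d], st, gap_open, gap_ext);
        if (sc < min_score || sc <= 0.0) continue;
        List al = align_pair(pep, dbs[d], st, gap_open, gap_ext, true);
        int alen = al["aln_len"];
        if (alen == 0) continue;
        int nid = al["n_identical"];
        int ps = al["start_a"], pe = al["end_a"];
        // peptide coords -> nucleotide coords on the original read
        int off = f % 3;
        int qs_nt, qe_nt;
        if (f < 3) {
          qs_nt = (ps - 1) * 3 + off + 1;
          qe_nt = qs_nt + (pe - ps + 1) * 3 - 1;
        } else {
          int s_rc = (ps - 1) * 3 + off + 1;
          int e_rc = s_rc + (pe - ps + 1) * 3 - 1;
          qs_nt = L - s_rc + 1; // descending coordinates for minus frames
          qe_nt = L - e_rc + 1;
        }
        r_read.push_back(r + 1);
        r_frame.push_back(FRAMES[f]);
        r_target.push_back(d + 1);
        r_score.push_back(Rcpp::as<double>(al["score"]));
        r_ident.push_back(100.0 * nid / alen);
        r_alnlen.push_back(alen);
        r_nid.push_back(nid);
        r_mism.push_back(Rcpp::as<int>(al["mismatch"]));
        r_gap.push_back(Rcpp::as<int>(al["gapopen"]));
        r_qs.push_back(qs_nt);
        r_qe.push_back(qe_nt);
        r_ss.push_back(Rcpp::as<int>(al["start_b"]));
        r_se.push_back(Rcpp::as<int>(al["end_b"]));
      }
    }
  }
  return DataFrame::create(
      _["read"] = r_read, _["frame"] = r_frame, _["target"] = r_target,
      _["score"] = r_score, _["identity_pct"] = r_ident,
      _["aln_len"] = r_alnlen, _["n_identical"] = r_nid,
      _["mismatch"] = r_mism, _["gapopen"] = r_gap, _["qstart"] = r_qs,
      _["qend"] = r_qe, _["sstart"] = r_ss, _["send"] = r_se,
      _["stringsAsFactors"] = false);
}
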