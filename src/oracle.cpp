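// Brute-force reference implementations used by the test suite as independent
// oracles.  These deliberately share no search machinery with kernels.cpp:
// every genome position is enumerated directly, and the DP oracles fill full
// matrices with no banding or score-only shortcuts.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int ocode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}
static inline bool omatch(int a, int b) { return a == b && a < 4; }

static std::vector<int> oenc(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = ocode(s[i]);
  return v;
}

// [[Rcpp::export]]
DataFrame naive_hamming_cpp(CharacterVector seqs, std::string pattern, int kmm) {
  std::vector<int> pat = oenc(pattern);
  int len = (int)pat.size();
  std::vector<int> chrom, mms;
  std::vector<double> pos;
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    std::vector<int> g = oenc(as<std::string>(seqs[c]));
    for (int p = 0; p + len <= (int)g.size(); ++p) {
      int mm = 0;
      for (int i = 0; i < len && mm <= kmm; ++i)
        if (!omatch(pat[i], g[p + i])) ++mm;
      if (mm <= kmm) { chrom.push_back(c + 1); pos.push_back(p); mms.push_back(mm); }
    }
  }
  return DataFrame::create(_["chrom_idx"] = wrap(chrom), _["pos"] = wrap(pos),
                           _["mismatches"] = wrap(mms));
}

// Exhaustive position x signature scan: for EVERY anchor in every chromosome,
// the least-penalty (mismatches, gap) configuration of the pattern within
// budget, using the same canonical configuration space as the seed search
// (gap split interior to the seed, mm <= max_mm).
// [[Rcpp::export]]
DataFrame naive_seed_scan_cpp(CharacterVector seqs, std::string pattern,
                              int max_mm, int d_seed, bool allow_gap,
                              double pen_mm, double pen_open, double pen_ext) {
  std::vector<int> pat = oenc(pattern);
  int len = (int)pat.size();
  std::vector<int> chromv, mmv, gapsv, glenv, gtypev, splitv;
  std::vector<double> posv, penv;
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    std::vector<int> g = oenc(as<std::string>(seqs[c]));
    int n = (int)g.size();
    for (int p = 0; p < n; ++p) {
      bool found = false;
      double bpen = 0; int bmm = 0, bgaps = 0, bg = 0, btype = 0, bsplit = 0;
      // candidate configurations evaluated with fresh counting each time
      std::vector<int> pre(len + 1, 0);
      for (int s = 0; s < len && p + s < n; ++s)
        pre[s + 1] = pre[s] + (omatch(pat[s], g[p + s]) ? 0 : 1);
      // no gap
      if (p + len <= n && pre[len] <= max_mm) {
        found = true; bpen = pen_mm * pre[len]; bmm = pre[len];
        bgaps = 0; bg = 0; btype = 0; bsplit = 0;
      }
      if (allow_gap) {
        for (int gl = 1; gl <= d_seed; ++gl) {
          double gpen = pen_open + gl * pen_ext;
          if (p + len + gl <= n) { // deletion (window skips gl)
            std::vector<int> suf(len + 1, 0);
            for (int s = len - 1; s >= 1; --s)
              suf[s] = suf[s + 1] + (omatch(pat[s], g[p + gl + s]) ? 0 : 1);
            for (int s = 1; s <= len - 1; ++s) {
              int mm = pre[s] + suf[s];
              if (mm > max_mm) continue;
              double pen = pen_mm * mm + gpen;
              bool better = !found || pen < bpen ||
                (pen == bpen && (1 < bgaps ||
                 (1 == bgaps && (mm < bmm ||
                  (mm == bmm && (gl < bg ||
                   (gl == bg && (1 < btype ||
                    (1 == btype && s < bsplit)))))))));
              if (better) {
                found = true; bpen = pen; bmm = mm; bgaps = 1; bg = gl;
                btype = 1; bsplit = s;
              }
            }
          }
          if (gl <= len - 2 && p + len - gl <= n) { // insertion (read skips gl)
            std::vector<int> sufI(len + 1, 0);
            for (int i = len - 1; i >= gl + 1; --i)
              sufI[i] = sufI[i + 1] + (omatch(pat[i], g[p + i - gl]) ? 0 : 1);
            for (int s = 1; s <= len - gl - 1; ++s) {
              int mm = pre[s] + sufI[s + gl];
              if (mm > max_mm) continue;
              double pen = pen_mm * mm + gpen;
              bool better = !found || pen < bpen ||
                (pen == bpen && (1 < bgaps ||
                 (1 == bgaps && (mm < bmm ||
                  (mm == bmm && (gl < bg ||
                   (gl == bg && (2 < btype ||
                    (2 == btype && s < bsplit)))))))));
              if (better) {
                found = true; bpen = pen; bmm = mm; bgaps = 1; bg = gl;
                btype = 2; bsplit = s;
              }
            }
          }
        }
      }
      if (found) {
        chromv.push_back(c + 1); posv.push_back(p); mmv.push_back(bmm);
        gapsv.push_back(bgaps); glenv.push_back(bg); gtypev.push_back(btype);
        splitv.push_back(bsplit); penv.push_back(bpen);
      }
    }
  }
  return DataFrame::create(_["chrom_idx"] = wrap(chromv), _["pos"] = wrap(posv),
                           _["mismatches"] = wrap(mmv), _["gaps"] = wrap(gapsv),
                           _["gap_len"] = wrap(glenv), _["gap_type"] = wrap(gtypev),
                           _["split"] = wrap(splitv), _["penalty"] = wrap(penv));
}

// Full-matrix affine-gap local alignment (three explicit matrices), score and
// end coordinates only.
// [[Rcpp::export]]
List naive_local_dp_cpp(std::string read, NumericVector mb, NumericVector mp,
                        std::string window, double gap_open, double gap_extend) {
  std::vector<int> R = oenc(read), W = oenc(window);
  int n = (int)R.size(), m = (int)W.size();
  const double NEG = -1e18;
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open, E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open, F[i - 1][j] - gap_extend);
      double s = omatch(R[i - 1], W[j - 1]) ? mb[i - 1] : -mp[i - 1];
      double h = H[i - 1][j - 1] + s;
      h = std::max(h, std::max(E[i][j], F[i][j]));
      h = std::max(h, 0.0);
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return List::create(_["score"] = best, _["end_read"] = bi, _["end_ref"] = bj);
}

// Affine-gap glocal DP: read aligned end-to-end, window ends free.  Full
// matrices with pointer traceback; reports the optimal score plus the number
// and maximal length of gap runs on one optimal path (ties broken towards the
// match state, which minimizes gratuitous run splitting).
// [[Rcpp::export]]
List naive_glocal_dp_cpp(std::string read, NumericVector mb, NumericVector mp,
                         std::string window, double gap_open, double gap_extend) {
  std::vector<int> R = oenc(read), W = oenc(window);
  int n = (int)R.size(), m = (int)W.size();
  const double NEG = -1e18;
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<uint8_t>> PH(n + 1, std::vector<uint8_t>(m + 1, 0));
  std::vector<std::vector<uint8_t>> PE(n + 1, std::vector<uint8_t>(m + 1, 0));
  std::vector<std::vector<uint8_t>> PF(n + 1, std::vector<uint8_t>(m + 1, 0));
  for (int j = 0; j <= m; ++j) H[0][j] = 0.0; // free window prefix
  for (int i = 1; i <= n; ++i) {
    F[i][0] = -(gap_open + (i - 1) * gap_extend);
    PF[i][0] = (i == 1) ? 0 : 1;
    H[i][0] = F[i][0];
    PH[i][0] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H[i][j - 1] - gap_open, ee = E[i][j - 1] - gap_extend;
      if (eo >= ee) { E[i][j] = eo; PE[i][j] = 0; } else { E[i][j] = ee; PE[i][j] = 1; }
      double fo = H[i - 1][j] - gap_open, fe = F[i - 1][j] - gap_extend;
      if (fo >= fe) { F[i][j] = fo; PF[i][j] = 0; } else { F[i][j] = fe; PF[i][j] = 1; }
      double s = omatch(R[i - 1], W[j - 1]) ? mb[i - 1] : -mp[i - 1];
      double dg = (H[i - 1][j - 1] <= NEG / 2) ? NEG : H[i - 1][j - 1] + s;
      double h = dg; uint8_t ph = 1; // prefer the match state on ties
      if (E[i][j] > h) { h = E[i][j]; ph = 2; }
      if (F[i][j] > h) { h = F[i][j]; ph = 3; }
      H[i][j] = h; PH[i][j] = ph;
    }
  }
  double best = NEG;
  int bj = 0;
  for (int j = 0; j <= m; ++j)
    if (H[n][j] > best) { best = H[n][j]; bj = j; }
  // traceback to count gap runs
  int i = n, j = bj, state = 0;
  int runs = 0, maxrun = 0, cur = 0;
  char last = 'X';
  while (i > 0) {
    if (state == 0) {
      uint8_t ph = PH[i][j];
      if (ph == 1) {
        if (last == 'D' || last == 'I') { if (cur > maxrun) maxrun = cur; cur = 0; }
        last = 'M'; --i; --j;
      } else if (ph == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // D run (consumes window)
      if (last != 'D') { ++runs; cur = 0; }
      last = 'D'; ++cur; if (cur > maxrun) maxrun = cur;
      uint8_t pe = PE[i][j];
      --j;
      state = (pe == 0) ? 0 : 1;
    } else { // I run (consumes read)
      if (last != 'I') { ++runs; cur = 0; }
      last = 'I'; ++cur; if (cur > maxrun) maxrun = cur;
      uint8_t pf = PF[i][j];
      --i;
      state = (pf == 0) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best, _["gap_runs"] = runs,
                      _["max_run"] = maxrun);
}

// Naive best one-gap-run alignment: direct enumeration over anchor, gap type,
// gap length and split point, each configuration re-summed from scratch via
// its own prefix loops.
// [[Rcpp::export]]
double naive_one_gap_cpp(std::string read, NumericVector mb, NumericVector mp,
                         std::string window, int d, double gap_open,
                         double gap_extend) {
  std::vector<int> R = oenc(read), W = oenc(window);
  int L = (int)R.size(), m = (int)W.size();
  const double NEG = -1e18;
  double best = NEG;
  std::vector<double> A(L + 1), B(L + 1);
  for (int p = 0; p + L <= m; ++p) { // zero gap
    double sc = 0;
    for (int i = 0; i < L; ++i)
      sc += omatch(R[i], W[p + i]) ? mb[i] : -mp[i];
    if (sc > best) best = sc;
  }
  for (int g = 1; g <= d; ++g) {
    double gpen = gap_open + (g - 1) * gap_extend;
    for (int p = 0; p + L + g <= m; ++p) { // deletion
      A[0] = 0;
      for (int i = 0; i < L; ++i)
        A[i + 1] = A[i] + (omatch(R[i], W[p + i]) ? mb[i] : -mp[i]);
      B[L] = 0;
      for (int i = L - 1; i >= 0; --i)
        B[i] = B[i + 1] + (omatch(R[i], W[p + g + i]) ? mb[i] : -mp[i]);
      for (int s = 1; s <= L - 1; ++s) {
        double sc = A[s] + B[s] - gpen;
        if (sc > best) best = sc;
      }
    }
    for (int p = 0; p + L - g <= m; ++p) { // insertion, end splits allowed
      A[0] = 0;
      for (int i = 0; i < L; ++i)
        A[i + 1] = (p + i < m)
          ? A[i] + (omatch(R[i], W[p + i]) ? mb[i] : -mp[i]) : NEG;
      for (int s = 0; s <= L - g; ++s) {
        if (s > 0 && A[s] <= NEG / 2) continue;
        double sc = (s > 0 ? A[s] : 0.0) - gpen;
        bool ok = true;
        for (int i = s + g; i < L; ++i) {
          int j = p + i - g;
          if (j < 0 || j >= m) { ok = false; break; }
          sc += omatch(R[i], W[j]) ? mb[i] : -mp[i];
        }
        if (ok && sc > best) best = sc;
      }
    }
  }
  return best;
}
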