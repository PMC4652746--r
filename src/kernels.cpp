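// Core alignment kernels: hashed k-mer genome index with pigeonhole candidate
// generation, cost-ordered seed verification, one-gap semi-global extension,
// affine local Smith-Waterman (score-only) and banded traceback.
// Coordinates are 0-based half-open throughout; conversion to SAM's 1-based
// convention happens only in the R-level SAM writer.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

static inline uint8_t code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N and anything else: matches nothing
  }
}

static std::vector<uint8_t> encode_str(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = code_of(s[i]);
  return v;
}

// match rule: N (code 4) on either side never matches
static inline bool is_match(uint8_t a, uint8_t b) { return a == b && a < 4; }

struct GenomeIdx {
  std::vector<uint8_t> seq;        // concatenated chromosome codes
  std::vector<long long> bounds;   // chromosome offsets, size nchrom + 1
  int k;
  std::vector<int> pos_sorted;     // k-mer start positions, sorted by code
  std::vector<uint32_t> code_sorted;
};

// chromosome index containing global position p
static inline int chrom_of(const GenomeIdx& G, long long p) {
  return int(std::upper_bound(G.bounds.begin() + 1, G.bounds.end(), p) -
             (G.bounds.begin() + 1));
}

// [[Rcpp::export]]
SEXP build_index_cpp(CharacterVector seqs, int k) {
  GenomeIdx* G = new GenomeIdx();
  G->k = k;
  G->bounds.push_back(0);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (char c : s) G->seq.push_back(code_of(c));
    G->bounds.push_back((long long)G->seq.size());
  }
  // collect k-mers per chromosome (never across boundaries, never over N)
  std::vector<std::pair<uint32_t, int>> v;
  for (size_t c = 0; c + 1 < G->bounds.size(); ++c) {
    long long lo = G->bounds[c], hi = G->bounds[c + 1];
    if (hi - lo < k) continue;
    uint32_t code = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
    int run = 0; // length of current non-N run ending here
    for (long long p = lo; p < hi; ++p) {
      uint8_t b = G->seq[p];
      if (b > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++run >= k) v.push_back(std::make_pair(code, int(p - k + 1)));
    }
  }
  std::sort(v.begin(), v.end());
  G->pos_sorted.resize(v.size());
  G->code_sorted.resize(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    G->code_sorted[i] = v[i].first;
    G->pos_sorted[i] = v[i].second;
  }
  XPtr<GenomeIdx> xp(G, true);
  return xp;
}

// [[Rcpp::export]]
bool ptr_valid_cpp(SEXP xp) {
  return R_ExternalPtrAddr(xp) != NULL;
}

// positions of the exact k-mer `code` (index lookup)
static void kmer_hits(const GenomeIdx& G, uint32_t code, std::vector<long long>& out) {
  std::pair<std::vector<uint32_t>::const_iterator,
            std::vector<uint32_t>::const_iterator> rng =
      std::equal_range(G.code_sorted.begin(), G.code_sorted.end(), code);
  size_t a = rng.first - G.code_sorted.begin();
  size_t b = rng.second - G.code_sorted.begin();
  for (size_t i = a; i < b; ++i) out.push_back(G.pos_sorted[i]);
}

// Hamming distance of pattern placed at p, or -1 if it does not fit inside one
// chromosome or exceeds maxmm.
static int hamming_at(const GenomeIdx& G, const std::vector<uint8_t>& pat,
                      long long p, int maxmm) {
  int c = chrom_of(G, p);
  long long hi = G.bounds[c + 1];
  if (p + (long long)pat.size() > hi) return -1;
  int mm = 0;
  for (size_t i = 0; i < pat.size(); ++i) {
    if (!is_match(pat[i], G.seq[p + i])) { if (++mm > maxmm) return -1; }
  }
  return mm;
}

// exact occurrences of pattern (both via index when long enough, else scan)
static std::vector<long long> exact_positions(const GenomeIdx& G,
                                              const std::vector<uint8_t>& pat) {
  std::vector<long long> out;
  int len = (int)pat.size();
  if (len == 0) return out;
  bool hasN = false;
  for (uint8_t b : pat) if (b > 3) hasN = true;
  if (hasN) return out; // N in pattern matches nothing
  if (len >= G.k) {
    uint32_t code = 0;
    for (int i = 0; i < G.k; ++i) code = (code << 2) | pat[i];
    std::vector<long long> cand;
    kmer_hits(G, code, cand);
    for (long long p : cand) if (hamming_at(G, pat, p, 0) == 0) out.push_back(p);
    std::sort(out.begin(), out.end());
  } else {
    for (size_t c = 0; c + 1 < G.bounds.size(); ++c) {
      long long lo = G.bounds[c], hi = G.bounds[c + 1];
      for (long long p = lo; p + len <= hi; ++p)
        if (hamming_at(G, pat, p, 0) == 0) out.push_back(p);
    }
  }
  return out;
}

// [[Rcpp::export]]
DataFrame find_exact_cpp(SEXP xp, std::string pattern) {
  XPtr<GenomeIdx> G(xp);
  std::vector<uint8_t> pat = encode_str(pattern);
  std::vector<long long> pos = exact_positions(*G, pat);
  IntegerVector chrom(pos.size());
  NumericVector p(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) {
    int c = chrom_of(*G, pos[i]);
    chrom[i] = c + 1;
    p[i] = double(pos[i] - G->bounds[c]);
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["pos"] = p);
}

// [[Rcpp::export]]
DataFrame find_kmm_cpp(SEXP xp, std::string pattern, int kmm) {
  XPtr<GenomeIdx> G(xp);
  std::vector<uint8_t> pat = encode_str(pattern);
  int len = (int)pat.size();
  std::vector<long long> cand;
  int plen = len / (kmm + 1);
  if (plen >= G->k && kmm > 0) {
    // pigeonhole: k+1 disjoint parts; query first k bases of each
    for (int part = 0; part <= kmm; ++part) {
      int off = part * plen;
      uint32_t code = 0;
      bool ok = true;
      for (int i = 0; i < G->k; ++i) {
        if (pat[off + i] > 3) { ok = false; break; }
        code = (code << 2) | pat[off + i];
      }
      if (!ok) continue;
      std::vector<long long> h;
      kmer_hits(*G, code, h);
      for (long long q : h) if (q - off >= 0) cand.push_back(q - off);
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  } else if (kmm == 0) {
    cand = exact_positions(*G, pat);
  } else {
    for (size_t c = 0; c + 1 < G->bounds.size(); ++c)
      for (long long p = G->bounds[c]; p + len <= G->bounds[c + 1]; ++p)
        cand.push_back(p);
  }
  std::vector<long long> pos;
  std::vector<int> mms;
  for (long long p : cand) {
    int mm = hamming_at(*G, pat, p, kmm);
    if (mm >= 0) { pos.push_back(p); mms.push_back(mm); }
  }
  IntegerVector chrom(pos.size()), mmv(pos.size());
  NumericVector pv(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) {
    int c = chrom_of(*G, pos[i]);
    chrom[i] = c + 1;
    pv[i] = double(pos[i] - G->bounds[c]);
    mmv[i] = mms[i];
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["pos"] = pv,
                           _["mismatches"] = mmv);
}

// ---- cost-ordered seed verification -----------------------------------------

struct Cfg {
  double pen;
  int gaps, mm, g, type, split; // type: 0 none, 1 D (ref skip), 2 I (read skip)
  bool ok;
};

static inline bool cfg_better(const Cfg& a, const Cfg& b) {
  if (!b.ok) return a.ok;
  if (!a.ok) return false;
  if (a.pen != b.pen) return a.pen < b.pen;
  if (a.gaps != b.gaps) return a.gaps < b.gaps;
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.g != b.g) return a.g < b.g;
  if (a.type != b.type) return a.type < b.type;
  return a.split < b.split;
}

// Best configuration (lowest enumeration penalty) of the seed anchored with its
// leftmost aligned base at global position p.  Gap split points are interior to
// the seed; mm <= max_mm is enforced for every configuration.
static Cfg best_config_at(const GenomeIdx& G, const std::vector<uint8_t>& pat,
                          long long p, int max_mm, int d_seed, bool allow_gap,
                          double pen_mm, double pen_open, double pen_ext) {
  Cfg best; best.ok = false; best.pen = 0;
  int len = (int)pat.size();
  if (p < 0 || p >= (long long)G.seq.size()) return best;
  int c = chrom_of(G, p);
  long long lo = G.bounds[c], hi = G.bounds[c + 1];
  (void)lo;
  // prefix mismatches of pat[0..s) at p (valid for s while p+s <= hi)
  std::vector<int> pre(len + 1, 0);
  int smax = (int)std::min((long long)len, hi - p);
  for (int s = 0; s < smax; ++s)
    pre[s + 1] = pre[s] + (is_match(pat[s], G.seq[p + s]) ? 0 : 1);
  if (p + len <= hi && pre[len] <= max_mm) {
    Cfg z; z.ok = true; z.gaps = 0; z.mm = pre[len]; z.g = 0; z.type = 0;
    z.split = 0; z.pen = pen_mm * z.mm;
    if (cfg_better(z, best)) best = z;
  }
  if (!allow_gap) return best;
  std::vector<int> suf(len + 2, 0);
  for (int g = 1; g <= d_seed; ++g) {
    double gpen = pen_open + g * pen_ext;
    // deletion: ref skips g bases after split s; span = len + g
    if (p + len + g <= hi) {
      suf[len] = 0;
      for (int s = len - 1; s >= 1; --s)
        suf[s] = suf[s + 1] + (is_match(pat[s], G.seq[p + g + s]) ? 0 : 1);
      for (int s = 1; s <= len - 1; ++s) {
        int mm = pre[s] + suf[s];
        if (mm > max_mm) continue;
        Cfg cf; cf.ok = true; cf.gaps = 1; cf.mm = mm; cf.g = g; cf.type = 1;
        cf.split = s; cf.pen = pen_mm * mm + gpen;
        if (cfg_better(cf, best)) best = cf;
      }
    }
    // insertion: read bases [s, s+g) unaligned; span = len - g
    if (g <= len - 2 && p + len - g <= hi) {
      std::vector<int> sufI(len + 1, 0);
      for (int i = len - 1; i >= g + 1; --i)
        sufI[i] = sufI[i + 1] + (is_match(pat[i], G.seq[p + i - g]) ? 0 : 1);
      for (int s = 1; s <= len - g - 1; ++s) {
        int mm = pre[s] + sufI[s + g];
        if (mm > max_mm) continue;
        Cfg cf; cf.ok = true; cf.gaps = 1; cf.mm = mm; cf.g = g; cf.type = 2;
        cf.split = s; cf.pen = pen_mm * mm + gpen;
        if (cfg_better(cf, best)) best = cf;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
DataFrame seed_scan_cpp(SEXP xp, std::string pattern, int max_mm, int d_seed,
                        bool allow_gap, double pen_mm, double pen_open,
                        double pen_ext) {
  XPtr<GenomeIdx> G(xp);
  std::vector<uint8_t> pat = encode_str(pattern);
  int len = (int)pat.size();
  int n_parts = max_mm + (allow_gap ? 1 : 0) + 1;
  int plen = len / n_parts;
  int D = allow_gap ? d_seed : 0;
  std::vector<long long> anchors;
  if (plen >= G->k) {
    for (int part = 0; part < n_parts; ++part) {
      int off = part * plen;
      uint32_t code = 0;
      bool ok = true;
      for (int i = 0; i < G->k; ++i) {
        if (pat[off + i] > 3) { ok = false; break; }
        code = (code << 2) | pat[off + i];
      }
      if (!ok) continue;
      std::vector<long long> h;
      kmer_hits(*G, code, h);
      for (long long q : h)
        for (int d = -D; d <= D; ++d) {
          long long a = q - off + d;
          if (a >= 0 && a < (long long)G->seq.size()) anchors.push_back(a);
        }
    }
    std::sort(anchors.begin(), anchors.end());
    anchors.erase(std::unique(anchors.begin(), anchors.end()), anchors.end());
  } else {
    // pattern too short for pigeonhole parts: verify every anchor
    for (size_t c = 0; c + 1 < G->bounds.size(); ++c)
      for (long long p = G->bounds[c];
           p + len - (allow_gap ? d_seed : 0) <= G->bounds[c + 1] &&
           p < G->bounds[c + 1]; ++p)
        anchors.push_back(p);
  }
  std::vector<long long> pos;
  std::vector<Cfg> cfgs;
  for (long long a : anchors) {
    Cfg cf = best_config_at(*G, pat, a, max_mm, d_seed, allow_gap,
                            pen_mm, pen_open, pen_ext);
    if (cf.ok) { pos.push_back(a); cfgs.push_back(cf); }
  }
  int n = (int)pos.size();
  IntegerVector chrom(n), mm(n), gaps(n), glen(n), gtype(n), split(n);
  NumericVector pv(n), pen(n);
  for (int i = 0; i < n; ++i) {
    int c = chrom_of(*G, pos[i]);
    chrom[i] = c + 1;
    pv[i] = double(pos[i] - G->bounds[c]);
    mm[i] = cfgs[i].mm; gaps[i] = cfgs[i].gaps; glen[i] = cfgs[i].g;
    gtype[i] = cfgs[i].type; split[i] = cfgs[i].split; pen[i] = cfgs[i].pen;
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["pos"] = pv,
                           _["mismatches"] = mm, _["gaps"] = gaps,
                           _["gap_len"] = glen, _["gap_type"] = gtype,
                           _["split"] = split, _["penalty"] = pen);
}

// ---- one-gap semi-global extension ------------------------------------------
// Best alignment of the whole read against the window with at most one
// contiguous gap run (length <= d), read fully aligned, window ends free.
// Uses prefix score tables per read/window offset so each (anchor, gap) pair is
// O(len) over split points.

// [[Rcpp::export]]
List semi_global_cpp(std::string read, NumericVector mb, NumericVector mp,
                     std::string window, int d, double gap_open,
                     double gap_extend) {
  std::vector<uint8_t> R = encode_str(read), W = encode_str(window);
  int L = (int)R.size(), Wn = (int)W.size();
  if (Wn < L) stop("window shorter than read");
  if (d > Wn - 1) d = Wn - 1;
  const double NEG = -1e18;
  // offsets o in [-d, Wn - L + d]; T[o][s] = prefix score of read[0..s) with
  // read base i facing window column o+i.  Out-of-range columns contribute 0;
  // every configuration below range-checks its own span, and the 0 entries
  // cancel in the prefix differences.
  int o_lo = -d, o_hi = Wn - L + d;
  int n_off = o_hi - o_lo + 1;
  std::vector<double> T((size_t)n_off * (L + 1));
  for (int oi = 0; oi < n_off; ++oi) {
    int o = o_lo + oi;
    double* row = &T[(size_t)oi * (L + 1)];
    row[0] = 0.0;
    for (int i = 0; i < L; ++i) {
      int j = o + i;
      double col = (j < 0 || j >= Wn)
        ? 0.0 : (is_match(R[i], W[j]) ? mb[i] : -mp[i]);
      row[i + 1] = row[i] + col;
    }
  }
  const double* Tp = T.data();
  #define TT(o, s) Tp[(size_t)((o) - o_lo) * (L + 1) + (s)]
  double best = NEG;
  int bp = 0, btype = 0, bg = 0, bs = 0;
  // zero-gap
  for (int p = 0; p + L <= Wn; ++p) {
    double sc = TT(p, L);
    if (sc > best) { best = sc; bp = p; btype = 0; bg = 0; bs = 0; }
  }
  for (int g = 1; g <= d; ++g) {
    double gpen = gap_open + (g - 1) * gap_extend;
    // deletion: window skips g bases after read split s
    for (int p = 0; p + L + g <= Wn; ++p) {
      double base = TT(p + g, L);
      for (int s = 1; s <= L - 1; ++s) {
        double sc = TT(p, s) + (base - TT(p + g, s)) - gpen;
        if (sc > best) { best = sc; bp = p; btype = 1; bg = g; bs = s; }
      }
    }
    // insertion: read bases [s, s+g) unaligned (end splits allowed)
    for (int p = 0; p + L - g <= Wn; ++p) {
      if (p - g < o_lo) continue;
      double base = TT(p - g, L);
      for (int s = 0; s <= L - g; ++s) {
        double sc = TT(p, s) + (base - TT(p - g, s + g)) - gpen;
        if (sc > best) { best = sc; bp = p; btype = 2; bg = g; bs = s; }
      }
    }
  }
  #undef TT
  return List::create(_["score"] = best, _["p"] = bp, _["type"] = btype,
                      _["g"] = bg, _["split"] = bs);
}

// ---- affine local Smith-Waterman: score-only then banded traceback ----------

// [[Rcpp::export]]
List sw_score_cpp(std::string read, NumericVector mb, NumericVector mp,
                  std::string window, double gap_open, double gap_extend) {
  std::vector<uint8_t> R = encode_str(read), W = encode_str(window);
  int n = (int)R.size(), m = (int)W.size();
  const double NEG = -1e18;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG), F(m + 1, NEG);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;  // H[i-1][0]
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double up = H[j]; // H[i-1][j]
      E[j] = std::max(H[j - 1] - gap_open, E[j - 1] - gap_extend);
      F[j] = std::max(up - gap_open, F[j] - gap_extend);
      double s = is_match(R[i - 1], W[j - 1]) ? mb[i - 1] : -mp[i - 1];
      double h = std::max(0.0, std::max(diag + s, std::max(E[j], F[j])));
      diag = up;
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return List::create(_["score"] = best, _["end_read"] = bi, _["end_ref"] = bj);
}

// Banded affine local DP with pointers over [0..ei] x [0..ej], band half-width
// `band` around the diagonal through (ei, ej); traceback from (ei, ej) to the
// first zero cell.  Returns the banded score so the caller can grow the band
// until it matches the score-only pass.
// [[Rcpp::export]]
List banded_traceback_cpp(std::string read, NumericVector mb, NumericVector mp,
                          std::string window, int ei, int ej, int band,
                          double gap_open, double gap_extend) {
  std::vector<uint8_t> R = encode_str(read), W = encode_str(window);
  const double NEG = -1e18;
  int diag0 = ei - ej;
  int nr = ei + 1, nc = ej + 1;
  std::vector<double> H((size_t)nr * nc, NEG), E((size_t)nr * nc, NEG),
      F((size_t)nr * nc, NEG);
  // pointers: for H: 0 stop, 1 diag, 2 from E, 3 from F; for E/F: open vs extend
  std::vector<uint8_t> PH((size_t)nr * nc, 0), PE((size_t)nr * nc, 0),
      PF((size_t)nr * nc, 0);
  #define IX(i, j) ((size_t)(i) * nc + (j))
  for (int i = 0; i <= ei; ++i) {
    int j_lo = std::max(0, i - diag0 - band), j_hi = std::min(ej, i - diag0 + band);
    for (int j = j_lo; j <= j_hi; ++j) {
      if (i == 0 || j == 0) { H[IX(i, j)] = 0.0; continue; }
      double e = NEG, f = NEG;
      if (j - 1 >= j_lo) {
        double open = (H[IX(i, j - 1)] <= NEG / 2) ? NEG : H[IX(i, j - 1)] - gap_open;
        double ext = (E[IX(i, j - 1)] <= NEG / 2) ? NEG : E[IX(i, j - 1)] - gap_extend;
        if (open >= ext) { e = open; PE[IX(i, j)] = 0; }
        else { e = ext; PE[IX(i, j)] = 1; }
      }
      {
        int pj_lo = std::max(0, (i - 1) - diag0 - band),
            pj_hi = std::min(ej, (i - 1) - diag0 + band);
        if (j >= pj_lo && j <= pj_hi) {
          double open = (H[IX(i - 1, j)] <= NEG / 2) ? NEG : H[IX(i - 1, j)] - gap_open;
          double ext = (F[IX(i - 1, j)] <= NEG / 2) ? NEG : F[IX(i - 1, j)] - gap_extend;
          if (open >= ext) { f = open; PF[IX(i, j)] = 0; }
          else { f = ext; PF[IX(i, j)] = 1; }
        }
      }
      E[IX(i, j)] = e;
      F[IX(i, j)] = f;
      double dscore = NEG;
      {
        int pj_lo = std::max(0, (i - 1) - diag0 - band),
            pj_hi = std::min(ej, (i - 1) - diag0 + band);
        if (j - 1 >= pj_lo && j - 1 <= pj_hi && H[IX(i - 1, j - 1)] > NEG / 2) {
          double s = is_match(R[i - 1], W[j - 1]) ? mb[i - 1] : -mp[i - 1];
          dscore = H[IX(i - 1, j - 1)] + s;
        }
      }
      double h = 0.0; uint8_t ph = 0;
      if (dscore > h) { h = dscore; ph = 1; }
      if (e > h) { h = e; ph = 2; }
      if (f > h) { h = f; ph = 3; }
      H[IX(i, j)] = h;
      PH[IX(i, j)] = ph;
    }
  }
  double score = (H[IX(ei, ej)] <= NEG / 2) ? NEG : H[IX(ei, ej)];
  // traceback
  std::vector<int> lens;
  std::vector<char> ops;
  int i = ei, j = ej, state = 0; // 0 in H, 1 in E, 2 in F
  if (score > 0) {
    while (i > 0 && j > 0) {
      if (state == 0) {
        uint8_t ph = PH[IX(i, j)];
        if (ph == 0) break;
        if (ph == 1) {
          if (!ops.empty() && ops.back() == 'M') lens.back()++;
          else { ops.push_back('M'); lens.push_back(1); }
          --i; --j;
        } else if (ph == 2) state = 1;
        else state = 2;
      } else if (state == 1) { // E: gap consuming window (D)
        uint8_t pe = PE[IX(i, j)];
        if (!ops.empty() && ops.back() == 'D') lens.back()++;
        else { ops.push_back('D'); lens.push_back(1); }
        --j;
        state = (pe == 0) ? 0 : 1;
      } else { // F: gap consuming read (I)
        uint8_t pf = PF[IX(i, j)];
        if (!ops.empty() && ops.back() == 'I') lens.back()++;
        else { ops.push_back('I'); lens.push_back(1); }
        --i;
        state = (pf == 0) ? 0 : 2;
      }
    }
  }
  #undef IX
  std::reverse(lens.begin(), lens.end());
  std::reverse(ops.begin(), ops.end());
  CharacterVector opv(ops.size());
  IntegerVector lenv(lens.size());
  for (size_t t = 0; t < ops.size(); ++t) {
    opv[t] = std::string(1, ops[t]);
    lenv[t] = lens[t];
  }
  return List::create(_["score"] = (score <= NEG / 2 ? NA_REAL : score),
                      _["start_read"] = i, _["start_ref"] = j,
                      _["op"] = opv, _["len"] = lenv);
}
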