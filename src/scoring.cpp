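#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Translate a DNA string codon-by-codon using a 64-entry codon table
// (index 16*b1 + 4*b2 + b3 with A=0, C=1, G=2, T=3). Trailing 1-2 bases are
// dropped. In-frame stops come through as whatever symbol the table holds
// ('*' for the standard code); optional truncation at the first stop.
// [[Rcpp::export]]
std::string cpp_translate(const std::string& dna, const std::string& code64,
                          bool truncate_at_stop) {
  const size_t n = dna.size();
  std::string out;
  out.reserve(n / 3);
  int idx = 0, k = 0;
  for (size_t i = 0; i < n; ++i) {
    int b;
    switch (dna[i]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default:
        stop("invalid DNA character '%s' at position %d",
             std::string(1, dna[i]).c_str(), (int)(i + 1));
    }
    idx = idx * 4 + b;
    if (++k == 3) {
      char aa = code64[idx];
      if (aa == '*' && truncate_at_stop) return out;
      out.push_back(aa);
      idx = 0;
      k = 0;
    }
  }
  return out;
}

// Ends-free ("overlap") affine-gap alignment score of a protein against a
// consensus schema. Wildcard positions in the pattern ('-') cost 0 against
// any residue; required positions score `match` on identity and `mismatch`
// otherwise. A gap of length L costs open + (L-1)*ext (both passed as
// positive penalties). End gaps are free: first row/column are 0 and the
// score is the maximum over the last row and last column.
// [[Rcpp::export]]
double cpp_schema_align(const std::string& a, const std::string& b,
                        double match, double mismatch,
                        double open, double ext) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0.0;
  std::vector<double> Hprev(n + 1), Hcur(n + 1), E(n + 1);
  for (int j = 0; j <= n; ++j) { Hprev[j] = 0.0; E[j] = NEG_INF; }
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    double F = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      double e = std::max(Hprev[j] - open, E[j] - ext);
      double f = std::max(Hcur[j - 1] - open, F - ext);
      double s;
      if (b[j - 1] == '-') s = 0.0;
      else s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = std::max(Hprev[j - 1] + s, std::max(e, f));
      E[j] = e;
      F = f;
      Hcur[j] = h;
      if (i == m && h > best) best = h;
    }
    if (Hcur[n] > best) best = Hcur[n];
    std::swap(Hprev, Hcur);
  }
  return best;
}

static inline int charge_code(char c, const std::string& pos,
                              const std::string& neg) {
  if (pos.find(c) != std::string::npos) return 1;
  if (neg.find(c) != std::string::npos) return -1;
  return 0;
}

// Best ungapped sliding-window binding tally between two proteins: at each
// relative offset, +1 per aligned (positive, negative) charge pair and -1
// per repelling (same-charge) pair; returns the maximum tally over all
// offsets (may be negative; caller floors/caps/normalises).
// [[Rcpp::export]]
int cpp_binding_tally(const std::string& a, const std::string& b,
                      const std::string& positive, const std::string& negative) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> ca(m), cb(n);
  for (int i = 0; i < m; ++i) ca[i] = charge_code(a[i], positive, negative);
  for (int j = 0; j < n; ++j) cb[j] = charge_code(b[j], positive, negative);
  int best = std::numeric_limits<int>::min();
  for (int s = -(n - 1); s <= m - 1; ++s) {
    int i0 = std::max(0, s);
    int i1 = std::min(m - 1, s + n - 1);
    int tally = 0;
    for (int i = i0; i <= i1; ++i) {
      int p = ca[i] * cb[i - s];
      if (p == -1) ++tally; else if (p == 1) --tally;
    }
    if (tally > best) best = tally;
  }
  return best;
}

// Banded ends-free affine-gap alignment with traceback. The band allows
// diagonals j - i in [min(0, n-m) - w, max(0, n-m) + w]; pairs whose DP
// matrix fits inside the band are scored exactly. Rolling two-row value
// arrays; a packed traceback byte per band cell
// (bits 0-1: H source 0=diag 1=E 2=F 3=free-start; bit 2: E opened from H;
// bit 3: F opened from H). Buffers are reused across calls.
struct IdentityResult { double score; long matches; long columns; };

static IdentityResult band_identity(const std::string& a, const std::string& b,
                                    double match, double mismatch,
                                    double open, double ext, int w) {
  const int m = (int)a.size(), n = (int)b.size();
  IdentityResult res = {0.0, 0, 0};
  if (m == 0 || n == 0) return res;
  const int lo = std::min(0, n - m) - w;
  const int hi = std::max(0, n - m) + w;
  const int W = hi - lo + 1;
  static thread_local std::vector<double> Hprev_v, Hcur_v, Eprev_v, Ecur_v;
  static thread_local std::vector<unsigned char> tb_v;
  Hprev_v.resize(W + 2); Hcur_v.resize(W + 2);
  Eprev_v.resize(W + 2); Ecur_v.resize(W + 2);
  tb_v.resize((size_t)(m + 1) * W);
  // row i holds positions pos = j - (i + lo), pos in [0, W-1]; +1 shift so
  // pos -1 and W are safe sentinels
  double *Hprev = Hprev_v.data() + 1, *Hcur = Hcur_v.data() + 1;
  double *Eprev = Eprev_v.data() + 1, *Ecur = Ecur_v.data() + 1;
  unsigned char *tb = tb_v.data();
  // end-cell values collected in full, so the traceback start is chosen in a
  // fixed scan order (last row by ascending j, then last column by ascending
  // i) independent of the banded evaluation order
  std::vector<double> rowH(n + 1, NEG_INF), colH(m + 1, NEG_INF);
  {
    int jhi0 = std::min(n, hi);
    for (int j = 0; j <= jhi0; ++j) {
      Hprev[j - lo] = 0.0;
      Eprev[j - lo] = NEG_INF;
    }
    if (jhi0 == n) colH[0] = 0.0;
  }
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(0, i + lo), jhi = std::min(n, i + hi);
    if (jlo > jhi) break;
    const int off = i + lo;            // j = pos + off
    const int offp = off - 1;          // previous row offset
    unsigned char *tbrow = tb + (size_t)i * W;
    // sentinels for out-of-band neighbours
    Hcur[jlo - 1 - off] = NEG_INF;
    Ecur[jlo - 1 - off] = NEG_INF;
    const int jhi_prev = std::min(n, i - 1 + hi);
    if (jhi > jhi_prev) {              // up-neighbour of jhi is out of band
      Hprev[jhi - offp] = NEG_INF;
      Eprev[jhi - offp] = NEG_INF;
    }
    double Fleft = NEG_INF;
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int pos = j - off;
      unsigned char t;
      if (j == 0) {
        Hcur[pos] = 0.0; Ecur[pos] = NEG_INF; Fleft = NEG_INF;
        tbrow[pos] = 3;
        if (i == m) rowH[0] = 0.0;
        continue;
      }
      // E: gap in b, consuming a_i (from row above, same j -> pos + 1)
      double fromH = Hprev[pos + 1] - open, fromE = Eprev[pos + 1] - ext;
      double e; unsigned char te;
      if (fromH >= fromE) { e = fromH; te = 4; } else { e = fromE; te = 0; }
      // F: gap in a, consuming b_j (from same row, j-1 -> pos - 1)
      double fH = Hcur[pos - 1] - open, fF = Fleft - ext;
      double f; unsigned char tf;
      if (fH >= fF) { f = fH; tf = 8; } else { f = fF; tf = 0; }
      // diagonal (i-1, j-1) -> prev row, pos
      double d = Hprev[pos] + ((ai == b[j - 1]) ? match : mismatch);
      double h = d; t = 0;
      if (e > h) { h = e; t = 1; }
      if (f > h) { h = f; t = 2; }
      Hcur[pos] = h; Ecur[pos] = e; Fleft = f;
      tbrow[pos] = (unsigned char)(t | te | tf);
      if (i == m) rowH[j] = h;
      if (j == n) colH[i] = h;
    }
    std::swap(Hprev_v, Hcur_v); std::swap(Eprev_v, Ecur_v);
    Hprev = Hprev_v.data() + 1; Hcur = Hcur_v.data() + 1;
    Eprev = Eprev_v.data() + 1; Ecur = Ecur_v.data() + 1;
  }
  double best = 0.0;  // the empty alignment is always available
  int bi = 0, bj = 0;
  for (int j = 0; j <= n; ++j)
    if (rowH[j] > best) { best = rowH[j]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (colH[i] > best) { best = colH[i]; bi = i; bj = n; }
  // traceback from the best cell on the last row/column
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  long matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * W + (j - i - lo)];
    if (state == 0) {
      unsigned char th = t & 3;
      if (th == 3) break;
      if (th == 0) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else state = th;
    } else if (state == 1) {
      ++columns;
      state = (t & 4) ? 0 : 1;
      --i;
    } else {
      ++columns;
      state = (t & 8) ? 0 : 2;
      --j;
    }
  }
  res.score = best; res.matches = matches; res.columns = columns;
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_align_identity(const std::string& a, const std::string& b,
                                 double match, double mismatch,
                                 double open, double ext, int w) {
  IdentityResult r = band_identity(a, b, match, mismatch, open, ext, w);
  return NumericVector::create(r.score, (double)r.matches, (double)r.columns);
}

// Pairwise identity fractions (matches / aligned columns) for all C(n,2)
// pairs of proteins, in combn order (1,2), (1,3), ..., (n-1,n). Two empty
// strings are identical (1); empty vs non-empty scores 0; a zero-column
// optimal alignment scores 0.
// [[Rcpp::export]]
NumericVector cpp_pairwise_identity(CharacterVector proteins,
                                    double match, double mismatch,
                                    double open, double ext, int w) {
  const int n = proteins.size();
  std::vector<std::string> ps(n);
  for (int i = 0; i < n; ++i) ps[i] = as<std::string>(proteins[i]);
  NumericVector out(n * (n - 1) / 2);
  int k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      if (ps[i] == ps[j]) { out[k] = 1.0; continue; }  // clonal fast path
      if (ps[i].empty() || ps[j].empty()) { out[k] = 0.0; continue; }
      IdentityResult r = band_identity(ps[i], ps[j], match, mismatch,
                                       open, ext, w);
      out[k] = (r.columns == 0) ? 0.0 : (double)r.matches / (double)r.columns;
    }
  }
  return out;
}
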