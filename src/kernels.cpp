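#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Residue codes: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches, so N scores as a mismatch in alignment scoring.
static inline uint8_t enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> encode_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static inline int subst(uint8_t a, uint8_t b, int match, int mismatch) {
  return (a < 4 && b < 4 && a == b) ? match : mismatch;
}

static const double NEG = -1e15;

// ---------------------------------------------------------------------------
// Global pairwise alignment (Gotoh, affine gaps).
// A gap of length k costs gap_open + k * gap_ext (both negative).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1,
                  double gap_open = -4.0, double gap_ext = -1.0) {
  std::vector<uint8_t> ea = encode_seq(a), eb = encode_seq(b);
  int m = ea.size(), n = eb.size();
  size_t W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) X[i * W] = gap_open + i * gap_ext;
  for (int j = 1; j <= n; ++j) Y[j] = gap_open + j * gap_ext;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double hprev = std::max(M[(i - 1) * W + (j - 1)],
                     std::max(X[(i - 1) * W + (j - 1)], Y[(i - 1) * W + (j - 1)]));
      M[i * W + j] = hprev + subst(ea[i - 1], eb[j - 1], match, mismatch);
      double hup = std::max(M[(i - 1) * W + j], Y[(i - 1) * W + j]);
      X[i * W + j] = std::max(hup + gap_open + gap_ext, X[(i - 1) * W + j] + gap_ext);
      double hleft = std::max(M[i * W + (j - 1)], X[i * W + (j - 1)]);
      Y[i * W + j] = std::max(hleft + gap_open + gap_ext, Y[i * W + (j - 1)] + gap_ext);
    }
  }
  double sM = M[m * W + n], sX = X[m * W + n], sY = Y[m * W + n];
  double score = std::max(sM, std::max(sX, sY));
  // traceback; deterministic priority M > X > Y on ties
  std::string ra, rb;
  int i = m, j = n;
  int state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 1 : 2);
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double hprev = M[i * W + j] - subst(ea[i - 1], eb[j - 1], match, mismatch);
      --i; --j;
      if (std::abs(M[i * W + j] - hprev) < 1e-9) state = 0;
      else if (std::abs(X[i * W + j] - hprev) < 1e-9) state = 1;
      else state = 2;
    } else if ((state == 1 && i > 0) || j == 0) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      double cur = X[i * W + j];
      --i;
      if (i >= 0 && std::abs(X[i * W + j] + gap_ext - cur) < 1e-9) state = 1;
      else if (std::abs(M[i * W + j] + gap_open + gap_ext - cur) < 1e-9) state = 0;
      else state = 2;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double cur = Y[i * W + j];
      --j;
      if (j >= 0 && std::abs(Y[i * W + j] + gap_ext - cur) < 1e-9) state = 2;
      else if (std::abs(M[i * W + j] + gap_open + gap_ext - cur) < 1e-9) state = 0;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}

// ---------------------------------------------------------------------------
// Align one ungapped sequence onto an existing gapped profile (set of rows).
// Column score against a base = sum of substitution scores over non-gap
// residues in that column, divided by the number of rows; gap penalties are
// the plain affine ones. Returns the rows with any new all-gap columns
// inserted plus the aligned new sequence.
// [[Rcpp::export]]
List profile_align_cpp(CharacterVector rows, std::string seq,
                       int match = 1, int mismatch = -1,
                       double gap_open = -4.0, double gap_ext = -1.0) {
  int R = rows.size();
  std::vector<std::string> prof(R);
  for (int r = 0; r < R; ++r) prof[r] = as<std::string>(rows[r]);
  int P = prof[0].size();
  std::vector<uint8_t> es = encode_seq(seq);
  int L = es.size();
  // per-column score against each residue code 0..4
  std::vector<double> colsc(P * 5, 0.0);
  for (int j = 0; j < P; ++j) {
    for (int r = 0; r < R; ++r) {
      char c = prof[r][j];
      if (c == '-') continue;
      uint8_t e = enc(c);
      for (int x = 0; x < 5; ++x)
        colsc[j * 5 + x] += subst(e, (uint8_t)x, match, mismatch);
    }
    for (int x = 0; x < 5; ++x) colsc[j * 5 + x] /= R;
  }
  size_t W = L + 1;
  std::vector<double> M((P + 1) * W, NEG), X((P + 1) * W, NEG), Y((P + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= P; ++i) X[i * W] = gap_open + i * gap_ext;
  for (int j = 1; j <= L; ++j) Y[j] = gap_open + j * gap_ext;
  for (int i = 1; i <= P; ++i) {
    for (int j = 1; j <= L; ++j) {
      double hprev = std::max(M[(i - 1) * W + (j - 1)],
                     std::max(X[(i - 1) * W + (j - 1)], Y[(i - 1) * W + (j - 1)]));
      M[i * W + j] = hprev + colsc[(i - 1) * 5 + es[j - 1]];
      double hup = std::max(M[(i - 1) * W + j], Y[(i - 1) * W + j]);
      X[i * W + j] = std::max(hup + gap_open + gap_ext, X[(i - 1) * W + j] + gap_ext);
      double hleft = std::max(M[i * W + (j - 1)], X[i * W + (j - 1)]);
      Y[i * W + j] = std::max(hleft + gap_open + gap_ext, Y[i * W + (j - 1)] + gap_ext);
    }
  }
  double sM = M[P * W + L], sX = X[P * W + L], sY = Y[P * W + L];
  double score = std::max(sM, std::max(sX, sY));
  // traceback as ops: 0 = column+char, 1 = column+gap, 2 = all-gap column+char
  std::vector<uint8_t> ops;
  int i = P, j = L;
  int state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 1 : 2);
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      ops.push_back(0);
      double hprev = M[i * W + j] - colsc[(i - 1) * 5 + es[j - 1]];
      --i; --j;
      if (std::abs(M[i * W + j] - hprev) < 1e-9) state = 0;
      else if (std::abs(X[i * W + j] - hprev) < 1e-9) state = 1;
      else state = 2;
    } else if ((state == 1 && i > 0) || j == 0) {
      ops.push_back(1);
      double cur = X[i * W + j];
      --i;
      if (std::abs(X[i * W + j] + gap_ext - cur) < 1e-9) state = 1;
      else if (std::abs(M[i * W + j] + gap_open + gap_ext - cur) < 1e-9) state = 0;
      else state = 2;
    } else {
      ops.push_back(2);
      double cur = Y[i * W + j];
      --j;
      if (std::abs(Y[i * W + j] + gap_ext - cur) < 1e-9) state = 2;
      else if (std::abs(M[i * W + j] + gap_open + gap_ext - cur) < 1e-9) state = 0;
      else state = 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int outlen = ops.size();
  std::vector<std::string> out(R, std::string(outlen, '-'));
  std::string sal(outlen, '-');
  int pi = 0, sj = 0;
  for (int k = 0; k < outlen; ++k) {
    if (ops[k] == 0) {
      for (int r = 0; r < R; ++r) out[r][k] = prof[r][pi];
      sal[k] = seq[sj];
      ++pi; ++sj;
    } else if (ops[k] == 1) {
      for (int r = 0; r < R; ++r) out[r][k] = prof[r][pi];
      ++pi;
    } else {
      sal[k] = seq[sj];
      ++sj;
    }
  }
  CharacterVector rout(R);
  for (int r = 0; r < R; ++r) rout[r] = out[r];
  return List::create(_["rows"] = rout, _["seq"] = sal, _["score"] = score);
}

// ---------------------------------------------------------------------------
// Banded local alignment (Smith-Waterman, affine) restricted to diagonals
// d = i - j in [lo, hi] (i indexes a, j indexes b, 1-based DP cells).
struct SWResult {
  double score;
  int qstart, qend, sstart, send;  // 0-based half-open on success
  int matches, aln_len, gaps, gapopen;
};

static SWResult banded_sw(const std::vector<uint8_t> &ea,
                          const std::vector<uint8_t> &eb,
                          int lo, int hi,
                          int match, int mismatch,
                          double gap_open, double gap_ext) {
  int m = ea.size(), n = eb.size();
  int W = hi - lo + 1;
  // w index: w = j - (i - hi); diagonal neighbor (i-1,j-1) keeps w,
  // up (i-1,j) maps to w+1, left (i,j-1) maps to w-1.
  // H initialized to 0 doubles as the local-alignment boundary for any
  // never-computed (out-of-band or row/column 0) cell.
  std::vector<double> H((size_t)(m + 1) * W, 0.0),
                      E((size_t)(m + 1) * W, NEG),
                      F((size_t)(m + 1) * W, NEG);
  auto idx = [&](int i, int w) { return (size_t)i * W + w; };
  double best = 0.0; int bi = -1, bw = -1;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - hi), jhi = std::min(n, i - lo);
    for (int j = jlo; j <= jhi; ++j) {
      int w = j - (i - hi);
      double diag = H[idx(i - 1, w)];
      double e = NEG, f = NEG;
      if (w - 1 >= 0 && j - 1 >= 1)
        e = std::max(H[idx(i, w - 1)] + gap_open + gap_ext, E[idx(i, w - 1)] + gap_ext);
      if (w + 1 < W && i - 1 >= 1)
        f = std::max(H[idx(i - 1, w + 1)] + gap_open + gap_ext, F[idx(i - 1, w + 1)] + gap_ext);
      double h = diag + subst(ea[i - 1], eb[j - 1], match, mismatch);
      h = std::max(h, std::max(e, f));
      if (h < 0) h = 0;
      H[idx(i, w)] = h; E[idx(i, w)] = e; F[idx(i, w)] = f;
      if (h > best) { best = h; bi = i; bw = w; }
    }
  }
  SWResult r; r.score = best;
  r.qstart = r.qend = r.sstart = r.send = 0;
  r.matches = r.aln_len = r.gaps = r.gapopen = 0;
  if (best <= 0) { r.score = 0; return r; }
  int i = bi, w = bw;
  int j = w + (i - hi);
  r.qend = i; r.send = j;
  int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  bool ingap = false;
  while (i > 0 && j > 0) {
    if (state == 0) {
      double cur = H[idx(i, w)];
      if (cur <= 0) break;
      if (std::abs(cur - E[idx(i, w)]) < 1e-9) { state = 1; continue; }
      if (std::abs(cur - F[idx(i, w)]) < 1e-9) { state = 2; continue; }
      ++r.aln_len;
      if (ea[i - 1] < 4 && ea[i - 1] == eb[j - 1]) ++r.matches;
      ingap = false;
      --i; --j;  // same w
    } else if (state == 1) {
      double cur = E[idx(i, w)];
      ++r.aln_len; ++r.gaps;
      if (!ingap) { ++r.gapopen; ingap = true; }
      bool ext = (w - 1 >= 0) && std::abs(E[idx(i, w - 1)] + gap_ext - cur) < 1e-9;
      --j; --w;
      if (!ext) { state = 0; ingap = false; }
    } else {
      double cur = F[idx(i, w)];
      ++r.aln_len; ++r.gaps;
      if (!ingap) { ++r.gapopen; ingap = true; }
      bool ext = (w + 1 < W) && std::abs(F[idx(i - 1, w + 1)] + gap_ext - cur) < 1e-9;
      --i; ++w;
      if (!ext) { state = 0; ingap = false; }
    }
  }
  r.qstart = i; r.sstart = j;  // 0-based half-open starts
  return r;
}

// [[Rcpp::export]]
List banded_sw_cpp(std::string a, std::string b, int lo, int hi,
                   int match = 1, int mismatch = -1,
                   double gap_open = -4.0, double gap_ext = -1.0) {
  std::vector<uint8_t> ea = encode_seq(a), eb = encode_seq(b);
  SWResult r = banded_sw(ea, eb, lo, hi, match, mismatch, gap_open, gap_ext);
  return List::create(_["score"] = r.score,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["sstart"] = r.sstart, _["send"] = r.send,
                      _["matches"] = r.matches, _["aln_len"] = r.aln_len,
                      _["gaps"] = r.gaps, _["gapopen"] = r.gapopen);
}

// ---------------------------------------------------------------------------
// Seeded similarity search: shared-k-mer candidate pairs, banded local
// alignment around the modal seed diagonal, ungapped Karlin-Altschul
// E-value E = K * m * n * exp(-lambda * S).
// self_mode: qseqs == sseqs conceptually; only pairs i < j are aligned and
// both hit directions are emitted.
// [[Rcpp::export]]
DataFrame search_hits_cpp(CharacterVector qseqs, CharacterVector sseqs,
                          bool self_mode,
                          int k = 12, int band_extra = 16,
                          int match = 1, int mismatch = -1,
                          double gap_open = -4.0, double gap_ext = -1.0,
                          double K = 0.13, double lambda = 0.318,
                          double evalue_max = 1e-15, int max_kmer_occ = 100) {
  int nq = qseqs.size(), ns = sseqs.size();
  std::vector<std::vector<uint8_t>> eq(nq), es(ns);
  for (int i = 0; i < nq; ++i) eq[i] = encode_seq(as<std::string>(qseqs[i]));
  for (int i = 0; i < ns; ++i) es[i] = encode_seq(as<std::string>(sseqs[i]));
  CharacterVector qnames = qseqs.attr("names");
  CharacterVector snames = sseqs.attr("names");

  // k-mer index over subjects
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < ns; ++s) {
    const std::vector<uint8_t> &v = es[s];
    if ((int)v.size() < k) continue;
    uint64_t kmer = 0; int valid = 0;
    for (size_t p = 0; p < v.size(); ++p) {
      if (v[p] >= 4) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | v[p]) & mask;
      ++valid;
      if (valid >= k) index[kmer].push_back({s, (int)(p + 1 - k)});
    }
  }
  // candidate (pair, diagonal) tuples
  std::vector<std::pair<uint64_t, int>> cand;
  for (int q = 0; q < nq; ++q) {
    const std::vector<uint8_t> &v = eq[q];
    if ((int)v.size() < k) continue;
    uint64_t kmer = 0; int valid = 0;
    for (size_t p = 0; p < v.size(); ++p) {
      if (v[p] >= 4) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | v[p]) & mask;
      ++valid;
      if (valid < k) continue;
      auto it = index.find(kmer);
      if (it == index.end()) continue;
      if ((int)it->second.size() > max_kmer_occ) continue;
      int qpos = (int)(p + 1 - k);
      for (auto &hit : it->second) {
        int s = hit.first;
        if (self_mode && s <= q) continue;
        cand.push_back({(uint64_t)q * ns + s, qpos - hit.second});
      }
    }
  }
  std::sort(cand.begin(), cand.end());

  std::vector<std::string> out_q, out_s;
  std::vector<double> out_pident, out_score, out_bit, out_eval;
  std::vector<int> out_len, out_mm, out_go, out_qs, out_qe, out_ss, out_se;

  size_t a = 0;
  while (a < cand.size()) {
    size_t b = a;
    while (b < cand.size() && cand[b].first == cand[a].first) ++b;
    int q = (int)(cand[a].first / ns), s = (int)(cand[a].first % ns);
    // modal diagonal (ties -> smallest)
    int best_d = cand[a].second, best_c = 0;
    size_t i = a;
    while (i < b) {
      size_t j = i;
      while (j < b && cand[j].second == cand[i].second) ++j;
      int c = (int)(j - i);
      if (c > best_c) { best_c = c; best_d = cand[i].second; }
      i = j;
    }
    int lo = best_d - band_extra, hi = best_d + band_extra;
    SWResult r = banded_sw(eq[q], es[s], lo, hi, match, mismatch, gap_open, gap_ext);
    a = b;
    if (r.score <= 0) continue;
    double m = eq[q].size(), n = es[s].size();
    double ev = K * m * n * std::exp(-lambda * r.score);
    if (ev > evalue_max) continue;
    double bit = (lambda * r.score - std::log(K)) / std::log(2.0);
    double pid = r.aln_len > 0 ? 100.0 * r.matches / r.aln_len : 0.0;
    int mm = r.aln_len - r.matches - r.gaps;
    out_q.push_back(as<std::string>(qnames[q]));
    out_s.push_back(as<std::string>(snames[s]));
    out_pident.push_back(pid); out_len.push_back(r.aln_len);
    out_mm.push_back(mm); out_go.push_back(r.gapopen);
    out_qs.push_back(r.qstart); out_qe.push_back(r.qend);
    out_ss.push_back(r.sstart); out_se.push_back(r.send);
    out_score.push_back(r.score); out_bit.push_back(bit); out_eval.push_back(ev);
    if (self_mode) {
      out_q.push_back(as<std::string>(snames[s]));
      out_s.push_back(as<std::string>(qnames[q]));
      out_pident.push_back(pid); out_len.push_back(r.aln_len);
      out_mm.push_back(mm); out_go.push_back(r.gapopen);
      out_qs.push_back(r.sstart); out_qe.push_back(r.send);
      out_ss.push_back(r.qstart); out_se.push_back(r.qend);
      out_score.push_back(r.score); out_bit.push_back(bit); out_eval.push_back(ev);
    }
  }
  return DataFrame::create(
    _["query_id"] = out_q, _["subject_id"] = out_s,
    _["pident"] = out_pident, _["length"] = out_len,
    _["mismatch"] = out_mm, _["gapopen"] = out_go,
    _["qstart"] = out_qs, _["qend"] = out_qe,
    _["sstart"] = out_ss, _["send"] = out_se,
    _["score"] = out_score, _["bitscore"] = out_bit,
    _["evalue"] = out_eval,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Percent p-distance between two gapped rows: 100 * mismatches / compared,
// comparing only columns where both rows have a non-gap, non-N character.
// Returns NA-coded -1 when no column is comparable.
// [[Rcpp::export]]
double p_distance_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("rows differ in length");
  long compared = 0, diff = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint8_t x = (a[i] == '-') ? 5 : enc(a[i]);
    uint8_t y = (b[i] == '-') ? 5 : enc(b[i]);
    if (x >= 4 || y >= 4) continue;
    ++compared;
    if (x != y) ++diff;
  }
  if (compared == 0) return -1.0;
  return 100.0 * diff / compared;
}
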