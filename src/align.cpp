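// Affine-gap pairwise alignment (Gotoh) used by the read-QC and OTU
// modules, plus a shared-k-mer screen for picking the closest reference.
//
// Two modes:
//   global       - both sequences end-to-end (OTU identity computations)
//   global-local - the pattern (read) is aligned end-to-end, the subject
//                  (reference) has free ends (frame classification)
//
// Gap cost for a run of length L is gap_open + gap_ext * L.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static const double NEG = -1e18;

struct Aln {
  std::string ap, as;  // aligned pattern / subject over the used span
  double score;
  int sub_start, sub_end;  // 1-based subject coordinates of the span
};

static Aln gotoh(const std::string& a, const std::string& b,
                 double match, double mismatch,
                 double gap_open, double gap_ext, bool free_subject_ends) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: predecessor state per cell (0 = M, 1 = X, 2 = Y, 3 = start)
  std::vector<uint8_t> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  auto id = [W](int i, int j) { return i * W + j; };

  M[id(0, 0)] = 0;
  tM[id(0, 0)] = 3;
  for (int i = 1; i <= n; i++) {  // X: gap in subject (read base vs '-')
    X[id(i, 0)] = -(gap_open + gap_ext * i);
    tX[id(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; j++) {
    if (free_subject_ends) {
      M[id(0, j)] = 0;  // alignment may start anywhere in the subject
      tM[id(0, j)] = 3;
    } else {
      Y[id(0, j)] = -(gap_open + gap_ext * j);
      tY[id(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  for (int i = 1; i <= n; i++) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; j++) {
      const double s = (ai == b[j - 1]) ? match : mismatch;
      // M
      double best = M[id(i - 1, j - 1)];
      uint8_t tb = 0;
      if (X[id(i - 1, j - 1)] > best) { best = X[id(i - 1, j - 1)]; tb = 1; }
      if (Y[id(i - 1, j - 1)] > best) { best = Y[id(i - 1, j - 1)]; tb = 2; }
      M[id(i, j)] = best + s;
      tM[id(i, j)] = tb;
      // X: consume a_i, gap in b
      double xo = M[id(i - 1, j)] - (gap_open + gap_ext);
      double xe = X[id(i - 1, j)] - gap_ext;
      if (xo >= xe) { X[id(i, j)] = xo; tX[id(i, j)] = 0; }
      else          { X[id(i, j)] = xe; tX[id(i, j)] = 1; }
      // Y: consume b_j, gap in a
      double yo = M[id(i, j - 1)] - (gap_open + gap_ext);
      double ye = Y[id(i, j - 1)] - gap_ext;
      if (yo >= ye) { Y[id(i, j)] = yo; tY[id(i, j)] = 0; }
      else          { Y[id(i, j)] = ye; tY[id(i, j)] = 2; }
    }
  }

  // choose the end cell
  int ei = n, ej = m;
  uint8_t est = 0;
  double best = NEG;
  if (free_subject_ends) {
    for (int j = 0; j <= m; j++) {
      if (M[id(n, j)] > best) { best = M[id(n, j)]; ej = j; est = 0; }
      if (X[id(n, j)] > best) { best = X[id(n, j)]; ej = j; est = 1; }
    }
  } else {
    best = M[id(n, m)]; est = 0;
    if (X[id(n, m)] > best) { best = X[id(n, m)]; est = 1; }
    if (Y[id(n, m)] > best) { best = Y[id(n, m)]; est = 2; }
  }

  // traceback
  std::string ap, as;
  int i = ei, j = ej;
  uint8_t st = est;
  while (true) {
    if (st == 0) {
      uint8_t prev = tM[id(i, j)];
      if (prev == 3 && i == 0) break;  // start cell
      ap.push_back(a[i - 1]);
      as.push_back(b[j - 1]);
      i--; j--;
      st = prev;
    } else if (st == 1) {
      uint8_t prev = tX[id(i, j)];
      ap.push_back(a[i - 1]);
      as.push_back('-');
      i--;
      st = prev;
    } else {
      uint8_t prev = tY[id(i, j)];
      ap.push_back('-');
      as.push_back(b[j - 1]);
      j--;
      st = prev;
    }
  }
  std::reverse(ap.begin(), ap.end());
  std::reverse(as.begin(), as.end());
  Aln out;
  out.ap = ap;
  out.as = as;
  out.score = best;
  out.sub_start = j + 1;
  out.sub_end = ej;
  return out;
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_ext,
                     bool free_subject_ends) {
  const int n = reads.size();
  CharacterVector ap(n), asub(n);
  NumericVector score(n);
  IntegerVector sub_start(n), sub_end(n);
  for (int k = 0; k < n; k++) {
    Aln r = gotoh(as<std::string>(reads[k]), ref, match, mismatch,
                  gap_open, gap_ext, free_subject_ends);
    ap[k] = r.ap;
    asub[k] = r.as;
    score[k] = r.score;
    sub_start[k] = r.sub_start;
    sub_end[k] = r.sub_end;
  }
  return List::create(_["pattern"] = ap, _["subject"] = asub,
                      _["score"] = score, _["subject_start"] = sub_start,
                      _["subject_end"] = sub_end);
}

static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; i++) {
    int code;
    switch (s[pos + i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: return false;  // ambiguous base: skip this k-mer
    }
    v = (v << 2) | code;
  }
  out = v;
  return true;
}

// For each read, the index (1-based) of the reference sharing the most
// k-mers; ties go to the lowest index.
// [[Rcpp::export(name = ".cpp_best_ref_kmer")]]
IntegerVector cpp_best_ref_kmer(CharacterVector reads, CharacterVector refs,
                                int k) {
  const int nr = refs.size();
  std::vector<std::unordered_set<uint64_t>> sets(nr);
  for (int r = 0; r < nr; r++) {
    std::string s = as<std::string>(refs[r]);
    for (int p = 0; p + k <= (int)s.size(); p++) {
      uint64_t v;
      if (encode_kmer(s, p, k, v)) sets[r].insert(v);
    }
  }
  const int n = reads.size();
  IntegerVector out(n);
  std::vector<int> cnt(nr);
  for (int q = 0; q < n; q++) {
    std::string s = as<std::string>(reads[q]);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int p = 0; p + k <= (int)s.size(); p++) {
      uint64_t v;
      if (!encode_kmer(s, p, k, v)) continue;
      for (int r = 0; r < nr; r++)
        if (sets[r].count(v)) cnt[r]++;
    }
    int bi = 0;
    for (int r = 1; r < nr; r++)
      if (cnt[r] > cnt[bi]) bi = r;
    out[q] = bi + 1;
  }
  return out;
}
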