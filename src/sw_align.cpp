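#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment.
//
// Gap cost convention: a gap of length k costs gap_open + k * gap_extend
// (so a length-1 gap costs gap_open + gap_extend).
//
// Tie-breaks, for determinism: the reported cell is the first maximum in
// row-major scan order (earliest query end, then earliest subject end);
// traceback prefers diagonal over up (gap in subject) over left (gap in
// query).
//
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s, IntegerMatrix sub,
                  std::string alphabet, int gap_open, int gap_extend) {
  const int NEG = -1000000000;
  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    lut[(unsigned char)alphabet[k]] = (int)k;

  const int m = (int)q.size(), n = (int)s.size();
  std::vector<int> qi(m), si(n);
  for (int i = 0; i < m; ++i) {
    int v = lut[(unsigned char)q[i]];
    if (v < 0)
      stop("query residue '%s' at position %d is not in the scoring alphabet",
           std::string(1, q[i]).c_str(), i + 1);
    qi[i] = v;
  }
  for (int j = 0; j < n; ++j) {
    int v = lut[(unsigned char)s[j]];
    if (v < 0)
      stop("subject residue '%s' at position %d is not in the scoring alphabet",
           std::string(1, s[j]).c_str(), j + 1);
    si[j] = v;
  }

  const size_t sz = (size_t)(m + 1) * (size_t)(n + 1);
  std::vector<int> H(sz, 0), E(sz, NEG), F(sz, NEG);
  // E: alignment ending with a gap in the subject (consumes query, "up")
  // F: alignment ending with a gap in the query   (consumes subject, "left")
  auto at = [n](int i, int j) { return (size_t)i * (size_t)(n + 1) + (size_t)j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i - 1, j)] - (gap_open + gap_extend),
                       E[at(i - 1, j)] - gap_extend);
      int f = std::max(H[at(i, j - 1)] - (gap_open + gap_extend),
                       F[at(i, j - 1)] - gap_extend);
      int d = H[at(i - 1, j - 1)] + sub(qi[i - 1], si[j - 1]);
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best == 0)
    return List::create(_["score"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);

  // traceback for the aligned spans
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int d = H[at(i - 1, j - 1)] + sub(qi[i - 1], si[j - 1]);
      if (h == d) { --i; --j; if (H[at(i, j)] == 0) break; }
      else if (h == E[at(i, j)]) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (E[at(i, j)] == H[at(i - 1, j)] - (gap_open + gap_extend)) {
        --i; state = 0;
        if (H[at(i, j)] == 0) break;
      } else { --i; }
    } else {
      if (F[at(i, j)] == H[at(i, j - 1)] - (gap_open + gap_extend)) {
        --j; state = 0;
        if (H[at(i, j)] == 0) break;
      } else { --j; }
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj);
}

// Best local alignment of one query against a set of subject peptides
// (e.g. the six-frame segments of one nucleotide subject). Returns the
// first subject attaining the maximal score, with its spans.
//
// [[Rcpp::export]]
List sw_best_cpp(std::string q, std::vector<std::string> subjects,
                 IntegerMatrix sub, std::string alphabet, int gap_open,
                 int gap_extend) {
  int best_score = -1, best_idx = -1;
  List best;
  for (size_t k = 0; k < subjects.size(); ++k) {
    List a = sw_align_cpp(q, subjects[k], sub, alphabet, gap_open,
                          gap_extend);
    int sc = as<int>(a["score"]);
    if (sc > best_score) {
      best_score = sc;
      best_idx = (int)k;
      best = a;
    }
  }
  if (best_idx < 0)
    return List::create(_["score"] = 0, _["index"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  return List::create(_["score"] = best_score, _["index"] = best_idx + 1,
                      _["q_start"] = best["q_start"],
                      _["q_end"] = best["q_end"],
                      _["s_start"] = best["s_start"],
                      _["s_end"] = best["s_end"]);
}
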