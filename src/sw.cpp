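#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_ext.
// Traceback ties prefer diagonal, then up (gap in subject), then left.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  NumericMatrix scores, CharacterVector alphabet,
                  double gap_open, double gap_ext) {
  const int n = query.size(), m = subject.size();
  // residue -> index lookup
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char) as<std::string>(alphabet[i])[0]] = i;
  for (int i = 0; i < n; ++i)
    if (lut[(unsigned char) query[i]] < 0)
      stop("unknown residue in query");
  for (int j = 0; j < m; ++j)
    if (lut[(unsigned char) subject[j]] < 0)
      stop("unknown residue in subject");

  const double NEG = -1e18, gi = gap_open + gap_ext;
  std::vector<double> H((n + 1) * (m + 1), 0.0), E(H), F(H);
  for (size_t k = 0; k < E.size(); ++k) { E[k] = NEG; F[k] = NEG; }
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = lut[(unsigned char) query[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int sj = lut[(unsigned char) subject[j - 1]];
      const double e = std::max(H[at(i, j - 1)] - gi, E[at(i, j - 1)] - gap_ext);
      const double f = std::max(H[at(i - 1, j)] - gi, F[at(i - 1, j)] - gap_ext);
      const double d = H[at(i - 1, j - 1)] + scores(qi, sj);
      double h = d;
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      E[at(i, j)] = e; F[at(i, j)] = f; H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in H state until a zero cell
  int i = bi, j = bj, matches = 0, cols = 0, qlen = 0, slen = 0;
  std::string state = "H";
  int qe = bi, se = bj;  // 1-based inclusive ends
  while (i > 0 && j > 0) {
    if (state == "H") {
      double h = H[at(i, j)];
      if (h <= 0) break;
      const int qi = lut[(unsigned char) query[i - 1]];
      const int sj = lut[(unsigned char) subject[j - 1]];
      const double d = H[at(i - 1, j - 1)] + scores(qi, sj);
      if (h == d) {
        ++cols; ++qlen; ++slen;
        if (query[i - 1] == subject[j - 1]) ++matches;
        --i; --j;
      } else if (h == F[at(i, j)]) {
        state = "F";
      } else if (h == E[at(i, j)]) {
        state = "E";
      } else {
        break;  // opened at 0 (shouldn't happen for best > 0)
      }
    } else if (state == "F") {  // gap in subject, consume query char
      ++cols; ++qlen;
      const double f = F[at(i, j)];
      --i;
      if (f == H[at(i, j)] - gi) state = "H";
      // else stay in F (extension)
    } else {  // E: gap in query, consume subject char
      ++cols; ++slen;
      const double e = E[at(i, j)];
      --j;
      if (e == H[at(i, j)] - gi) state = "H";
    }
  }
  if (state == "H" && i >= 0 && j >= 0 && H[at(i, j)] > 0 && (i == 0 || j == 0)) {
    // cannot extend past border; alignment ends here
  }
  const int qs = i + 1, ss = j + 1;  // 1-based starts
  double identity = cols > 0 ? 100.0 * matches / cols : 0.0;
  return List::create(
    _["score"] = best, _["identity"] = identity,
    _["matches"] = matches, _["aligned_cols"] = cols,
    _["query_start"] = best > 0 ? qs : NA_INTEGER,
    _["query_end"] = best > 0 ? qe : NA_INTEGER,
    _["subject_start"] = best > 0 ? ss : NA_INTEGER,
    _["subject_end"] = best > 0 ? se : NA_INTEGER,
    _["query_span"] = best > 0 ? qlen : 0,
    _["subject_span"] = best > 0 ? slen : 0);
}
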