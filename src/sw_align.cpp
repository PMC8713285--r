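#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
//
// Scoring: substitution matrix lookup for matches/mismatches; a gap of
// length k costs gap_open + k * gap_ext (NCBI convention: opening a gap
// costs open + ext for its first position).
//
// Deterministic traceback: on ties the move preference is diagonal > up
// (gap in subject, consume query) > left (gap in query, consume subject).
// Among tied maximal end cells the alignment with the smallest subject
// start wins, then the smallest query start.
//
// q, s are 0-based integer encodings into the rows/cols of submat.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix submat,
                  double gap_open, double gap_ext) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e18;
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["q_gapped"] = IntegerVector(0),
                        _["s_gapped"] = IntegerVector(0));
  }
  // H: best ending in (i,j) match/mismatch or any; E: gap in query (left),
  // F: gap in subject (up). Store full matrices for traceback.
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - (gap_open + gap_ext),
                         E(i, j - 1) - gap_ext);
      F(i, j) = std::max(H(i - 1, j) - (gap_open + gap_ext),
                         F(i - 1, j) - gap_ext);
      double diag = H(i - 1, j - 1) + submat(q[i - 1], s[j - 1]);
      double h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      if (h < 0.0) h = 0.0;
      H(i, j) = h;
      if (h > best) best = h;
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["q_gapped"] = IntegerVector(0),
                        _["s_gapped"] = IntegerVector(0));
  }
  // candidate end cells with the maximal score
  std::vector<std::pair<int,int> > ends;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      if (H(i, j) == best) ends.push_back(std::make_pair(i, j));

  std::vector<int> best_qg, best_sg;
  int best_qs = -1, best_ss = -1, best_qe = -1, best_se = -1;
  for (size_t k = 0; k < ends.size(); ++k) {
    int i = ends[k].first, j = ends[k].second;
    std::vector<int> qg, sg;  // reversed; -1 encodes a gap
    int state = 0;            // 0 = H, 1 = E (left), 2 = F (up)
    while (i > 0 && j > 0) {
      if (state == 0) {
        if (H(i, j) == 0.0) break;
        double diag = H(i - 1, j - 1) + submat(q[i - 1], s[j - 1]);
        if (H(i, j) == diag) {
          qg.push_back(q[i - 1]); sg.push_back(s[j - 1]); --i; --j;
        } else if (H(i, j) == F(i, j)) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 2) {  // up: consume query, gap in subject
        qg.push_back(q[i - 1]); sg.push_back(-1);
        if (F(i, j) == H(i - 1, j) - (gap_open + gap_ext)) { --i; state = 0; }
        else { --i; state = 2; }
      } else {                  // left: consume subject, gap in query
        qg.push_back(-1); sg.push_back(s[j - 1]);
        if (E(i, j) == H(i, j - 1) - (gap_open + gap_ext)) { --j; state = 0; }
        else { --j; state = 1; }
      }
    }
    int qs = i, ss = j;  // 0-based starts
    if (best_qs < 0 || ss < best_ss || (ss == best_ss && qs < best_qs)) {
      best_qs = qs; best_ss = ss;
      best_qe = ends[k].first; best_se = ends[k].second;
      best_qg.assign(qg.rbegin(), qg.rend());
      best_sg.assign(sg.rbegin(), sg.rend());
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = best_qs, _["q_end"] = best_qe,
                      _["s_start"] = best_ss, _["s_end"] = best_se,
                      _["q_gapped"] = IntegerVector(best_qg.begin(), best_qg.end()),
                      _["s_gapped"] = IntegerVector(best_sg.begin(), best_sg.end()));
}
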