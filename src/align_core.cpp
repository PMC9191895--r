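#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming kernels shared by the pairwise aligner,
// the profile search and the progressive MSA.  Gap convention: opening a
// gap costs `gap_open` (this pays for the first gapped residue), every
// further gapped residue costs `gap_ext`.  Both are negative.

static const double NEG_INF = -1e30;

// Local (Smith-Waterman) alignment of two integer-encoded sequences.
// a, b: 1-based residue codes indexing into the substitution matrix S.
// Traceback tie order: diagonal > up (gap in b) > left (gap in a), and the
// best cell is the first maximal M cell in row-major order, so the result
// is fully deterministic.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_ext) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["a_path"] = IntegerVector(0),
                        _["b_path"] = IntegerVector(0));
  }
  // DP matrices, (n+1) x (m+1), row-major vectors.
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF); // gap in b, move up
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF); // gap in a, move left
  // traceback codes per matrix: 0 = restart/none, 1 = from M, 2 = from Ix,
  // 3 = from Iy
  std::vector<signed char> tbM((n + 1) * (m + 1), 0);
  std::vector<signed char> tbX((n + 1) * (m + 1), 0);
  std::vector<signed char> tbY((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      int diag = (i - 1) * (m + 1) + (j - 1);

      double openx = M[up] + gap_open, extx = Ix[up] + gap_ext;
      if (openx >= extx) { Ix[idx] = openx; tbX[idx] = 1; }
      else               { Ix[idx] = extx;  tbX[idx] = 2; }

      double openy = M[left] + gap_open, exty = Iy[left] + gap_ext;
      if (openy >= exty) { Iy[idx] = openy; tbY[idx] = 1; }
      else               { Iy[idx] = exty;  tbY[idx] = 3; }

      double s = S(a[i - 1] - 1, b[j - 1] - 1);
      double prev = M[diag]; signed char code = 1;
      if (Ix[diag] > prev) { prev = Ix[diag]; code = 2; }
      if (Iy[diag] > prev) { prev = Iy[diag]; code = 3; }
      double val;
      if (prev > 0.0) { val = prev + s; }
      else { val = s; code = 0; } // local restart at this cell
      if (val < 0.0) { val = 0.0; code = 0; }
      M[idx] = val; tbM[idx] = code;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["a_path"] = IntegerVector(0),
                        _["b_path"] = IntegerVector(0));
  }
  // traceback from (bi, bj) in M
  std::vector<int> pa, pb;
  int i = bi, j = bj, state = 1; // 1=M, 2=Ix, 3=Iy
  while (i > 0 && j > 0) {
    int idx = i * (m + 1) + j;
    if (state == 1) {
      signed char code = tbM[idx];
      pa.push_back(i); pb.push_back(j);
      --i; --j;
      if (code == 0) break;
      state = code;
    } else if (state == 2) {
      signed char code = tbX[idx];
      pa.push_back(i); pb.push_back(0);
      --i;
      state = code;
    } else {
      signed char code = tbY[idx];
      pa.push_back(0); pb.push_back(j);
      --j;
      state = code;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  int a_start = 0, b_start = 0;
  for (size_t k = 0; k < pa.size(); ++k) { if (pa[k] > 0) { a_start = pa[k]; break; } }
  for (size_t k = 0; k < pb.size(); ++k) { if (pb[k] > 0) { b_start = pb[k]; break; } }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = bi, _["b_start"] = b_start,
                      _["b_end"] = bj,
                      _["a_path"] = wrap(pa), _["b_path"] = wrap(pb));
}

// Best local alignment of a position profile against an integer-encoded
// sequence.  prof is L x K (columns = residue codes); profile rows may be
// deleted (gap in target, cost affine) and target residues inserted.
// Returns score and the 1-based target range of the best alignment.
// [[Rcpp::export]]
List sw_profile_cpp(NumericMatrix prof, IntegerVector t,
                    double gap_open, double gap_ext) {
  int n = prof.nrow(), m = t.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["p_start"] = 0, _["p_end"] = -1,
                        _["t_start"] = 0, _["t_end"] = -1);
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  // start bookkeeping: origin cell (i0*(m+1)+j0) of each local path
  std::vector<int> SM((n + 1) * (m + 1), 0);
  std::vector<int> SX((n + 1) * (m + 1), 0);
  std::vector<int> SY((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      int diag = (i - 1) * (m + 1) + (j - 1);
      double openx = M[up] + gap_open, extx = Ix[up] + gap_ext;
      if (openx >= extx) { Ix[idx] = openx; SX[idx] = SM[up]; }
      else               { Ix[idx] = extx;  SX[idx] = SX[up]; }
      double openy = M[left] + gap_open, exty = Iy[left] + gap_ext;
      if (openy >= exty) { Iy[idx] = openy; SY[idx] = SM[left]; }
      else               { Iy[idx] = exty;  SY[idx] = SY[left]; }
      double s = prof(i - 1, t[j - 1] - 1);
      double prev = M[diag]; int src = SM[diag];
      if (Ix[diag] > prev) { prev = Ix[diag]; src = SX[diag]; }
      if (Iy[diag] > prev) { prev = Iy[diag]; src = SY[diag]; }
      double val;
      if (prev > 0.0) { val = prev + s; }
      else { val = s; src = diag; }
      if (val < 0.0) { val = 0.0; src = idx; }
      M[idx] = val; SM[idx] = src;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["p_start"] = 0, _["p_end"] = -1,
                        _["t_start"] = 0, _["t_end"] = -1);
  int origin = SM[bi * (m + 1) + bj];
  int oi = origin / (m + 1), oj = origin % (m + 1);
  return List::create(_["score"] = best, _["p_start"] = oi + 1,
                      _["p_end"] = bi, _["t_start"] = oj + 1,
                      _["t_end"] = bj);
}

// Global (Needleman-Wunsch) affine alignment on a precomputed column-score
// matrix S (n x m), used for profile-profile merging in the progressive
// MSA.  Returns the aligned column paths (0 = gap).
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tbM((n + 1) * (m + 1), 0);
  std::vector<signed char> tbX((n + 1) * (m + 1), 0);
  std::vector<signed char> tbY((n + 1) * (m + 1), 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int idx = i * (m + 1);
    Ix[idx] = gap_open + (i - 1) * gap_ext;
    tbX[idx] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = gap_open + (j - 1) * gap_ext;
    tbY[j] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      int diag = (i - 1) * (m + 1) + (j - 1);
      double openx = M[up] + gap_open, extx = Ix[up] + gap_ext;
      if (openx >= extx) { Ix[idx] = openx; tbX[idx] = 1; }
      else               { Ix[idx] = extx;  tbX[idx] = 2; }
      double openy = M[left] + gap_open, exty = Iy[left] + gap_ext;
      if (openy >= exty) { Iy[idx] = openy; tbY[idx] = 1; }
      else               { Iy[idx] = exty;  tbY[idx] = 3; }
      double s = S(i - 1, j - 1);
      double v = M[diag]; signed char code = 1;
      if (Ix[diag] > v) { v = Ix[diag]; code = 2; }
      if (Iy[diag] > v) { v = Iy[diag]; code = 3; }
      M[idx] = v + s; tbM[idx] = code;
    }
  }
  int end = n * (m + 1) + m;
  int state = 1;
  double bestEnd = M[end];
  if (Ix[end] > bestEnd) { bestEnd = Ix[end]; state = 2; }
  if (Iy[end] > bestEnd) { bestEnd = Iy[end]; state = 3; }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int idx = i * (m + 1) + j;
    if (state == 1) {
      signed char code = tbM[idx];
      pa.push_back(i); pb.push_back(j); --i; --j;
      state = code;
    } else if (state == 2) {
      signed char code = tbX[idx];
      pa.push_back(i); pb.push_back(0); --i;
      state = code;
    } else {
      signed char code = tbY[idx];
      pa.push_back(0); pb.push_back(j); --j;
      state = code;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = bestEnd,
                      _["a_path"] = wrap(pa), _["b_path"] = wrap(pb));
}
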