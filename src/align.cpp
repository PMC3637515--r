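#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of an integer-coded amino-acid query
// against an L x 20 position-specific score matrix, affine gaps.
//
// Query codes are 0-based indices into the profile's residue columns;
// code 20 denotes 'X' (unknown) and scores a flat -1 everywhere.
//
// Gap cost convention: the first column of a gap costs `gap_open`,
// each further column `gap_extend` (a length-k gap costs
// gap_open + (k-1) * gap_extend).
//
// Three-state DP:
//   M(i,j)  ends with query[i] matched to profile column j
//   Ix(i,j) ends with query[i] opposite a gap (consumes query)
//   Iy(i,j) ends with profile column j opposite a gap (consumes profile)
// Local: M may restart at 0; optimal local alignments begin and end in M.

static const double NEG_INF = -1e30;

static inline double subst_score(const NumericMatrix &pssm, int j, int code) {
  if (code >= 20)
    return -1.0; // X
  return pssm(j, code);
}

// [[Rcpp::export(name = ".sw_pssm_align")]]
List sw_pssm_align(IntegerVector query, NumericMatrix pssm, double gap_open,
                   double gap_extend, bool traceback) {
  const int n = query.size();
  const int L = pssm.nrow();
  if (pssm.ncol() != 20)
    stop("profile score matrix must have 20 columns");
  if (n < 1 || L < 1)
    stop("empty query or profile");

  NumericMatrix M(n + 1, L + 1), Ix(n + 1, L + 1), Iy(n + 1, L + 1);
  for (int j = 0; j <= L; ++j) {
    M(0, j) = 0.0;
    Ix(0, j) = NEG_INF;
    Iy(0, j) = NEG_INF;
  }
  for (int i = 0; i <= n; ++i) {
    M(i, 0) = 0.0;
    Ix(i, 0) = NEG_INF;
    Iy(i, 0) = NEG_INF;
  }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int code = query[i - 1];
    for (int j = 1; j <= L; ++j) {
      // gap states (never floored; local optima end in M)
      double ix = std::max(M(i - 1, j) - gap_open, Ix(i - 1, j) - gap_extend);
      double iy = std::max(M(i, j - 1) - gap_open, Iy(i, j - 1) - gap_extend);
      Ix(i, j) = ix;
      Iy(i, j) = iy;
      double prev = M(i - 1, j - 1);
      if (Ix(i - 1, j - 1) > prev)
        prev = Ix(i - 1, j - 1);
      if (Iy(i - 1, j - 1) > prev)
        prev = Iy(i - 1, j - 1);
      if (prev < 0.0)
        prev = 0.0;
      double m = prev + subst_score(pssm, j - 1, code);
      if (m < 0.0)
        m = 0.0;
      M(i, j) = m;
      // first best cell in row-major order is kept (deterministic)
      if (m > best + 1e-12) {
        best = m;
        bi = i;
        bj = j;
      }
    }
  }

  List out = List::create(Named("score") = best);
  if (!traceback || best <= 0.0) {
    out["qpos"] = IntegerVector(0);
    out["ppos"] = IntegerVector(0);
    return out;
  }

  // Traceback from (bi, bj) in state M. Preference order on ties:
  // stop (shortest alignment), then M (diagonal), then Ix, then Iy.
  std::vector<int> qpos, ppos;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
  const double eps = 1e-9;
  while (true) {
    if (state == 0) {
      qpos.push_back(i);
      ppos.push_back(j);
      double m = M(i, j);
      double s = subst_score(pssm, j - 1, query[i - 1]);
      double rem = m - s; // score of the prefix ending at (i-1, j-1)
      if (rem <= eps)
        break; // local start
      if (std::abs(M(i - 1, j - 1) - rem) <= eps)
        state = 0;
      else if (std::abs(Ix(i - 1, j - 1) - rem) <= eps)
        state = 1;
      else
        state = 2;
      --i;
      --j;
    } else if (state == 1) {
      qpos.push_back(i);
      ppos.push_back(0); // gap in profile
      double v = Ix(i, j);
      if (std::abs(M(i - 1, j) - gap_open - v) <= eps)
        state = 0;
      else
        state = 1;
      --i;
    } else {
      qpos.push_back(0); // gap in query
      ppos.push_back(j);
      double v = Iy(i, j);
      if (std::abs(M(i, j - 1) - gap_open - v) <= eps)
        state = 0;
      else
        state = 2;
      --j;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(ppos.begin(), ppos.end());
  out["qpos"] = wrap(qpos);
  out["ppos"] = wrap(ppos);
  return out;
}

// Score-only batch variant: maximal local alignment score of each of a list
// of integer-coded sequences against the same profile. Rolling rows keep
// memory at O(L).
// [[Rcpp::export(name = ".sw_pssm_scores")]]
NumericVector sw_pssm_scores(List queries, NumericMatrix pssm, double gap_open,
                             double gap_extend) {
  const int nq = queries.size();
  const int L = pssm.nrow();
  if (pssm.ncol() != 20)
    stop("profile score matrix must have 20 columns");
  NumericVector out(nq);
  std::vector<double> Mprev(L + 1), Mcur(L + 1), Ixprev(L + 1), Ixcur(L + 1),
      Iyprev(L + 1), Iycur(L + 1);
  for (int q = 0; q < nq; ++q) {
    IntegerVector query = queries[q];
    const int n = query.size();
    double best = 0.0;
    std::fill(Mprev.begin(), Mprev.end(), 0.0);
    std::fill(Ixprev.begin(), Ixprev.end(), NEG_INF);
    std::fill(Iyprev.begin(), Iyprev.end(), NEG_INF);
    for (int i = 1; i <= n; ++i) {
      const int code = query[i - 1];
      Mcur[0] = 0.0;
      Ixcur[0] = NEG_INF;
      Iycur[0] = NEG_INF;
      for (int j = 1; j <= L; ++j) {
        Ixcur[j] = std::max(Mprev[j] - gap_open, Ixprev[j] - gap_extend);
        Iycur[j] = std::max(Mcur[j - 1] - gap_open, Iycur[j - 1] - gap_extend);
        double prev = Mprev[j - 1];
        if (Ixprev[j - 1] > prev)
          prev = Ixprev[j - 1];
        if (Iyprev[j - 1] > prev)
          prev = Iyprev[j - 1];
        if (prev < 0.0)
          prev = 0.0;
        double m = prev + subst_score(pssm, j - 1, code);
        if (m < 0.0)
          m = 0.0;
        Mcur[j] = m;
        if (m > best)
          best = m;
      }
      std::swap(Mprev, Mcur);
      std::swap(Ixprev, Ixcur);
      std::swap(Iyprev, Iycur);
    }
    out[q] = best;
  }
  return out;
}
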