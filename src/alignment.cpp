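#include <Rcpp.h>
#include <climits>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap convention follows BLAST: a gap of length k costs
// gap_open + k * gap_extend, so the first gap column costs go + ge.

// Score-only Smith-Waterman over a batch of sequence pairs.
// seqs: list of 0-based integer residue encodings; pi/pj: 0-based indices.
// [[Rcpp::export(name = ".sw_score_pairs")]]
NumericVector sw_score_pairs(List seqs, IntegerVector pi, IntegerVector pj,
                             IntegerMatrix submat, double gap_open,
                             double gap_extend) {
  const int npairs = pi.size();
  if (pj.size() != npairs) stop("pair index vectors differ in length");
  const int nseq = seqs.size();
  std::vector< std::vector<int> > enc(nseq);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector v = seqs[s];
    enc[s].assign(v.begin(), v.end());
  }
  const int A = submat.nrow();
  std::vector<int> S((size_t)A * A);
  for (int x = 0; x < A; ++x)
    for (int y = 0; y < A; ++y) S[(size_t)x * A + y] = submat(x, y);
  const int go = (int)gap_open, ge = (int)gap_extend;
  const int goe = go + ge;
  const int NEG = INT_MIN / 4;
  NumericVector out(npairs);
  std::vector<int> H, Fv;
  for (int p = 0; p < npairs; ++p) {
    const std::vector<int>& a = enc[pi[p]];
    const std::vector<int>& b = enc[pj[p]];
    const int n = (int)a.size(), m = (int)b.size();
    const int* bp = b.data();
    H.assign(m + 1, 0);
    Fv.assign(m + 1, NEG);
    int* Hr = H.data();
    int* Fr = Fv.data();
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      const int* srow = &S[(size_t)a[i - 1] * A];
      int diag = 0;  // H[i-1][j-1]
      int e = NEG;   // E[i][j-1] running
      int hj = 0;    // H[i][j-1] running
      for (int j = 1; j <= m; ++j) {
        int fv = Fr[j] - ge;
        int fo = Hr[j] - goe;  // H[i-1][j]
        fv = fo > fv ? fo : fv;
        Fr[j] = fv;
        int eo = hj - goe;
        e -= ge;
        e = eo > e ? eo : e;
        int h = diag + srow[bp[j - 1]];
        h = e > h ? e : h;
        h = fv > h ? fv : h;
        h = h < 0 ? 0 : h;
        diag = Hr[j];
        Hr[j] = h;
        hj = h;
        best = h > best ? h : best;
      }
    }
    out[p] = best;
  }
  return out;
}

// Full local alignment with traceback; deterministic tie-breaking
// (diagonal > gap-in-query > gap-in-subject). Integer scores throughout.
// [[Rcpp::export(name = ".sw_align_pair")]]
List sw_align_pair(IntegerVector av, IntegerVector bv, IntegerMatrix submat,
                   double gap_open, double gap_extend) {
  const int n = av.size(), m = bv.size();
  const int A = submat.nrow();
  std::vector<int> S((size_t)A * A);
  for (int x = 0; x < A; ++x)
    for (int y = 0; y < A; ++y) S[(size_t)x * A + y] = submat(x, y);
  const int go = (int)gap_open, ge = (int)gap_extend;
  const int goe = go + ge;
  const int NEG = INT_MIN / 4;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);
  int best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int* srow = &S[(size_t)av[i - 1] * A];
    size_t idx = (size_t)i * (m + 1);
    size_t up = idx - (m + 1);
    int diag = H[up];  // H[i-1][j-1] as j advances
    for (int j = 1; j <= m; ++j) {
      ++idx; ++up;
      int e = std::max(H[idx - 1] - goe, E[idx - 1] - ge);
      int f = std::max(H[up] - goe, F[up] - ge);
      int h = diag + srow[bv[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[up];
      E[idx] = e;
      F[idx] = f;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj;
  int n_ident = 0, n_mismatch = 0, align_len = 0, gap_opens = 0;
  int state = 0;  // 0 = H, 1 = E (gap in query a), 2 = F (gap in subject b)
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    size_t up = idx - (m + 1), left = idx - 1, dg = up - 1;
    if (state == 0) {
      if (H[idx] <= 0) break;  // local alignment starts here
      int dscore = H[dg] + S[(size_t)av[i - 1] * A + bv[j - 1]];
      if (H[idx] == dscore) {
        ++align_len;
        if (av[i - 1] == bv[j - 1]) ++n_ident; else ++n_mismatch;
        --i; --j;
      } else if (H[idx] == E[idx]) {
        state = 1;
      } else if (H[idx] == F[idx]) {
        state = 2;
      } else {
        stop("traceback failure");
      }
    } else if (state == 1) {  // gap in a: consume a column of b
      ++align_len;
      if (E[idx] == H[left] - goe) {
        ++gap_opens;
        state = 0;
      }
      --j;
    } else {  // gap in b: consume a column of a
      ++align_len;
      if (F[idx] == H[up] - goe) {
        ++gap_opens;
        state = 0;
      }
      --i;
    }
  }
  return List::create(
      _["score"] = best, _["q_start"] = i + 1, _["q_end"] = bi,
      _["s_start"] = j + 1, _["s_end"] = bj, _["n_ident"] = n_ident,
      _["n_mismatch"] = n_mismatch, _["align_len"] = align_len,
      _["gap_opens"] = gap_opens);
}

// Global (Needleman-Wunsch) profile-profile alignment with affine gaps,
// terminal gaps penalized. Profiles are residue-count matrices
// (alphabet x columns); nrow_a/b are the number of sequences per profile.
// Column score = sum over residue pairs of count_a * count_b * S / (na * nb);
// pairs involving a gap contribute 0. Returns 1-based source-column paths
// (0 = gap) for both profiles.
// [[Rcpp::export(name = ".nw_profile_align")]]
List nw_profile_align(NumericMatrix profA, NumericMatrix profB,
                      IntegerMatrix submat, double nrow_a, double nrow_b,
                      double gap_open, double gap_extend) {
  const int A = submat.nrow();
  if (profA.nrow() != A || profB.nrow() != A)
    stop("profile alphabet does not match the substitution matrix");
  const int La = profA.ncol(), Lb = profB.ncol();
  const double goe = gap_open + gap_extend;
  const double NEG = -1e30;
  std::vector< std::vector< std::pair<int, double> > > sa(La), sb(Lb);
  for (int c = 0; c < La; ++c)
    for (int x = 0; x < A; ++x)
      if (profA(x, c) > 0) sa[c].push_back(std::make_pair(x, profA(x, c)));
  for (int c = 0; c < Lb; ++c)
    for (int x = 0; x < A; ++x)
      if (profB(x, c) > 0) sb[c].push_back(std::make_pair(x, profB(x, c)));
  const double denom = nrow_a * nrow_b;
  std::vector<double> colsc((size_t)La * Lb, 0.0);
  for (int i = 0; i < La; ++i) {
    for (int j = 0; j < Lb; ++j) {
      double s = 0.0;
      for (size_t u = 0; u < sa[i].size(); ++u)
        for (size_t v = 0; v < sb[j].size(); ++v)
          s += sa[i][u].second * sb[j][v].second *
               submat(sa[i][u].first, sb[j][v].first);
      colsc[(size_t)i * Lb + j] = s / denom;
    }
  }
  std::vector<double> H((size_t)(La + 1) * (Lb + 1), NEG);
  std::vector<double> E((size_t)(La + 1) * (Lb + 1), NEG);
  std::vector<double> F((size_t)(La + 1) * (Lb + 1), NEG);
  H[0] = 0.0;
  for (int j = 1; j <= Lb; ++j) {
    E[j] = -(goe + (j - 1) * gap_extend);
    H[j] = E[j];
  }
  for (int i = 1; i <= La; ++i) {
    size_t idx0 = (size_t)i * (Lb + 1);
    F[idx0] = -(goe + (i - 1) * gap_extend);
    H[idx0] = F[idx0];
  }
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      size_t idx = (size_t)i * (Lb + 1) + j;
      size_t up = idx - (Lb + 1), left = idx - 1, dg = up - 1;
      double e = std::max(H[left] - goe, E[left] - gap_extend);
      double f = std::max(H[up] - goe, F[up] - gap_extend);
      double h = H[dg] + colsc[(size_t)(i - 1) * Lb + (j - 1)];
      if (e > h) h = e;
      if (f > h) h = f;
      E[idx] = e; F[idx] = f; H[idx] = h;
    }
  }
  std::vector<int> pa, pb;
  int i = La, j = Lb, state = 0;
  const double eps = 1e-9;
  if (La > 0 && Lb > 0) {
    size_t idx = (size_t)La * (Lb + 1) + Lb;
    double h = H[idx];
    double dscore = H[idx - (Lb + 1) - 1] + colsc[(size_t)(La - 1) * Lb + (Lb - 1)];
    if (std::abs(h - dscore) < eps) state = 0;
    else if (std::abs(h - E[idx]) < eps) state = 1;
    else state = 2;
  }
  while (i > 0 || j > 0) {
    if (i == 0) { pa.push_back(0); pb.push_back(j); --j; continue; }
    if (j == 0) { pa.push_back(i); pb.push_back(0); --i; continue; }
    size_t idx = (size_t)i * (Lb + 1) + j;
    size_t up = idx - (Lb + 1), left = idx - 1, dg = up - 1;
    if (state == 0) {
      double dscore = H[dg] + colsc[(size_t)(i - 1) * Lb + (j - 1)];
      if (std::abs(H[idx] - dscore) < eps) {
        pa.push_back(i); pb.push_back(j); --i; --j;
      } else if (std::abs(H[idx] - E[idx]) < eps) {
        state = 1;
      } else if (std::abs(H[idx] - F[idx]) < eps) {
        state = 2;
      } else stop("profile traceback failure");
    } else if (state == 1) {  // gap in A: consume B column
      pa.push_back(0); pb.push_back(j);
      if (std::abs(E[idx] - (H[left] - goe)) < eps) state = 0;
      --j;
    } else {  // gap in B: consume A column
      pa.push_back(i); pb.push_back(0);
      if (std::abs(F[idx] - (H[up] - goe)) < eps) state = 0;
      --i;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["path_a"] = wrap(pa), _["path_b"] = wrap(pb),
                      _["score"] = H[(size_t)La * (Lb + 1) + Lb]);
}
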