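// Per-voxel restricted CCA solver.
//
// For each voxel, maximizes the canonical correlation between a common
// temporal basis (covariance Cxx, n x n, n <= 2) and the voxel's spatially
// filtered data (covariances Cyy m x m, Cxy n x m, m <= 6), subject to
// nonnegative spatial weights and a nonnegative first temporal weight.
// Solved exactly by enumerating active-constraint faces; each face is an
// unconstrained CCA on the reduced basis. The per-face eigenproblems are
// tiny (<= 2 temporal dimensions), so everything is hand-rolled on stack
// arrays: rho^2 solves det(A - lambda Cxx) = 0 with
// A = Cxy_S Cyy_S^-1 Cyx_S, and gamma = Cyy_S^-1 Cyx_S beta.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int MAXM = 6;

// Solve S z = b for an s x s symmetric system by Gaussian elimination with
// partial pivoting (in-place copies; s <= MAXM). Returns false if singular.
static bool solve_small(int s, const double* S, const double* b, int nrhs,
                        double* z) {
  double a[MAXM * MAXM];
  double r[MAXM * 2];
  for (int i = 0; i < s * s; ++i) a[i] = S[i];
  for (int i = 0; i < s * nrhs; ++i) r[i] = b[i];
  for (int c = 0; c < s; ++c) {
    int piv = c;
    double mx = std::fabs(a[c * s + c]);
    for (int i = c + 1; i < s; ++i) {
      double v = std::fabs(a[c * s + i]);
      if (v > mx) { mx = v; piv = i; }
    }
    if (mx < 1e-300) return false;
    if (piv != c) {
      for (int j = 0; j < s; ++j) std::swap(a[j * s + c], a[j * s + piv]);
      for (int j = 0; j < nrhs; ++j) std::swap(r[j * s + c], r[j * s + piv]);
    }
    double d = a[c * s + c];
    for (int i = c + 1; i < s; ++i) {
      double f = a[c * s + i] / d;
      if (f == 0.0) continue;
      for (int j = c; j < s; ++j) a[j * s + i] -= f * a[j * s + c];
      for (int j = 0; j < nrhs; ++j) r[j * s + i] -= f * r[j * s + c];
    }
  }
  for (int j = 0; j < nrhs; ++j) {
    for (int i = s - 1; i >= 0; --i) {
      double acc = r[j * s + i];
      for (int k = i + 1; k < s; ++k) acc -= a[k * s + i] * z[j * s + k];
      z[j * s + i] = acc / a[i * s + i];
    }
  }
  return true;
}

struct Cand {
  double rho2;
  double beta[2];
  double gsub[MAXM];
};

// Canonical pairs for one face: nb in {1,2} temporal dims with covariance
// B (nb x nb), s spatial dims with covariance S (s x s), cross C (nb x s,
// column-major nb fast). Fills up to nb candidates.
static int face_candidates(int nb, const double* B, int s, const double* S,
                           const double* C, Cand* out) {
  // Z = S^-1 C' (s x nb)
  double Ct[MAXM * 2];
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < s; ++j) Ct[i * s + j] = C[j * nb + i];
  }
  double Z[MAXM * 2];
  if (!solve_small(s, S, Ct, nb, Z)) return 0;
  // A = C Z (nb x nb)
  double A[4];
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < nb; ++j) {
      double acc = 0;
      for (int k = 0; k < s; ++k) acc += C[k * nb + i] * Z[j * s + k];
      A[j * nb + i] = acc;
    }
  }
  int ncand = 0;
  double lam[2];
  double bvec[2][2];
  if (nb == 1) {
    if (B[0] <= 0) return 0;
    lam[0] = A[0] / B[0];
    bvec[0][0] = 1.0;
    bvec[0][1] = 0.0;
    ncand = 1;
  } else {
    // det(A - lambda B) = 0
    double b11 = B[0], b21 = B[1], b12 = B[2], b22 = B[3];
    double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3];
    double qa = b11 * b22 - b12 * b21;
    double qb = -(a11 * b22 + a22 * b11 - a12 * b21 - a21 * b12);
    double qc = a11 * a22 - a12 * a21;
    if (std::fabs(qa) < 1e-300) return 0;
    double disc = qb * qb - 4 * qa * qc;
    if (disc < 0) disc = 0;
    double sq = std::sqrt(disc);
    lam[0] = (-qb + sq) / (2 * qa);
    lam[1] = (-qb - sq) / (2 * qa);
    for (int e = 0; e < 2; ++e) {
      double m11 = a11 - lam[e] * b11, m12 = a12 - lam[e] * b12;
      double m21 = a21 - lam[e] * b21, m22 = a22 - lam[e] * b22;
      // null vector of [[m11,m12],[m21,m22]]: pick the larger row
      double v0, v1;
      if (m11 * m11 + m12 * m12 >= m21 * m21 + m22 * m22) {
        v0 = -m12; v1 = m11;
      } else {
        v0 = -m22; v1 = m21;
      }
      double nrm = std::sqrt(v0 * v0 + v1 * v1);
      if (nrm < 1e-300) { v0 = 1; v1 = 0; }
      else { v0 /= nrm; v1 /= nrm; }
      bvec[e][0] = v0;
      bvec[e][1] = v1;
    }
    ncand = 2;
  }
  for (int e = 0; e < ncand; ++e) {
    Cand& cd = out[e];
    cd.rho2 = lam[e] < 0 ? 0 : (lam[e] > 1 ? 1 : lam[e]);
    // normalize beta in the B metric
    double b0 = bvec[e][0], b1 = (nb == 2) ? bvec[e][1] : 0.0;
    double q;
    if (nb == 1) q = b0 * B[0] * b0;
    else q = b0 * (B[0] * b0 + B[2] * b1) + b1 * (B[1] * b0 + B[3] * b1);
    if (q <= 0) { cd.rho2 = -1; continue; }
    double sc = 1.0 / std::sqrt(q);
    cd.beta[0] = b0 * sc;
    cd.beta[1] = b1 * sc;
    // gamma_sub = Z beta (unnormalized)
    for (int k = 0; k < s; ++k) {
      double acc = Z[0 * s + k] * cd.beta[0];
      if (nb == 2) acc += Z[1 * s + k] * cd.beta[1];
      cd.gsub[k] = acc;
    }
  }
  return ncand;
}

// [[Rcpp::export]]
arma::mat rcca_solve_cpp(const arma::mat& Cxx_in, const arma::mat& Cxy_flat,
                         const arma::mat& Cyy_flat, bool gamma_nonneg,
                         bool beta1_nonneg, double ridge_rel) {
  const int n = Cxx_in.n_rows;
  const int nv = Cxy_flat.n_cols;
  const int m = Cxy_flat.n_rows / n;
  if (n > 2) Rcpp::stop("temporal basis dimension must be <= 2");
  if (m > MAXM) Rcpp::stop("spatial basis dimension must be <= %d", MAXM);

  // ridged Cxx (common to all voxels), plus the beta1 = 0 reduced version
  double Bfull[4], Bred[1];
  {
    mat Cxx = Cxx_in;
    Cxx.diag() += ridge_rel * trace(Cxx) / n;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) Bfull[j * n + i] = Cxx(i, j);
    if (n == 2) Bred[0] = Cxx(1, 1);
  }
  const int n_gfaces = gamma_nonneg ? (1 << m) - 1 : 1;
  const bool use_bred = beta1_nonneg && n == 2;

  mat out(1 + n + m, nv, fill::zeros);
  Cand cands[2];

  for (int v = 0; v < nv; ++v) {
    const double* cxy = Cxy_flat.colptr(v);  // n x m column-major
    const double* cyy = Cyy_flat.colptr(v);  // m x m
    double trC = 0;
    for (int i = 0; i < m; ++i) trC += cyy[i * m + i];
    double ridge = ridge_rel * trC / m;

    double best = -1.0;
    double best_b[2] = {0, 0};
    double best_g[MAXM] = {0, 0, 0, 0, 0, 0};

    for (int face = 1; face <= n_gfaces; ++face) {
      int bits = gamma_nonneg ? face : (1 << m) - 1;
      int idx[MAXM];
      int s = 0;
      for (int j = 0; j < m; ++j) {
        if (bits & (1 << j)) idx[s++] = j;
      }
      // sub-covariances
      double S[MAXM * MAXM], C[MAXM * 2], Cr[MAXM];
      for (int j = 0; j < s; ++j) {
        for (int i = 0; i < s; ++i) S[j * s + i] = cyy[idx[j] * m + idx[i]];
        S[j * s + j] += ridge;
        for (int i = 0; i < n; ++i) C[j * n + i] = cxy[idx[j] * n + i];
        if (use_bred) Cr[j] = cxy[idx[j] * n + 1];
      }
      for (int bface = 0; bface < (use_bred ? 2 : 1); ++bface) {
        int nc;
        if (bface == 0) {
          nc = face_candidates(n, Bfull, s, S, C, cands);
        } else {
          nc = face_candidates(1, Bred, s, S, Cr, cands);
        }
        for (int e = 0; e < nc; ++e) {
          Cand& cd = cands[e];
          if (cd.rho2 <= best) continue;
          // normalize gamma in the S metric and orient corr positive
          double q = 0;
          for (int i = 0; i < s; ++i) {
            double acc = 0;
            for (int k = 0; k < s; ++k) acc += S[k * s + i] * cd.gsub[k];
            q += cd.gsub[i] * acc;
          }
          if (q <= 0) continue;
          double sc = 1.0 / std::sqrt(q);
          double g[MAXM];
          double corr = 0;
          for (int i = 0; i < s; ++i) {
            g[i] = cd.gsub[i] * sc;
            double ci = C[i * n + 0] * ((bface == 0) ? cd.beta[0] : 0.0);
            if (bface == 0 && n == 2) ci += C[i * n + 1] * cd.beta[1];
            if (bface == 1) ci = Cr[i] * cd.beta[0];
            corr += ci * g[i];
          }
          double b0 = (bface == 0) ? cd.beta[0] : 0.0;
          double b1 = (bface == 0) ? ((n == 2) ? cd.beta[1] : 0.0) : cd.beta[0];
          // orientations with positive correlation: (b,g) if corr>=0 else
          // the two mixed flips
          double gmax = 0, bmax = std::max(std::fabs(b0), std::fabs(b1));
          for (int i = 0; i < s; ++i) gmax = std::max(gmax, std::fabs(g[i]));
          double tg = 1e-8 * std::max(gmax, 1e-300);
          double tb = 1e-8 * std::max(bmax, 1e-300);
          bool found = false;
          double fb0 = 0, fb1 = 0, fg[MAXM];
          for (int o = 0; o < 2 && !found; ++o) {
            double sb = (corr >= 0) ? (o == 0 ? 1 : -1) : (o == 0 ? -1 : 1);
            double sg = (o == 0 ? 1 : -1);
            bool ok = true;
            if (beta1_nonneg && sb * b0 < -tb) ok = false;
            if (ok && gamma_nonneg) {
              for (int i = 0; i < s; ++i) {
                if (sg * g[i] < -tg) { ok = false; break; }
              }
            }
            if (ok) {
              found = true;
              fb0 = sb * b0;
              fb1 = sb * b1;
              for (int i = 0; i < s; ++i) fg[i] = sg * g[i];
            }
          }
          if (!found) continue;
          best = cd.rho2;
          best_b[0] = fb0;
          best_b[1] = fb1;
          for (int i = 0; i < m; ++i) best_g[i] = 0;
          for (int i = 0; i < s; ++i) best_g[idx[i]] = fg[i];
        }
      }
    }
    if (best < 0) best = 0;
    out(0, v) = std::sqrt(best);
    for (int i = 0; i < n; ++i) out(1 + i, v) = best_b[i];
    for (int i = 0; i < m; ++i) out(1 + n + i, v) = best_g[i];
  }
  return out;
}
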