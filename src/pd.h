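#ifndef IPDPOP_PD_H
#define IPDPOP_PD_H

// Stationary-score machinery for memory-one strategy pairs: the
// Press-Dyson determinant with a lazy power-iteration fallback for
// (near-)degenerate chains.
//
// Conventions: moves 0 = C, 1 = D; outcomes indexed (CC, CD, DC, DD) =
// (0, 1, 2, 3) from the focal player's perspective. Swapping perspective
// exchanges CD and DC.

#include <cmath>
#include <cstring>

namespace ipdpop_pd {

static const int SWAP[4] = {0, 2, 1, 3};

inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// noise-adjusted cooperation probability
inline double eff1(double p, double eps) { return (1.0 - 2.0 * eps) * p + eps; }

inline void eff4(const double p[4], double eps, double out[4]) {
  for (int i = 0; i < 4; ++i) out[i] = eff1(p[i], eps);
}

// 4x4 determinant, Gaussian elimination with partial pivoting
inline double det4(double M[4][4]) {
  double det = 1.0;
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    double best = std::fabs(M[c][c]);
    for (int r = c + 1; r < 4; ++r) {
      double v = std::fabs(M[r][c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return 0.0;
    if (piv != c) {
      for (int k = 0; k < 4; ++k) { double t = M[c][k]; M[c][k] = M[piv][k]; M[piv][k] = t; }
      det = -det;
    }
    det *= M[c][c];
    for (int r = c + 1; r < 4; ++r) {
      double f = M[r][c] / M[c][c];
      for (int k = c; k < 4; ++k) M[r][k] -= f * M[c][k];
    }
  }
  return det;
}

// D(p, q, f) exactly as the Press-Dyson construction prints it
inline double pd_det(const double p[4], const double q[4], const double f[4]) {
  double M[4][4] = {
    {-1.0 + p[0] * q[0], -1.0 + p[0], -1.0 + q[0], f[0]},
    {p[1] * q[2],        -1.0 + p[1], q[2],        f[1]},
    {p[2] * q[1],        p[2],        -1.0 + q[1], f[2]},
    {p[3] * q[3],        p[3],        q[3],        f[3]}};
  return det4(M);
}

// one-round transition matrix on focal-perspective outcomes
inline void transition(const double p[4], const double q[4], double T[4][4]) {
  for (int i = 0; i < 4; ++i) {
    double pc = p[i], qc = q[SWAP[i]];
    T[i][0] = pc * qc;
    T[i][1] = pc * (1.0 - qc);
    T[i][2] = (1.0 - pc) * qc;
    T[i][3] = (1.0 - pc) * (1.0 - qc);
  }
}

// lazy power iteration s <- (s + sT)/2; init: 0..3 = delta at that outcome,
// -1 = uniform. The lazy step removes periodicity without changing the
// stationary distribution.
inline void power_stationary(const double p[4], const double q[4], double s[4],
                             int init = -1, int max_iter = 10000, double tol = 1e-13) {
  double T[4][4];
  transition(p, q, T);
  if (init < 0) { for (int i = 0; i < 4; ++i) s[i] = 0.25; }
  else { for (int i = 0; i < 4; ++i) s[i] = (i == init) ? 1.0 : 0.0; }
  for (int it = 0; it < max_iter; ++it) {
    double ns[4] = {0, 0, 0, 0};
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) ns[j] += s[i] * T[i][j];
    double diff = 0.0, tot = 0.0;
    for (int j = 0; j < 4; ++j) {
      ns[j] = 0.5 * (ns[j] + s[j]);
      diff += std::fabs(ns[j] - s[j]);
      tot += ns[j];
    }
    for (int j = 0; j < 4; ++j) s[j] = ns[j] / tot;
    if (diff < tol) break;
  }
}

// stationary mean of f for focal p against q (no noise adjustment here)
inline double pd_score(const double p[4], const double q[4], const double f[4],
                       int degenerate_init = -1) {
  static const double ONES[4] = {1.0, 1.0, 1.0, 1.0};
  double den = pd_det(p, q, ONES);
  if (std::fabs(den) >= 1e-12) return pd_det(p, q, f) / den;
  double s[4];
  power_stationary(p, q, s, degenerate_init);
  return s[0] * f[0] + s[1] * f[1] + s[2] * f[2] + s[3] * f[3];
}

}  // namespace ipdpop_pd

#endif
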