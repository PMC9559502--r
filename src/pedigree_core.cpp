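#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Inbreeding coefficients for a topologically ordered pedigree.
// sire/dam are 1-based positional indices, 0 = unknown.
//
// Uses the T-row identity a_ii = sum_j t_ij^2 d_j, where t is animal i's
// gene-flow row and d_j the Mendelian sampling variance of ancestor j
// (Meuwissen & Luo style).  F_i = a_ii - 1.
// [[Rcpp::export]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n), t(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], dd = dam[i];
    // Mendelian sampling variance given parental inbreeding
    if (s > 0 && dd > 0)
      d[i] = 0.5 - 0.25 * (F[s - 1] + F[dd - 1]);
    else if (s > 0)
      d[i] = 0.75 - 0.25 * F[s - 1];
    else if (dd > 0)
      d[i] = 0.75 - 0.25 * F[dd - 1];
    else
      d[i] = 1.0;

    if (s == 0 || dd == 0) { F[i] = 0.0; continue; }

    // accumulate t over ancestors of i (parents precede offspring)
    t[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      const double tj = t[j];
      if (tj == 0.0) continue;
      if (sire[j] > 0) t[sire[j] - 1] += 0.5 * tj;
      if (dam[j] > 0)  t[dam[j] - 1]  += 0.5 * tj;
      aii += tj * tj * d[j];
      t[j] = 0.0; // reset as we go
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Takahashi/Erisman-Tinney selected inversion (Davis-style scatter).
//
// Inputs: the unit lower-triangular factor L and diagonal d of an LDL'
// factorization C = L D L' (CSC slots Lp/Li/Lx, rows sorted, diagonal
// first in each column), plus the full symmetric pattern P = L + L'
// (CSC slots Pp/Pi, rows sorted).  Returns the entries of C^{-1} on P.
//
// For column j (processed last to first) the upper-triangle Takahashi
// relation  Z_ij = (i==j)/d_j - sum_{k>i} L_ki Z_kj  is evaluated for
// i = j down the column pattern, with the already-known lower entries
// (i > j, symmetric copies from earlier columns) scattered into a dense
// work vector so every lookup is O(1).  The Cholesky pattern is closed
// under the elimination tree, so every Z_kj the recurrence touches lies
// on P.
// [[Rcpp::export]]
NumericVector takahashi_selinv(IntegerVector Lp, IntegerVector Li,
                               NumericVector Lx, NumericVector d,
                               IntegerVector Pp, IntegerVector Pi) {
  const int n = Lp.size() - 1;
  NumericVector Zx(Pi.size());
  std::vector<double> w(n, 0.0);

  // slot of (r, c) in P, binary search (used once per computed entry)
  auto pslot = [&](int r, int c) -> int {
    const int *base = &Pi[0];
    const int *it = std::lower_bound(base + Pp[c], base + Pp[c + 1], r);
    return int(it - base);
  };

  for (int j = n - 1; j >= 0; --j) {
    const int q0 = Pp[j], q1 = Pp[j + 1];
    // scatter known lower entries (i > j) of column j
    for (int q = q1 - 1; q >= q0 && Pi[q] > j; --q) w[Pi[q]] = Zx[q];
    // upper entries i = j, then descending through the column pattern
    int qd = q1 - 1;
    while (qd >= q0 && Pi[qd] > j) --qd;   // now Pi[qd] == j (diagonal)
    for (int q = qd; q >= q0; --q) {
      const int i = Pi[q];
      double acc = (i == j) ? 1.0 / d[i] : 0.0;
      for (int r = Lp[i] + 1; r < Lp[i + 1]; ++r)
        acc -= Lx[r] * w[Li[r]];
      w[i] = acc;
      Zx[q] = acc;
      if (i < j) Zx[pslot(j, i)] = acc;    // symmetric copy
    }
    for (int q = q0; q < q1; ++q) w[Pi[q]] = 0.0;
  }
  return Zx;
}
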