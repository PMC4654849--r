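// Core lattice dynamics of the contact-inhibition Cellular Potts Model.
//
// Lattice convention: sigma is an (L+2) x (L+2) integer matrix; the
// outermost ring is an immutable frame of type "border" (sigma = -1),
// the interior L x L sites hold cell identifiers (> 0) or ECM (0).
// The chemoattractant field has the same shape; the frame ring is a
// fixed Dirichlet boundary at value 0.
//
// Randomness comes from R's global RNG stream (unif_rand), so results
// are reproducible with set.seed(). Draw order per copy attempt:
//   1. source site index, uniform over the L*L interior sites,
//      row-major (index = row * L + col, 0-based interior coordinates);
//   2. target, uniform over the 8 second-order neighbours, enumerated
//      in the fixed order below;
//   3. if the attempt is energetically unfavourable (dH > 0), one
//      uniform draw for the Boltzmann acceptance test.
// Attempts skipped because source and target share an identifier, or a
// border site is involved, consume only draws 1 and 2.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 8-neighbourhood enumeration order (row offset, col offset)
static const int NBR[8][2] = {
  {-1, -1}, {-1, 0}, {-1, 1},
  { 0, -1},          { 0, 1},
  { 1, -1}, { 1, 0}, { 1, 1}
};

// Adhesion energy between two lattice sites holding identifiers s1, s2
// (types: -1 border, 0 ECM, >0 cell). The Kronecker delta in the
// Hamiltonian removes same-identifier pairs; border-ECM contacts carry
// no energy.
static inline double j_pair(int s1, int s2,
                            double j_cc, double j_ce, double j_cb) {
  if (s1 == s2) return 0.0;
  const bool c1 = s1 > 0, c2 = s2 > 0;
  if (c1 && c2) return j_cc;
  if ((c1 && s2 == 0) || (c2 && s1 == 0)) return j_ce;
  if ((c1 && s2 == -1) || (c2 && s1 == -1)) return j_cb;
  return 0.0; // ECM-border
}

// Energy change of copying the identifier at (sr, sc) into (tr, tc)
// (0-based full-lattice coordinates). Adhesion over the target's 8
// neighbour pairs, volume penalty for the growing and the shrinking
// cell, and the contact-inhibited chemotaxis bias
// lambda_c * (c(source) - c(target)), active only at cell-ECM pairs.
static double delta_h_raw(const int* sg, const double* ch, const int* ar,
                          int nr, int sr, int sc, int tr, int tc,
                          double j_cc, double j_ce, double j_cb,
                          double lambda_A, double A_target,
                          double lambda_c) {
  const size_t si = (size_t)sc * nr + sr, ti = (size_t)tc * nr + tr;
  const int s = sg[si], t = sg[ti];
  double dH = 0.0;
  for (int k = 0; k < 8; ++k) {
    const int q = sg[(size_t)(tc + NBR[k][1]) * nr + (tr + NBR[k][0])];
    dH += j_pair(s, q, j_cc, j_ce, j_cb) - j_pair(t, q, j_cc, j_ce, j_cb);
  }
  if (s > 0) { // growing cell
    const double a = ar[s - 1];
    dH += lambda_A * ((A_target - (a + 1)) * (A_target - (a + 1)) -
                      (A_target - a) * (A_target - a));
  }
  if (t > 0) { // shrinking cell
    const double a = ar[t - 1];
    dH += lambda_A * ((A_target - (a - 1)) * (A_target - (a - 1)) -
                      (A_target - a) * (A_target - a));
  }
  if ((s > 0 && t == 0) || (s == 0 && t > 0))
    dH += lambda_c * (ch[si] - ch[ti]);
  return dH;
}

// [[Rcpp::export(.cpm_delta_h)]]
double cpm_delta_h(IntegerMatrix sigma, NumericMatrix chem,
                   IntegerVector areas,
                   int sr, int sc, int tr, int tc,
                   double j_cc, double j_ce, double j_cb,
                   double lambda_A, double A_target, double lambda_c) {
  // coordinates arrive 1-based (R convention), full lattice
  sr -= 1; sc -= 1; tr -= 1; tc -= 1;
  if (std::abs(sr - tr) > 1 || std::abs(sc - tc) > 1 ||
      (sr == tr && sc == tc))
    stop("target must be one of the source's 8 neighbours");
  if (sigma(sr, sc) == sigma(tr, tc))
    stop("source and target hold the same identifier");
  return delta_h_raw(INTEGER(sigma), REAL(chem), INTEGER(areas),
                     sigma.nrow(), sr, sc, tr, tc,
                     j_cc, j_ce, j_cb, lambda_A, A_target, lambda_c);
}

// One forward-Euler reaction-diffusion step on the interior, 5-point
// Laplacian, frame ring fixed. Secretion (no decay) at cell sites,
// decay at ECM sites.
static void pde_step_inplace(NumericMatrix& chem, const IntegerMatrix& sigma,
                             std::vector<double>& buf,
                             double alpha, double eps,
                             double d_dt_dx2, double dt) {
  const int nr = chem.nrow(), nc = chem.ncol();
  const double* ch = REAL(chem);
  const int* sg = INTEGER(sigma);
  const double a_dt = alpha * dt, e_dt = eps * dt;
  for (int c = 1; c < nc - 1; ++c) {
    const size_t col = (size_t)c * nr;
    for (int r = 1; r < nr - 1; ++r) {
      const size_t i = col + r;
      const double cc = ch[i];
      const double lap = ch[i - 1] + ch[i + 1] + ch[i - nr] + ch[i + nr] -
                         4.0 * cc;
      const int s = sg[i];
      double v = cc + d_dt_dx2 * lap;
      if (s > 0) v += a_dt;
      else if (s == 0) v -= e_dt * cc;
      buf[i] = v;
    }
  }
  double* chw = REAL(chem);
  for (int c = 1; c < nc - 1; ++c) {
    const size_t col = (size_t)c * nr;
    for (int r = 1; r < nr - 1; ++r) chw[col + r] = buf[col + r];
  }
}

// [[Rcpp::export(.cpm_pde_steps)]]
NumericMatrix cpm_pde_steps(NumericMatrix chem, IntegerMatrix sigma,
                            double alpha, double eps,
                            double d_dt_dx2, double dt, int n_steps) {
  NumericMatrix out = clone(chem);
  std::vector<double> buf((size_t)out.nrow() * out.ncol(), 0.0);
  for (int i = 0; i < n_steps; ++i)
    pde_step_inplace(out, sigma, buf, alpha, eps, d_dt_dx2, dt);
  return out;
}

// Advance the state by n_mcs Monte Carlo Steps. Each MCS performs L*L
// copy attempts followed by n_sub diffusion substeps of length dt.
// [[Rcpp::export(.cpm_advance)]]
List cpm_advance(IntegerMatrix sigma_in, NumericMatrix chem_in,
                 IntegerVector areas_in, int n_mcs,
                 double j_cc, double j_ce, double j_cb,
                 double lambda_A, double A_target, double lambda_c,
                 double mu, double alpha, double eps,
                 double d_dt_dx2, double dt, int n_sub) {
  IntegerMatrix sigma = clone(sigma_in);
  NumericMatrix chem = clone(chem_in);
  IntegerVector areas = clone(areas_in);
  const int L = sigma.nrow() - 2;
  const int nr = sigma.nrow();
  const long attempts = (long)L * L;
  std::vector<double> buf((size_t)chem.nrow() * chem.ncol(), 0.0);
  int* sg = INTEGER(sigma);
  int* ar = INTEGER(areas);

  for (int step = 0; step < n_mcs; ++step) {
    const double* ch = REAL(chem);
    for (long a = 0; a < attempts; ++a) {
      const long site = (long)(unif_rand() * attempts);
      const int sr = 1 + (int)(site / L);
      const int sc = 1 + (int)(site % L);
      const int k = (int)(unif_rand() * 8);
      const int tr = sr + NBR[k][0], tc = sc + NBR[k][1];
      const int s = sg[(size_t)sc * nr + sr];
      const int t = sg[(size_t)tc * nr + tr];
      if (s == t || s == -1 || t == -1) continue;
      const double dH = delta_h_raw(sg, ch, ar, nr, sr, sc, tr, tc,
                                    j_cc, j_ce, j_cb,
                                    lambda_A, A_target, lambda_c);
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / mu)) {
        sg[(size_t)tc * nr + tr] = s;
        if (s > 0) ar[s - 1] += 1;
        if (t > 0) ar[t - 1] -= 1;
      }
    }
    for (int i = 0; i < n_sub; ++i)
      pde_step_inplace(chem, sigma, buf, alpha, eps, d_dt_dx2, dt);
  }
  return List::create(_["sigma"] = sigma, _["chem"] = chem,
                      _["areas"] = areas);
}

// 4-connected component labelling of ECM sites (sigma == 0) on an
// interior label image (no frame). Returns a matrix of component labels
// (1, 2, ...) with 0 on non-ECM sites.
// [[Rcpp::export(.label_ecm)]]
IntegerMatrix label_ecm(IntegerMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<long> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (img(r0, c0) != 0 || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back((long)c0 * nr + r0);
      while (!stack.empty()) {
        const long p = stack.back(); stack.pop_back();
        const int r = (int)(p % nr), c = (int)(p / nr);
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (img(rr, cc) == 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back((long)cc * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

// Deterministic seed schedule for replicated batches: a splitmix64-style
// mix of (base seed, design point, replicate) truncated to the non-
// negative 32-bit range usable by set.seed().
// [[Rcpp::export(.hash_seed)]]
int hash_seed(int base, int point, int replicate) {
  uint64_t z = (uint64_t)(uint32_t)base;
  z = z * 0x9E3779B97F4A7C15ULL + (uint64_t)(uint32_t)point;
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z = z + (uint64_t)(uint32_t)replicate;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return (int)(z & 0x7FFFFFFFULL);
}
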