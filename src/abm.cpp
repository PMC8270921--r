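// Agent-based donation game with private continuous reputations.
//
// Norms are corner-based: each player carries 8 trilinear assessment
// corners (index 4u + 2X + v over donor reputation u, action X, recipient
// reputation v) and 4 bilinear behaviour corners (index 2u + v). All
// randomness comes from R's generator, so runs are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

static inline double trilinear(const double* a, double x, double y, double z) {
  const double xm = 1.0 - x, ym = 1.0 - y, zm = 1.0 - z;
  double v = a[0] * xm * ym * zm + a[1] * xm * ym * z +
             a[2] * xm * y * zm + a[3] * xm * y * z +
             a[4] * x * ym * zm + a[5] * x * ym * z +
             a[6] * x * y * zm + a[7] * x * y * z;
  return clamp01(v);
}

static inline double bilinear(const double* b, double x, double y) {
  const double xm = 1.0 - x, ym = 1.0 - y;
  double v = b[0] * xm * ym + b[1] * xm * y + b[2] * x * ym + b[3] * x * y;
  return clamp01(v);
}

// One full simulation. m0: N x N image matrix; acorn: N x 8 assessment
// corners (row = player, column-major binary order); bcorn: N x 4
// behaviour corners. force_donor / force_recipient (0-based, or -1) pin
// the interacting pair, which is useful for mean-field comparisons.
// traj_every > 0 records (round, mean deviation, running cooperation).
// [[Rcpp::export]]
List abm_run_cpp(NumericMatrix m0, NumericMatrix acorn, NumericMatrix bcorn,
                 int M, double q, double e, double gamma, double b, double c,
                 bool self_update, int traj_every,
                 int force_donor, int force_recipient) {
  const int N = m0.nrow();
  if (m0.ncol() != N) stop("image matrix must be square");
  if (N < 2) stop("N must be >= 2");
  if (acorn.nrow() != N || acorn.ncol() != 8) stop("acorn must be N x 8");
  if (bcorn.nrow() != N || bcorn.ncol() != 4) stop("bcorn must be N x 4");
  if (M < 1) stop("M must be >= 1");

  // copy norms into row-contiguous buffers
  std::vector<double> A(N * 8), B(N * 4);
  for (int i = 0; i < N; ++i) {
    for (int t = 0; t < 8; ++t) A[i * 8 + t] = acorn(i, t);
    for (int t = 0; t < 4; ++t) B[i * 4 + t] = bcorn(i, t);
  }
  NumericMatrix m = clone(m0);
  NumericVector payoff(N);
  double coop_sum = 0.0;

  int n_rec = (traj_every > 0) ? (M / traj_every) : 0;
  NumericVector traj_round(n_rec), traj_eps(n_rec), traj_coop(n_rec);
  int rec = 0;

  for (int round = 0; round < M; ++round) {
    int i = (force_donor >= 0) ? force_donor
                               : (int)(unif_rand() * N) % N;
    int j;
    if (force_recipient >= 0) {
      j = force_recipient;
    } else {
      j = (int)(unif_rand() * (N - 1)) % (N - 1);
      if (j >= i) ++j;
    }
    double a = bilinear(&B[i * 4], m(i, i), m(i, j));
    if (gamma > 0.0 && unif_rand() < gamma) a = unif_rand();
    payoff[j] += b * a;
    payoff[i] -= c * a;
    coop_sum += a;
    for (int k = 0; k < N; ++k) {
      if (k == i && !self_update) continue;
      if (unif_rand() < q) {
        double v = trilinear(&A[k * 8], m(k, i), a, m(k, j));
        if (e > 0.0 && unif_rand() < e) v = unif_rand();
        m(k, i) = v;
      }
    }
    if (traj_every > 0 && (round + 1) % traj_every == 0 && rec < n_rec) {
      double s = 0.0;
      for (int t = 0; t < N * N; ++t) s += 1.0 - m[t];
      traj_round[rec] = round + 1;
      traj_eps[rec] = s / (N * N);
      traj_coop[rec] = coop_sum / (round + 1);
      ++rec;
    }
  }

  // normalize by expected donor appearances M/N, so a fully cooperative
  // homogeneous error-free run averages to b - c per player
  for (int i = 0; i < N; ++i) payoff[i] *= (double)N / M;

  return List::create(
    _["payoff"] = payoff,
    _["coop_rate"] = coop_sum / M,
    _["final_matrix"] = m,
    _["traj_round"] = traj_round,
    _["traj_eps"] = traj_eps,
    _["traj_coop"] = traj_coop);
}
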