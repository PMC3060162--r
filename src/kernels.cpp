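#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Within-patch growth time for one seeding: unique positive root T of
//   sum_k m_k (exp(mu_k T) - 1) / Y_k = R.
// The left side is convex and strictly increasing in T, so Newton started
// from an upper bound (the fastest-depleting single-species bound) converges
// monotonically from above without bracketing.
static double growth_time_one(const int* m, int N, const double* mu,
                              const double* Y, double R) {
  double Tup = R_PosInf, mumax = 0.0;
  for (int k = 0; k < N; ++k) {
    if (m[k] > 0) {
      double t = log1p(R * Y[k] / m[k]) / mu[k];
      if (t < Tup) Tup = t;
      if (mu[k] > mumax) mumax = mu[k];
    }
  }
  if (!R_FINITE(Tup)) return 0.0;  // empty seeding
  // keep exponents representable; still an upper bound for the root
  if (mumax * Tup > 690.0) Tup = 690.0 / mumax;
  double T = Tup;
  for (int it = 0; it < 200; ++it) {
    double g = -R, dg = 0.0;
    for (int k = 0; k < N; ++k) {
      if (m[k] > 0) {
        double em1 = expm1(mu[k] * T);
        g += m[k] * em1 / Y[k];
        dg += m[k] * mu[k] * (em1 + 1.0) / Y[k];
      }
    }
    if (g < 1e-12) break;  // monotone from above: g >= 0 throughout
    T -= g / dg;
    if (T < 0.0) { T = 0.0; break; }
  }
  return T;
}

// [[Rcpp::export]]
NumericVector growth_time_batch_cpp(IntegerMatrix mm, NumericVector mu,
                                    NumericVector Y, double R) {
  int C = mm.nrow(), N = mm.ncol();
  NumericVector T(C);
  std::vector<int> row(N);
  for (int i = 0; i < C; ++i) {
    for (int k = 0; k < N; ++k) row[k] = mm(i, k);
    T[i] = growth_time_one(row.data(), N, mu.begin(), Y.begin(), R);
  }
  return T;
}

// All seedings m >= 0 with sum(m) <= max_total, grouped by total in
// ascending order (so the table for a smaller bound is a prefix of the table
// for a larger one), reverse-lexicographic within each total.
// [[Rcpp::export]]
IntegerMatrix enum_seedings_cpp(int N, int max_total) {
  double nrows_d = 0.0;
  for (int t = 0; t <= max_total; ++t) nrows_d += Rf_choose(N + t - 1.0, (double)t);
  if (nrows_d > 2e9) stop("seeding table too large to enumerate");
  int C = (int)std::lround(nrows_d);
  IntegerMatrix mm(C, N);
  int r = 0;
  // total = 0 row is all zeros (already initialised)
  ++r;
  std::vector<int> x(N);
  for (int tot = 1; tot <= max_total; ++tot) {
    std::fill(x.begin(), x.end(), 0);
    x[0] = tot;
    for (;;) {
      for (int k = 0; k < N; ++k) mm(r, k) = x[k];
      ++r;
      if (x[N - 1] == tot) break;
      int j = N - 2;
      while (j >= 0 && x[j] == 0) --j;
      --x[j];
      int s = tot;
      for (int k = 0; k <= j; ++k) s -= x[k];
      x[j + 1] = s;
      for (int k = j + 2; k < N; ++k) x[k] = 0;
    }
  }
  return mm;
}

// One expectation update n -> n' over the first `rows` seedings of the table:
//   n'_l = sum_i w_i F_{il},  w_i = prod_k Pois(m_ik; alpha n_k).
// Weights are accumulated in log space; `mass` is the enumerated probability.
static void step_once(const int* mm, const double* Fm, const double* lfac,
                      int Ctot, int rows, int N, const double* n, double alpha,
                      double* logw, double* n_next, double* mass) {
  double lam = 0.0;
  for (int k = 0; k < N; ++k) lam += alpha * n[k];
  for (int i = 0; i < rows; ++i) logw[i] = -lam - lfac[i];
  for (int k = 0; k < N; ++k) {
    const int* col = mm + (R_xlen_t)k * Ctot;
    double L = (n[k] > 0.0) ? std::log(alpha * n[k]) : R_NegInf;
    if (R_FINITE(L)) {
      for (int i = 0; i < rows; ++i)
        if (col[i] > 0) logw[i] += col[i] * L;
    } else {
      for (int i = 0; i < rows; ++i)
        if (col[i] > 0) logw[i] = R_NegInf;
    }
  }
  // compact to the configurations that carry weight: anything below
  // exp(-60) ~ 9e-27 contributes < rows * 9e-27 of probability, far below
  // any admissible tail bound
  static thread_local std::vector<int> live;
  live.clear();
  double msum = 0.0;
  for (int i = 0; i < rows; ++i) {
    if (logw[i] > -60.0) {
      double w = std::exp(logw[i]);
      logw[live.size()] = w;
      live.push_back(i);
      msum += w;
    }
  }
  int L2 = (int)live.size();
  for (int l = 0; l < N; ++l) {
    const double* fc = Fm + (R_xlen_t)l * Ctot;
    double acc = 0.0;
    for (int j = 0; j < L2; ++j) acc += logw[j] * fc[live[j]];
    n_next[l] = acc;
  }
  *mass = msum;
}

// [[Rcpp::export]]
List step_kernel_cpp(IntegerMatrix mm, NumericMatrix Fm, NumericVector lfac,
                     int rows, NumericVector n, double alpha) {
  int N = mm.ncol(), Ctot = mm.nrow();
  NumericVector out(N);
  std::vector<double> logw(rows);
  double mass = 0.0;
  step_once(mm.begin(), Fm.begin(), lfac.begin(), Ctot, rows, N, n.begin(),
            alpha, logw.data(), out.begin(), &mass);
  return List::create(_["n_next"] = out, _["mass"] = mass);
}

static int derive_M(double lam, double tail_eps) {
  int M = 0;
  while (R::ppois(M, lam, 0, 0) >= tail_eps) {
    ++M;
    if (M > 100000) stop("truncation bound did not converge");
  }
  return M;
}

// Iterated stochastic dynamics. Per cycle: pick the truncation total M for
// the current Poisson intensity (adaptive) or use the fixed paper-style M;
// run the exact truncated update, or Monte-Carlo estimate it when the
// enumeration would exceed `config_ceiling` configurations; then re-impose
// clamped species at nstar. Returns early (status 1) when the table must be
// extended by the caller.
// [[Rcpp::export]]
List sim_loop_cpp(IntegerMatrix mm, NumericMatrix Fm, NumericVector lfac,
                  IntegerVector cumrows, NumericVector n_init,
                  NumericVector nstar, LogicalVector clamp,
                  NumericVector alphas, double tail_eps, bool adaptive,
                  int static_M, double config_ceiling, int mc_samples,
                  NumericVector mu, NumericVector Y, double R) {
  int N = mm.ncol(), Ctot = mm.nrow();
  int maxM = cumrows.size() - 1;  // cumrows[M] = rows with total <= M
  int cycles = alphas.size();
  NumericMatrix abund(cycles, N);
  IntegerVector Mused(cycles, NA_INTEGER);
  NumericVector mass(cycles, NA_REAL);
  LogicalVector mc(cycles);
  std::vector<double> n(n_init.begin(), n_init.end());
  std::vector<double> n_next(N), logw(cumrows[maxM]);
  std::vector<int> msamp(N);
  int status = 0, stop_cycle = cycles, needM = -1;

  for (int t = 0; t < cycles; ++t) {
    double alpha = alphas[t];
    double lam = 0.0;
    for (int k = 0; k < N; ++k) lam += alpha * n[k];
    int M = adaptive ? derive_M(lam, tail_eps) : static_M;
    double nconf = Rf_choose(N + (double)M, (double)M);
    bool use_mc = adaptive && nconf > config_ceiling;
    if (!use_mc && M > maxM) { status = 1; stop_cycle = t; needM = M; break; }
    if (use_mc) {
      std::fill(n_next.begin(), n_next.end(), 0.0);
      for (int s = 0; s < mc_samples; ++s) {
        for (int k = 0; k < N; ++k)
          msamp[k] = (n[k] > 0.0) ? (int)R::rpois(alpha * n[k]) : 0;
        double T = growth_time_one(msamp.data(), N, mu.begin(), Y.begin(), R);
        for (int k = 0; k < N; ++k)
          if (msamp[k] > 0) n_next[k] += msamp[k] * std::exp(mu[k] * T);
      }
      for (int k = 0; k < N; ++k) n_next[k] /= mc_samples;
      mc[t] = true;
      Mused[t] = M;
    } else {
      double msum = 0.0;
      step_once(mm.begin(), Fm.begin(), lfac.begin(), Ctot, cumrows[M], N,
                n.data(), alpha, logw.data(), n_next.data(), &msum);
      Mused[t] = M;
      mass[t] = msum;
    }
    bool bad = false;
    for (int k = 0; k < N; ++k) {
      if (clamp[k]) n_next[k] = nstar[k];
      if (!R_FINITE(n_next[k])) bad = true;
      n[k] = n_next[k];
      abund(t, k) = n_next[k];
    }
    if (bad) { status = 2; stop_cycle = t; break; }
  }
  return List::create(_["abund"] = abund, _["M"] = Mused, _["mass"] = mass,
                      _["mc"] = mc, _["status"] = status,
                      _["stop_cycle"] = stop_cycle, _["need_M"] = needM,
                      _["n_current"] = NumericVector(n.begin(), n.end()));
}
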