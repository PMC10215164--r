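#include <Rcpp.h>
using namespace Rcpp;

// Shared payoff machinery for the n-player task-selection game.
// Mirrors the R-level benefit/cost functions exactly (tested against them);
// kept in C++ because the generation loops dominate run time.

struct EnvC {
  double b1, b2, beta, winv; // winv = 1/w, the sigmoid midpoint
  int n;
  double cx, cy, ex, ey;     // cost coefficients and exponents
  explicit EnvC(const List &env) {
    b1 = as<double>(env["b1"]);
    b2 = as<double>(env["b2"]);
    beta = as<double>(env["beta"]);
    winv = 1.0 / as<double>(env["w"]);
    n = as<int>(env["n"]);
    cx = as<double>(env["cost_coeff_x"]);
    cy = as<double>(env["cost_coeff_y"]);
    ex = as<double>(env["cost_exp_x"]);
    ey = as<double>(env["cost_exp_y"]);
  }
  double benefit(double X, double Y) const {
    double bx = b1 * X + b2 * X * X;
    double by = 1.0 / (1.0 + std::exp(-beta * (Y - winv)));
    return bx * by / n;
  }
  double cost(double x, double y) const {
    return cx * std::pow(x, ex) + cy * std::pow(y, ey);
  }
};

// Fisher-Yates shuffle of 0..N-1 using R's RNG, giving a uniformly random
// partition into K = N/n consecutive blocks.
static void shuffle_indices(std::vector<int> &idx) {
  const int N = (int)idx.size();
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = N - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// Payoffs for the whole population under a fresh random partition.
static void population_payoffs(const std::vector<double> &x,
                               const std::vector<double> &y,
                               const EnvC &env, std::vector<int> &idx,
                               std::vector<double> &pay) {
  const int N = (int)x.size(), n = env.n, K = N / n;
  shuffle_indices(idx);
  for (int k = 0; k < K; ++k) {
    double X = 0.0, Y = 0.0;
    for (int s = 0; s < n; ++s) {
      int j = idx[k * n + s];
      X += x[j];
      Y += y[j];
    }
    double B = env.benefit(X, Y);
    for (int s = 0; s < n; ++s) {
      int j = idx[k * n + s];
      pay[j] = B - env.cost(x[j], y[j]);
    }
  }
}

// Clip a mutated/realized trait pair to [0,1] per trait, then rescale onto
// the simplex boundary if x + y exceeds 1 (minimal repair, preserves
// direction).
static inline void repair(double &x, double &y) {
  if (x < 0.0) x = 0.0;
  if (x > 1.0) x = 1.0;
  if (y < 0.0) y = 0.0;
  if (y > 1.0) y = 1.0;
  double s = x + y;
  if (s > 1.0) {
    x /= s;
    y /= s;
  }
}

// [[Rcpp::export]]
List sim_social_cpp(List env, int N, int T, double zeta, double mu,
                    double sigma, double x0, double y0, int thin,
                    bool store_payoffs) {
  EnvC e(env);
  const int n = e.n;
  if (N % n != 0) stop("N must be divisible by the group size n");

  std::vector<double> x(N, x0), y(N, y0), pay(N), w(N);
  std::vector<double> xn(N), yn(N);
  std::vector<int> idx(N);

  // snapshot bookkeeping: the trajectory is p^0 .. p^{T-1}, each recorded
  // before its update; generations 0, thin, 2*thin, ... plus always T-1
  std::vector<int> snaps;
  for (int t = 0; t < T; t += thin) snaps.push_back(t);
  if (snaps.back() != T - 1) snaps.push_back(T - 1);
  const int S = (int)snaps.size();
  NumericMatrix XS(S, N), YS(S, N);
  NumericMatrix PS(store_payoffs ? S : 0, store_payoffs ? N : 0);
  IntegerVector gen(S);

  RNGScope scope;
  int si = 0;
  for (int t = 0; t < T; ++t) {
    // payoffs of generation t under a fresh random partition
    population_payoffs(x, y, e, idx, pay);

    if (si < S && snaps[si] == t) {
      for (int j = 0; j < N; ++j) {
        XS(si, j) = x[j];
        YS(si, j) = y[j];
      }
      if (store_payoffs)
        for (int j = 0; j < N; ++j) PS(si, j) = pay[j];
      gen[si] = t;
      ++si;
    }
    if (t == T - 1) break;

    // Boltzmann imitation weights over the whole population (max-shifted)
    double mx = pay[0];
    for (int j = 1; j < N; ++j) mx = std::max(mx, pay[j]);
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      w[j] = std::exp(zeta * (pay[j] - mx));
      tot += w[j];
    }
    // cumulative for inverse-cdf sampling
    double acc = 0.0;
    for (int j = 0; j < N; ++j) {
      acc += w[j] / tot;
      w[j] = acc;
    }
    w[N - 1] = 1.0;

    for (int j = 0; j < N; ++j) {
      double u = unif_rand();
      int l = (int)(std::lower_bound(w.begin(), w.end(), u) - w.begin());
      xn[j] = x[l];
      yn[j] = y[l];
    }

    // Gaussian exploration with probability mu per agent (both traits)
    for (int j = 0; j < N; ++j) {
      if (unif_rand() < mu) {
        xn[j] += sigma * norm_rand();
        yn[j] += sigma * norm_rand();
        repair(xn[j], yn[j]);
      }
    }
    x.swap(xn);
    y.swap(yn);
  }
  return List::create(_["x"] = XS, _["y"] = YS, _["generation"] = gen,
                      _["payoff"] = PS);
}

// [[Rcpp::export]]
List sim_cross_cpp(List env, int N, int T, double alpha, double h,
                   double jitter, int init_bin, NumericVector centers_x,
                   NumericVector centers_y, IntegerMatrix bin_lookup,
                   double pay_min, double pay_max, int thin,
                   bool store_payoffs) {
  EnvC e(env);
  const int n = e.n;
  if (N % n != 0) stop("N must be divisible by the group size n");
  const int m = centers_x.size();
  if (init_bin < 1 || init_bin > m) stop("initial bin out of range");
  const int mi = bin_lookup.nrow() - 1; // max index per axis
  const double range = pay_max - pay_min;
  if (range <= 0) stop("degenerate payoff bounds");

  // policies: N x m, row-major in a flat vector
  std::vector<double> pol((size_t)N * m, 0.0);
  for (int j = 0; j < N; ++j) pol[(size_t)j * m + (init_bin - 1)] = 1.0;

  std::vector<double> xr(N), yr(N), pay(N);
  std::vector<int> idx(N), real_bin(N), chosen(N);

  std::vector<int> snaps;
  for (int t = 0; t < T; t += thin) snaps.push_back(t);
  if (snaps.back() != T - 1) snaps.push_back(T - 1);
  const int S = (int)snaps.size();
  NumericMatrix XS(S, N), YS(S, N), EXS(S, N), EYS(S, N);
  NumericMatrix PS(store_payoffs ? S : 0, store_payoffs ? N : 0);
  IntegerMatrix CB(S, N), RB(S, N), MB(S, N);
  IntegerVector gen(S);

  RNGScope scope;
  int si = 0;
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      // sample an action bin from the agent's policy
      double u = unif_rand(), acc = 0.0;
      const double *pj = &pol[(size_t)j * m];
      int a = m - 1;
      for (int b = 0; b < m; ++b) {
        acc += pj[b];
        if (u <= acc) {
          a = b;
          break;
        }
      }
      chosen[j] = a;
      // Gaussian realization around the bin centre, clipped and repaired
      double xx = centers_x[a] + jitter * norm_rand();
      double yy = centers_y[a] + jitter * norm_rand();
      repair(xx, yy);
      xr[j] = xx;
      yr[j] = yy;
      // realized bin: half-open ranges; hypotenuse points fall to the
      // outermost bin still inside the simplex
      int ii = std::min((int)std::floor(xx / h), mi);
      int jj = std::min((int)std::floor(yy / h), mi);
      if (jj > mi - ii) jj = mi - ii;
      real_bin[j] = bin_lookup(ii, jj); // 1-based, 0 = invalid
      if (real_bin[j] == 0) stop("internal error: realized bin outside grid");
    }

    population_payoffs(xr, yr, e, idx, pay);

    // record the realized profile and the policy that generated it
    if (si < S && snaps[si] == t) {
      for (int j = 0; j < N; ++j) {
        XS(si, j) = xr[j];
        YS(si, j) = yr[j];
        CB(si, j) = chosen[j] + 1;
        RB(si, j) = real_bin[j];
        // policy-expected strategy (behavioural disposition) and modal bin
        const double *pj = &pol[(size_t)j * m];
        double ex_ = 0.0, ey_ = 0.0, best = -1.0;
        int argb = 0;
        for (int b = 0; b < m; ++b) {
          ex_ += pj[b] * centers_x[b];
          ey_ += pj[b] * centers_y[b];
          if (pj[b] > best) {
            best = pj[b];
            argb = b;
          }
        }
        EXS(si, j) = ex_;
        EYS(si, j) = ey_;
        MB(si, j) = argb + 1;
      }
      if (store_payoffs)
        for (int j = 0; j < N; ++j) PS(si, j) = pay[j];
      gen[si] = t;
      ++si;
    }

    // cross update on the realized bin with the normalised payoff
    for (int j = 0; j < N; ++j) {
      double ph = (pay[j] - pay_min) / range;
      if (ph < 0.0) ph = 0.0;
      if (ph > 1.0) ph = 1.0;
      double *pj = &pol[(size_t)j * m];
      double f = 1.0 - alpha * ph;
      for (int b = 0; b < m; ++b) pj[b] *= f;
      pj[real_bin[j] - 1] += alpha * ph;
    }
  }

  NumericMatrix polout(N, m);
  for (int j = 0; j < N; ++j)
    for (int b = 0; b < m; ++b) polout(j, b) = pol[(size_t)j * m + b];

  return List::create(_["x"] = XS, _["y"] = YS, _["expected_x"] = EXS,
                      _["expected_y"] = EYS, _["chosen_bin"] = CB,
                      _["realized_bin"] = RB, _["modal_bin"] = MB,
                      _["generation"] = gen, _["payoff"] = PS,
                      _["policy"] = polout);
}
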