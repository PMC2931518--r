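#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// sin(x)/x with series fallback near 0; x >= 0 in all callers.
static inline double sinc(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// Debye double sum I(q) = sum_i sum_j F_i(q) F_j(q) sinc(q r_ij), diagonal
// included, evaluated at every q in qvec. fmat is M x Q (per-scatterer
// factor at each q; constant factors are just repeated columns).
// [[Rcpp::export]]
NumericVector cpp_debye_curve(NumericMatrix coords, NumericMatrix fmat,
                              NumericVector qvec) {
  const int m = coords.nrow(), nq = qvec.size();
  if (fmat.nrow() != m) stop("factor matrix rows must match bead count");
  if (fmat.ncol() != nq) stop("factor matrix columns must match q grid");
  NumericVector out(nq);
  // diagonal terms
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += fmat(i, k) * fmat(i, k);
    out[k] = s;
  }
  // off-diagonal pairs, counted twice
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!std::isfinite(r)) stop("non-finite interparticle distance");
      for (int k = 0; k < nq; ++k) {
        out[k] += 2.0 * fmat(i, k) * fmat(j, k) * sinc(qvec[k] * r);
      }
    }
  }
  return out;
}

// Per-structure type-pair cross terms G_tu(q) = sum_{i in t, j in u}
// sinc(q r_ij) (ordered pairs, i=j diagonal included), so that
// I(q) = F' G(q) F for any form-factor vector F. Returned as an
// L*L x Q matrix, column-major in (t,u).
// [[Rcpp::export]]
NumericMatrix cpp_cross_terms(NumericMatrix coords, IntegerVector type,
                              int n_types, NumericVector qvec) {
  const int m = coords.nrow(), nq = qvec.size(), L = n_types;
  NumericMatrix out(L * L, nq);
  for (int i = 0; i < m; ++i) {
    int ti = type[i] - 1;
    // diagonal i = j
    for (int k = 0; k < nq; ++k) out(ti + L * ti, k) += 1.0;
    for (int j = i + 1; j < m; ++j) {
      int tj = type[j] - 1;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!std::isfinite(r)) stop("non-finite interparticle distance");
      for (int k = 0; k < nq; ++k) {
        double s = sinc(qvec[k] * r);
        out(ti + L * tj, k) += s;
        if (ti != tj) out(tj + L * ti, k) += s;
        else out(ti + L * ti, k) += s;  // both ordered pairs land in (t,t)
      }
    }
  }
  return out;
}

// Metropolis-Hastings chain for one q-bin. glist: per-structure L x L cross
// term matrices at this bin; iref, sig: reference intensity and sigma per
// structure. Truncated-uniform single-component proposal on
// [max(0, f - m), min(fmax, f + m)] with the window-width Hastings ratio.
// Uses R's RNG (unif_rand) so set.seed() in R fixes the stream.
// Returns kept samples (rows), acceptance rate, and final log-posterior.
// [[Rcpp::export]]
List cpp_mh_chain(List glist, NumericVector iref, NumericVector sig,
                  NumericVector init, double fmax, double halfw,
                  int iterations, int burnin, int thin) {
  const int n = glist.size(), L = init.size();
  if (iterations <= burnin) stop("iterations must exceed burnin");
  std::vector<NumericMatrix> G(n);
  for (int s = 0; s < n; ++s) {
    G[s] = as<NumericMatrix>(glist[s]);
    if (G[s].nrow() != L || G[s].ncol() != L) stop("cross-term matrix shape mismatch");
  }
  std::vector<double> f(init.begin(), init.end());
  // cached per-structure g = G f and intensity I' = f' G f
  std::vector<std::vector<double> > gv(n, std::vector<double>(L));
  std::vector<double> intens(n);
  const double LOG2PI = std::log(2.0 * M_PI);
  double lp = 0.0;
  for (int s = 0; s < n; ++s) {
    double ii = 0.0;
    for (int t = 0; t < L; ++t) {
      double acc = 0.0;
      for (int u = 0; u < L; ++u) acc += G[s](t, u) * f[u];
      gv[s][t] = acc;
      ii += f[t] * acc;
    }
    intens[s] = ii;
    double z = (iref[s] - ii) / sig[s];
    lp += -0.5 * z * z - std::log(sig[s]) - 0.5 * LOG2PI;
  }
  int n_keep = (iterations - burnin) / thin;
  NumericMatrix samples(n_keep, L);
  long accepted = 0;
  int kept = 0;
  GetRNGstate();
  for (int it = 1; it <= iterations; ++it) {
    int t = (int)std::floor(unif_rand() * L);
    if (t >= L) t = L - 1;
    double lo = std::max(0.0, f[t] - halfw), hi = std::min(fmax, f[t] + halfw);
    double w_fwd = hi - lo;
    double fnew = lo + unif_rand() * w_fwd;
    double lo2 = std::max(0.0, fnew - halfw), hi2 = std::min(fmax, fnew + halfw);
    double w_rev = hi2 - lo2;
    double d = fnew - f[t];
    // delta update of I'_s and log-posterior
    double lp_new = lp;
    for (int s = 0; s < n; ++s) {
      double inew = intens[s] + 2.0 * d * gv[s][t] + d * d * G[s](t, t);
      double z0 = (iref[s] - intens[s]) / sig[s];
      double z1 = (iref[s] - inew) / sig[s];
      lp_new += 0.5 * (z0 * z0 - z1 * z1);
    }
    double log_alpha = lp_new - lp + std::log(w_fwd) - std::log(w_rev);
    if (log_alpha >= 0.0 || std::log(unif_rand()) < log_alpha) {
      for (int s = 0; s < n; ++s) {
        intens[s] += 2.0 * d * gv[s][t] + d * d * G[s](t, t);
        for (int u = 0; u < L; ++u) gv[s][u] += d * G[s](u, t);
      }
      f[t] = fnew;
      lp = lp_new;
      ++accepted;
    }
    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int u = 0; u < L; ++u) samples(kept, u) = f[u];
      ++kept;
    }
  }
  PutRNGstate();
  return List::create(_["samples"] = samples,
                      _["acceptance_rate"] = (double)accepted / iterations,
                      _["final_log_posterior"] = lp);
}

// Index (1-based) of the sample minimizing the summed Euclidean distance to
// all other samples; ties broken by first index.
// [[Rcpp::export]]
int cpp_medoid(NumericMatrix x) {
  const int n = x.nrow(), L = x.ncol();
  if (n < 1) stop("empty sample set");
  std::vector<double> tot(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < L; ++k) {
        double d = x(i, k) - x(j, k);
        d2 += d * d;
      }
      double d = std::sqrt(d2);
      tot[i] += d;
      tot[j] += d;
    }
  }
  int best = 0;
  for (int i = 1; i < n; ++i) if (tot[i] < tot[best]) best = i;
  return best + 1;
}
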